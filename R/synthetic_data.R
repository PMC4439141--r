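#' Default residual correlation among the seven cortisol features
#'
#' A fixed positive-definite 7 x 7 correlation matrix used by the phenotype
#' simulator, echoing the qualitative structure of observed diurnal cortisol
#' features: waking level and AUC strongly correlated, bedtime level tied to
#' AUC and to shallower declines, the late and overall decline slopes the
#' most strongly coupled pair (0.77, the maximum off-diagonal), and the
#' awakening response moderately opposed to the early decline.
#'
#' @return Named 7 x 7 correlation matrix (unit diagonal, positive definite).
#' @export
default_residual_corr <- function() {
  f <- c("wakeup", "car", "edslope", "ldslope", "odslope", "bedtime", "auc")
  C <- diag(7)
  dimnames(C) <- list(f, f)
  set_r <- function(a, b, r) {
    C[a, b] <<- r; C[b, a] <<- r
  }
  set_r("wakeup", "car", -0.30); set_r("wakeup", "edslope", -0.35)
  set_r("wakeup", "ldslope", -0.15); set_r("wakeup", "odslope", -0.40)
  set_r("wakeup", "bedtime", 0.15); set_r("wakeup", "auc", 0.70)
  set_r("car", "edslope", -0.50); set_r("car", "ldslope", -0.10)
  set_r("car", "odslope", -0.15); set_r("car", "bedtime", 0.05)
  set_r("car", "auc", 0.15)
  set_r("edslope", "ldslope", 0.30); set_r("edslope", "odslope", 0.45)
  set_r("edslope", "bedtime", 0.10); set_r("edslope", "auc", -0.20)
  set_r("ldslope", "odslope", 0.77); set_r("ldslope", "bedtime", 0.35)
  set_r("ldslope", "auc", -0.10)
  set_r("odslope", "bedtime", 0.45); set_r("odslope", "auc", -0.15)
  set_r("bedtime", "auc", 0.50)
  C
}

#' Simulate an LD-structured common-variant dosage panel
#'
#' Gaussian-copula genotypes: a latent multivariate normal with first-order
#' autoregressive correlation `ld_rho` across adjacent SNPs is thresholded
#' per SNP at the quantiles implied by Hardy-Weinberg proportions for a MAF
#' drawn uniformly from `maf_range`, yielding calls in `{0, 1, 2}`; optional
#' Gaussian dosage noise is added and clipped to `[0, 2]` to mimic
#' imputation uncertainty. Positions are laid out on a toy chromosome so
#' that region extraction is exercisable.
#'
#' @param n_samples,n_snps Panel dimensions.
#' @param maf_range MAF interval within `(0, 0.5]`.
#' @param ld_rho Adjacent-SNP latent correlation in `[0, 1)`.
#' @param dosage_noise_sd Gaussian noise SD added to calls (0 keeps integer
#'   dosages).
#' @param seed Integer seed.
#' @param chrom Chromosome label for the SNP metadata.
#' @param positions Optional integer positions (length `n_snps`); default
#'   1 kb spacing starting at 1e6.
#' @param sample_ids Optional sample ids; default `S0001`, ...
#' @return A [dosage_panel()].
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               ld_rho = 0.5, dosage_noise_sd = 0, seed,
                               chrom = "1", positions = NULL,
                               sample_ids = NULL) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5, ld_rho >= 0, ld_rho < 1,
            dosage_noise_sd >= 0)
  set.seed(as.integer(seed))
  Z <- matrix(NA_real_, n_samples, n_snps)
  Z[, 1] <- rnorm(n_samples)
  if (n_snps > 1) {
    for (j in 2:n_snps) {
      Z[, j] <- ld_rho * Z[, j - 1] + sqrt(1 - ld_rho^2) * rnorm(n_samples)
    }
  }
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  q0 <- qnorm((1 - maf)^2)              # below: hom-ref
  q1 <- qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  calls <- sweep(Z, 2, q0, `>`) + sweep(Z, 2, q1, `>`)
  dosage <- calls
  if (dosage_noise_sd > 0) {
    dosage <- pmin(pmax(calls + rnorm(length(calls), sd = dosage_noise_sd), 0), 2)
  }
  if (is.null(positions)) positions <- 1e6 + 1000 * (seq_len(n_snps) - 1)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  snps <- data.frame(id = sprintf("snp_%s_%d", chrom, positions),
                     chrom = chrom, pos = as.integer(positions),
                     ref_allele = "A", alt_allele = "B",
                     stringsAsFactors = FALSE)
  dosage_panel(dosage, snps, sample_ids)
}

#' Simulate correlated phenotypes from genotypes and covariates
#'
#' Generative form of the per-feature linear model:
#' `Y = X A + G B + E`, with `E` rows drawn from a zero-mean multivariate
#' normal whose covariance is `residual_corr` (unit variances). The
#' ground-truth effect matrix is retained as an attribute for
#' parameter-recovery tests.
#'
#' @param panel A [dosage_panel()] supplying `G`.
#' @param X Covariate matrix or `NULL`.
#' @param K Number of features (default 7, named as the cortisol features).
#' @param residual_corr K x K positive-definite correlation matrix; default
#'   [default_residual_corr()] when `K = 7`, identity otherwise.
#' @param effect_matrix p x K genotype effect matrix `B` (default zero).
#' @param covariate_effects ncol(X) x K covariate effect matrix `A`
#'   (default zero).
#' @param seed Integer seed.
#' @return Phenotype matrix (samples x K) with attributes `effect_matrix`
#'   and `residual_corr`.
#' @export
simulate_phenotypes <- function(panel, X = NULL, K = 7, residual_corr = NULL,
                                effect_matrix = NULL, covariate_effects = NULL,
                                seed) {
  set.seed(as.integer(seed))
  G <- panel$dosage
  n <- nrow(G); p <- ncol(G)
  if (is.null(residual_corr)) {
    residual_corr <- if (K == 7) default_residual_corr() else diag(K)
  }
  stopifnot(nrow(residual_corr) == K, isSymmetric(unname(residual_corr)))
  if (is.null(effect_matrix)) effect_matrix <- matrix(0, p, K)
  if (nrow(effect_matrix) != p || ncol(effect_matrix) != K) {
    stop("effect_matrix must be p x K, aligned with the panel SNPs")
  }
  E <- matrix(rnorm(n * K), n, K) %*% chol(residual_corr)
  Y <- G %*% effect_matrix + E
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(covariate_effects)) covariate_effects <- matrix(0, ncol(X), K)
    if (nrow(covariate_effects) != ncol(X) || ncol(covariate_effects) != K) {
      stop("covariate_effects must be ncol(X) x K")
    }
    Y <- Y + X %*% covariate_effects
  }
  colnames(Y) <- if (K == 7) colnames(default_residual_corr()) else
    paste0("ph", seq_len(K))
  rownames(Y) <- panel$sample_ids
  attr(Y, "effect_matrix") <- effect_matrix
  attr(Y, "residual_corr") <- residual_corr
  Y
}

#' Simulate salivary diary records with a known diurnal curve
#'
#' Six samples per day at protocol-like times since waking (0, 0.5, 2, ~4,
#' ~10, ~16 h). The first three samples are anchored at their protocol
#' offsets (waking, +30 min peak, end of the early decline window) so the
#' early-decline slope is always estimable; the midday and evening samples
#' carry the collection-time jitter, where compliance is poorest in
#' practice. Each subject's noiseless log-cortisol curve is linear decline
#' from the waking level, except that the +30 min peak sample equals the
#' waking level plus the subject's awakening-response amplitude (so the CAR
#' parameter is exactly the CAR feature of the noiseless curve); Gaussian
#' noise of SD `noise_sd` is added on the log
#' scale and records carry raw nmol/L concentrations. The ground-truth
#' feature vector of each subject (features of the noiseless sampled curve)
#' is retained.
#'
#' @param n_subjects Number of subjects.
#' @param days Diary days per subject (default 3).
#' @param curve_params List with `wake_mean`, `wake_sd` (log nmol/L),
#'   `car_mean`, `car_sd` (log-units), `slope_mean`, `slope_sd`
#'   (log-units/hour).
#' @param noise_sd Log-scale measurement noise SD.
#' @param time_jitter Half-width (hours) of the uniform jitter on samples
#'   4-6.
#' @param seed Integer seed.
#' @param subject_ids Optional ids; default `D0001`, ...
#' @return List with `records` (long-format diary `data.frame`) and `truth`
#'   (subjects x 7 feature matrix).
#' @export
simulate_diary <- function(n_subjects, days = 3,
                           curve_params = list(wake_mean = 2.4, wake_sd = 0.5,
                                               car_mean = 0.38, car_sd = 0.25,
                                               slope_mean = -0.11,
                                               slope_sd = 0.04),
                           noise_sd = 0.2, time_jitter = 0.5, seed,
                           subject_ids = NULL) {
  set.seed(as.integer(seed))
  if (is.null(subject_ids)) subject_ids <- sprintf("D%04d", seq_len(n_subjects))
  base_t <- c(0, 0.5, 2, 4, 10, 16)
  wake <- rnorm(n_subjects, curve_params$wake_mean, curve_params$wake_sd)
  car <- rnorm(n_subjects, curve_params$car_mean, curve_params$car_sd)
  slope <- rnorm(n_subjects, curve_params$slope_mean, curve_params$slope_sd)
  rec <- list(); clean <- list()
  for (i in seq_len(n_subjects)) {
    for (d in seq_len(days)) {
      t <- base_t
      if (time_jitter > 0) {
        t[4:6] <- t[4:6] + runif(3, -time_jitter, time_jitter)
      }
      v <- wake[i] + slope[i] * t
      v[2] <- wake[i] + car[i]  # peak sample: wake level plus the CAR itself
      df <- data.frame(subject_id = subject_ids[i], day = d,
                       sample_index = 1:6, time_since_wake = t,
                       stringsAsFactors = FALSE)
      clean[[length(clean) + 1]] <- transform(df, log_cortisol = v)
      rec[[length(rec) + 1]] <- transform(
        df, cortisol = exp(v + rnorm(6, sd = noise_sd)))
    }
  }
  clean_df <- do.call(rbind, clean)
  truth <- t(vapply(subject_ids, function(s) compute_features(clean_df, s),
                    numeric(7)))
  list(records = do.call(rbind, rec), truth = truth)
}

#' Build the full synthetic study fixture
#'
#' A complete, seed-reproducible stand-in for a three-stratum candidate-gene
#' study: stratum sample sizes 181/254/515, six gene regions on a toy
#' chromosome with sizes spanning roughly 2 kb to 364 kb, LD-structured
#' common-variant panels, seven correlated phenotype features, covariates
#' (age, sex, five principal-component stand-ins) and salivary diaries.
#' By default a sparse genetic effect in one small gene is shared across a
#' subset of features; set `effect_size = 0` for a global null.
#'
#' All objects are synthetic; when `dir` is given the bundle is written as
#' plain TSV files plus a JSON manifest recording seeds and the ground-truth
#' effect matrix.
#'
#' @param seed Integer seed driving every stratum.
#' @param dir Optional output directory (created if needed).
#' @param effect_gene Index (1-6) of the causal gene.
#' @param effect_size Per-SNP effect on the dosage scale (default 0.25).
#' @param effect_features Features sharing the effect.
#' @param n_causal Number of causal SNPs inside the causal gene.
#' @return List with `panels`, `Y`, `X`, `diaries` (per-stratum lists),
#'   `regions`, `effect_matrix`, `strata` and, when written, `paths`.
#' @export
make_study_fixture <- function(seed, dir = NULL, effect_gene = 2,
                               effect_size = 0.25,
                               effect_features = c("car", "bedtime", "auc",
                                                   "odslope"),
                               n_causal = 3) {
  strata <- c(EUR = 181L, AFA = 254L, HIS = 515L)
  widths <- c(3650L, 2033L, 157582L, 363729L, 37810L, 7877L)
  n_snps_gene <- c(9L, 16L, 40L, 60L, 25L, 15L)
  gap <- 50000L
  starts <- integer(6); pos <- 1000000L
  for (k in 1:6) { starts[k] <- pos; pos <- pos + widths[k] + gap }
  regions <- gene_region(paste0("SGENE", 1:6), "1", starts,
                         starts + widths - 1L, flank_bp = 5000L)

  set.seed(as.integer(seed))
  positions <- sort(unlist(lapply(1:6, function(k) {
    sort(sample(seq(starts[k] - 5000L, starts[k] + widths[k] - 1L + 5000L),
                n_snps_gene[k]))
  })))
  p <- length(positions)
  B <- matrix(0, p, 7,
              dimnames = list(NULL, colnames(default_residual_corr())))
  gene_lo <- starts[effect_gene] - 5000L
  gene_hi <- starts[effect_gene] + widths[effect_gene] - 1L + 5000L
  in_gene <- which(positions >= gene_lo & positions <= gene_hi)
  causal <- in_gene[seq_len(min(n_causal, length(in_gene)))]
  B[causal, effect_features] <- effect_size

  # SNP-to-gene assignment for per-gene LD blocks (LD must not bridge the
  # inter-gene gaps, or a causal gene's signal leaks into its neighbour)
  block <- findInterval(positions, starts - 5000L)

  panels <- list(); Y <- list(); X <- list(); diaries <- list()
  for (s in names(strata)) {
    i <- match(s, names(strata))
    n <- strata[[s]]
    ids <- sprintf("%s_%03d", s, seq_len(n))
    per_gene <- lapply(1:6, function(k) {
      idx <- which(block == k)
      simulate_genotypes(n, length(idx), maf_range = c(0.08, 0.5),
                         ld_rho = 0.8, dosage_noise_sd = 0.05,
                         seed = seed + 17 * i + 1000 * k,
                         positions = positions[idx], sample_ids = ids)
    })
    panels[[s]] <- dosage_panel(
      do.call(cbind, lapply(per_gene, function(p) p$dosage)),
      do.call(rbind, lapply(per_gene, function(p)
        p$snps[setdiff(names(p$snps), "maf")])),
      ids)
    Xs <- cbind(age = rnorm(n, 65, 9), sex = rbinom(n, 1, 0.5),
                matrix(rnorm(n * 5, 0, 0.05), n, 5,
                       dimnames = list(NULL, paste0("PC", 1:5))))
    rownames(Xs) <- ids
    X[[s]] <- Xs
    A <- matrix(0, ncol(Xs), 7)
    A[1, ] <- -0.005   # mild age trend on every feature
    Y[[s]] <- simulate_phenotypes(panels[[s]], Xs, K = 7, effect_matrix = B,
                                  covariate_effects = A, seed = seed + 31 * i)
    diaries[[s]] <- simulate_diary(n, seed = seed + 53 * i, subject_ids = ids)
  }

  out <- list(panels = panels, Y = Y, X = X, diaries = diaries,
              regions = regions, effect_matrix = B, strata = strata)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(regions = file.path(dir, "regions.tsv"))
    write.table(regions, paths$regions, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (s in names(strata)) {
      paths[[paste0("dosage_", s)]] <- file.path(dir, sprintf("dosage_%s.tsv", s))
      paths[[paste0("snps_", s)]] <- file.path(dir, sprintf("snps_%s.tsv", s))
      write_dosage_tabular(panels[[s]], paths[[paste0("dosage_", s)]],
                           paths[[paste0("snps_", s)]])
      paths[[paste0("phenotypes_", s)]] <- file.path(dir, sprintf("phenotypes_%s.tsv", s))
      write.table(data.frame(sample_id = rownames(Y[[s]]), Y[[s]],
                             check.names = FALSE),
                  paths[[paste0("phenotypes_", s)]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paths[[paste0("covariates_", s)]] <- file.path(dir, sprintf("covariates_%s.tsv", s))
      write.table(data.frame(sample_id = rownames(X[[s]]), X[[s]],
                             check.names = FALSE),
                  paths[[paste0("covariates_", s)]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paths[[paste0("diary_", s)]] <- file.path(dir, sprintf("diary_%s.tsv", s))
      write.table(diaries[[s]]$records, paths[[paste0("diary_", s)]],
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    paths$manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(seed = seed, strata = as.list(strata),
           effect_gene = effect_gene, effect_size = effect_size,
           effect_features = effect_features,
           causal_rows = causal,
           effect_matrix = B),
      paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}
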