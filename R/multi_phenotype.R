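#' Fisher's combined probability test
#'
#' `T = -2 * sum(log(p_k))`, referred to chi-square with `2K` degrees of
#' freedom. The chi-square reference (the "naive" p) is exact only when the
#' inputs are independent uniform p-values; with correlated phenotypes it is
#' anti-conservative, which is what the permutation null of
#' [gene_multiphenotype_test()] corrects.
#'
#' @param p_values p-values in `(0, 1]` (at least one). Exact zeros are a
#'   domain error: permutation-derived inputs must be floored at
#'   `1/(n_perm + 1)` by the caller.
#' @return List with `statistic` and `naive_p`.
#' @examples
#' fisher_combine(c(0.5, 0.5))$statistic   # 2.772589
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) stop("need at least one p-value")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stat <- -2 * sum(log(p_values))
  list(statistic = stat,
       naive_p = pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE))
}

#' Gene-level multi-phenotype test with a permutation-calibrated Fisher null
#'
#' The gene-level joint test across all K phenotype features: per-feature
#' SKAT p-values for the gene are combined by Fisher's method, and the
#' combined statistic is calibrated against a genotype-permutation null.
#' Each permutation shuffles genotype rows only — phenotypes and covariates
#' stay fixed — which destroys genotype-phenotype association while
#' preserving the correlation structure among the features (and between
#' features and covariates). One shuffle per replicate is shared by all K
#' features; that sharing is what carries the cross-feature dependence of
#' the per-feature p-values into the null.
#'
#' The permutation p-value uses the add-one estimator
#' `(1 + #\{T_b >= T\}) / (n_perm + 1)`, ties counting as extreme.
#' Untestable features (e.g. constant) are excluded from both the observed
#' and permuted combinations, with K reduced accordingly.
#'
#' A caveat inherited from the design: genotype-covariate correlation is not
#' preserved by the shuffle, so calibration can degrade when genotypes are
#' correlated with covariates; a warning is emitted when any
#' `|cor(G_j, X_l)| > 0.2`.
#'
#' @param panel_region [dosage_panel()] restricted to one gene (non-empty).
#' @param Y Phenotype matrix (samples x K).
#' @param X Covariate matrix or `NULL`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @param weights,acc Passed to the per-feature SKAT tests.
#' @return List with `gene`, `per_feature_p` (named), `fisher_stat`,
#'   `naive_p`, `perm_p`, `n_perm`, `seed`, `K_used`.
#' @export
gene_multiphenotype_test <- function(panel_region, Y, X = NULL,
                                     n_perm = 10000, seed,
                                     weights = NULL, acc = 1e-9) {
  if (missing(seed)) stop("seed is required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  G <- panel_region$dosage
  if (ncol(G) == 0) stop("empty region")
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("ph", seq_len(ncol(Y)))
  Xm <- if (is.null(X)) NULL else as.matrix(X)
  cc <- stats::complete.cases(Y, G, Xm)
  Y <- Y[cc, , drop = FALSE]; G <- G[cc, , drop = FALSE]
  Xm <- if (is.null(Xm)) NULL else Xm[cc, , drop = FALSE]
  if (is.null(weights)) weights <- rep(1, ncol(G))

  usable <- apply(Y, 2, var) > 0
  if (!all(usable)) {
    message("excluding untestable features: ",
            paste(colnames(Y)[!usable], collapse = ", "))
    Y <- Y[, usable, drop = FALSE]
  }
  K <- ncol(Y)
  if (K < 1) stop("no testable features")
  if (!is.null(Xm) && ncol(Xm) > 0) {
    gx <- suppressWarnings(abs(cor(G, Xm)))
    if (any(gx > 0.2, na.rm = TRUE)) {
      warning("genotype-covariate correlation > 0.2: permutation null may be miscalibrated")
    }
  }

  null <- skat_null_model(Y, Xm)
  obs <- skat_pvals_for_G(null, G, weights, acc)
  fc <- fisher_combine(obs)
  t_obs <- fc$statistic

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  n <- nrow(G)
  n_extreme <- 0L
  for (b in seq_len(n_perm)) {
    pb <- skat_pvals_for_G(null, G[sample.int(n), , drop = FALSE], weights, acc)
    if (-2 * sum(log(pb)) >= t_obs) n_extreme <- n_extreme + 1L
  }
  list(gene = NA_character_, per_feature_p = obs, fisher_stat = t_obs,
       naive_p = fc$naive_p, perm_p = (1 + n_extreme) / (n_perm + 1),
       n_perm = as.integer(n_perm), seed = as.integer(seed), K_used = K)
}

# K SKAT p-values for one genotype matrix against a shared null model
skat_pvals_for_G <- function(null, G, weights, acc) {
  kern <- skat_kernel(null, G, weights)
  S <- crossprod(kern$Gres, null$R)            # p x K
  q <- colSums(S^2 * weights) / null$sigma2    # length K
  p <- mixture_chisq_tail(q, kern$lambdas, acc = acc)$p
  setNames(p, colnames(null$R))
}

#' Multi-phenotype scan over all gene regions
#'
#' One permutation-calibrated multi-phenotype test per region; the
#' region-level Bonferroni threshold `alpha / #regions` is attached.
#'
#' @inheritParams gene_multiphenotype_test
#' @param panel A MAF-filtered [dosage_panel()].
#' @param regions Region table as from [read_regions()].
#' @param alpha Family-wise error rate for the reported threshold.
#' @return `data.frame` with one row per gene: `gene`, `K_used`, per-feature
#'   p columns, `fisher_stat`, `naive_p`, `perm_p`; attribute `bonferroni`.
#' @export
multiphenotype_scan <- function(panel, regions, Y, X = NULL, n_perm = 10000,
                                seed, weights = NULL, acc = 1e-9,
                                alpha = 0.05) {
  if (missing(seed)) stop("seed is required")
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("ph", seq_len(ncol(Y)))
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    sub <- suppressWarnings(extract_region(panel, regions[i, ]))
    if (ncol(sub$dosage) == 0) {
      pf <- setNames(rep(NA_real_, ncol(Y)), paste0("p_", colnames(Y)))
      rows[[i]] <- data.frame(gene = regions$name[i], K_used = 0L, t(pf),
                              fisher_stat = NA_real_, naive_p = NA_real_,
                              perm_p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    r <- gene_multiphenotype_test(sub, Y, X, n_perm = n_perm,
                                  seed = seed + i, weights = weights, acc = acc)
    pf <- setNames(rep(NA_real_, ncol(Y)), paste0("p_", colnames(Y)))
    pf[paste0("p_", names(r$per_feature_p))] <- r$per_feature_p
    rows[[i]] <- data.frame(gene = regions$name[i], K_used = r$K_used, t(pf),
                            fisher_stat = r$fisher_stat, naive_p = r$naive_p,
                            perm_p = r$perm_p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, nrow(regions))
  out
}
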