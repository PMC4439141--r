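#' SKAT null model: residualize phenotypes on covariates once
#'
#' Precomputes the QR decomposition of `[1, X]`, the per-feature residuals
#' and the unbiased residual variances (denominator `n - rank`). Reused
#' across genes and across genotype permutations, where only the genotype
#' side changes.
#'
#' @param Y Phenotype matrix (samples x K) or a single column.
#' @param X Covariate matrix or `NULL`.
#' @return List with `qrX`, residual matrix `R`, `sigma2` vector, `n`,
#'   `rank`.
#' @export
skat_null_model <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Xt <- cbind(rep(1, n), if (is.null(X)) NULL else as.matrix(X))
  qx <- qr(Xt)
  if (qx$rank < ncol(Xt)) stop("[1, X] is rank deficient")
  if (any(apply(Y, 2, var) == 0)) stop("constant phenotype column")
  R <- qr.resid(qx, Y)
  sigma2 <- colSums(R^2) / (n - qx$rank)
  list(qrX = qx, R = R, sigma2 = sigma2, n = n, rank = qx$rank)
}

# mixture coefficients and residualized genotypes for one gene
skat_kernel <- function(null, G, weights) {
  Gres <- qr.resid(null$qrX, G)
  Gw <- sweep(Gres, 2, sqrt(weights), `*`)
  lam <- eigen(crossprod(Gw), symmetric = TRUE, only.values = TRUE)$values
  list(Gres = Gres, lambdas = lam[lam > 1e-10 * max(lam, 0)])
}

#' SKAT variance-component score test of a SNP set
#'
#' Tests whether a gene's SNPs are jointly associated with one phenotype
#' feature. Under the linear model `y = a0 + a'X + b'G + e` with the `b_j`
#' treated as random with variance `w_j * tau^2`, the score test of
#' `tau^2 = 0` is `Q = r' G W G' r / sigma^2` with `r` the null-model
#' residuals; its null distribution is the positively weighted mixture of
#' 1-df chi-squares whose coefficients are the nonzero eigenvalues of
#' `W^(1/2) G' P0 G W^(1/2)` (`P0` the residual projection off `[1, X]`).
#' Weights default to 1, the appropriate choice for common variants.
#'
#' @param y Phenotype column (non-constant).
#' @param G Samples x p dosage matrix for one gene (`p >= 1`).
#' @param X Covariate matrix or `NULL`.
#' @param weights Nonnegative SNP weights `w_j` (default all 1).
#' @param acc Absolute accuracy passed to [mixture_chisq_tail()].
#' @return List with `q_stat`, `eigenvalues` (nonincreasing),
#'   `p`, `method_used`, `n_used` and `testable`.
#' @export
skat_test <- function(y, G, X = NULL, weights = NULL, acc = 1e-9) {
  G <- as.matrix(G)
  if (is.null(weights)) weights <- rep(1, ncol(G))
  if (length(weights) != ncol(G) || any(weights < 0)) stop("bad weights")
  cc <- stats::complete.cases(y, G, if (is.null(X)) NULL else as.matrix(X))
  y <- y[cc]; G <- G[cc, , drop = FALSE]
  X <- if (is.null(X)) NULL else as.matrix(X)[cc, , drop = FALSE]
  null <- skat_null_model(y, X)
  kern <- skat_kernel(null, G, weights)
  if (length(kern$lambdas) == 0) {
    return(list(q_stat = NA_real_, eigenvalues = numeric(0), p = NA_real_,
                method_used = NA_character_, n_used = null$n, testable = FALSE))
  }
  q_stat <- sum(weights * drop(crossprod(G, null$R))^2) / null$sigma2[1]
  tail <- mixture_chisq_tail(q_stat, kern$lambdas, acc = acc)
  list(q_stat = q_stat, eigenvalues = tail$lambdas, p = tail$p,
       method_used = tail$method_used, n_used = null$n, testable = TRUE)
}

#' Gene x feature SKAT scan
#'
#' Runs [skat_test()] for every (region, feature) pair — the "42 tests"
#' design at 6 genes x 7 features — and reports the family-wise Bonferroni
#' threshold `alpha / (#regions x #features)`.
#'
#' @param panel A MAF-filtered [dosage_panel()].
#' @param regions Region table as from [read_regions()].
#' @param Y Phenotype matrix.
#' @param X Covariate matrix or `NULL`.
#' @param weights,acc Passed to [skat_test()].
#' @param alpha Family-wise error rate for the reported threshold.
#' @return `data.frame` with one row per (gene, feature): `gene`, `feature`,
#'   `n_snps`, `n_used`, `q_stat`, `p`, `method_used`, `testable`, plus
#'   attribute `bonferroni` (the threshold).
#' @export
gene_feature_scan <- function(panel, regions, Y, X = NULL, weights = NULL,
                              acc = 1e-9, alpha = 0.05) {
  Y <- as.matrix(Y)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    sub <- suppressWarnings(extract_region(panel, regions[i, ]))
    for (f in colnames(Y)) {
      if (ncol(sub$dosage) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = regions$name[i], feature = f, n_snps = 0L, n_used = NA_integer_,
          q_stat = NA_real_, p = NA_real_, method_used = NA_character_,
          testable = FALSE, stringsAsFactors = FALSE)
        next
      }
      w <- if (is.null(weights)) NULL else weights
      r <- skat_test(Y[, f], sub$dosage, X, weights = w, acc = acc)
      rows[[length(rows) + 1]] <- data.frame(
        gene = regions$name[i], feature = f, n_snps = ncol(sub$dosage),
        n_used = r$n_used, q_stat = r$q_stat, p = r$p,
        method_used = r$method_used, testable = r$testable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, nrow(regions) * ncol(Y))
  out
}
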