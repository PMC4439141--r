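#' Single-SNP Wald test of one phenotype feature
#'
#' Ordinary least squares of the feature on an intercept, the covariates and
#' the SNP dosage; the reported p-value is the two-sided Wald test of the
#' dosage coefficient against the t reference with residual degrees of
#' freedom. Complete-case analysis: rows missing the feature, the dosage or
#' any covariate are dropped.
#'
#' @param y Numeric phenotype column.
#' @param g Numeric dosage (or best-call) column.
#' @param X Covariate matrix (or `NULL`); an intercept is always added and
#'   `[1, X]` must be full rank.
#' @return List with `beta`, `se`, `wald_p`, `n_used` and `testable`. A SNP
#'   constant among complete cases is flagged untestable (`wald_p = NA`).
#' @export
single_snp_wald <- function(y, g, X = NULL) {
  X <- if (is.null(X)) matrix(numeric(0), length(y), 0) else as.matrix(X)
  cc <- stats::complete.cases(y, g, X)
  y <- y[cc]; g <- g[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  Xt <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xt)
  if (qx$rank < ncol(Xt)) {
    drop_cols <- colnames(Xt)[qx$pivot[seq(qx$rank + 1, ncol(Xt))]]
    stop("rank-deficient covariates: ", paste(drop_cols, collapse = ", "))
  }
  if (var(g) == 0) {
    return(list(beta = NA_real_, se = NA_real_, wald_p = NA_real_,
                n_used = n, testable = FALSE))
  }
  fit <- lm(y ~ 0 + Xt + g)
  sm <- summary(fit)$coefficients
  row <- sm["g", ]
  list(beta = unname(row[1]), se = unname(row[2]),
       wald_p = unname(2 * pt(abs(row[1] / row[2]),
                              df = n - ncol(Xt) - 1, lower.tail = FALSE)),
       n_used = n, testable = TRUE)
}

# intercept-only ordinal log-likelihood (ML = observed category proportions)
ordinal_null_loglik <- function(g_factor) {
  counts <- table(g_factor)
  counts <- counts[counts > 0]
  sum(counts * log(counts / sum(counts)))
}

#' MultiPhen joint test of one SNP against multiple phenotypes
#'
#' Reverse regression: the ordinal genotype (minor-allele count in
#' `{0, 1, 2}`) is modelled on the covariates plus the K phenotype columns
#' by proportional-odds logistic regression, and compared by likelihood
#' ratio against the covariates-only model; the LRT statistic is referred to
#' chi-square with K degrees of freedom. The model is used purely as a joint
#' association test: the fitted coefficients are not interpretable effect
#' estimates and are not reported.
#'
#' Genotype categories with fewer than 5 observations are merged toward the
#' adjacent category (2 into 1) before fitting; with only two categories the
#' model degrades to binary logistic regression with the same LRT
#' construction. Phenotype columns are standardized before entering the fit
#' (the LRT is invariant to affine phenotype scaling).
#'
#' @param g_calls Best-call genotype column, values in `{0, 1, 2}`.
#' @param Y Phenotype matrix (samples x K).
#' @param X Covariate matrix or `NULL`.
#' @return List with `lrt_stat`, `df` (= K), `p`, `converged`, `n_used` and
#'   `testable`.
#' @export
multiphen_test <- function(g_calls, Y, X = NULL) {
  Y <- as.matrix(Y)
  X <- if (is.null(X)) matrix(numeric(0), nrow(Y), 0) else as.matrix(X)
  cc <- stats::complete.cases(g_calls, Y, X)
  g <- g_calls[cc]; Y <- Y[cc, , drop = FALSE]; X <- X[cc, , drop = FALSE]
  if (!all(g %in% 0:2)) stop("g_calls must be best-call genotypes in {0,1,2}")
  K <- ncol(Y)
  # collinear phenotype columns cannot enter a K-df test
  if (qr(cbind(1, Y))$rank < K + 1) {
    stop("phenotype columns are collinear; K-df LRT undefined")
  }
  # sparse-category rule: <5 observations merged toward the adjacent category
  tab <- table(factor(g, levels = 0:2))
  if (tab["2"] > 0 && tab["2"] < 5) { g[g == 2] <- 1; tab <- table(factor(g, levels = 0:2)) }
  if (tab["0"] > 0 && tab["0"] < 5) g[g == 0] <- 1
  g <- factor(g)
  if (nlevels(g) < 2) {
    return(list(lrt_stat = NA_real_, df = K, p = NA_real_,
                converged = FALSE, n_used = length(g), testable = FALSE))
  }
  Ys <- scale(Y)
  colnames(Ys) <- paste0("ph", seq_len(K))
  dat <- data.frame(g = g, Ys, check.names = FALSE)
  if (ncol(X) > 0) {
    colnames(X) <- paste0("cv", seq_len(ncol(X)))
    dat <- cbind(dat, X)
  }
  full_rhs <- paste(c(colnames(Ys), if (ncol(X) > 0) colnames(X)), collapse = " + ")
  null_rhs <- if (ncol(X) > 0) paste(colnames(X), collapse = " + ") else NULL
  fit2 <- function(rhs) {
    f <- stats::as.formula(paste("g ~", if (is.null(rhs)) "1" else rhs))
    if (nlevels(g) == 2) {
      fit <- glm(f, family = stats::binomial(), data = dat)
      list(ll = as.numeric(logLik(fit)), ok = fit$converged)
    } else if (is.null(rhs)) {
      list(ll = ordinal_null_loglik(g), ok = TRUE)
    } else {
      fit <- MASS::polr(f, data = dat, method = "logistic",
                        control = list(maxit = 100, reltol = 1e-8))
      list(ll = as.numeric(logLik(fit)), ok = fit$convergence == 0)
    }
  }
  res <- tryCatch({
    full <- fit2(full_rhs)
    null <- fit2(null_rhs)
    stat <- 2 * (full$ll - null$ll)
    list(lrt_stat = max(stat, 0), df = K,
         p = pchisq(max(stat, 0), df = K, lower.tail = FALSE),
         converged = full$ok && null$ok, n_used = length(g), testable = TRUE)
  }, error = function(e) {
    message("multiphen fit failed: ", conditionMessage(e))
    list(lrt_stat = NA_real_, df = K, p = NA_real_, converged = FALSE,
         n_used = length(g), testable = FALSE)
  })
  if (!isTRUE(res$converged)) res$p <- if (res$testable) NA_real_ else res$p
  res
}

#' Run Method-1 and Method-2 scans over a panel
#'
#' @param panel A [dosage_panel()]; Method 2 converts it to best calls.
#' @param Y Phenotype matrix.
#' @param X Covariate matrix or `NULL`.
#' @return `single_snp_scan`: one row per SNP x feature with Wald results.
#'   `multiphen_scan`: one row per SNP with the K-df LRT.
#' @export
single_snp_scan <- function(panel, Y, X = NULL) {
  Y <- as.matrix(Y)
  out <- expand.grid(snp = panel$snps$id, feature = colnames(Y),
                     stringsAsFactors = FALSE)
  res <- mapply(function(s, f) {
    r <- single_snp_wald(Y[, f], panel$dosage[, s], X)
    c(r$beta, r$se, r$wald_p, r$n_used)
  }, out$snp, out$feature)
  out$beta <- res[1, ]; out$se <- res[2, ]
  out$wald_p <- res[3, ]; out$n_used <- as.integer(res[4, ])
  out
}

#' @rdname single_snp_scan
#' @export
multiphen_scan <- function(panel, Y, X = NULL) {
  calls <- if (inherits(panel, "best_call_panel")) panel else best_call(panel)
  rows <- lapply(calls$snps$id, function(s) {
    r <- multiphen_test(calls$dosage[, s], Y, X)
    data.frame(snp = s, lrt_stat = r$lrt_stat, df = r$df, p = r$p,
               converged = r$converged, n_used = r$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
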