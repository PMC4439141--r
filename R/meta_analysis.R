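#' @name meta_analysis
#' @title Cross-stratum p-value meta-analysis
#' @description
#' Per-stratum analyses (per SNP, per gene, or per gene-multi-phenotype
#' test) are combined across ethnic strata using only the stratum p-values
#' and sample sizes, under three combiners: the weighted Z-score (Stouffer)
#' test with weights `sqrt(n)`, Fisher's combined probability test, and a
#' Lancaster-style weighted Fisher test whose per-stratum degrees of freedom
#' are proportional to sample size and normalized to total `2S`, so that
#' equal sample sizes reduce it exactly to Fisher. Because SKAT and
#' Fisher-combined inputs carry no effect direction, the z-transform is
#' one-sided on the association-evidence scale; p-values exactly 1 are
#' nudged to `1 - 1e-16` before quantile transforms.
NULL

check_strata <- function(p, n) {
  if (length(p) < 1) stop("need at least one stratum")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  if (any(n < 1)) stop("stratum sizes must be >= 1")
  pmin(p, 1 - 1e-16)
}

#' Weighted Z-score (Stouffer) meta-analysis
#'
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))` with
#' `z_i = qnorm(1 - p_i)`; combined p is the upper normal tail at `Z`.
#'
#' @param p Per-stratum p-values in `(0, 1]`.
#' @param n Per-stratum sample sizes (weight basis).
#' @return List with `method`, `combined_p`, `weights`, `inputs`.
#' @export
meta_weighted_z <- function(p, n) {
  pp <- check_strata(p, n)
  w <- sqrt(n)
  z <- qnorm(pp, lower.tail = FALSE)
  Z <- sum(w * z) / sqrt(sum(w^2))
  list(method = "weighted_z", combined_p = pnorm(Z, lower.tail = FALSE),
       weights = w, inputs = data.frame(p = p, n = n))
}

#' Fisher's combined probability meta-analysis
#'
#' `-2 sum(log p_i)` against chi-square with `2S` degrees of freedom.
#'
#' @inheritParams meta_weighted_z
#' @return List as in [meta_weighted_z()] with `method = "fisher"`.
#' @export
meta_fisher <- function(p, n = rep(1, length(p))) {
  pp <- check_strata(p, n)
  fc <- fisher_combine(pp)
  list(method = "fisher", combined_p = fc$naive_p, statistic = fc$statistic,
       weights = rep(1, length(p)), inputs = data.frame(p = p, n = n))
}

#' Weighted Fisher (Lancaster) meta-analysis
#'
#' Each stratum contributes the upper-tail chi-square quantile of its
#' p-value with `df_i = 2 * S * n_i / sum(n)`; the summed statistic is
#' referred to chi-square with `sum(df_i) = 2S` degrees of freedom. Equal
#' sample sizes recover Fisher's test exactly.
#'
#' @inheritParams meta_weighted_z
#' @return List as in [meta_weighted_z()] with `method = "weighted_fisher"`.
#' @export
meta_weighted_fisher <- function(p, n) {
  pp <- check_strata(p, n)
  S <- length(pp)
  df_i <- 2 * S * n / sum(n)
  stat <- sum(qchisq(pp, df = df_i, lower.tail = FALSE))
  list(method = "weighted_fisher",
       combined_p = pchisq(stat, df = 2 * S, lower.tail = FALSE),
       statistic = stat, weights = df_i, inputs = data.frame(p = p, n = n))
}

#' Run all three meta-analysis combiners on a table of stratum results
#'
#' @param tab `data.frame` with columns `unit` (SNP/gene identifier),
#'   `stratum`, `p`, `n`.
#' @return `data.frame` with one row per unit and columns `meta_wz`,
#'   `meta_fisher`, `meta_wfisher` (untestable strata with `NA` p are
#'   dropped per unit; a unit with no usable stratum gets `NA`s).
#' @export
meta_all <- function(tab) {
  units <- unique(tab$unit)
  rows <- lapply(units, function(u) {
    sub <- tab[tab$unit == u & !is.na(tab$p), , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(unit = u, n_strata = 0L, meta_wz = NA_real_,
                        meta_fisher = NA_real_, meta_wfisher = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(unit = u, n_strata = nrow(sub),
               meta_wz = meta_weighted_z(sub$p, sub$n)$combined_p,
               meta_fisher = meta_fisher(sub$p, sub$n)$combined_p,
               meta_wfisher = meta_weighted_fisher(sub$p, sub$n)$combined_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
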