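#' @name cortisol_features
#' @title Diurnal cortisol curve features
#' @description
#' Salivary diary records (six samples per day over several days) are reduced
#' to seven features of the diurnal log-cortisol curve, computed per day and
#' then averaged across days:
#' \describe{
#'   \item{wakeup}{log concentration at the waking sample (sample 1, time 0).}
#'   \item{car}{cortisol awakening response: sample 2 (the +30 min peak by
#'     protocol) minus sample 1.}
#'   \item{edslope}{early decline: OLS slope of log value on hours since wake
#'     over samples with time in `[0.5, 2]`.}
#'   \item{ldslope}{late decline: OLS slope over time in `[2, 16]`.}
#'   \item{odslope}{overall decline: OLS slope over all samples from wake to
#'     bedtime, excluding the peak (sample 2).}
#'   \item{bedtime}{log concentration at the bedtime sample (sample 6).}
#'   \item{auc}{standardized area under the curve: trapezoidal integral of
#'     log value over `[0, 16]` h divided by the interval actually covered
#'     (interpolated at 16 h when sampling runs longer, truncated at the last
#'     sample when it runs shorter; no extrapolation).}
#' }
#' A day contributes a feature only when the samples the feature needs exist
#' (slopes need at least two points in their window); a subject's feature
#' requires at least one contributing day, otherwise it is `NA`.
NULL

feature_names <- c("wakeup", "car", "edslope", "ldslope", "odslope",
                   "bedtime", "auc")

#' Log-transform raw diary cortisol concentrations
#'
#' Replaces raw nmol/L concentrations by their natural logarithm. Records
#' with nonpositive concentration are rejected (count reported).
#'
#' @param records Long-format diary `data.frame` with columns `subject_id`,
#'   `day`, `sample_index` (1-6), `time_since_wake` (hours, sample 1 at 0)
#'   and `cortisol` (nmol/L).
#' @return The records with an added `log_cortisol` column.
#' @export
log_transform <- function(records) {
  bad <- !is.finite(records$cortisol) | records$cortisol <= 0
  if (any(bad)) {
    message(sprintf("rejecting %d records with nonpositive cortisol", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  records$log_cortisol <- log(records$cortisol)
  records
}

# one day's feature vector (log scale); NA where the day cannot contribute
day_features <- function(day_rec) {
  t <- day_rec$time_since_wake
  v <- day_rec$log_cortisol
  si <- day_rec$sample_index
  ols_slope <- function(keep) {
    if (sum(keep) < 2 || length(unique(t[keep])) < 2) return(NA_real_)
    x <- t[keep]; y <- v[keep]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  wake <- if (any(si == 1)) v[si == 1][1] else NA_real_
  peak <- if (any(si == 2)) v[si == 2][1] else NA_real_
  bed <- if (any(si == 6)) v[si == 6][1] else NA_real_
  auc <- {
    o <- order(t)
    tt <- t[o]; vv <- v[o]
    if (length(tt) < 2) NA_real_ else {
      if (max(tt) > 16) {  # interpolate at 16 h, truncate beyond
        vv16 <- stats::approx(tt, vv, xout = 16)$y
        keep <- tt < 16
        tt <- c(tt[keep], 16); vv <- c(vv[keep], vv16)
      }
      span <- max(tt) - min(tt)
      if (span <= 0) NA_real_ else
        sum(diff(tt) * (head(vv, -1) + vv[-1]) / 2) / span
    }
  }
  c(wakeup = wake,
    car = peak - wake,
    edslope = ols_slope(t >= 0.5 & t <= 2),
    ldslope = ols_slope(t >= 2 & t <= 16),
    odslope = ols_slope(si != 2),
    bedtime = bed,
    auc = auc)
}

#' Compute the seven diurnal features for one subject
#'
#' Features are computed per day from log-transformed records and averaged
#' across the days that can contribute them.
#'
#' @param records Diary records carrying `log_cortisol` (see
#'   [log_transform()]).
#' @param subject Subject id to extract.
#' @return Named numeric vector of the seven features (`NA` when no day
#'   contributes).
#' @export
compute_features <- function(records, subject) {
  if (is.null(records$log_cortisol)) {
    stop("records must be log-transformed first (see log_transform)")
  }
  rec <- records[records$subject_id == subject, , drop = FALSE]
  if (nrow(rec) == 0) return(setNames(rep(NA_real_, 7), feature_names))
  per_day <- vapply(split(rec, rec$day), day_features, numeric(7))
  setNames(rowMeans(per_day, na.rm = TRUE), feature_names)
}

#' Assemble per-subject feature vectors into a phenotype matrix
#'
#' @param records Log-transformed diary records for all subjects.
#' @param roster Sample ids defining row order; subjects absent from the
#'   diary get all-`NA` rows.
#' @return Numeric matrix (roster x 7 features) with a missingness summary
#'   reported via `message()`; constant feature columns trigger a warning.
#' @export
assemble_phenotypes <- function(records, roster) {
  if (anyDuplicated(roster)) stop("duplicate subject in roster")
  Y <- t(vapply(roster, function(s) compute_features(records, s), numeric(7)))
  rownames(Y) <- roster
  Y[!is.finite(Y)] <- NA
  miss <- colSums(is.na(Y))
  if (any(miss > 0)) {
    message("missing feature values per column: ",
            paste(sprintf("%s=%d", colnames(Y), miss), collapse = ", "))
  }
  const <- apply(Y, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) > 1 && var(col) == 0
  })
  if (any(const)) {
    warning("constant feature columns: ",
            paste(colnames(Y)[const], collapse = ", "))
  }
  Y
}
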