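#' Upper tail of a positively weighted mixture of 1-df chi-squares
#'
#' Computes `P(sum_j lambda_j * chisq_1 >= q)`, the null distribution of the
#' SKAT score statistic. The tail is obtained by numerical inversion of the
#' Laplace transform of the survival function on a fixed Talbot contour; when
#' the inversion's internal error estimate exceeds `acc` (or the result falls
#' outside `[0, 1]`), the four-moment (Liu-Tang-Zhang) chi-square
#' approximation is used instead and flagged.
#'
#' Mixture coefficients smaller than `1e-10 * max(lambdas)` are treated as
#' numerical zeros (rank deficiency from LD-collinear SNPs) and dropped.
#'
#' @param q Nonnegative quadratic-form value(s) at which to evaluate the tail.
#' @param lambdas Positive mixture coefficients (eigenvalues of the projected
#'   kernel matrix).
#' @param acc Requested absolute accuracy (default `1e-9`).
#' @return A list with `p` (tail probabilities in `(0, 1]`, same length as
#'   `q`), `method_used` (`"inversion"` or `"moment_match"`, per element) and
#'   `lambdas` (the coefficients actually used, nonincreasing).
#' @examples
#' mixture_chisq_tail(qchisq(0.95, 1), 1)$p           # 0.05
#' mixture_chisq_tail(3, c(1, 1))$p                   # exp(-1.5)
#' @export
mixture_chisq_tail <- function(q, lambdas, acc = 1e-9) {
  if (any(q < 0)) stop("q must be nonnegative")
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) == 0L || all(lambdas <= 0)) {
    stop("lambdas must contain at least one positive value")
  }
  lambdas <- lambdas[lambdas > 1e-10 * max(lambdas)]
  lambdas <- sort(lambdas, decreasing = TRUE)

  out <- cpp_mixture_tail(as.numeric(q), lambdas)
  p <- out$p
  method <- rep("inversion", length(p))
  bad <- !is.finite(p) | out$err > acc | p < -acc | p > 1 + acc
  if (any(bad)) {
    p[bad] <- liu_tail(q[bad], lambdas)
    method[bad] <- "moment_match"
  }
  p <- pmin(pmax(p, 1e-300), 1)
  list(p = p, method_used = method, lambdas = lambdas)
}

#' Four-moment chi-square approximation to the mixture tail
#'
#' Matches the first four cumulants of `sum_j lambda_j chisq_1` with a scaled
#' noncentral chi-square. Used as the fallback when transform inversion cannot
#' reach the requested accuracy.
#'
#' @inheritParams mixture_chisq_tail
#' @return Tail probabilities, same length as `q`.
#' @keywords internal
liu_tail <- function(q, lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- a^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2 * (l + 2 * delta))
  pchisq((q - mu_q) / sigma_q * sigma_x + mu_x, df = l, ncp = delta,
         lower.tail = FALSE)
}
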