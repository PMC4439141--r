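# Small in-code fixtures shared across test files.

# a tiny deterministic panel: 4 samples x 3 SNPs with metadata
tiny_panel <- function() {
  dos <- matrix(c(0, 1, 2, 1,
                  0, 0, 0, 0,
                  2, 2, 1, 1), nrow = 4,
                dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  snps <- data.frame(id = c("rs1", "rs2", "rs3"), chrom = c("5", "5", "7"),
                     pos = c(100L, 2000L, 100L),
                     ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  dosage_panel(dos, snps, paste0("s", 1:4))
}

# diary for one subject sampling an exactly linear log-cortisol curve a - b*t
linear_diary <- function(a, b, days = 1, subject = "subj1",
                         times = c(0, 0.5, 2, 4, 10, 16)) {
  do.call(rbind, lapply(seq_len(days), function(d) {
    data.frame(subject_id = subject, day = d, sample_index = seq_along(times),
               time_since_wake = times, cortisol = exp(a - b * times),
               stringsAsFactors = FALSE)
  }))
}

# Imhof-formula oracle for P(sum lambda_j chisq_1 >= q): direct numerical
# quadrature of the Gil-Pelaez inversion integral on [0, U]. The integrand is
# env(u) * sin(theta(u)) with theta'(u) -> -q, so integration by parts bounds
# the truncated tail by ~ 2 env(U) / q, and chunked adaptive quadrature
# (a couple of oscillation periods per chunk) handles [0, U]. Independent of
# the package's Talbot-contour path.
imhof_oracle <- function(q, lam, acc = 1e-8) {
  stopifnot(length(lam) >= 3, q > 0)
  p <- length(lam)
  env_bound <- function(u) (2 * u)^(-p / 2) * prod(lam)^(-0.5) / u
  U <- 10
  while (4 * env_bound(U) / q > acc / 2) U <- U * 1.5
  f <- function(u) {
    theta <- 0.5 * colSums(atan(2 * outer(lam, u))) - q * u
    rho <- exp(0.25 * colSums(log1p(4 * outer(lam^2, u^2))))
    sin(theta) / (u * rho)
  }
  width <- max(4 * pi / q, U / 2000)
  breaks <- unique(c(seq(0, U, by = width), U))
  val <- sum(vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(f, breaks[i], breaks[i + 1], rel.tol = 1e-9,
              abs.tol = acc / (2 * length(breaks)),
              subdivisions = 200L)$value
  }, numeric(1)))
  0.5 + val / pi
}
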