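test_that("Wald test recovers a simulated effect and its p is affine invariant", {
  set.seed(101)
  n <- 500
  pan <- simulate_genotypes(n, 1, ld_rho = 0, seed = 102)
  g <- pan$dosage[, 1]
  X <- cbind(age = rnorm(n, 65, 9))
  y <- 0.3 * g + 0.01 * X[, 1] + rnorm(n)
  r <- single_snp_wald(y, g, X)
  expect_true(abs(r$beta - 0.3) < 3 * r$se)
  expect_equal(r$n_used, n)
  # affine rescaling of y and g leaves the p-value unchanged
  r2 <- single_snp_wald(5 * y - 2, 0.5 * g + 1, X)
  expect_equal(r2$wald_p, r$wald_p, tolerance = 1e-9)
  expect_equal(r2$beta, 10 * r$beta, tolerance = 1e-9)
})

test_that("Wald type-I error rate sits in the binomial band under the null", {
  # scaled down: 1000 reps here (acceptance covers SKAT/MultiPhen/perm at scale)
  reps <- 1000; n <- 200
  pan <- simulate_genotypes(n, 1, ld_rho = 0, seed = 103)
  g <- pan$dosage[, 1]
  set.seed(104)
  hits <- sum(vapply(seq_len(reps), function(i) {
    single_snp_wald(rnorm(n), g)$wald_p < 0.05
  }, logical(1)))
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(hits / reps, band[1]); expect_lt(hits / reps, band[2])
})

test_that("constant genotype is untestable; rank-deficient covariates error", {
  y <- rnorm(20)
  r <- single_snp_wald(y, rep(1, 20))
  expect_false(r$testable); expect_true(is.na(r$wald_p))
  X <- cbind(a = 1:20, b = 2 * (1:20))
  expect_error(single_snp_wald(y, rnorm(20), X), "rank-deficient")
})

test_that("complete-case filtering drops rows missing y, g or X", {
  set.seed(105)
  y <- rnorm(50); g <- rbinom(50, 2, 0.3); X <- cbind(rnorm(50))
  y[1] <- NA; g[2] <- NA; X[3, 1] <- NA
  r <- single_snp_wald(y, g, X)
  expect_equal(r$n_used, 47)
})

test_that("multiphen LRT has df = K and a null type-I rate in the binomial band", {
  # 500 reps of K = 3 at n = 500 (where the asymptotic chi-square reference
  # of the LRT applies; it is mildly inflated at n = 300)
  reps <- 500; n <- 500; K <- 3
  pan <- simulate_genotypes(n, 1, ld_rho = 0, maf_range = c(0.2, 0.4), seed = 106)
  g <- best_call(pan)$dosage[, 1]
  set.seed(107)
  hits <- 0; dfs <- integer(0)
  for (i in seq_len(reps)) {
    Y <- matrix(rnorm(n * K), n, K)
    r <- multiphen_test(g, Y)
    dfs <- union(dfs, r$df)
    hits <- hits + (r$p < 0.05)
  }
  expect_equal(dfs, K)
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(hits / reps, band[1]); expect_lt(hits / reps, band[2])
})

test_that("multiphen detects a genotype-phenotype association", {
  set.seed(108)
  n <- 400
  pan <- simulate_genotypes(n, 1, ld_rho = 0, maf_range = c(0.3, 0.4), seed = 109)
  g <- best_call(pan)$dosage[, 1]
  Y <- cbind(0.4 * g + rnorm(n), 0.4 * g + rnorm(n), rnorm(n))
  r <- multiphen_test(g, Y)
  expect_lt(r$p, 1e-4)
  expect_true(r$converged)
})

test_that("collinear phenotype columns never produce a silent K-df test", {
  set.seed(110)
  g <- rbinom(100, 2, 0.3)
  y <- rnorm(100)
  expect_error(multiphen_test(g, cbind(y, y)), "collinear")
})

test_that("sparse genotype category is merged and two categories degrade to logistic", {
  set.seed(111)
  n <- 200
  g <- c(rep(0L, 150), rep(1L, 47), rep(2L, 3))  # 3 hom-alt: merged into het
  Y <- cbind(rnorm(n), rnorm(n))
  r <- multiphen_test(g, Y)                       # binary logistic path
  expect_true(r$testable)
  expect_equal(r$df, 2)
  # monomorphic after merging: untestable
  r2 <- multiphen_test(rep(0L, n), Y)
  expect_false(r2$testable)
})

test_that("multiphen with K = 1 tracks the forward association test (rank correlation)", {
  # run at full stated size: asymptotic equivalence needs n large
  reps <- 500; n <- 1000
  pan <- simulate_genotypes(n, 1, ld_rho = 0, maf_range = c(0.2, 0.4), seed = 112)
  g <- best_call(pan)$dosage[, 1]
  set.seed(113)
  p_mp <- p_wald <- numeric(reps)
  for (i in seq_len(reps)) {
    y <- rnorm(n)
    p_mp[i] <- multiphen_test(g, cbind(y))$p
    p_wald[i] <- single_snp_wald(y, g)$wald_p
  }
  expect_gt(cor(p_mp, p_wald, method = "spearman"), 0.95)
})

test_that("identical row permutation of g, Y, X leaves statistics unchanged", {
  set.seed(114)
  n <- 150
  pan <- simulate_genotypes(n, 1, ld_rho = 0, seed = 115)
  g <- best_call(pan)$dosage[, 1]
  Y <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(rnorm(n))
  perm <- sample(n)
  a <- multiphen_test(g, Y, X)
  b <- multiphen_test(g[perm], Y[perm, ], X[perm, , drop = FALSE])
  expect_equal(a$lrt_stat, b$lrt_stat, tolerance = 1e-6)
  aw <- single_snp_wald(Y[, 1], g, X)
  bw <- single_snp_wald(Y[perm, 1], g[perm], X[perm, , drop = FALSE])
  expect_equal(aw$wald_p, bw$wald_p, tolerance = 1e-9)
})

test_that("scan wrappers return one row per unit", {
  set.seed(116)
  pan <- simulate_genotypes(60, 3, ld_rho = 0.3, seed = 117)
  Y <- simulate_phenotypes(pan, K = 2, seed = 118)
  s1 <- single_snp_scan(pan, Y)
  expect_equal(nrow(s1), 6L)  # 3 SNPs x 2 features
  s2 <- multiphen_scan(pan, Y)
  expect_equal(nrow(s2), 3L)
  expect_true(all(s2$df == 2))
})
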