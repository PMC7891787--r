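# a small reproducible reference model used across blocks
ref_maxent <- function(T_ = 8, n_max = 3) {
  set.seed(7)
  h <- matrix(rnorm(3 * T_, -0.5, 0.5), 3)
  J <- matrix(0, 3, 3)
  J[upper.tri(J)] <- rnorm(3, 0, 0.15)
  J <- J + t(J); diag(J) <- rnorm(3, 0, 0.1)
  maxent_model(h, J, n_max)
}

test_that("log weights follow the energy function", {
  mod <- ref_maxent()
  st <- c(1L, 2L, 0L)
  manual <- sum(mod$h[, 2] * st) +
    mod$J[1, 1] * 1 + mod$J[2, 2] * 4 + mod$J[1, 2] * 2 -
    lfactorial(1) - lfactorial(2)
  expect_equal(log_weight(mod, st, 2), manual, tolerance = 1e-12)
  expect_equal(log_weight(mod, c(0L, 0L, 0L), 1), 0)   # empty sums, ln 0! = 0
  expect_error(log_weight(mod, c(4L, 0L, 0L), 1), "0..n_max")
})

test_that("with zero couplings the model is independent truncated Poisson", {
  lam <- 0.7; n_max <- 3
  mod0 <- maxent_model(matrix(log(lam), 2, 4), matrix(0, 2, 2), n_max)
  em <- exact_moments(mod0)
  k <- 0:n_max
  p <- dpois(k, lam) / ppois(n_max, lam)
  expect_equal(as.numeric(em$mean), rep(sum(k * p), 8), tolerance = 1e-12)
  expect_equal(as.numeric(em$second), rep(sum(k^2 * p), 8), tolerance = 1e-12)
  # cross moment of independent cells factorises
  expect_equal(em$cross_sum[1, 2], 4 * sum(k * p)^2, tolerance = 1e-12)
  ed <- exact_distribution(mod0)
  expect_equal(colSums(ed$prob), rep(1, 4), tolerance = 1e-12)
  expect_true(all(em$log_z > -Inf))
})

test_that("Gibbs sampling agrees with exact enumeration and is deterministic", {
  mod <- ref_maxent()
  em <- exact_moments(mod)
  smp <- gibbs_sample(mod, n_sweeps = 60, n_chains = 400, burn_in = 20, seed = 3)
  n_s <- smp$n_reps
  m_mean <- rowMeans(smp$counts, dims = 2L)
  # per-site Monte-Carlo standard error from the sample variance
  v <- apply(smp$counts, c(1, 2), var) / n_s
  expect_true(all(abs(m_mean - em$mean) < 3 * sqrt(v) + 0.02))
  # fixed seed: bit-identical
  smp2 <- gibbs_sample(mod, n_sweeps = 60, n_chains = 400, burn_in = 20, seed = 3)
  expect_identical(smp$counts, smp2$counts)
  # J = 0: chi-square goodness of fit against truncated Poisson
  lam <- 0.7
  mod0 <- maxent_model(matrix(log(lam), 1, 2), matrix(0, 1, 1), 3)
  s0 <- gibbs_sample(mod0, n_sweeps = 25, n_chains = 2000, burn_in = 24, seed = 5)
  obs <- table(factor(s0$counts[1, 1, ], levels = 0:3))
  p <- dpois(0:3, lam) / ppois(3, lam)
  expect_gt(chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("moment matching recovers an enumerable ground-truth model", {
  mod <- ref_maxent()
  em <- exact_moments(mod)
  tg <- moment_targets(em$mean, em$second, em$cross_sum)
  fit <- fit_maxent(tg, n_max = 3, max_iter = 8000, tol = 5e-5)
  expect_true(attr(fit, "converged"))
  emf <- exact_moments(fit)
  expect_lt(max(abs(emf$mean - em$mean)), 1e-3)
  expect_lt(max(abs(emf$cross_sum - em$cross_sum)) / mod$n_bins, 1e-3)
  expect_lt(max(abs(fit$J - mod$J)), 0.05)
  # zero noise-covariance targets drive the off-diagonal couplings to zero
  mu <- em$mean; sec <- em$second
  cross0 <- tcrossprod(mu)                      # sum_t mu_i(t) mu_j(t): independence
  tg0 <- moment_targets(mu, sec, cross0)
  fit0 <- fit_maxent(tg0, n_max = 3, max_iter = 8000, tol = 5e-5)
  off <- fit0$J[upper.tri(fit0$J)]
  expect_lt(max(abs(off)), 0.02)
})

test_that("population-rate distributions expose correlated transients", {
  # single cell: the population-rate law is the cell's pooled count law
  tn <- random_tensor(1, 10, 40, seed = 51)
  pr <- population_rate_distribution(tn)
  pooled <- table(factor(tn$counts, levels = 0:max(tn$counts)))
  expect_equal(pr$prob, as.numeric(pooled) / sum(pooled))
  expect_equal(sum(pr$prob), 1)
  # correlated population vs its shuffle: heavier tails at both extremes
  g <- generate_lattice(8, seed = 52)
  lam <- simulate_rate_profiles(8, 50, seed = 53, mean_rate = 0.4)
  tc <- simulate_population(g, lam, 150, function(d) 0.45 * exp(-d / 300), seed = 54)
  ts <- shuffle_repetitions(tc, seed = 55)
  pc <- population_rate_distribution(tc); ps <- population_rate_distribution(ts)
  k_star <- ceiling(2 * sum(rowMeans(lam)) / 1)  # ~2x the mean population rate
  tailmass <- function(p, k) sum(p$prob[p$k >= k])
  expect_gt(pc$prob[pc$k == 0], ps$prob[ps$k == 0])
  expect_gt(tailmass(pc, k_star), tailmass(ps, k_star))
  # top-activity restriction keeps a valid distribution
  pt <- population_rate_distribution(tc, top_fraction = 0.05)
  expect_equal(sum(pt$prob), 1)
})

test_that("model triplet correlations match enumeration and are permutation-invariant", {
  mod <- ref_maxent(T_ = 6)
  ex <- exact_triplet_correlation(mod, 1, 2, 3)
  expect_equal(ex, exact_triplet_correlation(mod, 3, 1, 2), tolerance = 1e-12)
  mc <- predict_triplet_correlations(mod, rbind(c(1, 2, 3)), n_samples = 4000,
                                     seed = 9, n_sweeps = 25)
  expect_lt(abs(mc - ex), 0.05)
  # zero couplings: triplet correlations vanish
  mod0 <- maxent_model(mod$h, matrix(0, 3, 3), 3)
  expect_lt(abs(exact_triplet_correlation(mod0, 1, 2, 3)), 1e-12)
})

test_that("model files round-trip through JSON", {
  td <- withr::local_tempdir()
  mod <- ref_maxent()
  f <- file.path(td, "maxent.json")
  write_model(mod, f)
  back <- read_model(f)
  expect_equal(back$h, mod$h, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$J, mod$J, tolerance = 1e-12, ignore_attr = TRUE)
  law <- ref_law()
  fl <- file.path(td, "law.json")
  write_model(law, fl)
  lb <- read_model(fl)
  expect_equal(lb$a, law$a)
  expect_equal(lb$cutoff_um, 1000)
})
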