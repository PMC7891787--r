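families_with_theta <- list(gumbel = 2, gaussian = 0.5, frank = 4,
                            clayton = 1.5, independent = NA)

test_that("all families satisfy the copula boundary contract", {
  u <- c(0, 0.2, 0.5, 0.9, 1)
  for (fam in names(families_with_theta)) {
    m <- copula_model(fam, families_with_theta[[fam]])
    expect_equal(copula_cdf(m, u, rep(0, 5)), rep(0, 5), info = fam)
    expect_equal(copula_cdf(m, rep(0, 5), u), rep(0, 5), info = fam)
    expect_equal(copula_cdf(m, u, rep(1, 5)), u, tolerance = 1e-9, info = fam)
    expect_equal(copula_cdf(m, rep(1, 5), u), u, tolerance = 1e-9, info = fam)
  }
})

test_that("all families are 2-increasing on random rectangles", {
  set.seed(14)
  for (fam in names(families_with_theta)) {
    m <- copula_model(fam, families_with_theta[[fam]])
    u <- matrix(runif(200), 50); v <- matrix(runif(200), 50)
    u1 <- pmin(u[, 1], u[, 2]); u2 <- pmax(u[, 1], u[, 2])
    v1 <- pmin(v[, 3], v[, 4]); v2 <- pmax(v[, 3], v[, 4])
    mass <- copula_cdf(m, u2, v2) - copula_cdf(m, u1, v2) -
            copula_cdf(m, u2, v1) + copula_cdf(m, u1, v1)
    expect_true(all(mass > -1e-10), info = fam)
  }
})

test_that("independence limits collapse to the product copula", {
  set.seed(3)
  u <- runif(30); v <- runif(30)
  expect_equal(copula_cdf(copula_model("gumbel", 1), u, v), u * v, tolerance = 1e-12)
  expect_equal(copula_cdf(copula_model("frank", 1e-10), u, v), u * v, tolerance = 1e-8)
  expect_equal(copula_cdf(copula_model("independent"), u, v), u * v)
  # closed-form Gumbel value: C(1/2, 1/2 | 2) = 2^(-sqrt(2))
  expect_equal(copula_cdf(copula_model("gumbel", 2), 0.5, 0.5), 2^(-sqrt(2)),
               tolerance = 1e-12)
  expect_error(copula_model("gumbel", 0.5), "domain")
  expect_error(copula_model("gaussian", 1.2), "domain")
  expect_error(copula_model("clayton", 0), "domain")
})

test_that("discrete joint laws reproduce their marginals (Sklar construction)", {
  set.seed(4)
  for (fam in names(families_with_theta)) {
    m <- copula_model(fam, families_with_theta[[fam]])
    px <- c(0.3, 0.5, 0.2); py <- c(0.6, 0.3, 0.1)
    P <- discrete_joint_pmf(m, cumsum(px), cumsum(py))
    expect_equal(rowSums(P), px, tolerance = 1e-10, info = fam)
    expect_equal(colSums(P), py, tolerance = 1e-10, info = fam)
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
  # independent family: exact outer product
  px <- c(0.2, 0.8); py <- c(0.7, 0.2, 0.1)
  P <- discrete_joint_pmf(copula_model("independent"), cumsum(px), cumsum(py))
  expect_equal(P, px %o% py, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(discrete_joint_pmf(copula_model("independent"), c(0.5, 0.4, 1),
                                  c(0.5, 1)), "non-decreasing")
})

test_that("Gaussian copula on Bernoulli margins equals the normal orthant probability", {
  # dichotomized-Gaussian equivalence, closed form at p = 1/2:
  # P(1,1) = 1/4 + asin(theta) / (2 pi)
  for (th in c(-0.6, 0.25, 0.5, 0.8)) {
    P <- discrete_joint_pmf(copula_model("gaussian", th), c(0.5, 1), c(0.5, 1))
    expect_equal(P[2, 2], 1 / 4 + asin(th) / (2 * pi), tolerance = 1e-7)
  }
  # general thresholds against direct 2-d normal integration
  th <- 0.4; px <- 0.3; py <- 0.7
  P <- discrete_joint_pmf(copula_model("gaussian", th), c(px, 1), c(py, 1))
  orthant <- mvtnorm::pmvnorm(lower = c(qnorm(px), qnorm(py)),
                              corr = matrix(c(1, th, th, 1), 2))[1]
  expect_equal(P[2, 2], orthant, tolerance = 1e-6)
})

test_that("pair log-likelihood equals full-table summation and factorises when independent", {
  lam <- simulate_rate_profiles(2, 2, seed = 15, mean_rate = 0.8)
  tp <- simulate_pair(lam[1, ], lam[2, ], 25, copula_model("gumbel", 2.5), seed = 16)
  mg <- empirical_marginals(tp)
  x <- matrix(tp$counts[1, , ], 2); y <- matrix(tp$counts[2, , ], 2)
  cx <- marginal_slice(mg, 1)$cdf; cy <- marginal_slice(mg, 2)$cdf
  for (fam in c("gumbel", "gaussian", "frank")) {
    m <- copula_model(fam, families_with_theta[[fam]])
    expect_equal(pair_log_likelihood(m, x, y, cx, cy),
                 oracle_pair_ll(m, x, y, cx, cy), tolerance = 1e-8, info = fam)
  }
  ind <- pair_log_likelihood(copula_model("independent"), x, y, cx, cy)
  marg_ll <- function(z, cdf) {
    s <- 0
    for (t in seq_len(nrow(z))) {
      p <- diff(c(0, cdf[, t]))
      s <- s + sum(log(p[z[t, ] + 1]))
    }
    s
  }
  expect_equal(ind, marg_ll(x, cx) + marg_ll(y, cy), tolerance = 1e-6)
  expect_equal(pair_log_likelihood(copula_model("gumbel", 1), x, y, cx, cy), ind,
               tolerance = 1e-6)
})

test_that("maximum-likelihood fitting recovers the Gumbel parameter", {
  lam <- simulate_rate_profiles(2, 600, seed = 11)
  tp <- simulate_pair(lam[1, ], lam[2, ], 79, copula_model("gumbel", 3), seed = 12)
  mg <- empirical_marginals(tp)
  x <- matrix(tp$counts[1, , ], 600); y <- matrix(tp$counts[2, , ], 600)
  cx <- marginal_slice(mg, 1)$cdf; cy <- marginal_slice(mg, 2)$cdf
  fit <- fit_copula_parameter("gumbel", x, y, cx, cy)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta - 3) / 3, 0.10)
  # nesting: optimum at least as good as independence within the family
  expect_gte(fit$loglik, pair_log_likelihood(copula_model("gumbel", 1), x, y, cx, cy))
  # independent data push the Gumbel fit to its boundary
  ti <- simulate_pair(lam[1, 1:300], lam[2, 1:300], 79,
                      copula_model("independent"), seed = 13)
  mgi <- empirical_marginals(ti)
  fi <- fit_copula_parameter("gumbel", matrix(ti$counts[1, , ], 300),
                             matrix(ti$counts[2, , ], 300),
                             marginal_slice(mgi, 1)$cdf, marginal_slice(mgi, 2)$cdf)
  expect_lt(fi$theta, 1.05)
  # all-deterministic data are rejected
  z <- matrix(1L, 4, 6)
  cz <- matrix(rep(c(0, 1, 1), 4), 3)
  expect_error(fit_copula_parameter("gumbel", z, z, cz, cz), "informative")
})

test_that("copula sampling converges to the discrete joint law", {
  cfx <- c(0.4, 0.8, 1); cfy <- c(0.5, 0.9, 1)
  for (fam in c("gumbel", "gaussian", "frank", "clayton")) {
    th <- if (fam == "gaussian") 0.6 else 2
    m <- copula_model(fam, th)
    s <- sample_pair(m, cfx, cfy, 1e5, seed = 44)
    P <- discrete_joint_pmf(m, cfx, cfy)
    emp <- table(factor(s[, 1], 0:2), factor(s[, 2], 0:2)) / nrow(s)
    expect_lt(sum(abs(emp - P)) / 2, 0.01)  # total variation
    # marginals of the samples converge to the inputs
    expect_lt(max(abs(cumsum(rowSums(emp)) - cfx)), 0.01)
  }
  # independent family: two independent streams
  s <- sample_pair(copula_model("independent"), cfx, cfy, 2e4, seed = 45)
  expect_lt(abs(cor(s[, 1], s[, 2])), 0.02)
})

test_that("KL divergence to the empirical joint behaves as a divergence", {
  lam <- simulate_rate_profiles(2, 80, seed = 21, mean_rate = 0.6)
  tp <- simulate_pair(lam[1, ], lam[2, ], 79, copula_model("gumbel", 3), seed = 22)
  mg <- empirical_marginals(tp)
  x <- matrix(tp$counts[1, , ], 80); y <- matrix(tp$counts[2, , ], 80)
  cx <- marginal_slice(mg, 1)$cdf; cy <- marginal_slice(mg, 2)$cdf
  fit <- fit_copula_parameter("gumbel", x, y, cx, cy)
  kl_g <- kl_empirical_vs_model(copula_model("gumbel", fit$theta), x, y, cx, cy)
  kl_i <- kl_empirical_vs_model(copula_model("independent"), x, y, cx, cy)
  expect_gte(kl_g, 0)
  expect_lt(kl_g, kl_i)   # the generating family explains the data better
})

test_that("family selection ranks the generating family first", {
  lam <- simulate_rate_profiles(4, 150, seed = 31, mean_rate = 0.5)
  g <- cell_geometry(paste0("c", 1:4), c(0, 100, 0, 100), c(0, 0, 100, 100))
  # strong Gumbel-like upper-tail dependence via a latent-Gaussian population
  # would blur the test; simulate explicit Gumbel pairs cell-by-cell instead
  counts <- array(0L, c(4, 150, 79))
  tp1 <- simulate_pair(lam[1, ], lam[2, ], 79, copula_model("gumbel", 2.5), seed = 32)
  tp2 <- simulate_pair(lam[3, ], lam[4, ], 79, copula_model("gumbel", 2.5), seed = 33)
  counts[1:2, , ] <- tp1$counts; counts[3:4, , ] <- tp2$counts
  tn <- spike_count_tensor(counts, 1000 / 60)
  rank <- select_family(tn, families = c("independent", "gumbel", "gaussian"),
                        pairs = rbind(c(1, 2), c(3, 4)))
  expect_equal(rank$family[1], "gumbel")
  expect_equal(rank$n_pairs, rep(2L, 3))
  # ranking invariant to pair ordering
  rank2 <- select_family(tn, families = c("independent", "gumbel", "gaussian"),
                         pairs = rbind(c(3, 4), c(1, 2)))
  expect_equal(rank$family, rank2$family)
  expect_equal(rank$mean_kl, rank2$mean_kl, tolerance = 1e-12)
})
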