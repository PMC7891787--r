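# seeded random tensors and brute-force oracles shared across test files

random_tensor <- function(n_cells, n_bins, n_reps, lambda = 0.6, seed = 1L) {
  set.seed(seed)
  spike_count_tensor(array(rpois(n_cells * n_bins * n_reps, lambda),
                           c(n_cells, n_bins, n_reps)),
                     bin_width_ms = 1000 / 60)
}

# two-pass covariance decomposition oracle, written from the definitions
# with explicit loops (independent of the package's vectorised path)
oracle_cov_decomp <- function(tensor, i, j) {
  x <- tensor$counts[i, , ]; y <- tensor$counts[j, , ]
  T_ <- tensor$n_bins; R <- tensor$n_reps
  mu_x_t <- rowMeans(x); mu_y_t <- rowMeans(y)
  mu_x <- mean(mu_x_t); mu_y <- mean(mu_y_t)
  tot <- noi <- sti <- 0
  for (t in seq_len(T_)) {
    for (r in seq_len(R)) {
      tot <- tot + (x[t, r] - mu_x) * (y[t, r] - mu_y)
      noi <- noi + (x[t, r] - mu_x_t[t]) * (y[t, r] - mu_y_t[t])
    }
    sti <- sti + (mu_x_t[t] - mu_x) * (mu_y_t[t] - mu_y)
  }
  list(total = tot / (T_ * R), noise = noi / (T_ * R), stimulus = sti / T_)
}

oracle_triplet <- function(tensor, i, j, k) {
  T_ <- tensor$n_bins; R <- tensor$n_reps
  res <- lapply(c(i, j, k), function(a) {
    x <- matrix(tensor$counts[a, , ], T_)
    x - rowMeans(x)
  })
  v <- vapply(c(i, j, k), function(a) oracle_cov_decomp(tensor, a, a)$total, 0)
  s <- 0
  for (t in seq_len(T_)) for (r in seq_len(R))
    s <- s + res[[1]][t, r] * res[[2]][t, r] * res[[3]][t, r]
  s / (T_ * R) / sqrt(prod(v))
}

# full-table pair log-likelihood oracle: per bin, build the whole discrete
# joint law and sum the log masses of the observed pairs
oracle_pair_ll <- function(model, x, y, cdf_x, cdf_y) {
  s <- 0
  for (t in seq_len(nrow(x))) {
    P <- discrete_joint_pmf(model, cdf_x[, t], cdf_y[, t])
    s <- s + sum(log(P[cbind(x[t, ] + 1L, y[t, ] + 1L)]))
  }
  s
}

# standard Gumbel-law coefficients and a ready distance model
ref_law <- function() theta_distance_model(0.73, -0.014, 8e-6)
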