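#' Stimulus/noise covariance decomposition for a cell pair
#'
#' Decomposes the total spike-count covariance of two cells into a stimulus
#' part (carried by the time-varying trial-averaged rates) and a noise part
#' (trial-to-trial fluctuations around those rates):
#' \deqn{Cov_{total} = \frac1T\sum_t \frac1R\sum_r (n_i(t,r)-\mu_i)(n_j(t,r)-\mu_j)}
#' \deqn{Cov_{noise} = \frac1T\sum_t \frac1R\sum_r (n_i(t,r)-\mu_i(t))(n_j(t,r)-\mu_j(t))}
#' \deqn{Cov_{stimulus} = \frac1T\sum_t (\mu_i(t)-\mu_i)(\mu_j(t)-\mu_j)}
#' with \eqn{\mu_i(t)} the across-repetition mean and \eqn{\mu_i} its time
#' average.  The maximum-likelihood 1/R, 1/T normalisations (no Bessel
#' correction) make the identity `total = stimulus + noise` hold to machine
#' precision on any tensor.
#'
#' @param tensor a [spike_count_tensor()] with `n_reps >= 2`.
#' @param i,j cell ids or indices.
#' @return list with `total`, `stimulus`, `noise`.
#' @export
covariance_decomposition <- function(tensor, i, j) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (tensor$n_reps < 2L) stop("covariance decomposition requires R >= 2")
  i <- .cell_index(tensor, i); j <- .cell_index(tensor, j)
  xi <- matrix(tensor$counts[i, , ], tensor$n_bins)   # T x R
  xj <- matrix(tensor$counts[j, , ], tensor$n_bins)
  mui_t <- rowMeans(xi); muj_t <- rowMeans(xj)
  mui <- mean(mui_t);    muj <- mean(muj_t)
  total <- mean(rowMeans((xi - mui) * (xj - muj)))
  noise <- mean(rowMeans((xi - mui_t) * (xj - muj_t)))
  stimulus <- mean((mui_t - mui) * (muj_t - muj))
  list(total = total, stimulus = stimulus, noise = noise)
}

#' Total variance of one cell's counts
#'
#' `V_i = Cov_total(n_i, n_i)`: the normaliser used by the pairwise and
#' triplet noise-correlation estimators (total, not noise, variance).
#' @inheritParams covariance_decomposition
#' @param i cell id or index.
#' @export
total_variance <- function(tensor, i) covariance_decomposition(tensor, i, i)$total

#' Pairwise zero-lag noise correlation
#'
#' `Cov_noise(n_i, n_j) / sqrt(V_i V_j)` with `V` the *total* variances.
#' Returns `NA` (never a silent zero) when either total variance vanishes.
#'
#' @inheritParams covariance_decomposition
#' @return a real in `[-1, 1]` up to the total-variance normalisation, or
#'   `NA_real_` when undefined.
#' @export
noise_correlation <- function(tensor, i, j) {
  vi <- total_variance(tensor, i); vj <- total_variance(tensor, j)
  if (vi <= 0 || vj <= 0) return(NA_real_)
  covariance_decomposition(tensor, i, j)$noise / sqrt(vi * vj)
}

#' Full matrix of pairwise noise covariances
#'
#' `N x N` symmetric matrix of Eq.-style noise covariances, diagonal included
#' (the diagonal is each cell's noise variance).  The grand sum of this matrix
#' equals `N` times the tensor-route population synchrony.
#' @inheritParams covariance_decomposition
#' @export
noise_covariance_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (tensor$n_reps < 2L) stop("noise covariance requires R >= 2")
  N <- tensor$n_cells; T_ <- tensor$n_bins; R <- tensor$n_reps
  mu_t <- rowMeans(tensor$counts, dims = 2L)          # N x T
  resid <- tensor$counts - as.vector(mu_t)            # recycles over reps
  m <- matrix(0, N, N)
  for (r in seq_len(R)) {
    x <- matrix(resid[, , r], N)
    m <- m + tcrossprod(x)
  }
  m <- m / (R * T_)
  dimnames(m) <- list(tensor$cell_ids, tensor$cell_ids)
  m
}

#' Triplet zero-lag noise correlation
#'
#' Third-order central moment of the trial-to-trial fluctuations,
#' `1/(T R) * sum_{t,r} prod_{c in (i,j,k)} (n_c(t,r) - mu_c(t))`, normalised
#' by `sqrt(V_i V_j V_k)` with total variances `V`.  Symmetric under any
#' permutation of the triplet.
#'
#' @inheritParams covariance_decomposition
#' @param k third cell id or index.
#' @export
triplet_noise_correlation <- function(tensor, i, j, k) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (tensor$n_reps < 2L) stop("triplet correlation requires R >= 2")
  idx <- c(.cell_index(tensor, i), .cell_index(tensor, j), .cell_index(tensor, k))
  v <- vapply(idx, function(a) total_variance(tensor, a), 0)
  if (any(v <= 0)) return(NA_real_)
  T_ <- tensor$n_bins
  resid <- lapply(idx, function(a) {
    x <- matrix(tensor$counts[a, , ], T_)
    x - rowMeans(x)
  })
  mean(rowMeans(resid[[1L]] * resid[[2L]] * resid[[3L]])) / sqrt(prod(v))
}

#' Cross-correlogram of spike counts and of firing rates
#'
#' At each integer lag, the lagged covariance of the two cells' counts
#' (averaged over repetitions, then over the overlapping bins) and the lagged
#' covariance of their per-bin mean rates, both centred on the grand means.
#' The zero-lag count value is the total covariance, the zero-lag rate value
#' the stimulus covariance, so their difference at lag 0 is exactly the noise
#' covariance.
#'
#' @inheritParams covariance_decomposition
#' @param max_lag_bins maximum |lag| in bins (must be `< n_bins`).
#' @return data frame with `lag`, `count_cov`, `rate_cov`.
#' @export
cross_correlogram <- function(tensor, i, j, max_lag_bins) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (max_lag_bins < 0 || max_lag_bins >= tensor$n_bins)
    stop("`max_lag_bins` must be in [0, n_bins)")
  i <- .cell_index(tensor, i); j <- .cell_index(tensor, j)
  T_ <- tensor$n_bins
  xi <- matrix(tensor$counts[i, , ], T_); xj <- matrix(tensor$counts[j, , ], T_)
  mui_t <- rowMeans(xi); muj_t <- rowMeans(xj)
  mui <- mean(mui_t); muj <- mean(muj_t)
  lags <- -max_lag_bins:max_lag_bins
  cc <- rc <- numeric(length(lags))
  for (a in seq_along(lags)) {
    L <- lags[a]
    ti <- seq_len(T_ - abs(L)) + max(0L, -L)   # index into cell i
    tj <- ti + L                               # index into cell j
    cc[a] <- mean(rowMeans((xi[ti, , drop = FALSE] - mui) *
                           (xj[tj, , drop = FALSE] - muj)))
    rc[a] <- mean((mui_t[ti] - mui) * (muj_t[tj] - muj))
  }
  data.frame(lag = lags, count_cov = cc, rate_cov = rc)
}

#' Prediction-quality metrics
#'
#' Pearson correlation and coefficient of determination
#' `cod = 1 - sum((emp - pred)^2) / sum((emp - mean(emp))^2)` between an
#' empirical vector and its model prediction.  `cod` can be negative (worse
#' than predicting the mean).  Pairs with missing values are dropped; if the
#' empirical variance is zero both metrics are `NA`.
#'
#' @param empirical,predicted numeric vectors of equal length (>= 2 after
#'   removing missing pairs).
#' @return list with `pearson`, `cod`, `n`.
#' @export
prediction_metrics <- function(empirical, predicted) {
  if (length(empirical) != length(predicted))
    stop("`empirical` and `predicted` must have equal length")
  ok <- is.finite(empirical) & is.finite(predicted)
  e <- empirical[ok]; p <- predicted[ok]
  if (length(e) < 2L) stop("fewer than 2 usable pairs")
  ss <- sum((e - mean(e))^2)
  if (ss == 0) return(list(pearson = NA_real_, cod = NA_real_, n = length(e)))
  list(pearson = if (stats::sd(p) == 0) NA_real_ else stats::cor(e, p),
       cod = 1 - sum((e - p)^2) / ss,
       n = length(e))
}
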