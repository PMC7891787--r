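#' Smooth synthetic firing-rate profiles
#'
#' Per-cell rate traces in spikes per bin, built as log-normal noise smoothed
#' with a circular Gaussian kernel: `lambda_i(t) = mean_rate *
#' exp(g_i(t) - Var(g)/2)` with `g` kernel-smoothed white noise scaled by
#' `sd_log`.  The variance correction makes `E[lambda] = mean_rate` exactly;
#' as `smoothness` grows the smoothed noise contracts to its mean and the
#' profiles become constant at `mean_rate`.  Defaults emulate the
#' fluctuation-driven peaky rate profiles of ganglion cells under
#' checkerboard stimulation.
#'
#' @param n_cells number of cells.
#' @param n_bins number of time bins.
#' @param seed integer RNG seed.
#' @param smoothness Gaussian kernel sd in bins.
#' @param mean_rate mean rate in spikes per bin.
#' @param sd_log log-scale sd of the unsmoothed noise.
#' @return `n_cells x n_bins` matrix of non-negative rates.
#' @export
simulate_rate_profiles <- function(n_cells, n_bins, seed = 1L, smoothness = 5,
                                   mean_rate = 0.25, sd_log = 1) {
  stopifnot(mean_rate >= 0, smoothness > 0)
  set.seed(as.integer(seed))
  half <- ceiling(4 * smoothness)
  w <- stats::dnorm(-half:half, sd = smoothness)
  w <- w / sum(w)
  # circular convolution (via index wrapping) keeps the trace stationary
  # across the edges and works for any n_bins relative to the kernel width
  idx <- outer(seq_len(n_bins) - 1L, -half:half, "+") %% n_bins + 1L
  lam <- matrix(0, n_cells, n_bins)
  for (i in seq_len(n_cells)) {
    z <- stats::rnorm(n_bins)
    g <- sd_log * as.numeric(matrix(z[idx], n_bins) %*% w)
    lam[i, ] <- mean_rate * exp(g - sd_log^2 * sum(w^2) / 2)
  }
  lam
}

# truncated-Poisson cdf matrix ((n_max+1) x T) for one rate profile
.trunc_pois_cdf <- function(lambda, n_max) {
  F <- vapply(lambda, function(l) stats::ppois(0:n_max, l), numeric(n_max + 1L))
  sweep(F, 2L, F[n_max + 1L, ], "/")
}

# default truncation cap: the 1 - 1e-6 Poisson quantile of the largest rate
.default_n_max <- function(lambda) max(1L, stats::qpois(1 - 1e-6, max(lambda)))

#' Cell marginal from a rate profile
#'
#' Truncated-Poisson per-bin marginals (cap at the `1 - 1e-6` quantile of
#' the largest rate unless given), packaged as a [marginal_slice()]-style
#' object for the prediction functions.
#'
#' @param lambda rate profile in spikes/bin (length `T`).
#' @param n_max optional truncation cap.
#' @param cell_id identifier.
#' @return a `cell_marginal`.
#' @export
rate_profile_marginal <- function(lambda, n_max = NULL, cell_id = "synthetic") {
  if (is.null(n_max)) n_max <- .default_n_max(lambda)
  cdf <- .trunc_pois_cdf(lambda, n_max)
  pmf <- apply(cdf, 2L, function(col) diff(c(0, col)))
  structure(list(pmf = pmf, cdf = cdf, n_max = as.integer(n_max),
                 n_bins = length(lambda), cell_id = cell_id),
            class = "cell_marginal")
}

#' Simulate a recorded cell pair with copula dependence
#'
#' Ground-truth generator for the pairwise stage: per bin, `R` count pairs
#' are drawn from the discrete joint law coupling truncated-Poisson marginals
#' `Poisson(lambda_i(t))` through the given copula (one parameter shared by
#' all bins, as in the model).  The copula uniforms for all bins and
#' repetitions are drawn in one batch, then mapped through each bin's
#' generalised inverse c.d.f.
#'
#' @param lambda_x,lambda_y rate profiles (spikes/bin, length `T`).
#' @param n_reps repetitions.
#' @param model a [copula_model()].
#' @param n_max optional truncation cap (default: `1 - 1e-6` quantile).
#' @param seed integer RNG seed.
#' @param bin_width_ms bin width recorded in the tensor.
#' @return a two-cell [spike_count_tensor()].
#' @export
simulate_pair <- function(lambda_x, lambda_y, n_reps, model, n_max = NULL,
                          seed = 1L, bin_width_ms = 1000 / 60) {
  stopifnot(inherits(model, "copula_model"), length(lambda_x) == length(lambda_y))
  T_ <- length(lambda_x)
  if (is.null(n_max)) n_max <- .default_n_max(c(lambda_x, lambda_y))
  u <- copula_sample_uniforms(model, T_ * n_reps, seed)
  cdfx <- .trunc_pois_cdf(lambda_x, n_max)
  cdfy <- .trunc_pois_cdf(lambda_y, n_max)
  counts <- array(0L, dim = c(2L, T_, n_reps))
  for (t in seq_len(T_)) {
    rows <- t + T_ * (seq_len(n_reps) - 1L)
    counts[1L, t, ] <- findInterval(u[rows, 1L], cdfx[, t], left.open = TRUE)
    counts[2L, t, ] <- findInterval(u[rows, 2L], cdfy[, t], left.open = TRUE)
  }
  spike_count_tensor(counts, bin_width_ms, c("cell_x", "cell_y"))
}

#' Simulate a correlated population (latent-Gaussian route)
#'
#' Full-population ground truth with exact marginals and distance-decaying
#' noise correlations: per bin and repetition a latent multivariate normal
#' with correlation `rho(d_ij)` is drawn, each coordinate is pushed through
#' the standard normal c.d.f. and then through the generalised inverse of
#' that cell's truncated-Poisson c.d.f.  For two cells this construction
#' coincides with a Gaussian copula of parameter `rho` (the dichotomized-
#' Gaussian equivalence), which is why a single latent correlation function
#' yields a globally consistent joint law - something arbitrary pairwise
#' Archimedean margins cannot guarantee.
#'
#' If `rho(d)` does not produce a positive semi-definite matrix on the given
#' geometry it is repaired by clipping negative eigenvalues to zero and
#' renormalising the diagonal; a repair that moves any eigenvalue by more
#' than 0.05 triggers a warning.
#'
#' @param geometry a [cell_geometry()].
#' @param rates `N x T` matrix of per-cell rate profiles (spikes/bin).
#' @param n_reps repetitions.
#' @param rho_fun function of distance (um) returning the latent correlation
#'   in `[-1, 1]`; evaluated at all pairwise distances.
#' @param n_max optional truncation cap.
#' @param seed integer RNG seed.
#' @param bin_width_ms recorded bin width.
#' @return a [spike_count_tensor()] with the geometry's cell ids.
#' @export
simulate_population <- function(geometry, rates, n_reps, rho_fun, n_max = NULL,
                                seed = 1L, bin_width_ms = 1000 / 60) {
  stopifnot(inherits(geometry, "cell_geometry"))
  rates <- as.matrix(rates)
  N <- nrow(geometry); T_ <- ncol(rates)
  if (nrow(rates) != N) stop("`rates` must have one row per cell")
  if (is.null(n_max)) n_max <- .default_n_max(rates)
  C <- rho_fun(pair_distances(geometry))
  diag(C) <- 1
  if (any(abs(C) > 1)) stop("rho(d) must lie in [-1, 1]")
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    C2 <- ev$vectors %*% (vals * t(ev$vectors))
    C2 <- C2 / sqrt(diag(C2) %o% diag(C2))
    if (max(abs(ev$values - vals)) > 0.05)
      warning("latent correlation matrix repaired; largest eigenvalue change ",
              signif(max(abs(ev$values - vals)), 3))
    C <- C2
  }
  set.seed(as.integer(seed))
  L <- chol(C + diag(1e-12, N))
  Z <- matrix(stats::rnorm(T_ * n_reps * N), T_ * n_reps, N) %*% L
  U <- stats::pnorm(Z)
  counts <- array(0L, dim = c(N, T_, n_reps))
  tix <- rep.int(seq_len(T_), n_reps)
  for (i in seq_len(N)) {
    lam <- rates[i, tix]
    # generalised inverse of the truncated-Poisson cdf in closed form
    counts[i, , ] <- stats::qpois(U[, i] * stats::ppois(n_max, lam), lam)
  }
  spike_count_tensor(counts, bin_width_ms, geometry$cell_id)
}
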