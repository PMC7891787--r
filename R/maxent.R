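#' Time-dependent maximum-entropy population model
#'
#' A collection of per-bin Boltzmann distributions over integer count vectors
#' `n in {0..n_max}^N` sharing one symmetric coupling matrix:
#' \deqn{P_t(n) \propto \exp\{\sum_i h_i(t) n_i + \sum_{i \le j} J_{ij} n_i n_j - \sum_i \ln(n_i!)\}}
#' Fields `h_i(t)` set each cell's time-varying firing probability; the
#' time-shared couplings `J_ij` (including diagonal terms `J_ii`, which pin
#' each cell's variance) carry the noise correlations.  With `J = 0` the
#' model factorises into independent Poisson distributions truncated at
#' `n_max`.
#'
#' @param h `N x T` matrix of fields.
#' @param J `N x N` symmetric coupling matrix (diagonal included).
#' @param n_max count cap (counts live in `0..n_max`).
#' @param cell_ids optional cell identifiers.
#' @return object of class `maxent_model`.
#' @export
maxent_model <- function(h, J, n_max, cell_ids = NULL) {
  h <- as.matrix(h); J <- as.matrix(J)
  N <- nrow(h)
  if (nrow(J) != N || ncol(J) != N) stop("`J` must be N x N with N = nrow(h)")
  if (max(abs(J - t(J))) > 1e-10) stop("`J` must be symmetric")
  J <- (J + t(J)) / 2
  dimnames(h) <- dimnames(J) <- NULL
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("`n_max` must be >= 1")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(N))
  structure(list(h = h, J = J, n_max = n_max, cell_ids = as.character(cell_ids),
                 n_cells = N, n_bins = ncol(h)),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d cells x %d bins, counts 0..%d, max|J| = %.4g\n",
              x$n_cells, x$n_bins, x$n_max, max(abs(x$J))))
  invisible(x)
}

#' Unnormalised log-probability of a count state
#'
#' `sum_i h_i(t) n_i + sum_{i<=j} J_ij n_i n_j - sum_i log(n_i!)`.
#'
#' @param model a [maxent_model()].
#' @param state integer vector of counts in `0..n_max`, one per cell.
#' @param t time-bin index.
#' @export
log_weight <- function(model, state, t) {
  stopifnot(inherits(model, "maxent_model"))
  if (length(state) != model$n_cells) stop("`state` must have one count per cell")
  if (any(state < 0 | state > model$n_max)) stop("counts must lie in 0..n_max")
  n <- as.numeric(state)
  quad <- (sum(n * (model$J %*% n)) + sum(diag(model$J) * n^2)) / 2
  sum(model$h[, t] * n) + quad - sum(lfactorial(n))
}

# enumerate the state space: K x N matrix, K = (n_max+1)^N
.state_space <- function(n_cells, n_max) {
  as.matrix(expand.grid(rep(list(0:n_max), n_cells)))
}

# log unnormalised weights for all states and bins: list(S = K x N states,
# logw = K x T)
.exact_logw <- function(model) {
  S <- .state_space(model$n_cells, model$n_max)
  quad <- (rowSums((S %*% model$J) * S) + S^2 %*% diag(model$J)) / 2
  state_part <- as.numeric(quad) - rowSums(lfactorial(S))
  list(S = S, logw = state_part + S %*% model$h)
}

#' Exact moments and partition function by enumeration
#'
#' Enumerates all `(n_max+1)^N` states per bin (refused above 1e6) and
#' returns exact per-bin means and second moments, time-summed pairwise cross
#' moments, and the per-bin log partition function.  This is the small-system
#' oracle against which the Gibbs sampler and the fitter are validated.
#'
#' @param model a [maxent_model()].
#' @return list with `mean` (`N x T`), `second` (`N x T`), `cross_sum`
#'   (`N x N`, time-summed `E[n_i n_j]`, diagonal = time-summed second
#'   moments), `log_z` (length `T`).
#' @export
exact_moments <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  K <- (model$n_max + 1)^model$n_cells
  if (K > 1e6) stop("state space too large for enumeration: ", K, " > 1e6")
  ew <- .exact_logw(model)
  mx <- apply(ew$logw, 2L, max)
  W <- exp(sweep(ew$logw, 2L, mx))
  z <- colSums(W)
  P <- sweep(W, 2L, z, "/")                     # K x T
  mean_ <- t(crossprod(P, ew$S))                # N x T
  second <- t(crossprod(P, ew$S^2))
  Pt <- rowSums(P)                              # sum over bins of P_t(state)
  cross_sum <- crossprod(ew$S, ew$S * Pt)       # N x N time-summed E[n_i n_j]
  list(mean = mean_, second = second, cross_sum = (cross_sum + t(cross_sum)) / 2,
       log_z = log(z) + mx)
}

#' Exact per-bin state distribution (small systems)
#'
#' @param model a [maxent_model()].
#' @return list with `states` (`K x N`) and `prob` (`K x T`).
#' @export
exact_distribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  K <- (model$n_max + 1)^model$n_cells
  if (K > 1e6) stop("state space too large for enumeration: ", K, " > 1e6")
  ew <- .exact_logw(model)
  mx <- apply(ew$logw, 2L, max)
  W <- exp(sweep(ew$logw, 2L, mx))
  list(states = ew$S, prob = sweep(W, 2L, colSums(W), "/"))
}

# one heat-bath sweep over all cells; state is N x M (M = bins*replicas
# columns), tbin maps each column to its time bin. Modifies and returns state.
.gibbs_sweep <- function(model, state, tbin) {
  k <- 0:model$n_max
  lfk <- lfactorial(k)
  for (i in seq_len(model$n_cells)) {
    field <- model$h[i, tbin] + colSums(model$J[i, -i, drop = FALSE] %*%
                                          state[-i, , drop = FALSE])
    # log weight of count k in column m: k*field_m + Jii*k^2 - log k!
    lw <- outer(k, field) + diag(model$J)[i] * k^2 - lfk
    lw <- sweep(lw, 2L, apply(lw, 2L, max))
    w <- exp(lw)
    cw <- apply(w, 2L, cumsum)
    u <- stats::runif(ncol(state)) * cw[model$n_max + 1L, ]
    state[i, ] <- colSums(sweep(cw, 2L, u, "<"))
  }
  state
}

#' Gibbs sampling from the population model
#'
#' Single-site heat-bath Gibbs: each (cell, bin) variable is resampled from
#' its exact conditional over `0..n_max` given the rest; one sweep updates
#' every site of every chain.  Because bins interact only through the shared
#' couplings within a bin, all bins and chains are updated as independent
#' columns, vectorised.  Chains start from the independent (truncated
#' Poisson) part of the model; each chain contributes one sample per sweep
#' after `burn_in`.
#'
#' @param model a [maxent_model()].
#' @param n_sweeps sweeps per chain.
#' @param n_chains number of independent chains.
#' @param burn_in sweeps discarded from the start of each chain.
#' @param seed integer RNG seed (fixed seed gives bit-identical output).
#' @return a [spike_count_tensor()] with `n_chains * (n_sweeps - burn_in)`
#'   repetitions (samples).
#' @export
gibbs_sample <- function(model, n_sweeps, n_chains, burn_in = 0L, seed) {
  stopifnot(inherits(model, "maxent_model"))
  if (burn_in >= n_sweeps) stop("`burn_in` must be < `n_sweeps`")
  set.seed(as.integer(seed))
  N <- model$n_cells; T_ <- model$n_bins
  M <- T_ * n_chains
  tbin <- rep.int(seq_len(T_), n_chains)
  lam <- exp(model$h[, tbin, drop = FALSE])
  state <- matrix(pmin(stats::rpois(N * M, pmin(as.vector(lam), 50)), model$n_max), N, M)
  kept <- array(0L, dim = c(N, T_, n_chains * (n_sweeps - burn_in)))
  s <- 0L
  for (sw in seq_len(n_sweeps)) {
    state <- .gibbs_sweep(model, state, tbin)
    if (sw > burn_in) {
      kept[, , s * n_chains + seq_len(n_chains)] <- state
      s <- s + 1L
    }
  }
  spike_count_tensor(kept, bin_width_ms = 1000 / 60, cell_ids = model$cell_ids)
}

#' Moment targets for the population model
#'
#' The sufficient statistics the model is fitted to: per-cell per-bin means
#' (conjugate to the fields), and the time-summed second and cross moments
#' (conjugate to `J_ii` and `J_ij`).  Build them from a recorded tensor, or -
#' the sequential-recording route - from marginals plus a predicted pairwise
#' noise-covariance matrix via [moment_targets_from_prediction()].
#'
#' @param mean `N x T` matrix of per-bin means.
#' @param second `N x T` matrix of per-bin second moments `E[n_i(t)^2]`.
#' @param cross_sum `N x N` symmetric matrix of time-summed cross moments
#'   `sum_t E[n_i(t) n_j(t)]` (off-diagonal; the diagonal is ignored and
#'   replaced by the time-summed second moments).
#' @return object of class `moment_targets`.
#' @export
moment_targets <- function(mean, second, cross_sum) {
  mean <- as.matrix(mean); second <- as.matrix(second); cross_sum <- as.matrix(cross_sum)
  if (!all(dim(mean) == dim(second))) stop("`mean` and `second` must share dimensions")
  N <- nrow(mean)
  if (any(dim(cross_sum) != N)) stop("`cross_sum` must be N x N")
  if (any(second < mean^2 - 1e-9)) stop("second moments below squared means")
  diag(cross_sum) <- rowSums(second)
  cross_sum <- (cross_sum + t(cross_sum)) / 2
  structure(list(mean = mean, second = second, cross_sum = cross_sum,
                 n_cells = N, n_bins = ncol(mean)),
            class = "moment_targets")
}

#' Moment targets from a recorded tensor
#' @param tensor a [spike_count_tensor()].
#' @return a [moment_targets()].
#' @export
moment_targets_from_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  mean_ <- rowMeans(tensor$counts, dims = 2L)
  second <- rowMeans(tensor$counts^2, dims = 2L)
  N <- tensor$n_cells
  cross <- matrix(0, N, N)
  for (r in seq_len(tensor$n_reps))
    cross <- cross + tcrossprod(matrix(tensor$counts[, , r], N))
  moment_targets(mean_, second, cross / tensor$n_reps)
}

#' Moment targets from marginals and predicted noise covariances
#'
#' Assembles the fitting targets of the two-stage method: single-cell moments
#' come from the (sequentially recorded) marginals; the pairwise time-summed
#' cross moments come from the copula-predicted noise covariances,
#' `sum_t E[n_i n_j] = T * cov_noise_ij + sum_t mu_i(t) mu_j(t)`.
#'
#' @param marginals an [empirical_marginals()] result.
#' @param cov_noise `N x N` matrix of predicted pairwise noise covariances
#'   (off-diagonal entries used).
#' @return a [moment_targets()].
#' @export
moment_targets_from_prediction <- function(marginals, cov_noise) {
  stopifnot(inherits(marginals, "marginal_set"))
  N <- marginals$n_cells; T_ <- marginals$n_bins
  k <- 0:marginals$n_max
  mean_ <- matrix(0, N, T_); second <- matrix(0, N, T_)
  for (i in seq_len(N)) {
    cm <- marginal_slice(marginals, i)
    mm <- .marginal_moments(cm)
    mean_[i, ] <- mm$mean; second[i, ] <- mm$second
  }
  cross <- T_ * as.matrix(cov_noise) + tcrossprod(mean_)
  moment_targets(mean_, second, cross)
}

#' Fit the population model by iterative moment matching
#'
#' Exponential-family gradient ascent: every parameter moves on its own
#' gradient component, the difference between its target statistic and the
#' current model statistic (per-bin means for the fields; time-summed second
#' and cross moments, expressed per bin, for the couplings).  Steps follow a
#' sign-based adaptive rule (resilient propagation: a step grows by 1.2 while
#' its gradient keeps sign and halves on a sign flip, clipped to
#' `[1e-7, 0.5]`).  Model moments come from exact enumeration when
#' `(n_max+1)^N <= exact_limit`, otherwise from persistent Gibbs chains that
#' survive across iterations.  Iteration starts from the
#' conditionally-independent solution `J = 0`,
#' `h_i(t) = log(max(mu_i(t), 1e-4))`.
#'
#' @param targets a [moment_targets()].
#' @param n_max count cap of the model.
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the largest absolute gradient
#'   component (per-bin moment units).
#' @param exact_limit state-space size up to which enumeration is used.
#' @param n_chains,n_sweeps Gibbs replicas and sweeps per iteration (Gibbs
#'   mode only).
#' @param seed RNG seed (Gibbs mode).
#' @param verbose print progress every 100 iterations.
#' @return a [maxent_model()] with attributes `converged`, `iterations`, and
#'   `trace` (max |gradient| per iteration).
#' @export
fit_maxent <- function(targets, n_max, max_iter = 5000L, tol = 2e-4,
                       exact_limit = 1e6, n_chains = 200L, n_sweeps = 5L,
                       seed = 1L, verbose = FALSE) {
  stopifnot(inherits(targets, "moment_targets"))
  N <- targets$n_cells; T_ <- targets$n_bins
  n_max <- as.integer(n_max)
  if (any(targets$mean > n_max) )
    stop("targets unreachable: a mean exceeds n_max")
  exact <- (n_max + 1)^N <= exact_limit
  h <- log(pmax(targets$mean, 1e-4))
  J <- matrix(0, N, N)
  step_h <- matrix(0.01, N, T_)
  step_J <- matrix(0.01, N, N)
  prev_gh <- matrix(0, N, T_); prev_gJ <- matrix(0, N, N)
  trace <- numeric(0)
  state <- NULL; tbin <- NULL
  if (!exact) {
    set.seed(as.integer(seed))
    tbin <- rep.int(seq_len(T_), n_chains)
    lam <- exp(h[, tbin, drop = FALSE])
    state <- matrix(pmin(stats::rpois(N * length(tbin), pmin(as.vector(lam), 50)), n_max),
                    N, length(tbin))
  }
  model <- maxent_model(h, J, n_max)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    model <- maxent_model(h, J, n_max)
    if (exact) {
      mom <- exact_moments(model)
      m_mean <- mom$mean; m_cross <- mom$cross_sum
    } else {
      for (sw in seq_len(n_sweeps)) state <- .gibbs_sweep(model, state, tbin)
      m_mean <- matrix(0, N, T_); m_cross <- matrix(0, N, N)
      for (t in seq_len(T_)) {
        cols <- which(tbin == t)
        sub <- state[, cols, drop = FALSE]
        m_mean[, t] <- rowMeans(sub)
        m_cross <- m_cross + tcrossprod(sub) / length(cols)
      }
    }
    g_h <- targets$mean - m_mean
    g_J <- (targets$cross_sum - m_cross) / T_
    gmax <- max(max(abs(g_h)), max(abs(g_J)))
    trace[it] <- gmax
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %d: max|grad| = %.3g", it, gmax))
    if (exact && gmax < tol) { converged <- TRUE; break }
    if (!exact && it > 50L && stats::median(utils::tail(trace, 20L)) < tol) {
      converged <- TRUE; break
    }
    # resilient-propagation update
    step_h <- pmin(pmax(step_h * ifelse(g_h * prev_gh > 0, 1.2,
                                        ifelse(g_h * prev_gh < 0, 0.5, 1)), 1e-7), 0.5)
    step_J <- pmin(pmax(step_J * ifelse(g_J * prev_gJ > 0, 1.2,
                                        ifelse(g_J * prev_gJ < 0, 0.5, 1)), 1e-7), 0.5)
    h <- h + step_h * sign(g_h)
    J <- J + step_J * sign(g_J)
    J <- (J + t(J)) / 2
    prev_gh <- g_h; prev_gJ <- g_J
  }
  model <- maxent_model(h, J, n_max)
  attr(model, "converged") <- converged
  attr(model, "iterations") <- it
  attr(model, "trace") <- trace
  if (!converged)
    warning("fit_maxent did not reach tol = ", tol, " after ", it,
            " iterations (max|grad| = ", signif(trace[it], 3), ")")
  model
}

#' Distribution of the population rate
#'
#' `K(t) = sum_i n_i(t)`: total spikes of the population in one bin, pooled
#' over bins and repetitions (or samples).  Optionally restricted to the top
#' fraction of bins by mean population rate (the high-activity transients).
#'
#' @param tensor a [spike_count_tensor()] (recorded, shuffled or sampled).
#' @param top_fraction if non-`NULL`, keep only this fraction of bins with
#'   the highest across-repetition mean population rate (e.g. `0.05`).
#' @return data frame with `k` and `prob` (sums to 1).
#' @export
population_rate_distribution <- function(tensor, top_fraction = NULL) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  K <- apply(tensor$counts, c(2L, 3L), sum)     # T x R
  if (!is.null(top_fraction)) {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    keep <- ceiling(top_fraction * nrow(K))
    ord <- order(rowMeans(K), decreasing = TRUE)
    K <- K[ord[seq_len(keep)], , drop = FALSE]
  }
  tab <- table(factor(K, levels = 0:max(K)))
  data.frame(k = as.integer(names(tab)), prob = as.numeric(tab) / sum(tab))
}

#' Model-predicted triplet noise correlations
#'
#' Monte-Carlo estimate of the triplet noise-correlation statistic under the
#' population model: Gibbs samples play the role of repetitions, per-bin
#' means are the model's own (estimated from the same samples).
#'
#' @param model a [maxent_model()].
#' @param triplets 3-column matrix of cell indices.
#' @param n_samples number of Gibbs samples (chains).
#' @param seed RNG seed.
#' @param n_sweeps sweeps before the single retained sample per chain.
#' @return numeric vector of predicted triplet correlations.
#' @export
predict_triplet_correlations <- function(model, triplets, n_samples = 2000L,
                                         seed = 1L, n_sweeps = 30L) {
  stopifnot(inherits(model, "maxent_model"))
  triplets <- as.matrix(triplets)
  smp <- gibbs_sample(model, n_sweeps = n_sweeps, n_chains = n_samples,
                      burn_in = n_sweeps - 1L, seed = seed)
  vapply(seq_len(nrow(triplets)), function(a)
    triplet_noise_correlation(smp, triplets[a, 1L], triplets[a, 2L], triplets[a, 3L]),
    0)
}

#' Exact triplet noise correlation of an enumerable model
#'
#' Enumeration counterpart of [predict_triplet_correlations()] for small
#' systems: per-bin third central cross moments and total variances are
#' computed from the exact per-bin distribution.
#'
#' @param model an enumerable [maxent_model()].
#' @param i,j,k cell indices.
#' @export
exact_triplet_correlation <- function(model, i, j, k) {
  ed <- exact_distribution(model)
  S <- ed$states; P <- ed$prob
  T_ <- ncol(P)
  mu <- t(crossprod(P, S))                      # N x T
  sec <- t(crossprod(P, S^2))
  idx <- c(i, j, k)
  num <- 0
  for (t in seq_len(T_)) {
    c1 <- S[, i] - mu[i, t]; c2 <- S[, j] - mu[j, t]; c3 <- S[, k] - mu[k, t]
    num <- num + sum(P[, t] * c1 * c2 * c3)
  }
  num <- num / T_
  v <- vapply(idx, function(a) mean(sec[a, ]) - mean(mu[a, ])^2, 0)
  num / sqrt(prod(v))
}
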