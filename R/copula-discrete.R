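#' Discrete joint law from a copula and two count c.d.f.s
#'
#' Sklar construction for integer counts: the joint mass of `(x, y)` is the
#' copula measure of the rectangle
#' `(F_x(x-1), F_x(x)] x (F_y(y-1), F_y(y)]`, obtained by inclusion-exclusion
#' on the copula c.d.f. (`F(-1) = 0`).  Tiny negative masses from floating
#' cancellation are clipped to zero and the table renormalised.
#'
#' @param model a [copula_model()].
#' @param cdf_x,cdf_y non-decreasing c.d.f. vectors over counts `0..n_max`
#'   ending at 1.
#' @return matrix `P` of dimension `length(cdf_x) x length(cdf_y)`;
#'   `P[x+1, y+1] = P(X = x, Y = y)`.
#' @export
discrete_joint_pmf <- function(model, cdf_x, cdf_y) {
  stopifnot(inherits(model, "copula_model"))
  if (any(diff(cdf_x) < -1e-12) || any(diff(cdf_y) < -1e-12))
    stop("marginal cdfs must be non-decreasing")
  if (abs(cdf_x[length(cdf_x)] - 1) > 1e-9 || abs(cdf_y[length(cdf_y)] - 1) > 1e-9)
    stop("marginal cdfs must end at 1")
  Fx <- c(0, pmin(cdf_x, 1)); Fy <- c(0, pmin(cdf_y, 1))
  Cm <- matrix(.cop_cdf(model$family, model$theta,
                        rep(Fx, times = length(Fy)), rep(Fy, each = length(Fx))),
               length(Fx), length(Fy))
  P <- Cm[-1, -1, drop = FALSE] - Cm[-nrow(Cm), -1, drop = FALSE] -
       Cm[-1, -ncol(Cm), drop = FALSE] + Cm[-nrow(Cm), -ncol(Cm), drop = FALSE]
  P[P < 0] <- 0
  P / sum(P)
}

# gather per-observation rectangle corner cdf values for a pair of cells.
# x, y: T x R integer count matrices; cdfx, cdfy: (n_max+1) x T cdf matrices.
# returns the vector of observation masses (length T*R), bins varying fastest.
.obs_rectangle_mass <- function(family, theta, x, y, cdfx, cdfy) {
  T_ <- nrow(x); R <- ncol(x)
  m <- nrow(cdfx)
  tix <- rep.int(seq_len(T_), R)
  off_x <- (tix - 1L) * m
  off_y <- (tix - 1L) * nrow(cdfy)
  xv <- as.vector(x); yv <- as.vector(y)
  Fx_hi <- cdfx[off_x + xv + 1L]
  Fy_hi <- cdfy[off_y + yv + 1L]
  # index 0 (count 0, F(-1) = 0) must not reach `[`, which would drop it
  Fx_lo <- Fy_lo <- numeric(length(xv))
  px <- xv > 0L; Fx_lo[px] <- cdfx[off_x[px] + xv[px]]
  py <- yv > 0L; Fy_lo[py] <- cdfy[off_y[py] + yv[py]]
  p <- .cop_cdf(family, theta, Fx_hi, Fy_hi) - .cop_cdf(family, theta, Fx_lo, Fy_hi) -
       .cop_cdf(family, theta, Fx_hi, Fy_lo) + .cop_cdf(family, theta, Fx_lo, Fy_lo)
  pmax(p, 0)
}

#' Pairwise copula log-likelihood
#'
#' Log-likelihood of the observed count pairs of two cells under the
#' per-time-bin discrete joint laws built from a copula and the cells'
#' per-bin marginal c.d.f.s (a single copula parameter shared across all
#' bins): `sum over bins and repetitions of log P_t(x(t,r), y(t,r))`.
#' Bins where a cell is constant across repetitions contribute the other
#' margin's mass (a theta-independent constant), which the rectangle
#' construction produces automatically.  An observed pair with zero model
#' probability makes the value `-Inf`.
#'
#' @param model a [copula_model()].
#' @param x,y `T x R` integer count matrices for the two cells.
#' @param cdf_x,cdf_y `(n_max+1) x T` per-bin marginal c.d.f. matrices (e.g.
#'   from [marginal_slice()]`$cdf`).
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
pair_log_likelihood <- function(model, x, y, cdf_x, cdf_y) {
  stopifnot(inherits(model, "copula_model"))
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("`x` and `y` must have identical dimensions")
  if (ncol(cdf_x) != nrow(x) || ncol(cdf_y) != nrow(x))
    stop("cdf matrices must have one column per time bin")
  p <- .obs_rectangle_mass(model$family, model$theta, x, y, cdf_x, cdf_y)
  sum(log(p))
}

# bins where both cells vary across repetitions
.informative_bins <- function(x, y) {
  vx <- apply(x, 1L, function(r) any(r != r[1L]))
  vy <- apply(y, 1L, function(r) any(r != r[1L]))
  which(vx & vy)
}

#' Maximum-likelihood fit of a copula parameter for one cell pair
#'
#' Maximises [pair_log_likelihood()] over the family's parameter domain by
#' derivative-free bounded search on a transformed parameter
#' (Gumbel: `log(theta - 1)`, Gaussian: `atanh(theta)`, Clayton: `log(theta)`
#' on the positive branch with the negative branch `(-1, 0)` searched
#' separately and the better optimum kept, Frank: untransformed).  The Gumbel
#' boundary `theta = 1` (independence) is considered explicitly.
#'
#' @param family copula family name.
#' @param x,y `T x R` count matrices.
#' @param cdf_x,cdf_y per-bin marginal c.d.f. matrices.
#' @param tol optimisation tolerance on the transformed parameter.
#' @return list with `family`, `theta`, `loglik`, `converged`, `n_informative`
#'   (number of bins where both cells vary).
#' @export
fit_copula_parameter <- function(family, x, y, cdf_x, cdf_y, tol = 1e-6) {
  x <- as.matrix(x); y <- as.matrix(y)
  info <- .informative_bins(x, y)
  if (length(info) < 1L)
    stop("no informative bins: both cells are deterministic in every bin")
  ll <- function(theta) {
    # floor at a large negative finite value: extreme parameters visited by
    # the optimiser can put zero mass on an observed pair (-Inf), which the
    # optimiser cannot compare
    v <- pair_log_likelihood(copula_model(family, theta), x, y, cdf_x, cdf_y)
    if (is.finite(v)) v else -1e300
  }
  if (family == "independent") {
    mod <- copula_model("independent")
    return(list(family = family, theta = NA_real_,
                loglik = pair_log_likelihood(mod, x, y, cdf_x, cdf_y),
                converged = TRUE, n_informative = length(info)))
  }
  res <- switch(family,
    gumbel = {
      o <- stats::optimize(function(s) ll(1 + exp(s)), c(log(1e-6), log(99)),
                           maximum = TRUE, tol = tol)
      ll1 <- ll(1)
      if (ll1 >= o$objective) list(theta = 1, loglik = ll1)
      else list(theta = 1 + exp(o$maximum), loglik = o$objective)
    },
    gaussian = {
      o <- stats::optimize(function(s) ll(tanh(s)), c(-6, 6), maximum = TRUE, tol = tol)
      list(theta = tanh(o$maximum), loglik = o$objective)
    },
    frank = {
      o <- stats::optimize(ll, c(-100, 100), maximum = TRUE, tol = 1e-4)
      list(theta = o$maximum, loglik = o$objective)
    },
    clayton = {
      op <- stats::optimize(function(s) ll(exp(s)), c(log(1e-6), log(50)),
                            maximum = TRUE, tol = tol)
      on <- stats::optimize(ll, c(-1 + 1e-6, -1e-6), maximum = TRUE, tol = tol)
      if (op$objective >= on$objective) list(theta = exp(op$maximum), loglik = op$objective)
      else list(theta = on$maximum, loglik = on$objective)
    },
    stop("unknown family: ", family))
  list(family = family, theta = res$theta, loglik = res$loglik,
       converged = is.finite(res$loglik) && res$loglik > -1e299,
       n_informative = length(info))
}

#' Sample integer count pairs through a copula
#'
#' Draws `(u1, u2)` from the copula and maps each through the generalised
#' inverse `F^{-1}(u) = min{k : F(k) >= u}` of the corresponding count
#' c.d.f., so the empirical joint of many samples converges to
#' [discrete_joint_pmf()].
#'
#' @param model a [copula_model()].
#' @param cdf_x,cdf_y count c.d.f. vectors over `0..n_max`.
#' @param n number of pairs.
#' @param seed optional integer RNG seed.
#' @return `n x 2` integer matrix of counts.
#' @export
sample_pair <- function(model, cdf_x, cdf_y, n, seed = NULL) {
  u <- copula_sample_uniforms(model, n, seed)
  cbind(x = findInterval(u[, 1L], cdf_x, left.open = TRUE),
        y = findInterval(u[, 2L], cdf_y, left.open = TRUE))
}

#' Mean per-bin Kullback-Leibler divergence, empirical joint vs copula model
#'
#' For each time bin, the plug-in KL divergence between the empirical joint
#' distribution of the two cells' counts across repetitions and the model's
#' discrete joint law, restricted to the empirical support; averaged over
#' bins.  Bins where both cells are constant contribute 0.
#'
#' @inheritParams pair_log_likelihood
#' @return mean KL divergence in nats (>= 0 up to estimation error).
#' @export
kl_empirical_vs_model <- function(model, x, y, cdf_x, cdf_y) {
  x <- as.matrix(x); y <- as.matrix(y)
  T_ <- nrow(x); R <- ncol(x)
  kl <- numeric(T_)
  for (t in seq_len(T_)) {
    xs <- x[t, ]; ys <- y[t, ]
    if (all(xs == xs[1L]) && all(ys == ys[1L])) next   # degenerate bin
    tab <- table(xs, ys) / R
    P <- discrete_joint_pmf(model, cdf_x[, t], cdf_y[, t])
    xv <- as.integer(rownames(tab)); yv <- as.integer(colnames(tab))
    pm <- P[cbind(rep(xv + 1L, times = length(yv)), rep(yv + 1L, each = length(xv)))]
    pe <- as.vector(tab)
    keep <- pe > 0
    kl[t] <- sum(pe[keep] * (log(pe[keep]) - log(pm[keep])))
  }
  mean(kl)
}

#' Rank copula families on a recorded population
#'
#' Fits every requested family to every cell pair by maximum likelihood,
#' scores each with the mean per-bin KL divergence to the empirical joint and
#' with the log-likelihood, and returns per-family averages over pairs,
#' ranked by mean KL (winner first).  Pairs where a fit fails are propagated
#' as missing and excluded from that family's averages.
#'
#' @param tensor a [spike_count_tensor()].
#' @param families character vector of family names.
#' @param pairs optional 2-column matrix of cell indices; defaults to all
#'   unordered pairs.
#' @param marginals optional [empirical_marginals()] of `tensor` (recomputed
#'   if omitted).
#' @return data frame with `family`, `mean_kl`, `mean_loglik`, `n_pairs`,
#'   sorted by `mean_kl`.
#' @export
select_family <- function(tensor, families = c("independent", "gaussian", "gumbel",
                                               "frank", "clayton"),
                          pairs = NULL, marginals = NULL) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (is.null(marginals)) marginals <- empirical_marginals(tensor)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(tensor$n_cells, 2L))
  }
  if (nrow(pairs) < 1L) stop("at least one pair required")
  cms <- lapply(seq_len(tensor$n_cells), function(i) marginal_slice(marginals, i))
  counts <- lapply(seq_len(tensor$n_cells),
                   function(i) matrix(tensor$counts[i, , ], tensor$n_bins))
  rows <- lapply(families, function(fam) {
    kls <- lls <- rep(NA_real_, nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      fit <- tryCatch(fit_copula_parameter(fam, counts[[i]], counts[[j]],
                                           cms[[i]]$cdf, cms[[j]]$cdf),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$loglik)) next
      mod <- if (fam == "independent") copula_model("independent")
             else copula_model(fam, fit$theta)
      lls[p] <- fit$loglik
      kls[p] <- kl_empirical_vs_model(mod, counts[[i]], counts[[j]],
                                      cms[[i]]$cdf, cms[[j]]$cdf)
    }
    data.frame(family = fam, mean_kl = mean(kls, na.rm = TRUE),
               mean_loglik = mean(lls, na.rm = TRUE), n_pairs = sum(is.finite(kls)))
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_kl), , drop = FALSE]
}
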