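#' Distance law for the copula parameter
#'
#' Three-parameter law mapping the distance between two receptive-field
#' centres to a Gumbel copula parameter:
#' `theta(d) = exp(exp(a + b d + c d^2))` for `d <= cutoff`, and independence
#' (`theta = 1`, the Gumbel independence point) beyond the cutoff.  The
#' double exponential guarantees `theta(d) > 1` inside the cutoff.  Reference
#' coefficients for rat OFF-alpha retinal ganglion cells under checkerboard
#' stimulation: `a = 0.73`, `b = -0.014` per um, `c = 8e-6` per um^2, cutoff
#' 1 mm.
#'
#' @param a dimensionless intercept.
#' @param b linear coefficient, 1/um.
#' @param c quadratic coefficient, 1/um^2.
#' @param cutoff_um cutoff distance in um beyond which pairs are independent.
#' @param family copula family the law parameterises (default `"gumbel"`).
#' @return object of class `theta_distance_model`.
#' @export
theta_distance_model <- function(a, b, c, cutoff_um = 1000, family = "gumbel") {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), cutoff_um > 0)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 cutoff_um = as.numeric(cutoff_um), family = family),
            class = "theta_distance_model")
}

#' @export
print.theta_distance_model <- function(x, ...) {
  cat(sprintf("theta_distance_model (%s): theta(d) = exp(exp(%.4g %+.4g d %+.4g d^2)), independence beyond %g um\n",
              x$family, x$a, x$b, x$c, x$cutoff_um))
  invisible(x)
}

#' Evaluate the distance law
#'
#' @param model a [theta_distance_model()].
#' @param d distance(s) in um, `>= 0`.
#' @return theta value(s); exactly 1 (independence) beyond the cutoff.
#' @export
theta_of_distance <- function(model, d) {
  stopifnot(inherits(model, "theta_distance_model"))
  if (any(d < 0)) stop("distances must be non-negative")
  th <- exp(exp(model$a + model$b * d + model$c * d^2))
  th[d > model$cutoff_um] <- 1
  th
}

#' Fit the distance law to per-pair copula parameters
#'
#' Unweighted least squares of the quadratic `a + b d + c d^2` against
#' `log(log theta_ij)` over pairs with `d <= cutoff` (pairs at the
#' independence boundary, `theta <= 1`, carry no log-log value and are
#' dropped; pairs beyond the cutoff are excluded by construction).
#'
#' @param theta per-pair fitted copula parameters.
#' @param d per-pair distances in um.
#' @param cutoff_um cutoff for the fitted model.
#' @return a [theta_distance_model()] with attributes `fit` (the `lm` object)
#'   and `n_pairs`.
#' @export
fit_theta_distance <- function(theta, d, cutoff_um = 1000) {
  if (length(theta) != length(d)) stop("`theta` and `d` must have equal length")
  use <- is.finite(theta) & is.finite(d) & d <= cutoff_um & theta > 1
  if (sum(use) < 3L)
    stop("need at least 3 pairs with d <= cutoff and theta > 1 (got ", sum(use), ")")
  y <- log(log(theta[use])); x <- d[use]
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  out <- theta_distance_model(cf[[1L]], cf[[2L]], cf[[3L]], cutoff_um = cutoff_um)
  attr(out, "fit") <- fit
  attr(out, "n_pairs") <- sum(use)
  out
}

# per-bin E[X Y] under copula(theta) for marginal cdf matrices ((n_max+1) x T),
# via the survival identity E[XY] = sum_{x,y>=0} P(X > x, Y > y)
#   P(X > x, Y > y) = 1 - Fx(x) - Fy(y) + C(Fx(x), Fy(y)).
# theta is scalar here; returns length-T vector.
.pair_cross_moment <- function(family, theta, cdf_x, cdf_y) {
  T_ <- ncol(cdf_x)
  mx <- nrow(cdf_x) - 1L; my <- nrow(cdf_y) - 1L
  out <- numeric(T_)
  for (a in seq_len(mx)) {
    Fx <- cdf_x[a, ]
    for (b in seq_len(my)) {
      Fy <- cdf_y[b, ]
      out <- out + 1 - Fx - Fy + .cop_cdf(family, theta, Fx, Fy)
    }
  }
  out
}

# same identity, vectorised over a vector of thetas for one shared pair of
# marginal cdf matrices: returns the T-bin *average* cross moment per theta.
.cross_moment_by_theta <- function(family, thetas, cdf_x, cdf_y) {
  T_ <- ncol(cdf_x)
  mx <- nrow(cdf_x) - 1L; my <- nrow(cdf_y) - 1L
  acc <- numeric(length(thetas))
  for (t in seq_len(T_)) {
    for (a in seq_len(mx)) {
      Fx <- cdf_x[a, t]
      if (Fx >= 1) next
      for (b in seq_len(my)) {
        Fy <- cdf_y[b, t]
        if (Fy >= 1) next
        acc <- acc + (1 - Fx - Fy + .cop_cdf(family, thetas, Fx, Fy))
      }
    }
  }
  acc / T_
}

#' Predict pairwise statistics from marginals and distance alone
#'
#' The sequential-recording predictor: given only the two cells' per-bin
#' marginal count distributions and the distance between them (never a joint
#' recording), builds the per-bin discrete joint laws with the distance-law
#' copula parameter and returns the implied noise covariance and noise
#' correlation.  Covariance follows the noise-covariance estimator with model
#' expectations, `1/T sum_t (E[XY](t) - mu_x(t) mu_y(t))`; the correlation is
#' normalised by the marginals' total variances.  Beyond the cutoff the
#' prediction is exactly zero.
#'
#' @param marginal_x,marginal_y [marginal_slice()] objects for the two cells.
#' @param d distance between the cells in um.
#' @param model a [theta_distance_model()].
#' @param joint_laws if `TRUE`, also return the list of per-bin joint pmf
#'   matrices.
#' @return list with `theta`, `cov_noise`, `corr_noise`, `per_bin_cov`, and
#'   optionally `joint_laws`.
#' @export
predict_pair_statistics <- function(marginal_x, marginal_y, d, model,
                                    joint_laws = FALSE) {
  stopifnot(inherits(marginal_x, "cell_marginal"), inherits(marginal_y, "cell_marginal"),
            inherits(model, "theta_distance_model"))
  if (marginal_x$n_bins != marginal_y$n_bins) stop("marginals must share time bins")
  th <- theta_of_distance(model, d)
  mmx <- .marginal_moments(marginal_x); mmy <- .marginal_moments(marginal_y)
  exy <- .pair_cross_moment(model$family, th, marginal_x$cdf, marginal_y$cdf)
  per_bin_cov <- exy - mmx$mean * mmy$mean
  cov_noise <- mean(per_bin_cov)
  vx <- mean(mmx$second) - mean(mmx$mean)^2    # total variances, Eq-5 normaliser
  vy <- mean(mmy$second) - mean(mmy$mean)^2
  corr_noise <- if (vx > 0 && vy > 0) cov_noise / sqrt(vx * vy) else NA_real_
  out <- list(theta = th, cov_noise = cov_noise, corr_noise = corr_noise,
              per_bin_cov = per_bin_cov)
  if (joint_laws) {
    cm <- copula_model(model$family, th)
    out$joint_laws <- lapply(seq_len(marginal_x$n_bins), function(t)
      discrete_joint_pmf(cm, marginal_x$cdf[, t], marginal_y$cdf[, t]))
  }
  out
}

#' Predict noise correlations for every pair of a population
#'
#' Applies [predict_pair_statistics()] to all unordered pairs of a marginal
#' set given the cell geometry, returning a tidy table.
#'
#' @param marginals an [empirical_marginals()] result.
#' @param geometry a [cell_geometry()] covering the same cells.
#' @param model a [theta_distance_model()].
#' @return data frame with `cell_i`, `cell_j`, `distance_um`, `theta`,
#'   `cov_noise`, `corr_noise`.
#' @export
predict_population_pairs <- function(marginals, geometry, model) {
  stopifnot(inherits(marginals, "marginal_set"))
  geometry <- geometry[match(marginals$cell_ids, geometry$cell_id), , drop = FALSE]
  if (anyNA(geometry$cell_id))
    stop("geometry does not cover all cells of the marginal set")
  dm <- pair_distances(cell_geometry(geometry$cell_id, geometry$x_um, geometry$y_um))
  cms <- lapply(seq_len(marginals$n_cells), function(i) marginal_slice(marginals, i))
  pr <- t(utils::combn(marginals$n_cells, 2L))
  res <- lapply(seq_len(nrow(pr)), function(p) {
    i <- pr[p, 1L]; j <- pr[p, 2L]
    st <- predict_pair_statistics(cms[[i]], cms[[j]], dm[i, j], model)
    data.frame(cell_i = marginals$cell_ids[i], cell_j = marginals$cell_ids[j],
               distance_um = dm[i, j], theta = st$theta,
               cov_noise = st$cov_noise, corr_noise = st$corr_noise)
  })
  do.call(rbind, res)
}
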