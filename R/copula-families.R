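#' Parametric bivariate copula model
#'
#' A copula is a joint c.d.f. on the unit square with uniform marginals; by
#' Sklar's construction it carries the dependence of a bivariate law
#' separately from the marginals.  Families implemented (with parameter
#' domains): Gumbel (`theta in [1, Inf)`), Gaussian (`theta in [-1, 1]`),
#' Frank (`theta` real), Clayton (`theta in [-1, Inf) \ {0}`), and the
#' parameter-free independent copula `C(u, v) = u v`.
#'
#' @param family one of `"gumbel"`, `"gaussian"`, `"frank"`, `"clayton"`,
#'   `"independent"`.
#' @param theta copula parameter (ignored for `"independent"`).
#' @return object of class `copula_model`.
#' @export
copula_model <- function(family = c("gumbel", "gaussian", "frank", "clayton",
                                    "independent"), theta = NULL) {
  family <- match.arg(family)
  if (family == "independent") {
    theta <- NA_real_
  } else {
    if (is.null(theta) || !is.finite(theta)) stop("`theta` required for family ", family)
    .check_theta(family, theta)
  }
  structure(list(family = family, theta = as.numeric(theta)), class = "copula_model")
}

.check_theta <- function(family, theta) {
  ok <- switch(family,
               gumbel = theta >= 1,
               gaussian = theta >= -1 && theta <= 1,
               frank = TRUE,
               clayton = theta >= -1 && theta != 0,
               independent = TRUE)
  if (!ok) stop("theta = ", theta, " outside the ", family, " domain")
  invisible(TRUE)
}

#' @export
print.copula_model <- function(x, ...) {
  cat(sprintf("copula_model: %s%s\n", x$family,
              if (is.na(x$theta)) "" else sprintf(" (theta = %.6g)", x$theta)))
  invisible(x)
}

# interior clip: family formulas are evaluated away from 0/1, exact boundary
# values are patched afterwards
.EPS_U <- 1e-12

# vectorised copula cdf; u, v, theta recycled to common length
.cop_cdf <- function(family, theta, u, v) {
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  if (any(u < 0 | u > 1 | v < 0 | v > 1, na.rm = TRUE))
    stop("u, v must lie in [0, 1]")
  out <- numeric(n)
  lo <- u <= 0 | v <= 0
  hi_u <- !lo & v >= 1
  hi_v <- !lo & u >= 1 & v < 1
  mid <- !(lo | hi_u | hi_v)
  out[lo] <- 0
  out[hi_u] <- u[hi_u]
  out[hi_v] <- v[hi_v]
  if (any(mid)) {
    uc <- pmin(pmax(u[mid], .EPS_U), 1 - .EPS_U)
    vc <- pmin(pmax(v[mid], .EPS_U), 1 - .EPS_U)
    th <- theta[mid]
    out[mid] <- switch(family,
      independent = uc * vc,
      gumbel = {
        w <- ifelse(th == 1, uc * vc,
                    exp(-((-log(uc))^th + (-log(vc))^th)^(1 / th)))
        w
      },
      frank = ifelse(abs(th) < 1e-8, uc * vc,
                     -log1p((expm1(-th * uc) * expm1(-th * vc)) / expm1(-th)) / th),
      clayton = ifelse(abs(th) < 1e-12, uc * vc,
                       pmax(uc^(-th) + vc^(-th) - 1, 0)^(-1 / th)),
      gaussian = .gauss_cdf(uc, vc, th),
      stop("unknown family: ", family))
  }
  out
}

# bivariate normal cdf at (qnorm(u), qnorm(v)) with correlation theta
.gauss_cdf <- function(u, v, theta) {
  n <- length(u)
  out <- numeric(n)
  z0 <- abs(theta) < 1e-12
  out[z0] <- u[z0] * v[z0]
  co <- theta >= 1 - 1e-12
  out[co] <- pmin(u[co], v[co])
  ct <- theta <= -1 + 1e-12
  out[ct] <- pmax(u[ct] + v[ct] - 1, 0)
  rest <- which(!(z0 | co | ct))
  if (length(rest)) {
    x <- stats::qnorm(u[rest]); y <- stats::qnorm(v[rest]); th <- theta[rest]
    out[rest] <- vapply(seq_along(rest), function(a) {
      mvtnorm::pmvnorm(upper = c(x[a], y[a]),
                       corr = matrix(c(1, th[a], th[a], 1), 2),
                       algorithm = mvtnorm::Miwa(steps = 128))[1]
    }, 0)
  }
  out
}

#' Evaluate a copula c.d.f.
#'
#' `C(u, v | theta)` for the model's family, vectorised over `u`, `v`.
#' Boundary values are exact: `C(u, 0) = C(0, v) = 0`, `C(u, 1) = u`,
#' `C(1, v) = v`; interior arguments are clipped to
#' `[1e-12, 1 - 1e-12]` inside the family formulas for numerical safety.
#'
#' @param model a [copula_model()].
#' @param u,v numeric vectors in `[0, 1]` (recycled).
#' @export
copula_cdf <- function(model, u, v) {
  stopifnot(inherits(model, "copula_model"))
  .cop_cdf(model$family, model$theta, u, v)
}

# conditional cdf h(v | u) = dC/du, vectorised; used by the
# conditional-distribution (inverse Rosenblatt) sampler
.cop_hfun <- function(family, theta, u, v) {
  n <- max(length(u), length(v))
  u <- pmin(pmax(rep_len(u, n), .EPS_U), 1 - .EPS_U)
  v <- pmin(pmax(rep_len(v, n), .EPS_U), 1 - .EPS_U)
  th <- theta
  switch(family,
    independent = v,
    gumbel = {
      if (th == 1) return(v)
      lu <- -log(u); lv <- -log(v)
      s <- lu^th + lv^th
      exp(-s^(1 / th)) * s^(1 / th - 1) * lu^(th - 1) / u
    },
    frank = {
      if (abs(th) < 1e-8) return(v)
      eu <- expm1(-th * u); ev <- expm1(-th * v)
      eu1 <- exp(-th * u)
      eu1 * ev / (expm1(-th) + eu * ev)
    },
    clayton = {
      if (abs(th) < 1e-12) return(v)
      s <- pmax(u^(-th) + v^(-th) - 1, 0)
      ifelse(s > 0, u^(-th - 1) * s^(-1 / th - 1), if (th > 0) 0 else 1)
    },
    gaussian = {
      x <- stats::qnorm(u); y <- stats::qnorm(v)
      stats::pnorm((y - th * x) / sqrt(1 - th^2))
    },
    stop("unknown family: ", family))
}

# invert w = h(v | u) for v by bisection (h is nondecreasing in v)
.cop_hinv <- function(family, theta, u, w, tol = 1e-10) {
  lo <- rep_len(.EPS_U, length(w)); hi <- rep_len(1 - .EPS_U, length(w))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    too_low <- .cop_hfun(family, theta, u, mid) < w
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Sample pairs of uniforms from a copula
#'
#' Gaussian pairs come from a latent bivariate normal; Archimedean families
#' use the conditional-distribution method (draw `u1`, then invert the
#' conditional c.d.f. `h(v | u1)` at an independent uniform), with numeric
#' inversion to 1e-10.  Clayton with `theta > 0` uses its closed-form
#' conditional inverse.
#'
#' @param model a [copula_model()].
#' @param n number of pairs.
#' @param seed optional integer RNG seed.
#' @return `n x 2` matrix of uniforms.
#' @export
copula_sample_uniforms <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "copula_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fam <- model$family; th <- model$theta
  u1 <- stats::runif(n)
  if (fam == "independent" || (fam == "gumbel" && th == 1) ||
      (fam == "frank" && abs(th) < 1e-8))
    return(cbind(u1, stats::runif(n)))
  if (fam == "gaussian") {
    z1 <- stats::qnorm(u1)
    z2 <- th * z1 + sqrt(1 - th^2) * stats::rnorm(n)
    return(cbind(u1, stats::pnorm(z2)))
  }
  w <- stats::runif(n)
  if (fam == "clayton" && th > 0) {
    v <- ((w^(-th / (1 + th)) - 1) * u1^(-th) + 1)^(-1 / th)
    return(cbind(u1, v))
  }
  cbind(u1, .cop_hinv(fam, th, u1, w))
}
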