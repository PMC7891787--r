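#' Synthetic receptive-field mosaic
#'
#' Positions cells on a jittered triangular lattice, the canonical geometry
#' of a same-type retinal ganglion cell mosaic.  Rows are spaced
#' `side * sqrt(3)/2` apart with alternate rows offset by half a side; sites
#' are filled row-wise up to `n_cells`, centred on the origin, then
#' independent Gaussian jitter is added to each coordinate.  Defaults (side
#' 194 um, jitter sd 22 um) reproduce the inter-cell distance statistics of
#' recorded OFF-alpha mosaics.
#'
#' @param n_cells number of cells.
#' @param side_um lattice side in um.
#' @param jitter_sd_um Gaussian jitter standard deviation in um.
#' @param seed integer RNG seed.
#' @return a [cell_geometry()].
#' @export
generate_lattice <- function(n_cells, side_um = 194, jitter_sd_um = 22, seed = 1L) {
  stopifnot(n_cells >= 1)
  set.seed(as.integer(seed))
  ncol_ <- ceiling(sqrt(n_cells))
  nrow_ <- ceiling(n_cells / ncol_)
  row <- rep(seq_len(nrow_) - 1L, each = ncol_)[seq_len(n_cells)]
  col <- rep(seq_len(ncol_) - 1L, times = nrow_)[seq_len(n_cells)]
  x <- (col + 0.5 * (row %% 2L)) * side_um
  y <- row * side_um * sqrt(3) / 2
  x <- x - mean(x); y <- y - mean(y)
  x <- x + stats::rnorm(n_cells, 0, jitter_sd_um)
  y <- y + stats::rnorm(n_cells, 0, jitter_sd_um)
  cell_geometry(paste0("site_", seq_len(n_cells)), x, y)
}

#' Assemble a large population from pooled single-cell marginals
#'
#' Associates to each mosaic site the per-bin marginal distributions of a
#' randomly chosen library cell (uniform with replacement), then predicts
#' every within-cutoff pairwise noise covariance from the distance-law copula
#' alone; pairs beyond the cutoff get exactly zero.  Pairs sharing the same
#' ordered library assignment are evaluated together, vectorised over their
#' copula parameters.
#'
#' @param geometry a [cell_geometry()] (e.g. from [generate_lattice()]).
#' @param marginal_library list of [marginal_slice()] objects (the pooled
#'   single-cell responses); all must share `n_bins`.
#' @param model a [theta_distance_model()].
#' @param seed RNG seed for the site assignment.
#' @return object of class `population_model`: list with `geometry`,
#'   `assignment` (library index per site), `library`, `distance_model`,
#'   `cov_noise` (`N x N` predicted noise-covariance matrix, diagonal = each
#'   site's marginal noise variance), `distances`.
#' @export
assemble_population <- function(geometry, marginal_library, model, seed = 1L) {
  stopifnot(inherits(geometry, "cell_geometry"), inherits(model, "theta_distance_model"))
  if (!length(marginal_library)) stop("`marginal_library` must be non-empty")
  T_ <- marginal_library[[1L]]$n_bins
  if (!all(vapply(marginal_library, function(m) m$n_bins, 0L) == T_))
    stop("all library marginals must share the number of bins")
  set.seed(as.integer(seed))
  N <- nrow(geometry)
  assignment <- sample.int(length(marginal_library), N, replace = TRUE)
  dm <- pair_distances(geometry)
  pop <- structure(list(geometry = geometry, assignment = assignment,
                        library = marginal_library, distance_model = model,
                        distances = dm, n_cells = N, n_bins = T_),
                   class = "population_model")
  pop$cov_noise <- population_covariances(pop)
  pop
}

#' Predicted pairwise noise-covariance matrix of an assembled population
#'
#' Recomputes the full `N x N` noise-covariance matrix, optionally rescaling
#' the distance fed to the copula-parameter law: `theta(d / factor)`, so
#' `factor = 2` stretches the correlation structure to twice the spatial
#' scale and `factor = 0.5` compresses it (the independence cutoff scales
#' along).  `independent = TRUE` zeroes all off-diagonal terms (the
#' conditionally-independent control).
#'
#' @param pop a `population_model` from [assemble_population()].
#' @param length_scale_factor spatial rescaling of the correlation law.
#' @param independent if `TRUE`, return the diagonal-only control.
#' @return `N x N` symmetric covariance matrix.
#' @export
population_covariances <- function(pop, length_scale_factor = 1, independent = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  model <- pop$distance_model
  N <- pop$n_cells
  mm <- lapply(pop$library, .marginal_moments)
  # diagonal: per-site marginal noise variance, mean_t Var(n(t))
  nv <- vapply(mm, function(m) mean(m$second - m$mean^2), 0)
  covm <- diag(nv[pop$assignment], N)
  if (!independent) {
    pr <- which(upper.tri(pop$distances), arr.ind = TRUE)
    d_eff <- pop$distances[pr] / length_scale_factor
    th <- theta_of_distance(model, d_eff)
    act <- which(th > 1)
    if (length(act)) {
      li <- pop$assignment[pr[act, 1L]]
      lj <- pop$assignment[pr[act, 2L]]
      key <- paste(pmin(li, lj), pmax(li, lj))
      for (k in unique(key)) {
        sel <- which(key == k)
        a <- li[sel[1L]]; b <- lj[sel[1L]]   # cross moment is symmetric in (a, b)
        exy <- .cross_moment_by_theta(model$family, th[act][sel],
                                      pop$library[[a]]$cdf, pop$library[[b]]$cdf)
        cv <- exy - mean(mm[[a]]$mean * mm[[b]]$mean)
        ii <- pr[act[sel], 1L]; jj <- pr[act[sel], 2L]
        covm[cbind(ii, jj)] <- cv
        covm[cbind(jj, ii)] <- cv
      }
    }
  }
  covm
}

#' Cells inside a circular patch
#'
#' @param geometry a [cell_geometry()].
#' @param center numeric length-2 `(x, y)` in um.
#' @param radius_um patch radius (boundary inclusive).
#' @return integer vector of cell indices.
#' @export
circular_subsample <- function(geometry, center, radius_um) {
  stopifnot(inherits(geometry, "cell_geometry"), radius_um >= 0)
  d <- sqrt((geometry$x_um - center[1L])^2 + (geometry$y_um - center[2L])^2)
  which(d <= radius_um)
}

#' Population synchrony
#'
#' The time-averaged across-repetition variance of the population rate per
#' cell, `(1/N) <Var K(t)>_t` with `K(t) = sum_i n_i(t)`, which equals the
#' mean sum of all pairwise noise covariances (diagonal included).  Two
#' routes: from a recorded/sampled tensor (variance route, 1/R
#' normalisation), or from a noise-covariance matrix and a subset of cells
#' (covariance-sum route); the two agree exactly on the same data.
#'
#' @param x a [spike_count_tensor()] or an `N x N` noise-covariance matrix.
#' @param subset cell indices (matrix route only; default all).
#' @return synchrony in squared counts per cell per bin.
#' @export
synchrony <- function(x, subset = NULL) {
  if (inherits(x, "spike_count_tensor")) {
    if (!is.null(subset)) {
      x <- spike_count_tensor(x$counts[subset, , , drop = FALSE], x$bin_width_ms,
                              x$cell_ids[subset])
    }
    K <- apply(x$counts, c(2L, 3L), sum)        # T x R
    vt <- rowMeans(K^2) - rowMeans(K)^2         # 1/R variance per bin
    return(mean(vt) / x$n_cells)
  }
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("`x` must be a tensor or a square covariance matrix")
  if (is.null(subset)) subset <- seq_len(nrow(x))
  if (!length(subset)) stop("empty cell subset")
  sum(x[subset, subset]) / length(subset)
}

#' Synchrony versus patch size on a mosaic
#'
#' For each radius, draws `n_centers` patch centres uniformly over the
#' central region of the mosaic (eroded by `min(max(radii), a quarter of the
#' smaller mosaic extent)` to limit edge truncation), collects the cells in
#' each circular patch and evaluates the covariance-sum synchrony; returns
#' per-radius averages.  `length_scale_factor` stretches (`2`) or compresses
#' (`0.5`) the spatial scale of the correlation law; `independent = TRUE`
#' gives the flat conditionally-independent control.
#'
#' @param pop a `population_model` from [assemble_population()].
#' @param radii_um increasing patch radii in um.
#' @param n_centers patch centres averaged per radius.
#' @param seed RNG seed for the centre draw.
#' @param length_scale_factor see [population_covariances()].
#' @param independent see [population_covariances()].
#' @return `synchrony_curve`: data frame with `radius_um`, `n_cells` (mean
#'   patch occupancy), `synchrony` (mean over centres), `n_patches`.
#' @export
synchrony_scan <- function(pop, radii_um, n_centers = 20L, seed = 1L,
                           length_scale_factor = 1, independent = FALSE) {
  stopifnot(inherits(pop, "population_model"))
  if (is.unsorted(radii_um)) stop("`radii_um` must be sorted ascending")
  covm <- if (length_scale_factor == 1 && !independent) pop$cov_noise
          else population_covariances(pop, length_scale_factor, independent)
  g <- pop$geometry
  set.seed(as.integer(seed))
  margin <- min(max(radii_um),
                0.25 * min(diff(range(g$x_um)), diff(range(g$y_um))))
  cx <- stats::runif(n_centers, min(g$x_um) + margin, max(g$x_um) - margin)
  cy <- stats::runif(n_centers, min(g$y_um) + margin, max(g$y_um) - margin)
  rows <- lapply(radii_um, function(r) {
    syn <- nc <- rep(NA_real_, n_centers)
    for (a in seq_len(n_centers)) {
      s <- circular_subsample(g, c(cx[a], cy[a]), r)
      if (!length(s)) next
      syn[a] <- synchrony(covm, s)
      nc[a] <- length(s)
    }
    data.frame(radius_um = r, n_cells = mean(nc, na.rm = TRUE),
               synchrony = mean(syn, na.rm = TRUE),
               n_patches = sum(is.finite(syn)))
  })
  structure(do.call(rbind, rows), class = c("synchrony_curve", "data.frame"))
}

#' Saturation point of a synchrony curve
#'
#' Operationalises "the curve saturates": the smallest scanned radius whose
#' synchrony reaches `level` times the asymptote, the asymptote being the
#' value at the largest scanned radius.
#'
#' @param curve a `synchrony_curve` from [synchrony_scan()].
#' @param level fraction of the asymptote (default 0.95).
#' @return list with `radius_um`, `n_cells` (mean patch occupancy at that
#'   radius), `synchrony`, `asymptote`, `level`.
#' @export
saturation_point <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "synchrony_curve"), level > 0, level <= 1)
  ok <- is.finite(curve$synchrony)
  cv <- curve[ok, , drop = FALSE]
  asym <- cv$synchrony[nrow(cv)]
  hit <- which(cv$synchrony >= level * asym)
  if (!length(hit)) stop("curve never reaches the saturation level")
  i <- hit[1L]
  list(radius_um = cv$radius_um[i], n_cells = cv$n_cells[i],
       synchrony = cv$synchrony[i], asymptote = asym, level = level)
}
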