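#' Spike-count tensor
#'
#' Container for binned spike counts `n_i(t, r)` indexed by cell, time bin and
#' stimulus repetition.  This is the central data object of the package: all
#' correlation estimators, copula fits and population models consume it.
#'
#' @param counts non-negative integer array of dimension
#'   `n_cells x n_bins x n_reps`.
#' @param bin_width_ms width of the time bin in milliseconds (> 0).
#' @param cell_ids character vector of cell identifiers, one per row of
#'   `counts`.  Defaults to `"cell_1" ... "cell_N"`.
#'
#' @return An object of class `spike_count_tensor`: a list with elements
#'   `counts`, `bin_width_ms`, `cell_ids`, `n_cells`, `n_bins`, `n_reps`.
#' @export
spike_count_tensor <- function(counts, bin_width_ms, cell_ids = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (cell x bin x repetition)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must contain non-negative integers")
  if (!is.numeric(bin_width_ms) || length(bin_width_ms) != 1L || bin_width_ms <= 0)
    stop("`bin_width_ms` must be a single positive number")
  d <- dim(counts)
  if (any(d < 1L)) stop("all tensor dimensions must be >= 1")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(d[1L]))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != d[1L]) stop("`cell_ids` must have one entry per cell")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
                                    paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, bin_width_ms = as.numeric(bin_width_ms),
         cell_ids = cell_ids, n_cells = d[1L], n_bins = d[2L], n_reps = d[3L]),
    class = "spike_count_tensor")
}

#' @export
print.spike_count_tensor <- function(x, ...) {
  cat(sprintf("spike_count_tensor: %d cells x %d bins x %d repetitions (bin %.3f ms)\n",
              x$n_cells, x$n_bins, x$n_reps, x$bin_width_ms))
  cat(sprintf("  total spikes: %d, max count: %d\n", sum(x$counts), max(x$counts)))
  invisible(x)
}

.cell_index <- function(tensor, cell) {
  if (is.character(cell)) {
    i <- match(cell, tensor$cell_ids)
    if (is.na(i)) stop("unknown cell id: ", cell)
    return(i)
  }
  i <- as.integer(cell)
  if (i < 1L || i > tensor$n_cells) stop("cell index out of range: ", cell)
  i
}

#' Bin spike trains into a spike-count tensor
#'
#' Counts spikes of each cell in half-open, left-closed time bins
#' `[t*delta, (t+1)*delta)`, separately for each stimulus repetition.  The
#' trailing partial bin (if `duration_s` is not a multiple of the bin width)
#' is discarded.  The default bin width, 1000/60 ms, corresponds to a 60 Hz
#' bin rate.
#'
#' A 1e-9 ms guard is added before taking the floor so that spike times that
#' are mathematically on a bin edge, but land infinitesimally below it in
#' floating point, are still assigned to the upper (left-closed) bin.
#'
#' @param spikes data frame with columns `cell_id`, `repetition` (integer,
#'   contiguous from 0) and `time_s` (seconds, in `[0, duration_s)`).
#' @param bin_width_ms bin width in milliseconds.
#' @param duration_s stimulus duration in seconds.
#' @param cell_ids optional character vector fixing the cell order (and
#'   allowing silent cells); defaults to the sorted unique ids in `spikes`.
#' @param n_reps optional number of repetitions (allows empty repetitions);
#'   defaults to `max(repetition) + 1`.
#'
#' @return A [spike_count_tensor()].
#' @export
bin_spike_trains <- function(spikes, bin_width_ms = 1000 / 60, duration_s,
                             cell_ids = NULL, n_reps = NULL) {
  stopifnot(is.data.frame(spikes))
  need <- c("cell_id", "repetition", "time_s")
  miss <- setdiff(need, names(spikes))
  if (length(miss)) stop("`spikes` is missing columns: ", paste(miss, collapse = ", "))
  if (bin_width_ms <= 0) stop("`bin_width_ms` must be positive")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  bad <- which(!is.finite(spikes$time_s) | spikes$time_s < 0)
  if (length(bad)) stop("negative or non-finite spike times at rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(spikes$time_s >= duration_s)
  if (length(bad)) stop("spike times at/after `duration_s` at rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  rep_idx <- spikes$repetition
  bad <- which(rep_idx < 0 | rep_idx != round(rep_idx))
  if (length(bad)) stop("repetition indices must be non-negative integers; bad rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(n_reps)) n_reps <- if (nrow(spikes)) max(rep_idx) + 1L else 1L
  if (nrow(spikes) && !setequal(unique(rep_idx), seq_len(max(rep_idx) + 1L) - 1L))
    stop("repetition indices must be contiguous from 0")
  ids <- as.character(spikes$cell_id)
  if (is.null(cell_ids)) cell_ids <- sort(unique(ids))
  unknown <- setdiff(unique(ids), cell_ids)
  if (length(unknown)) stop("spikes reference cell ids absent from `cell_ids`: ",
                            paste(unknown, collapse = ", "))
  n_bins <- floor(duration_s * 1000 / bin_width_ms + 1e-9)
  if (n_bins < 1L) stop("`duration_s` shorter than one bin")
  n_cells <- length(cell_ids)
  counts <- array(0L, dim = c(n_cells, n_bins, n_reps))
  if (nrow(spikes)) {
    bin <- floor(spikes$time_s * 1000 / bin_width_ms + 1e-9)
    keep <- bin < n_bins                       # trailing partial bin dropped
    if (any(keep)) {
      ci <- match(ids[keep], cell_ids)
      flat <- ci + n_cells * bin[keep] + n_cells * n_bins * rep_idx[keep]
      tab <- table(flat)
      counts[as.numeric(names(tab))] <- as.integer(tab)
    }
  }
  spike_count_tensor(counts, bin_width_ms, cell_ids)
}

#' Empirical per-bin spike-count distributions
#'
#' For every cell and time bin, estimates the probability mass function of the
#' spike count across repetitions, and its cumulative distribution.  These
#' empirical marginals are the per-bin `F_i^(t)` that the copula model couples
#' into joint laws.
#'
#' @param tensor a [spike_count_tensor()].
#' @param n_max support cap; defaults to the maximum observed count.
#' @return An object of class `marginal_set`: list with `pmf` and `cdf`
#'   arrays of dimension `n_cells x n_bins x (n_max+1)` (count value k is
#'   slice k+1), plus `n_max`, `cell_ids`, `n_cells`, `n_bins`, `n_reps`.
#' @export
empirical_marginals <- function(tensor, n_max = NULL) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (is.null(n_max)) n_max <- max(tensor$counts)
  n_max <- as.integer(n_max)
  if (n_max < max(tensor$counts)) stop("`n_max` below the maximum observed count")
  N <- tensor$n_cells; T_ <- tensor$n_bins
  pmf <- array(0, dim = c(N, T_, n_max + 1L))
  for (k in 0:n_max)
    pmf[, , k + 1L] <- rowMeans(tensor$counts == k, dims = 2L)
  cdf <- aperm(apply(pmf, c(1L, 2L), cumsum), c(2L, 3L, 1L))
  cdf[, , n_max + 1L] <- 1                     # kill cumsum round-off at the top
  structure(list(pmf = pmf, cdf = cdf, n_max = n_max, cell_ids = tensor$cell_ids,
                 n_cells = N, n_bins = T_, n_reps = tensor$n_reps),
            class = "marginal_set")
}

#' @export
print.marginal_set <- function(x, ...) {
  cat(sprintf("marginal_set: %d cells x %d bins, counts 0..%d (R = %d)\n",
              x$n_cells, x$n_bins, x$n_max, x$n_reps))
  invisible(x)
}

#' Extract the marginals of a single cell
#'
#' Returns one cell's per-bin pmf/cdf as a `cell_marginal` object, the unit
#' the distance-based prediction functions work with: they may see single-cell
#' statistics and distances, never joint recordings.
#'
#' @param marginals a [empirical_marginals()] result.
#' @param cell cell id or index.
#' @return `cell_marginal`: list with `pmf`, `cdf` ((n_max+1) x n_bins
#'   matrices), `n_max`, `n_bins`, `cell_id`.
#' @export
marginal_slice <- function(marginals, cell) {
  stopifnot(inherits(marginals, "marginal_set"))
  i <- if (is.character(cell)) match(cell, marginals$cell_ids) else as.integer(cell)
  if (is.na(i) || i < 1L || i > marginals$n_cells) stop("unknown cell: ", cell)
  structure(list(pmf = t(matrix(marginals$pmf[i, , ], marginals$n_bins)),
                 cdf = t(matrix(marginals$cdf[i, , ], marginals$n_bins)),
                 n_max = marginals$n_max, n_bins = marginals$n_bins,
                 cell_id = marginals$cell_ids[i]),
            class = "cell_marginal")
}

# per-bin mean and second moment of a cell_marginal
.marginal_moments <- function(cm) {
  k <- 0:cm$n_max
  list(mean = as.numeric(crossprod(cm$pmf, k)),
       second = as.numeric(crossprod(cm$pmf, k^2)))
}

#' Trial-shuffle a tensor to destroy noise correlations
#'
#' Independently for each cell, permutes the repetition indices (keeping each
#' repetition's whole time course intact).  Per-cell per-bin marginals are
#' exactly preserved while cross-cell trial-to-trial covariability is
#' destroyed, which is the conditionally-independent control: shuffled data
#' behave as a population with the true marginals and zero noise correlations.
#'
#' @param tensor a [spike_count_tensor()] with at least 2 repetitions.
#' @param seed integer RNG seed.
#' @return A shuffled [spike_count_tensor()].
#' @export
shuffle_repetitions <- function(tensor, seed) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (tensor$n_reps < 2L) stop("shuffling requires at least 2 repetitions")
  set.seed(as.integer(seed))
  out <- tensor$counts
  for (i in seq_len(tensor$n_cells))
    out[i, , ] <- tensor$counts[i, , sample.int(tensor$n_reps), drop = FALSE]
  spike_count_tensor(out, tensor$bin_width_ms, tensor$cell_ids)
}
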