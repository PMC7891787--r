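#' Cell geometry (receptive-field centre positions)
#'
#' Positions are the receptive-field centres of the cells, in micrometres.
#' Pairwise Euclidean distances between them drive the distance law for the
#' copula parameter.
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param x_um,y_um numeric coordinates in micrometres.
#' @return `cell_geometry`: a data frame with columns `cell_id`, `x_um`,
#'   `y_um`.
#' @export
cell_geometry <- function(cell_id, x_um, y_um) {
  cell_id <- as.character(cell_id)
  if (length(x_um) != length(cell_id) || length(y_um) != length(cell_id))
    stop("`x_um` and `y_um` must have one entry per cell")
  if (anyDuplicated(cell_id))
    stop("duplicate cell ids in geometry: ",
         paste(unique(cell_id[duplicated(cell_id)]), collapse = ", "))
  if (any(!is.finite(x_um)) || any(!is.finite(y_um)))
    stop("non-finite coordinates")
  structure(data.frame(cell_id = cell_id, x_um = as.numeric(x_um),
                       y_um = as.numeric(y_um), stringsAsFactors = FALSE),
            class = c("cell_geometry", "data.frame"))
}

#' Pairwise inter-cell distances
#'
#' @param geometry a [cell_geometry()].
#' @return Symmetric matrix of Euclidean distances in micrometres, zero
#'   diagonal, dimnames set to the cell ids.
#' @export
pair_distances <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  d <- as.matrix(stats::dist(cbind(geometry$x_um, geometry$y_um)))
  dimnames(d) <- list(geometry$cell_id, geometry$cell_id)
  d
}

#' Check that a geometry covers all cells of a tensor
#'
#' @param tensor a [spike_count_tensor()].
#' @param geometry a [cell_geometry()].
#' @return Invisibly, the geometry reordered to the tensor's cell order.
#' @export
match_geometry <- function(tensor, geometry) {
  stopifnot(inherits(tensor, "spike_count_tensor"), inherits(geometry, "cell_geometry"))
  miss <- setdiff(tensor$cell_ids, geometry$cell_id)
  if (length(miss))
    stop("positions missing for cells present in spikes: ", paste(miss, collapse = ", "))
  invisible(geometry[match(tensor$cell_ids, geometry$cell_id), , drop = FALSE])
}
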