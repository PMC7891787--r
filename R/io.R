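#' Read a spike table
#'
#' Tab- or comma-delimited text with header columns `cell_id`, `repetition`,
#' `time_s`.  Rows failing validation are reported by row number.
#'
#' @param path file path.
#' @return data frame with the three columns, suitable for
#'   [bin_spike_trains()].
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  need <- c("cell_id", "repetition", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spike file ", path, " lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$time_s) | df$time_s < 0)
  if (length(bad)) stop("malformed spike times in ", path, " at rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(df$repetition) | df$repetition < 0 | df$repetition != round(df$repetition))
  if (length(bad)) stop("malformed repetition indices in ", path, " at rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  df[need]
}

#' Write a spike table
#' @param spikes data frame with columns `cell_id`, `repetition`, `time_s`.
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.table(spikes[c("cell_id", "repetition", "time_s")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell positions
#'
#' Delimited text with header columns `cell_id`, `x_um`, `y_um`.
#' @param path file path.
#' @return a [cell_geometry()].
#' @export
read_positions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("position file ", path, " lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad)) stop("malformed coordinates in ", path, " at rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  cell_geometry(df$cell_id, df$x_um, df$y_um)
}

#' Write cell positions
#' @param geometry a [cell_geometry()].
#' @param path file path.
#' @export
write_positions <- function(geometry, path) {
  utils::write.table(as.data.frame(geometry), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a spike-count tensor
#'
#' Two on-disk formats, chosen by file extension: `.h5`/`.hdf5` writes an
#' HDF5 container (datasets `counts`, `bin_width_ms`, `cell_ids`; requires the
#' rhdf5 package), anything else writes a self-describing sparse text format
#' (`#`-prefixed header with dimensions, then one `cell bin rep count` row per
#' non-zero entry, 1-based indices).
#'
#' @param tensor a [spike_count_tensor()].
#' @param path output path.
#' @export
write_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 output requires the rhdf5 package")
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(tensor$counts, path, "counts")
    rhdf5::h5write(tensor$bin_width_ms, path, "bin_width_ms")
    rhdf5::h5write(tensor$cell_ids, path, "cell_ids")
    rhdf5::h5closeAll()
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spike_count_tensor v1",
               sprintf("# bin_width_ms: %.17g", tensor$bin_width_ms),
               sprintf("# dims: %d %d %d", tensor$n_cells, tensor$n_bins, tensor$n_reps),
               paste0("# cell_ids: ", paste(tensor$cell_ids, collapse = "\t")),
               "cell\tbin\trep\tcount"), con)
  nz <- which(tensor$counts != 0L, arr.ind = TRUE)
  if (nrow(nz))
    utils::write.table(cbind(nz, count = tensor$counts[nz]), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spike-count tensor written by [write_tensor()]
#' @param path input path.
#' @return a [spike_count_tensor()].
#' @export
read_tensor <- function(path) {
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 input requires the rhdf5 package")
    counts <- rhdf5::h5read(path, "counts")
    bw <- as.numeric(rhdf5::h5read(path, "bin_width_ms"))
    ids <- as.character(rhdf5::h5read(path, "cell_ids"))
    rhdf5::h5closeAll()
    return(spike_count_tensor(counts, bw, ids))
  }
  lines <- readLines(path, n = 10L)
  if (!length(lines) || lines[1L] != "# spike_count_tensor v1")
    stop("not a spike_count_tensor text file: ", path)
  hdr <- function(key) sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"), lines, value = TRUE)[1L])
  bw <- as.numeric(hdr("bin_width_ms"))
  dims <- as.integer(strsplit(hdr("dims"), " ")[[1L]])
  ids <- strsplit(hdr("cell_ids"), "\t")[[1L]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  counts <- array(0L, dim = dims)
  if (nrow(df)) {
    bad <- which(df$cell < 1 | df$cell > dims[1L] | df$bin < 1 | df$bin > dims[2L] |
                 df$rep < 1 | df$rep > dims[3L] | df$count < 0)
    if (length(bad)) stop("malformed tensor rows in ", path, ": ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    counts[cbind(df$cell, df$bin, df$rep)] <- as.integer(df$count)
  }
  spike_count_tensor(counts, bw, ids)
}

#' Write a fitted model to JSON
#'
#' Serialises a [theta_distance_model()] or [maxent_model()] (dispatched on
#' class) to a JSON document.
#' @param model the model object.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "theta_distance_model")) {
    obj <- list(type = "theta_distance_model", a = model$a, b = model$b,
                c = model$c, cutoff_um = model$cutoff_um, family = model$family)
  } else if (inherits(model, "maxent_model")) {
    obj <- list(type = "maxent_model", h = model$h, J = model$J,
                n_max = model$n_max, cell_ids = model$cell_ids)
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a model JSON written by [write_model()]
#' @param path input path.
#' @return the model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    theta_distance_model = theta_distance_model(obj$a, obj$b, obj$c,
                                                cutoff_um = obj$cutoff_um,
                                                family = obj$family),
    maxent_model = maxent_model(obj$h, obj$J, obj$n_max, cell_ids = obj$cell_ids),
    stop("unknown model type in ", path, ": ", obj$type))
}
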