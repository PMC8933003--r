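#' Read and write localization tables
#'
#' The on-disk dialect is a CSV with the exact header
#' `frame,x_nm,y_nm,photons,sigma_nm,background,precision_nm`.
#'
#' @param table Localization table.
#' @param path File path.
#' @return `read_localizations()` returns the table;
#'   `write_localizations()` returns `path` invisibly.
#' @export
write_localizations <- function(table, path) {
  check_localization_table(table)
  for (col in loc_table_columns) {
    if (!col %in% names(table)) table[[col]] <- NA_real_
  }
  write.csv(table[, loc_table_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tab <- read.csv(path)
  missing <- setdiff(loc_table_columns, names(tab))
  if (length(missing)) {
    stop("localization CSV lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tab[, loc_table_columns]
}

#' Read and write frame stacks as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers (values above 65535
#' are clipped with a warning).
#'
#' @param frames A `frame_stack`.
#' @param path File path.
#' @param q_nm Pixel size to attach on read, nm.
#' @return `read_frames_tiff()` returns a `frame_stack`;
#'   `write_frames_tiff()` returns `path` invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  stopifnot(inherits(frames, "frame_stack"))
  d <- dim(frames$counts)
  if (any(frames$counts > 65535)) {
    warning("counts above 65535 clipped for 16-bit storage")
  }
  pages <- lapply(seq_len(d[3]), function(f) {
    pmin(frames$counts[, , f], 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path, q_nm) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  counts <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (f in seq_along(pages)) {
    counts[, , f] <- round(pages[[f]] * 65535)
  }
  structure(
    list(counts = counts, q_nm = q_nm,
         fov_nm = c(ncol(counts) * q_nm, nrow(counts) * q_nm),
         on_matrix = NULL, config = NULL),
    class = "frame_stack"
  )
}

#' Serialize a cluster map to JSON and back
#'
#' Footprints are stored as pixel linear indices into the render grid;
#' the round-trip is exact.
#'
#' @param map A `cluster_map`.
#' @param path File path.
#' @return `read_cluster_map()` returns the `cluster_map`;
#'   `write_cluster_map()` returns `path` invisibly.
#' @export
write_cluster_map <- function(map, path) {
  stopifnot(inherits(map, "cluster_map"))
  jsonlite::write_json(
    list(pixel_nm = map$pixel_nm, roi = map$roi, dim = map$dim,
         clusters = map$clusters, footprints = map$footprints,
         meta = map$meta),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- as.data.frame(obj$clusters)
  footprints <- lapply(obj$footprints, as.integer)
  cluster_map(
    clusters = clusters, footprints = footprints,
    pixel_nm = obj$pixel_nm, roi = obj$roi, dim = obj$dim,
    meta = as.list(obj$meta)
  )
}

#' Serialize simulation ground truth to JSON and back
#'
#' @param truth A `ground_truth` object from [simulate_localizations()].
#' @param path File path.
#' @return `read_ground_truth()` returns the `ground_truth`;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(clusters = truth$clusters, assignment = truth$assignment,
         roi_nm = as.list(truth$roi_nm)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- as.data.frame(obj$clusters)
  clusters$partner_id <- as.integer(clusters$partner_id)
  structure(
    list(clusters = clusters,
         assignment = lapply(obj$assignment, as.integer),
         roi_nm = unlist(obj$roi_nm)),
    class = "ground_truth"
  )
}

#' Read a two-column current-trace CSV
#'
#' Expects columns `time_s` and `current_pa`; capacitance and event
#' markers are supplied alongside (the sidecar-config convention).
#'
#' @param path CSV path.
#' @param capacitance_pf Membrane capacitance, pF.
#' @param markers Named list of event times, s.
#' @return A `current_trace`.
#' @export
read_current_trace <- function(path, capacitance_pf, markers = list()) {
  tab <- read.csv(path)
  if (!all(c("time_s", "current_pa") %in% names(tab))) {
    stop("trace CSV must have columns time_s, current_pa")
  }
  current_trace(tab$time_s, tab$current_pa, capacitance_pf, markers)
}
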