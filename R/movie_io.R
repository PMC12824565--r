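#' Write / read a two-channel movie as multi-page 16-bit TIFF
#'
#' @param movie a `fretspt_movie` array (or any integer array
#'   `(height, width, frames)` with values in 0..65535).
#' @param path output file.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns an integer array `(height, width, frames)`.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3L)
  pages <- lapply(seq_len(dim(movie)[3]), function(f) {
    movie[, , f, drop = TRUE] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param channel_split first column (1-based) of the acceptor half when
#'   re-attaching movie attributes on read.
#' @export
read_movie_tiff <- function(path, channel_split = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    arr[, , f] <- as.integer(round(pages[[f]] * 65535))
  }
  if (!is.null(channel_split)) attr(arr, "channel_split") <- channel_split
  arr
}

#' Write / read ground-truth emitter states as CSV
#'
#' Columns: frame, emitter_id, x_um, y_um, state, donor_bleached,
#' acceptor_bleached, pathway (per-emitter pathway repeated on each row;
#' NA while no dissociation occurred).
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  st <- truth$states
  pw <- truth$per_emitter$pathway[match(st$emitter_id, truth$per_emitter$emitter_id)]
  out <- data.frame(frame = st$frame, emitter_id = st$emitter_id,
                    x_um = st$x_um, y_um = st$y_um, state = st$state,
                    donor_bleached = st$donor_bleached,
                    acceptor_bleached = st$acceptor_bleached, pathway = pw)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Convert a camera frame to photon units
#'
#' @param frame integer matrix in ADU.
#' @param gain ADU per photon.
#' @param baseline camera offset in ADU.
#' @return numeric matrix of photons per pixel (can be slightly negative
#'   where noise undershoots the baseline).
#' @export
adu_to_photons <- function(frame, gain, baseline) {
  (frame - baseline) / gain
}
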