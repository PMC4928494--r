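#' Read an RGB image as an H x W x 3 array
#'
#' Reads PNG/TIFF/JPEG through EBImage and returns values on 0-255 with
#' rows = y (top to bottom) and columns = x, the orientation every function
#' in this package uses. Grayscale files are expanded to three channels.
#'
#' @param path image file.
#' @return numeric H x W x 3 array, values in \[0, 255\].
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img) # [x, y(, c)] in [0, 1]
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
  for (k in 1:3) out[, , k] <- t(a[, , k])
  out * 255
}

#' Write a map as plain text plus a PNG preview
#'
#' The float values go to a TSV (one row per image row); an 8-bit grayscale
#' PNG preview is written next to it.
#'
#' @param map a `salience_map` or matrix.
#' @param path output TSV path; the preview gets a `.png` extension.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.table(unclass(map), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  prev <- sub("\\.[^.]*$", ".png", path)
  m01 <- minmax01(unclass(map))
  EBImage::writeImage(t(m01), prev)
  invisible(path)
}

#' Gaze, event and fixation CSV interchange
#'
#' `read_gaze`/`write_gaze` use columns `time_ms, x_px, y_px`;
#' `write_events` writes `kind, start_ms, end_ms, x, y`;
#' `read_fixations`/`write_fixations` use `x_px, y_px, t_ms, run_id,
#' observer_id` (missing columns are filled with NA).
#'
#' @param path CSV file path.
#' @param image_size,px_per_dva geometry attached to the scan path on read.
#' @return `read_gaze` returns a [scan_path()]; `read_fixations` a tibble;
#'   writers return `path` invisibly.
#' @name gaze_io
NULL

#' @rdname gaze_io
#' @export
read_gaze <- function(path, image_size, px_per_dva = 25) {
  d <- utils::read.csv(path)
  scan_path(d$time_ms, d$x_px, d$y_px, image_size, px_per_dva)
}

#' @rdname gaze_io
#' @param gaze a [scan_path()].
#' @export
write_gaze <- function(gaze, path) {
  utils::write.csv(data.frame(time_ms = gaze$time_ms, x_px = gaze$x,
                              y_px = gaze$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname gaze_io
#' @param events a `gw_events` object or events tibble.
#' @export
write_events <- function(events, path) {
  ev <- if (inherits(events, "gw_events")) events$events else events
  utils::write.csv(ev[, c("kind", "start_ms", "end_ms", "x", "y")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname gaze_io
#' @param fixations a data frame of fixations.
#' @export
write_fixations <- function(fixations, path) {
  d <- as.data.frame(fixations)
  out <- data.frame(
    x_px = d$x %||% d$x_px, y_px = d$y %||% d$y_px,
    t_ms = d$start_ms %||% d$t_ms %||% NA,
    run_id = d$run_id %||% NA, observer_id = d$observer_id %||% NA
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname gaze_io
#' @export
read_fixations <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
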