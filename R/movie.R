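#' Construct a calcium-imaging movie object
#'
#' A movie is a 3-D numeric array of luminance, `height x width x frames`
#' (rows are y, columns are x, 1-based), carrying the frame interval and the
#' pixel size as attributes. The default pixel size matches a 20x objective
#' acquisition at 512 x 512 galvo resolution (1.183 um/pixel).
#'
#' @param data Numeric array `height x width x frames` (a single matrix is
#'   treated as a one-frame movie).
#' @param frame_duration_s Frame interval in seconds.
#' @param um_per_px Pixel size in micrometres per pixel.
#'
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(data, frame_duration_s = 0.249, um_per_px = 1.183) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L, is.numeric(data))
  stopifnot(frame_duration_s > 0, um_per_px > 0)
  structure(data, frame_duration_s = frame_duration_s, um_per_px = um_per_px,
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ca_movie> %d x %d px, %d frames @ %.3f s (%.3f um/px)\n",
              d[1], d[2], d[3], attr(x, "frame_duration_s"), attr(x, "um_per_px")))
  invisible(x)
}

#' @export
`[.ca_movie` <- function(x, ...) {
  out <- NextMethod()
  out
}

n_frames <- function(movie) dim(movie)[3]

#' Write a movie to a multi-page 16-bit grayscale TIFF
#'
#' Luminance is divided by `scale` and stored as 16-bit samples, one page
#' per frame. Use the same `scale` when reading the file back; values above
#' `scale` are clipped with a warning.
#'
#' @param movie A [ca_movie()].
#' @param path Output file path.
#' @param scale Luminance value mapped to the top of the 16-bit range
#'   (default 4096, comfortably above typical simulated luminance).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, scale = 4096) {
  stopifnot(inherits(movie, "ca_movie"))
  pages <- lapply(seq_len(n_frames(movie)), function(j) {
    pmin(pmax(unclass(movie)[, , j] / scale, 0), 1)
  })
  if (any(unclass(movie) > scale)) {
    warning("luminance values above `scale` were clipped on write")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a movie
#'
#' @param path TIFF file path.
#' @param frame_duration_s,um_per_px Acquisition metadata to attach (TIFF
#'   pages do not carry them).
#' @param scale Luminance scale used when the file was written.
#' @return A [ca_movie()].
#' @export
read_movie <- function(path, frame_duration_s = 0.249, um_per_px = 1.183,
                       scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (j in seq_along(pages)) {
    pg <- pages[[j]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # collapse grayscale channels
    arr[, , j] <- pg * scale
  }
  ca_movie(arr, frame_duration_s = frame_duration_s, um_per_px = um_per_px)
}
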