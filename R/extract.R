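#' Build disk ROIs around manually selected cell centers
#'
#' For each center, the ROI is the set of integer pixels whose center lies
#' within Euclidean distance `radius_px` of the selected point (distance
#' compared on squared terms, so membership is exact for integer centers).
#' Masks that would extend past the image edge are clipped to the image with
#' a warning.
#'
#' @param centers Data frame with columns `x_px`, `y_px` (1-based pixel
#'   coordinates, x = column, y = row) and optionally `cell_id`.
#' @param radius_px Disk radius in pixels (default 5, the soma-scale ROI
#'   used throughout the pipeline; radius 0 gives a single-pixel mask).
#' @param image_shape Integer vector `c(height, width)`.
#'
#' @return A tibble of class `ca_rois` with columns `cell_id`, `x_px`,
#'   `y_px`, `radius_px`, `n_px`, `clipped` and a list-column `mask` of
#'   per-cell data frames (`x`, `y`) of member pixels.
#' @examples
#' rois <- build_rois(data.frame(x_px = 20, y_px = 20), 5, c(40, 40))
#' rois$n_px  # 81 pixels in a radius-5 disk
#' @export
build_rois <- function(centers, radius_px = 5, image_shape) {
  centers <- as_tibble(as.data.frame(centers))
  stopifnot(all(c("x_px", "y_px") %in% names(centers)), radius_px >= 0,
            length(image_shape) == 2L)
  if (!"cell_id" %in% names(centers)) centers$cell_id <- seq_len(nrow(centers))
  if (anyDuplicated(centers[, c("x_px", "y_px")])) {
    stop("invalid ROI: duplicate cell centers", call. = FALSE)
  }
  h <- image_shape[1]; w <- image_shape[2]
  if (any(centers$x_px < 1 | centers$x_px > w |
          centers$y_px < 1 | centers$y_px > h)) {
    stop("invalid ROI: cell center outside the image", call. = FALSE)
  }
  r <- ceiling(radius_px)
  rel <- expand.grid(dx = -r:r, dy = -r:r)
  out <- centers[, c("cell_id", "x_px", "y_px")]
  out$radius_px <- radius_px
  masks <- vector("list", nrow(centers))
  clipped <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    px <- round(centers$x_px[i]) + rel$dx
    py <- round(centers$y_px[i]) + rel$dy
    inside <- (px - centers$x_px[i])^2 + (py - centers$y_px[i])^2 <= radius_px^2
    px <- px[inside]; py <- py[inside]
    keep <- px >= 1 & px <= w & py >= 1 & py <= h
    clipped[i] <- any(!keep)
    if (!any(keep)) stop("invalid ROI: empty mask after clipping", call. = FALSE)
    masks[[i]] <- data.frame(x = px[keep], y = py[keep])
  }
  if (any(clipped)) {
    warning(sum(clipped), " ROI mask(s) clipped at the image boundary")
  }
  out$n_px <- vapply(masks, nrow, integer(1))
  out$clipped <- clipped
  out$mask <- masks
  class(out) <- c("ca_rois", class(out))
  out
}

#' Pool luminance inside each ROI into a fluorescence matrix
#'
#' The fluorescence of cell i in frame j is the mean luminance over the
#' pixels of its disk mask in that frame.
#'
#' @param movie A [ca_movie()].
#' @param rois A [build_rois()] table.
#' @return A cells x frames numeric matrix with `rownames` the cell ids and
#'   attribute `frame_duration_s` carried over from the movie.
#' @export
extract_fluorescence <- function(movie, rois) {
  stopifnot(inherits(movie, "ca_movie"), inherits(rois, "ca_rois"))
  if (nrow(rois) == 0L) stop("invalid ROI: no ROIs supplied", call. = FALSE)
  arr <- unclass(movie)
  h <- dim(arr)[1]; w <- dim(arr)[2]; nfr <- dim(arr)[3]
  flat <- matrix(arr, h * w, nfr)   # pixels x frames view
  f <- matrix(0, nrow(rois), nfr)
  for (i in seq_len(nrow(rois))) {
    m <- rois$mask[[i]]
    idx <- (m$x - 1L) * h + m$y
    f[i, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  rownames(f) <- rois$cell_id
  attr(f, "frame_duration_s") <- attr(movie, "frame_duration_s")
  f
}

#' Convert raw fluorescence to dF/F with a median baseline
#'
#' The relative fluorescence of cell i in frame j is
#' `(F_ij - F_i0) / F_i0`, where `F_i0` is the median raw fluorescence of
#' that cell over all frames. Because the baseline is the running session
#' median, dF/F fluctuates below zero as well as above it; per-cell SD of
#' the full unsmoothed dF/F series is stored for thresholding during event
#' detection. Cells whose median fluorescence is not strictly positive have
#' no defined dF/F; they are excluded and reported.
#'
#' @param f Cells x frames raw fluorescence matrix (e.g. from
#'   [extract_fluorescence()]), or a `ca_sim_traces` object.
#' @param frame_duration_s Frame interval; taken from `f`'s attribute when
#'   present.
#' @return An object of class `ca_dff`: list with `dff` (cells x frames
#'   matrix), `f0`, `sd` (named per-cell vectors), `frame_duration_s`, and
#'   `excluded` (tibble of dropped cells with their offending median).
#' @export
compute_dff <- function(f, frame_duration_s = NULL) {
  if (inherits(f, "ca_sim_traces")) {
    frame_duration_s <- frame_duration_s %||% f$spec$frame_duration_s
    f <- f$f
  }
  stopifnot(is.matrix(f), is.numeric(f))
  frame_duration_s <- frame_duration_s %||% attr(f, "frame_duration_s") %||% 0.249
  ids <- rownames(f) %||% as.character(seq_len(nrow(f)))
  f0 <- apply(f, 1, stats::median)
  bad <- !is.finite(f0) | f0 <= 0
  excluded <- tibble(cell_id = ids[bad], f0 = f0[bad])
  if (any(bad)) {
    message("excluding ", sum(bad), " cell(s) with non-positive median fluorescence")
    f <- f[!bad, , drop = FALSE]
    f0 <- f0[!bad]
    ids <- ids[!bad]
  }
  dff <- sweep(sweep(f, 1, f0, "-"), 1, f0, "/")
  sdv <- apply(dff, 1, stats::sd)
  names(f0) <- names(sdv) <- rownames(dff) <- ids
  structure(
    list(dff = dff, f0 = f0, sd = sdv,
         frame_duration_s = frame_duration_s, excluded = excluded),
    class = "ca_dff"
  )
}

#' @export
print.ca_dff <- function(x, ...) {
  cat(sprintf("<ca_dff> %d cells x %d frames @ %.3f s; median F0 %.1f\n",
              nrow(x$dff), ncol(x$dff), x$frame_duration_s,
              stats::median(x$f0)))
  if (nrow(x$excluded)) cat("  excluded cells:", nrow(x$excluded), "\n")
  invisible(x)
}
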