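#' Simulate a two-photon movie with ground truth
#'
#' Renders a session as an image stack: each cell is an isotropic
#' Gaussian-profile disk (SD `cell_sd_px`, truncated at 3 SD) whose peak
#' intensity follows that cell's clean simulated luminance trace (baseline +
#' drift + transients, without trace noise); noise is instead added once, at
#' the pixel level, with SD `spec$noise_sd`. When `spec$motion_sd_px > 0`
#' (or `shifts` is given) every frame is rigidly displaced by a per-frame
#' (dx, dy), which is recorded in the ground truth for benchmarking motion
#' correction.
#'
#' Default cell centers are laid out on a grid with 16-px spacing, which
#' keeps neighbouring ROIs (default radius 5 px) disjoint.
#'
#' @param spec A [session_spec()].
#' @param kernel A [transient_kernel()] matching the spec's frame interval.
#' @param centers Optional tibble/data frame with columns `x_px`, `y_px`
#'   (one row per cell); defaults to a grid layout.
#' @param shifts Optional data frame with columns `dx_px`, `dy_px`
#'   (`spec$n_frames` rows); defaults to N(0, `motion_sd_px`) draws
#'   (all zero when `motion_sd_px` is 0).
#' @param cell_sd_px Gaussian footprint SD in pixels (default 3).
#' @param roi_radius_px ROI radius used for the minimum-separation check
#'   (default 5).
#' @param background Background luminance of the field (default 10).
#'
#' @return A list of class `ca_sim_movie`: `movie` (a [ca_movie()]),
#'   `truth` (list with `events`, `shifts`, `centers`), `spec`, `kernel`.
#' @examples
#' sim <- simulate_movie(session_spec(n_cells = 4, n_frames = 20, seed = 7))
#' sim$movie
#' @export
simulate_movie <- function(spec, kernel = transient_kernel(frame_duration_s = spec$frame_duration_s),
                           centers = NULL, shifts = NULL,
                           cell_sd_px = 3, roi_radius_px = 5, background = 10) {
  .with_own_rng({
    core <- .simulate_session_core(spec, kernel)
    nfr <- spec$n_frames
    set.seed(core$session_seed)

    if (is.null(shifts)) {
      if (spec$motion_sd_px > 0) {
        shifts <- tibble(frame = seq_len(nfr),
                         dx_px = stats::rnorm(nfr, 0, spec$motion_sd_px),
                         dy_px = stats::rnorm(nfr, 0, spec$motion_sd_px))
      } else {
        shifts <- tibble(frame = seq_len(nfr), dx_px = 0, dy_px = 0)
      }
    } else {
      shifts <- as_tibble(shifts)
      stopifnot(all(c("dx_px", "dy_px") %in% names(shifts)), nrow(shifts) == nfr)
      shifts$frame <- seq_len(nfr)
    }
    max_shift <- max(abs(c(shifts$dx_px, shifts$dy_px, 0)))
    margin <- ceiling(3 * cell_sd_px + max_shift) + 2L

    if (is.null(centers)) {
      ngrid <- ceiling(sqrt(spec$n_cells))
      spacing <- 16L
      pos <- expand.grid(col = seq_len(ngrid), row = seq_len(ngrid))[seq_len(spec$n_cells), ]
      centers <- tibble(x_px = margin + (pos$col - 1L) * spacing,
                        y_px = margin + (pos$row - 1L) * spacing)
      h <- margin * 2L + (max(pos$row) - 1L) * spacing
      w <- margin * 2L + (max(pos$col) - 1L) * spacing
    } else {
      centers <- as_tibble(centers)
      stopifnot(all(c("x_px", "y_px") %in% names(centers)),
                nrow(centers) == spec$n_cells)
      h <- ceiling(max(centers$y_px)) + margin
      w <- ceiling(max(centers$x_px)) + margin
    }
    if (nrow(centers) > 1L) {
      dmin <- min(stats::dist(cbind(centers$x_px, centers$y_px)))
      if (dmin < 2 * roi_radius_px) {
        stop("invalid geometry: cell centers closer than 2 * roi_radius_px",
             call. = FALSE)
      }
    }
    if (any(centers$x_px - margin < 0 | centers$x_px + margin > w + margin |
            centers$y_px - margin < 0 | centers$y_px + margin > h + margin)) {
      stop("invalid geometry: cells too close to the field edge for the ",
           "footprint plus maximum shift", call. = FALSE)
    }

    rad <- ceiling(3 * cell_sd_px)
    rel <- expand.grid(dy = -rad:rad, dx = -rad:rad)
    keep <- rel$dx^2 + rel$dy^2 <= (3 * cell_sd_px)^2
    rel <- rel[keep, ]

    arr <- array(background, c(h, w, nfr))
    for (i in seq_len(spec$n_cells)) {
      cx0 <- centers$x_px[i]; cy0 <- centers$y_px[i]
      for (j in seq_len(nfr)) {
        cx <- cx0 + shifts$dx_px[j]; cy <- cy0 + shifts$dy_px[j]
        px <- round(cx) + rel$dx; py <- round(cy) + rel$dy
        ok <- px >= 1 & px <= w & py >= 1 & py <= h
        g <- exp(-((px - cx)^2 + (py - cy)^2) / (2 * cell_sd_px^2))
        arr[cbind(py[ok], px[ok], j)] <- arr[cbind(py[ok], px[ok], j)] +
          g[ok] * core$signal[i, j]
      }
    }
    if (spec$noise_sd > 0) {
      arr <- arr + array(stats::rnorm(length(arr), 0, spec$noise_sd), dim(arr))
      arr[arr < 0] <- 0
    }

    centers$cell_id <- seq_len(spec$n_cells)
    structure(
      list(movie = ca_movie(arr, frame_duration_s = spec$frame_duration_s),
           truth = list(events = core$events, shifts = shifts,
                        centers = centers[, c("cell_id", "x_px", "y_px")],
                        clean_traces = core$signal),
           spec = spec, kernel = kernel),
      class = "ca_sim_movie"
    )
  })
}
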