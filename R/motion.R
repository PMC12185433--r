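#' Estimate per-frame rigid shifts by phase cross-correlation
#'
#' Registers every frame against a template (the mean of the first
#' `template_frames` frames) by FFT cross-correlation: the cross power
#' spectrum is inverted to a correlation surface whose peak is the frame's
#' rigid (dx, dy) displacement. The unnormalised (matched-filter) spectrum
#' is used rather than the phase-normalised one; on sparse low-texture
#' fields of view phase normalisation gives equal weight to noise-dominated
#' high frequencies and degrades subpixel accuracy several-fold. The integer
#' peak is refined to `1/upsample` pixel precision with a local upsampled
#' DFT evaluated on a +/- 1 px neighbourhood.
#'
#' The returned shift is the displacement of the frame content *relative to
#' the template*; [apply_shifts()] removes it by resampling each frame at
#' the shifted coordinates.
#'
#' @param movie A [ca_movie()] with at least 2 frames.
#' @param max_shift_px Maximum allowed shift magnitude per axis in pixels;
#'   the correlation peak is searched only within this range (default 20).
#' @param template_frames Number of leading frames averaged into the
#'   registration template (default 100, truncated to the movie length).
#' @param template Optional explicit template image (matrix of movie frame
#'   size); overrides `template_frames`.
#' @param upsample Subpixel refinement factor; 10 gives 0.1-px precision.
#'
#' @return A tibble with columns `frame`, `dx_px`, `dy_px` and attribute
#'   `template` describing the reference image.
#' @export
estimate_shifts <- function(movie, max_shift_px = 20, template_frames = 100,
                            upsample = 10, template = NULL) {
  stopifnot(inherits(movie, "ca_movie"))
  nfr <- n_frames(movie)
  if (nfr < 2) stop("movie must have at least 2 frames", call. = FALSE)
  arr <- unclass(movie)
  tf <- min(template_frames, nfr)
  if (is.null(template)) {
    template <- apply(arr[, , seq_len(tf), drop = FALSE], c(1, 2), mean)
  }
  stopifnot(is.matrix(template), all(dim(template) == dim(arr)[1:2]))

  if (stats::sd(template) == 0) {
    warning("template has no spatial structure; returning zero shifts")
    return(structure(tibble(frame = seq_len(nfr), dx_px = 0, dy_px = 0),
                     template = sprintf("mean of first %d frames", tf)))
  }

  Ft <- stats::fft(template)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  ky <- .fft_freqs(h); kx <- .fft_freqs(w)
  # wrapped shift value of each correlation-surface index
  sy <- ifelse(seq_len(h) - 1 > h / 2, seq_len(h) - 1 - h, seq_len(h) - 1)
  sx <- ifelse(seq_len(w) - 1 > w / 2, seq_len(w) - 1 - w, seq_len(w) - 1)
  ok_y <- abs(sy) <= max_shift_px; ok_x <- abs(sx) <= max_shift_px

  dx <- dy <- numeric(nfr)
  for (j in seq_len(nfr)) {
    Fg <- stats::fft(arr[, , j])
    R <- Conj(Ft) * Fg
    R <- R / max(Mod(R), .Machine$double.eps)   # scale only, no whitening
    cc <- Re(stats::fft(R, inverse = TRUE))
    cc_m <- cc[ok_y, ok_x, drop = FALSE]
    pk <- arrayInd(which.max(cc_m), dim(cc_m))
    dy0 <- sy[ok_y][pk[1]]; dx0 <- sx[ok_x][pk[2]]
    ref <- .upsampled_peak(R, ky, kx, dy0, dx0, upsample)
    dy[j] <- max(min(ref[1], max_shift_px), -max_shift_px)
    dx[j] <- max(min(ref[2], max_shift_px), -max_shift_px)
  }
  structure(tibble(frame = seq_len(nfr), dx_px = dx, dy_px = dy),
            template = sprintf("mean of first %d frames", tf))
}

.fft_freqs <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k > n / 2, k - n, k)
}

# Evaluate the correlation surface on a (2*upsample + 1)^2 grid of candidate
# shifts spaced 1/upsample px around (dy0, dx0) via an explicit local DFT,
# and return the refined (dy, dx) at the grid maximum.
.upsampled_peak <- function(R, ky, kx, dy0, dx0, upsample) {
  uy <- dy0 + seq(-1, 1, by = 1 / upsample)
  ux <- dx0 + seq(-1, 1, by = 1 / upsample)
  h <- length(ky); w <- length(kx)
  Ey <- exp(2i * pi * outer(uy, ky) / h)          # |uy| x h
  Ex <- exp(2i * pi * outer(kx, ux) / w)          # w x |ux|
  cc <- Re(Ey %*% R %*% Ex)
  pk <- arrayInd(which.max(cc), dim(cc))
  c(uy[pk[1]], ux[pk[2]])
}

#' Remove estimated rigid shifts from a movie
#'
#' Translates every frame by the negated estimated shift. Integer shifts move
#' pixels exactly; fractional shifts use bilinear interpolation. Pixels whose
#' source coordinate falls outside the field are filled with that frame's
#' median luminance so downstream ROI means are not biased at the borders.
#'
#' @param movie A [ca_movie()].
#' @param shifts A tibble from [estimate_shifts()] (columns `dx_px`,
#'   `dy_px`), one row per frame.
#' @return A motion-corrected [ca_movie()] of identical dimensions.
#' @export
apply_shifts <- function(movie, shifts) {
  stopifnot(inherits(movie, "ca_movie"))
  shifts <- as.data.frame(shifts)
  if (!all(c("dx_px", "dy_px") %in% names(shifts)) ||
      nrow(shifts) != n_frames(movie)) {
    stop("`shifts` must have columns dx_px, dy_px and one row per frame",
         call. = FALSE)
  }
  arr <- unclass(movie)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  out <- arr
  for (j in seq_len(dim(arr)[3])) {
    out[, , j] <- .translate_frame(arr[, , j], shifts$dx_px[j], shifts$dy_px[j])
  }
  ca_movie(out, frame_duration_s = attr(movie, "frame_duration_s"),
           um_per_px = attr(movie, "um_per_px"))
}

# Sample frame at (y + dy, x + dx): undoes a content displacement of (dx, dy).
# dx, dy are scalars, so the bilinear fractions are shared by every pixel.
.translate_frame <- function(fr, dx, dy) {
  h <- nrow(fr); w <- ncol(fr)
  fill <- stats::median(fr)
  fy <- dy - floor(dy); fx <- dx - floor(dx)
  y0 <- seq_len(h) + floor(dy); x0 <- seq_len(w) + floor(dx)
  valid_y <- y0 >= 1 & (y0 + (fy > 0)) <= h
  valid_x <- x0 >= 1 & (x0 + (fx > 0)) <= w
  cy0 <- pmin(pmax(y0, 1), h); cy1 <- pmin(pmax(y0 + 1, 1), h)
  cx0 <- pmin(pmax(x0, 1), w); cx1 <- pmin(pmax(x0 + 1, 1), w)
  out <- (1 - fy) * (1 - fx) * fr[cy0, cx0, drop = FALSE] +
    (1 - fy) * fx * fr[cy0, cx1, drop = FALSE] +
    fy * (1 - fx) * fr[cy1, cx0, drop = FALSE] +
    fy * fx * fr[cy1, cx1, drop = FALSE]
  out[!valid_y, ] <- fill
  out[, !valid_x] <- fill
  out
}
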