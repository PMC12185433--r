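#' Specify a simulated imaging session
#'
#' Collects the parameters of one synthetic two-photon session: how many
#' cells, how long, how active, and how noisy. Event rates are given per
#' 5-minute (300 s) analysis window, one rate per window, which is also how
#' the downstream statistics consume the data. The defaults emulate awake
#' cortical L2/3 somata imaged at ~4 fps after a subconvulsive PTZ challenge:
#' four 5-min windows of ~1205 frames each, a comfortably positive baseline
#' luminance, a few percent photon noise, and a slow baseline drift.
#'
#' @param n_cells Number of cells to simulate.
#' @param rate_per_window Numeric vector of expected events per cell per
#'   300-s window; its length sets the number of windows (default 4 windows
#'   at 6 events/window).
#' @param frame_duration_s Frame interval in seconds (default 0.249).
#' @param n_frames Total frames; defaults to one full 300-s block per window
#'   (`round(300 / frame_duration_s)` frames each, 1205 at the default rate).
#' @param noise_sd SD of additive Gaussian luminance noise (default 5, i.e.
#'   5% of the default baseline).
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift in
#'   luminance units (default 2).
#' @param baseline_f0 Resting fluorescence in luminance units; must be > 0
#'   because dF/F is undefined at zero baseline (default 100).
#' @param motion_sd_px SD in pixels of per-frame rigid jitter applied when a
#'   movie is rendered (default 0; traces are unaffected).
#' @param seed Integer master seed; fully determines every simulated output.
#'
#' @return An object of class `ca_session_spec`.
#' @seealso [simulate_traces()], [simulate_movie()]
#' @export
session_spec <- function(n_cells,
                         rate_per_window = rep(6, 4),
                         frame_duration_s = 0.249,
                         n_frames = length(rate_per_window) *
                           round(300 / frame_duration_s),
                         noise_sd = 5,
                         drift_amplitude = 2,
                         baseline_f0 = 100,
                         motion_sd_px = 0,
                         seed = 1L) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
  if (any(!is.finite(rate_per_window)) || any(rate_per_window < 0)) {
    stop("`rate_per_window` must be non-negative and finite", call. = FALSE)
  }
  if (!is.finite(baseline_f0) || baseline_f0 <= 0) {
    stop("`baseline_f0` must be > 0 (dF/F is undefined otherwise)", call. = FALSE)
  }
  stopifnot(frame_duration_s > 0, n_frames >= 1, noise_sd >= 0,
            drift_amplitude >= 0, motion_sd_px >= 0)
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  structure(
    list(n_cells = as.integer(n_cells),
         rate_per_window = as.numeric(rate_per_window),
         frame_duration_s = frame_duration_s,
         n_frames = as.integer(n_frames),
         noise_sd = noise_sd,
         drift_amplitude = drift_amplitude,
         baseline_f0 = baseline_f0,
         motion_sd_px = motion_sd_px,
         seed = seed),
    class = "ca_session_spec"
  )
}

#' @export
print.ca_session_spec <- function(x, ...) {
  cat("<ca_session_spec> ", x$n_cells, " cells, ", x$n_frames, " frames @ ",
      x$frame_duration_s, " s (", length(x$rate_per_window), " windows)\n",
      sep = "")
  cat("  rates/window:", paste(x$rate_per_window, collapse = ", "),
      " f0:", x$baseline_f0, " noise:", x$noise_sd,
      " drift:", x$drift_amplitude, " motion:", x$motion_sd_px,
      " seed:", x$seed, "\n")
  invisible(x)
}

# Deterministic subordinate seeds: one per cell plus one session-level stream,
# all derived from the master seed so equal seeds give bit-identical output.
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` without disturbing the caller's RNG state: the simulators seed
# themselves from the session spec, so they are pure functions of the spec.
.with_own_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}
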