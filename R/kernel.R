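#' GCaMP6f-like calcium transient kernel
#'
#' Parameterises the impulse response of a fast genetically encoded calcium
#' indicator as a difference of exponentials: a sub-second rise followed by a
#' slower mono-exponential decay. The defaults approximate GCaMP6f kinetics
#' (rise ~50 ms, decay ~400 ms) with a unit peak amplitude expressed in
#' dF/F units.
#'
#' @param rise_time_s Rise time constant in seconds. Must be > 0.
#' @param decay_time_s Decay time constant in seconds. Must be > 0.
#' @param amplitude_dff Peak transient amplitude in dF/F units (unitless
#'   fractional fluorescence change). Must be > 0.
#' @param frame_duration_s Sampling interval in seconds (default 0.249 s,
#'   i.e. ~4 frames per second).
#'
#' @return An object of class `ca_kernel`: a list with the four fields above.
#' @examples
#' k <- transient_kernel()
#' w <- kernel_weights(k, length_s = 2.5)
#' plot(w, type = "h")
#' @export
transient_kernel <- function(rise_time_s = 0.05, decay_time_s = 0.4,
                             amplitude_dff = 1, frame_duration_s = 0.249) {
  for (nm in c("rise_time_s", "decay_time_s", "amplitude_dff", "frame_duration_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  structure(
    list(rise_time_s = rise_time_s, decay_time_s = decay_time_s,
         amplitude_dff = amplitude_dff, frame_duration_s = frame_duration_s),
    class = "ca_kernel"
  )
}

#' Discretise a transient kernel into frame weights
#'
#' Samples the difference-of-exponentials impulse response at the frame
#' interval and normalises it to a unit peak. The weight at time zero is
#' exactly 0 (the transient starts at onset), the sequence has a single
#' maximum, and beyond the peak successive weights decay by a factor
#' approaching `exp(-frame_duration_s / decay_time_s)`.
#'
#' @param kernel A [transient_kernel()].
#' @param length_s Kernel support in seconds; must cover at least
#'   5 decay time constants so the tail is negligible at truncation.
#'
#' @return A numeric vector of non-negative weights with `max(w) == 1`.
#' @export
kernel_weights <- function(kernel, length_s = 5 * kernel$decay_time_s) {
  stopifnot(inherits(kernel, "ca_kernel"))
  if (length_s < 5 * kernel$decay_time_s) {
    stop("`length_s` must cover at least 5 decay time constants", call. = FALSE)
  }
  t <- seq(0, length_s, by = kernel$frame_duration_s)
  if (isTRUE(all.equal(kernel$rise_time_s, kernel$decay_time_s))) {
    # degenerate limit of the two-exponential form: alpha function
    tau <- kernel$decay_time_s
    w <- (t / tau) * exp(1 - t / tau)
  } else {
    w <- exp(-t / kernel$decay_time_s) - exp(-t / kernel$rise_time_s)
    # for decay < rise the difference is uniformly non-positive; flip sign so
    # the kernel is the same shape with the roles of the constants exchanged
    if (max(w) <= 0) w <- -w
  }
  w / max(w)
}
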