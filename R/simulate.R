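#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# Draw Poisson event onsets for every cell and build the clean (noise-free)
# luminance signal f0 + drift + f0 * amplitude * (events (*) kernel).
# Window w covers frames (w-1)*fpw + 1 .. w*fpw where fpw = round(300 s / dt);
# a trailing partial window gets its rate scaled by its fraction of 300 s.
.simulate_session_core <- function(spec, kernel) {
  stopifnot(inherits(spec, "ca_session_spec"), inherits(kernel, "ca_kernel"))
  if (!isTRUE(all.equal(spec$frame_duration_s, kernel$frame_duration_s))) {
    stop("spec and kernel disagree on `frame_duration_s`", call. = FALSE)
  }
  dt <- spec$frame_duration_s
  fpw <- round(300 / dt)
  n <- spec$n_frames
  rates <- spec$rate_per_window
  w <- kernel_weights(kernel)
  L <- length(w)

  seeds <- .derive_seeds(spec$seed, spec$n_cells + 1L)
  window_of <- pmin((seq_len(n) - 1L) %/% fpw + 1L, length(rates))

  signal <- matrix(spec$baseline_f0, spec$n_cells, n)
  t_s <- (seq_len(n) - 1) * dt
  onsets <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    set.seed(seeds[i])
    cell_on <- integer(0)
    for (wi in seq_along(rates)) {
      frames_w <- which(window_of == wi)
      if (!length(frames_w) || rates[wi] == 0) next
      lambda <- rates[wi] * length(frames_w) / fpw
      k <- stats::rpois(1L, lambda)
      if (k > 0) cell_on <- c(cell_on, sort(sample(frames_w, k, replace = TRUE)))
    }
    onsets[[i]] <- sort(cell_on)
    if (spec$drift_amplitude > 0) {
      phase <- stats::runif(1L, 0, 2 * pi)
      signal[i, ] <- signal[i, ] +
        spec$drift_amplitude * sin(2 * pi * t_s / (n * dt) + phase)
    }
    for (o in cell_on) {
      idx <- o:min(o + L - 1L, n)
      signal[i, idx] <- signal[i, idx] +
        kernel$amplitude_dff * spec$baseline_f0 * w[seq_along(idx)]
    }
  }
  events <- tibble(
    cell_id = rep.int(seq_len(spec$n_cells), lengths(onsets)),
    onset_frame = unlist(onsets, use.names = FALSE) %||% integer(0)
  )
  list(signal = signal, events = events, session_seed = seeds[spec$n_cells + 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-cell fluorescence traces with ground truth
#'
#' Generates raw luminance traces for a session: a constant baseline plus a
#' slow sinusoidal drift, Poisson-timed calcium transients convolved with the
#' indicator kernel (scaled so the kernel amplitude is in dF/F units of the
#' baseline), and additive Gaussian noise. Event times are drawn
#' independently per cell with the per-window rates in `spec`; each cell uses
#' its own RNG substream derived from the master seed, so the same seed
#' reproduces the same session exactly.
#'
#' @param spec A [session_spec()].
#' @param kernel A [transient_kernel()]; its `frame_duration_s` must match
#'   the spec.
#'
#' @return A list of class `ca_sim_traces` with elements
#'   * `f`: cells x frames matrix of raw luminance,
#'   * `truth`: list with `events` (tibble `cell_id`, `onset_frame`),
#'   * `spec`, `kernel`: the inputs.
#' @examples
#' sim <- simulate_traces(session_spec(n_cells = 3, seed = 42))
#' dim(sim$f)
#' @export
simulate_traces <- function(spec, kernel = transient_kernel(frame_duration_s = spec$frame_duration_s)) {
  .with_own_rng({
    core <- .simulate_session_core(spec, kernel)
    f <- core$signal
    if (spec$noise_sd > 0) {
      set.seed(core$session_seed)
      f <- f + matrix(stats::rnorm(length(f), 0, spec$noise_sd), nrow(f), ncol(f))
    }
    structure(
      list(f = f, truth = list(events = core$events), spec = spec, kernel = kernel),
      class = "ca_sim_traces"
    )
  })
}
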