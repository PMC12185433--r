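#' Detection configuration
#'
#' Parameters of the calcium-event detection and validation procedure. The
#' defaults implement the standard soma-imaging recipe at ~4 fps: smoothing
#' over 5 frames, an onset threshold of 1.96 x the per-cell dF/F SD, an
#' 8-frame (~2 s) pre-onset baseline that must stay within 1 SD of zero, a
#' 3-s response window tested against the baseline at alpha = 0.05, and
#' 5-minute (300 s) counting windows.
#'
#' @param smooth_frames Width of the centered moving-average smoother in
#'   frames; must be odd (default 5).
#' @param z_threshold Onset threshold in multiples of the per-cell dF/F SD
#'   (default 1.96).
#' @param baseline_frames Number of pre-onset baseline samples (default 8,
#'   ~2 s at a 0.249-s frame interval).
#' @param response_window_s Length of the post-onset response window in
#'   seconds (default 3).
#' @param alpha Significance level of the response-vs-baseline test
#'   (default 0.05).
#' @param window_length_s Length of the event-counting window in seconds
#'   (default 300).
#' @return An object of class `ca_detection_config`.
#' @export
detection_config <- function(smooth_frames = 5, z_threshold = 1.96,
                             baseline_frames = 8, response_window_s = 3,
                             alpha = 0.05, window_length_s = 300) {
  vals <- c(smooth_frames = smooth_frames, z_threshold = z_threshold,
            baseline_frames = baseline_frames,
            response_window_s = response_window_s, alpha = alpha,
            window_length_s = window_length_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all detection parameters must be positive and finite", call. = FALSE)
  }
  if (smooth_frames %% 2 == 0) {
    stop("`smooth_frames` must be odd (a centered window needs a center)",
         call. = FALSE)
  }
  structure(
    list(smooth_frames = as.integer(smooth_frames), z_threshold = z_threshold,
         baseline_frames = as.integer(baseline_frames),
         response_window_s = response_window_s, alpha = alpha,
         window_length_s = window_length_s),
    class = "ca_detection_config"
  )
}

# Guard gap between the baseline window and the onset: the smoothing
# half-width, so centered smoothing cannot leak the transient backwards
# into the baseline samples.
.baseline_guard <- function(config) (config$smooth_frames - 1L) %/% 2L

#' Centered moving-average smoothing
#'
#' Smooths a dF/F series with a centered window of `smooth_frames` frames;
#' at the series edges the window is truncated to the available samples, so
#' the output has the same length as the input.
#'
#' @param x Numeric series.
#' @param smooth_frames Odd window width in frames.
#' @return Smoothed numeric series of the same length.
#' @export
smooth_trace <- function(x, smooth_frames = 5) {
  if (smooth_frames %% 2 == 0) {
    stop("`smooth_frames` must be odd (a centered window needs a center)",
         call. = FALSE)
  }
  n <- length(x)
  if (n < smooth_frames) stop("series shorter than the smoothing window", call. = FALSE)
  half <- (smooth_frames - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Find candidate event onsets by threshold crossing
#'
#' Candidate onsets are the frames at which the smoothed dF/F series crosses
#' `z_threshold * sd_cell` from below. The crossing is hysteretic: once the
#' smoothed series is above threshold, no new onset is registered until it
#' has fallen back below, so one supra-threshold excursion yields one
#' candidate. Onsets too early to accommodate the pre-onset baseline window
#' (plus the smoothing guard gap) are discarded.
#'
#' @param dff_row dF/F series of one cell.
#' @param sd_cell SD of the cell's full raw dF/F series; must be > 0.
#' @param config A [detection_config()].
#' @return Integer vector of candidate onset frames (1-based).
#' @export
detect_candidates <- function(dff_row, sd_cell, config = detection_config()) {
  stopifnot(inherits(config, "ca_detection_config"))
  if (!is.finite(sd_cell) || sd_cell <= 0) {
    stop("`sd_cell` must be > 0", call. = FALSE)
  }
  if (stats::sd(dff_row) == 0) {
    warning("zero-variance trace: no candidates")
    return(integer(0))
  }
  s <- smooth_trace(dff_row, config$smooth_frames)
  above <- s > config$z_threshold * sd_cell
  onsets <- which(above & !c(TRUE, above[-length(above)]))
  min_onset <- config$baseline_frames + .baseline_guard(config) + 1L
  onsets[onsets >= min_onset]
}

# Validation on the smoothed local trace with precomputed smoothed series.
# Returns a plain list (one scalar per field) so callers can assemble many
# events without per-event data-frame overhead.
.validate_onset_core <- function(s, onset, sd_cell, frame_duration_s, config) {
  guard <- .baseline_guard(config)
  n_resp <- round(config$response_window_s / frame_duration_s)
  n <- length(s)
  out <- list(
    onset_frame = as.integer(onset),
    onset_time_s = (onset - 1) * frame_duration_s,
    baseline_ok = NA, baseline_mean = NA_real_, response_mean = NA_real_,
    p_value = NA_real_, validated = FALSE, reason = NA_character_,
    local_trace = numeric(0)
  )
  if (onset - guard - config$baseline_frames < 1L) {
    out$reason <- "insufficient_pre_frames"
    return(out)
  }
  if (onset + n_resp - 1L > n) {
    out$reason <- "insufficient_post_frames"
    return(out)
  }
  base <- s[(onset - guard - config$baseline_frames):(onset - guard - 1L)]
  resp <- s[onset:(onset + n_resp - 1L)]
  out$baseline_ok <- all(abs(base) <= sd_cell)
  out$baseline_mean <- mean(base)
  out$response_mean <- mean(resp)
  out$p_value <- .welch_p(resp, base)
  out$validated <- isTRUE(out$baseline_ok) && out$p_value < config$alpha &&
    out$response_mean > out$baseline_mean
  out$local_trace <- s[(onset - guard - config$baseline_frames):(onset + n_resp - 1L)]
  out
}

# Two-sided Welch two-sample t-test p-value (equivalent to
# stats::t.test(x, y)$p.value, without the htest plumbing overhead);
# degenerate zero-variance-on-both-sides input gives p = 1.
.welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(1)
  stderr2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(stderr2)
  df <- stderr2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(t), df)
}

#' Validate one candidate event against its pre-onset baseline
#'
#' The local trace is the smoothed dF/F from the start of the baseline
#' window through the end of the response window. The baseline consists of
#' `baseline_frames` samples ending one smoothing half-width before onset
#' (the guard gap keeps the centered smoother from leaking the transient
#' into the baseline). The event is validated when (i) every baseline sample
#' lies within 1 SD of zero (a flat ~2-s baseline), (ii) a two-sided Welch
#' two-sample t-test finds the 3-s response mean significantly different
#' from the baseline mean at `alpha`, and (iii) the response mean exceeds
#' the baseline mean (transients are positive-going).
#'
#' @param dff_row dF/F series of one cell.
#' @param onset Candidate onset frame (1-based).
#' @param sd_cell SD of the cell's full raw dF/F series.
#' @param frame_duration_s Frame interval in seconds.
#' @param config A [detection_config()].
#' @return A one-row tibble: `onset_frame`, `onset_time_s`, `baseline_ok`,
#'   `baseline_mean`, `response_mean`, `p_value`, `validated`, `reason`
#'   (reason code when an event cannot be evaluated), `local_trace`
#'   (list-column).
#' @export
validate_event <- function(dff_row, onset, sd_cell, frame_duration_s = 0.249,
                           config = detection_config()) {
  stopifnot(inherits(config, "ca_detection_config"))
  s <- smooth_trace(dff_row, config$smooth_frames)
  v <- .validate_onset_core(s, onset, sd_cell, frame_duration_s, config)
  v$local_trace <- list(v$local_trace)
  tibble::new_tibble(v, nrow = 1L)
}

#' Count validated events per cell per window
#'
#' Events are assigned to counting windows by onset time: window k covers
#' onset times in `[(k-1) * window_length_s, k * window_length_s)`. Events
#' whose onset falls beyond the last complete window are dropped and
#' reported via the `dropped` attribute.
#'
#' @param events Tibble with columns `cell_id`, `onset_time_s` and
#'   optionally `validated` (only validated rows are counted when present).
#' @param cell_ids Vector of all cell ids that should appear in the table
#'   (cells with no events get zero counts).
#' @param n_windows Number of complete counting windows.
#' @param config A [detection_config()] (supplies `window_length_s`).
#' @param groups Optional per-cell group labels, matched to `cell_ids`.
#' @return A tibble of class `ca_counts` with columns `cell_id`, `group`,
#'   `window`, `window_label`, `count`; attribute `dropped` holds the number
#'   of validated events past the last complete window.
#' @export
count_events <- function(events, cell_ids, n_windows,
                         config = detection_config(), groups = NULL) {
  stopifnot(inherits(config, "ca_detection_config"), n_windows >= 1)
  events <- as_tibble(events)
  if ("validated" %in% names(events)) events <- events[isTRUE_vec(events$validated), ]
  if (nrow(events) && any(events$onset_time_s < 0 | !is.finite(events$onset_time_s))) {
    stop("invalid event: negative or non-finite onset time", call. = FALSE)
  }
  win <- floor(events$onset_time_s / config$window_length_s) + 1L
  dropped <- sum(win > n_windows)
  if (dropped > 0) {
    message(dropped, " event(s) beyond the last complete window were dropped")
  }
  events <- events[win <= n_windows, ]
  win <- win[win <= n_windows]

  minutes <- config$window_length_s / 60
  labels <- sprintf("%g-%g min", (seq_len(n_windows) - 1) * minutes + 1,
                    seq_len(n_windows) * minutes)
  if (is.null(groups)) groups <- rep(NA_character_, length(cell_ids))
  stopifnot(length(groups) == length(cell_ids))

  grid <- tidyr::expand_grid(cell_id = cell_ids, window = seq_len(n_windows))
  tallied <- dplyr::count(tibble(cell_id = events$cell_id, window = win),
                          .data$cell_id, .data$window, name = "count")
  out <- dplyr::left_join(grid, tallied, by = c("cell_id", "window"))
  out$count <- ifelse(is.na(out$count), 0L, out$count)
  out$group <- groups[match(out$cell_id, cell_ids)]
  out$window_label <- factor(labels[out$window], levels = labels)
  out <- out[, c("cell_id", "group", "window", "window_label", "count")]
  attr(out, "dropped") <- dropped
  class(out) <- c("ca_counts", class(out))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run the full detection pipeline on a dF/F object
#'
#' Composes smoothing, threshold-crossing candidate detection, baseline
#' validation and per-window counting for every cell. Deterministic given
#' its inputs.
#'
#' @param dff A [compute_dff()] object.
#' @param config A [detection_config()].
#' @param groups Optional per-cell group labels (length = number of cells).
#' @param n_windows Number of complete counting windows; defaults to the
#'   number that fit in the session.
#' @return A list of class `ca_detection`: `events` (tibble of all
#'   candidates with validation columns) and `counts` (a `ca_counts`
#'   table of validated events).
#' @export
run_detection <- function(dff, config = detection_config(), groups = NULL,
                          n_windows = NULL) {
  stopifnot(inherits(dff, "ca_dff"), inherits(config, "ca_detection_config"))
  dt <- dff$frame_duration_s
  nfr <- ncol(dff$dff)
  n_windows <- n_windows %||% max(1L, floor(nfr * dt / config$window_length_s))
  ids <- rownames(dff$dff)
  ev_list <- vector("list", nrow(dff$dff))
  for (i in seq_len(nrow(dff$dff))) {
    x <- dff$dff[i, ]
    sd_cell <- dff$sd[i]
    if (!is.finite(sd_cell) || sd_cell <= 0) next
    onsets <- detect_candidates(x, sd_cell, config)
    if (!length(onsets)) next
    s <- smooth_trace(x, config$smooth_frames)
    vs <- lapply(onsets, .validate_onset_core, s = s, sd_cell = sd_cell,
                 frame_duration_s = dt, config = config)
    ev_list[[i]] <- data.frame(
      cell_id = ids[i],
      onset_frame = vapply(vs, `[[`, integer(1), "onset_frame"),
      onset_time_s = vapply(vs, `[[`, numeric(1), "onset_time_s"),
      baseline_ok = vapply(vs, `[[`, logical(1), "baseline_ok"),
      baseline_mean = vapply(vs, `[[`, numeric(1), "baseline_mean"),
      response_mean = vapply(vs, `[[`, numeric(1), "response_mean"),
      p_value = vapply(vs, `[[`, numeric(1), "p_value"),
      validated = vapply(vs, `[[`, logical(1), "validated"),
      reason = vapply(vs, `[[`, character(1), "reason")
    )
    ev_list[[i]]$local_trace <- lapply(vs, `[[`, "local_trace")
  }
  events <- as_tibble(dplyr::bind_rows(ev_list))
  if (!nrow(events)) {
    events <- tibble(cell_id = character(), onset_frame = integer(),
                     onset_time_s = numeric(), baseline_ok = logical(),
                     baseline_mean = numeric(), response_mean = numeric(),
                     p_value = numeric(), validated = logical(),
                     reason = character(), local_trace = list())
  }
  counts <- count_events(events, cell_ids = ids, n_windows = n_windows,
                         config = config, groups = groups)
  structure(list(events = events, counts = counts, config = config),
            class = "ca_detection")
}

#' @export
print.ca_detection <- function(x, ...) {
  cat(sprintf("<ca_detection> %d candidate(s), %d validated across %d cell(s)\n",
              nrow(x$events), sum(x$events$validated),
              length(unique(x$counts$cell_id))))
  invisible(x)
}
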