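# Independent brute-force oracles used across the suite.

# Frame-by-frame candidate scan with hysteresis: an onset is a frame whose
# smoothed value exceeds the threshold while the previous frame's did not;
# onsets without room for the baseline window (plus the smoothing guard
# gap) are discarded. Kept as an explicit state machine, independent of the
# vectorised implementation.
oracle_candidates <- function(x, sd_cell, config = detection_config()) {
  s <- oracle_smooth(x, config$smooth_frames)
  thr <- config$z_threshold * sd_cell
  guard <- (config$smooth_frames - 1) %/% 2
  min_onset <- config$baseline_frames + guard + 1
  onsets <- integer(0)
  above <- TRUE   # no crossing can be registered at the first frame
  for (j in seq_along(s)) {
    if (s[j] > thr) {
      if (!above && j >= min_onset) onsets <- c(onsets, j)
      above <- TRUE
    } else {
      above <- FALSE
    }
  }
  onsets
}

# Direct windowed mean, truncated at the edges.
oracle_smooth <- function(x, k) {
  half <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(j) {
    mean(x[max(1, j - half):min(n, j + half)])
  }, numeric(1))
}

# Poisson count table for ANOVA-level tests: n1 + n2 cells, one count per
# 5-min window, rates per window and group.
make_counts <- function(n1, n2, rates1 = c(6, 6, 6, 6), rates2 = rates1,
                        labels = c("BDK", "PBS")) {
  nw <- length(rates1)
  tibble::tibble(
    cell_id = rep(seq_len(n1 + n2), each = nw),
    group = rep(c(rep(labels[1], n1), rep(labels[2], n2)), each = nw),
    window = rep(seq_len(nw), n1 + n2),
    count = c(stats::rpois(n1 * nw, rates1), stats::rpois(n2 * nw, rates2))
  )
}

# One-to-one greedy matching of detected onsets to ground-truth onsets
# within a frame tolerance; returns precision/recall/F1.
match_f1 <- function(truth, detected, tol = 2) {
  tp <- 0
  truth <- sort(truth)
  detected <- sort(detected)
  used <- rep(FALSE, length(detected))
  for (t in truth) {
    d <- which(!used & abs(detected - t) <= tol)
    if (length(d)) {
      used[d[1]] <- TRUE
      tp <- tp + 1
    }
  }
  prec <- if (length(detected)) tp / length(detected) else 1
  rec <- if (length(truth)) tp / length(truth) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

# End-to-end: simulate one two-group session (traces), run detection per
# group, return the combined count table.
sim_two_group_counts <- function(seed_a, seed_b, n_cells = 100,
                                 rates_a = c(6, 6, 12, 6),
                                 rates_b = c(6, 6, 6, 6)) {
  run_one <- function(seed, rates, label) {
    sim <- simulate_traces(session_spec(n_cells = n_cells,
                                        rate_per_window = rates, seed = seed))
    det <- run_detection(compute_dff(sim), groups = rep(label, n_cells))
    cnt <- det$counts
    cnt$cell_id <- paste0(label, "_", cnt$cell_id)
    cnt
  }
  dplyr::bind_rows(run_one(seed_a, rates_a, "BDK"),
                   run_one(seed_b, rates_b, "PBS"))
}
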