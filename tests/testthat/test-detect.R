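test_that("moving-average smoothing matches its direct definition", {
  expect_equal(smooth_trace(rep(2.5, 20), 5), rep(2.5, 20))
  x <- numeric(101); x[50] <- 1
  s <- smooth_trace(x, 5)
  expect_equal(s[48:52], rep(0.2, 5))
  expect_equal(sum(s), 1)
  set.seed(31)
  y <- stats::rnorm(200)
  expect_equal(smooth_trace(y, 5), oracle_smooth(y, 5), tolerance = 1e-12)
  expect_equal(smooth_trace(y, 9), oracle_smooth(y, 9), tolerance = 1e-12)
  expect_error(smooth_trace(y, 4), "odd")
  expect_error(detection_config(smooth_frames = 4), "odd")
})

test_that("flat and zero-variance traces yield no candidates", {
  cfg <- detection_config()
  expect_warning(out <- detect_candidates(rep(0, 100), 0.1, cfg),
                 "zero-variance")
  expect_length(out, 0)
  expect_error(detect_candidates(stats::rnorm(100), 0, cfg), "sd_cell")
})

test_that("one clear transient gives one onset, where the oracle says", {
  set.seed(32)
  x <- stats::rnorm(300, 0, 0.02)
  w <- kernel_weights(transient_kernel())
  x[100:(99 + length(w))] <- x[100:(99 + length(w))] + 0.5 * w
  on <- detect_candidates(x, sd(x), detection_config())
  expect_length(on, 1)
  expect_lt(abs(on - 100), 3)
  expect_identical(on, oracle_candidates(x, sd(x), detection_config()))
})

test_that("hysteresis merges a plateau but splits dipped excursions", {
  cfg <- detection_config()
  sd_cell <- 0.1   # threshold 0.196
  two <- numeric(200); two[30:40] <- 1; two[90:100] <- 1
  expect_length(detect_candidates(two, sd_cell, cfg), 2)
  plateau <- numeric(200); plateau[30:100] <- 1
  expect_length(detect_candidates(plateau, sd_cell, cfg), 1)
  expect_identical(detect_candidates(two, sd_cell, cfg),
                   oracle_candidates(two, sd_cell, cfg))
})

test_that("onsets without room for the baseline window are discarded", {
  cfg <- detection_config()
  early <- numeric(100); early[6:12] <- 1    # crossing before frame 12
  expect_length(detect_candidates(early, 0.1, cfg), 0)
})

test_that("raising the threshold never adds candidates", {
  set.seed(33)
  for (r in 1:10) {
    x <- as.numeric(stats::filter(stats::rnorm(500), 0.9, "recursive"))
    n <- vapply(c(1, 1.96, 3), function(z) {
      length(detect_candidates(x, sd(x), detection_config(z_threshold = z)))
    }, numeric(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("a baseline excursion beyond 1 SD vetoes validation", {
  sd_cell <- 0.1
  x <- numeric(200)
  x[88:95] <- 0.15                       # 1.5 SD inside the baseline window
  x[100:120] <- 1
  ev <- validate_event(x, 100, sd_cell, 0.249, detection_config())
  expect_false(ev$baseline_ok)
  expect_false(ev$validated)
})

test_that("a flat continuation is not an event", {
  ev <- validate_event(numeric(100), 50, 0.1, 0.249, detection_config())
  expect_equal(ev$p_value, 1)
  expect_false(ev$validated)
})

test_that("a clear transient validates, with the Welch test recomputed by hand", {
  set.seed(34)
  cfg <- detection_config()
  x <- stats::rnorm(300, 0, 0.05)
  w <- kernel_weights(transient_kernel())
  x[100:(99 + length(w))] <- x[100:(99 + length(w))] + 0.5 * w
  ev <- validate_event(x, 100, sd(x), 0.249, cfg)
  expect_true(ev$baseline_ok)
  expect_true(ev$validated)
  expect_lt(ev$p_value, 0.05)
  # independent recomputation on the same sample windows
  s <- oracle_smooth(x, 5)
  guard <- 2; n_resp <- round(3 / 0.249)
  base <- s[(100 - guard - 8):(100 - guard - 1)]
  resp <- s[100:(100 + n_resp - 1)]
  expect_equal(ev$p_value, stats::t.test(resp, base)$p.value, tolerance = 1e-12)
  expect_equal(ev$response_mean, mean(resp))
})

test_that("events too close to the end of the session are discarded", {
  x <- numeric(100); x[92:100] <- 1
  ev <- validate_event(x, 92, 0.1, 0.249, detection_config())
  expect_false(ev$validated)
  expect_equal(ev$reason, "insufficient_post_frames")
})

test_that("events land in 5-min windows by onset time", {
  ev <- tibble::tibble(cell_id = "a", onset_time_s = c(10, 250, 310),
                       validated = TRUE)
  counts <- count_events(ev, cell_ids = c("a", "b"), n_windows = 2)
  expect_equal(counts$count[counts$cell_id == "a"], c(2L, 1L))
  expect_equal(counts$count[counts$cell_id == "b"], c(0L, 0L))
  expect_equal(levels(counts$window_label), c("1-5 min", "6-10 min"))
})

test_that("events past the last complete window are dropped and reported", {
  ev <- tibble::tibble(cell_id = "a", onset_time_s = c(10, 650), validated = TRUE)
  expect_message(counts <- count_events(ev, "a", n_windows = 2), "dropped")
  expect_equal(sum(counts$count), 1L)
  expect_equal(attr(counts, "dropped"), 1L)
  bad <- tibble::tibble(cell_id = "a", onset_time_s = -5, validated = TRUE)
  expect_error(count_events(bad, "a", 2), "negative")
})

test_that("per-window counts equal a brute-force tally and conserve totals", {
  sim <- simulate_traces(session_spec(n_cells = 10, seed = 51))
  det <- run_detection(compute_dff(sim))
  ev <- det$events[det$events$validated, ]
  for (wi in 1:4) {
    manual <- sum(ev$onset_time_s >= (wi - 1) * 300 & ev$onset_time_s < wi * 300)
    expect_equal(sum(det$counts$count[det$counts$window == wi]), manual)
  }
  in_windows <- sum(ev$onset_time_s < 4 * 300)
  expect_equal(sum(det$counts$count), in_windows)
})

test_that("candidate onsets equal the exhaustive scan on every cell", {
  sim <- simulate_traces(session_spec(n_cells = 5, rate_per_window = c(5, 5),
                                      n_frames = 2000, seed = 52))
  d <- compute_dff(sim)
  for (i in 1:5) {
    expect_identical(detect_candidates(d$dff[i, ], d$sd[i]),
                     oracle_candidates(d$dff[i, ], d$sd[i]))
  }
})

test_that("detection recovers ground-truth events with F1 >= 0.9", {
  sim <- simulate_traces(session_spec(n_cells = 30, seed = 53))
  det <- run_detection(compute_dff(sim))
  scores <- vapply(1:30, function(i) {
    truth <- sim$truth$events$onset_frame[sim$truth$events$cell_id == i]
    found <- det$events$onset_frame[det$events$cell_id == as.character(i) &
                                      det$events$validated]
    match_f1(truth, found)["f1"]
  }, numeric(1))
  expect_gte(mean(scores), 0.9)
})

test_that("noise-only sessions stay below 0.5 false positives per cell-window", {
  sim <- simulate_traces(session_spec(n_cells = 30,
                                      rate_per_window = rep(0, 4), seed = 54))
  det <- run_detection(compute_dff(sim))
  expect_lte(mean(det$counts$count), 0.5)
})

test_that("the default configuration states the published parameters", {
  cfg <- detection_config()
  expect_equal(cfg$z_threshold, 1.96)
  expect_equal(cfg$smooth_frames, 5L)
  expect_equal(cfg$baseline_frames, 8L)
  expect_equal(cfg$response_window_s, 3)
  expect_equal(cfg$window_length_s, 300)
})
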