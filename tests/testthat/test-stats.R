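# Deterministic "perfectly distributed" samples via quantile spacing keep the
# gating tests free of seed luck.
norm_sample <- function(n, mean = 0, sd = 1) mean + sd * stats::qnorm(stats::ppoints(n))

test_that("test gating follows normality and variance checks", {
  expect_equal(choose_two_group_test(norm_sample(40), norm_sample(40, 1)), "t")
  expect_equal(choose_two_group_test(norm_sample(30, sd = 1),
                                     norm_sample(30, sd = 4)), "welch")
  skewed <- stats::qexp(stats::ppoints(50))
  expect_equal(choose_two_group_test(skewed, norm_sample(50)), "mann-whitney")
  expect_error(choose_two_group_test(1:2, 1:5), "insufficient")
})

test_that("gating holds up across random draws", {
  set.seed(61)
  picks <- replicate(20, choose_two_group_test(stats::rexp(50), stats::rnorm(50)))
  expect_gte(mean(picks == "mann-whitney"), 0.9)
  picks2 <- replicate(20, choose_two_group_test(stats::rnorm(30, sd = 1),
                                                stats::rnorm(30, sd = 4)))
  expect_gte(mean(picks2 == "welch"), 0.8)
})

test_that("identical samples give null effect sizes", {
  x <- norm_sample(20)
  res <- two_group_compare(x, x)
  expect_equal(res$delta_mean, 0)
  expect_equal(res$effect_size, 0)
  expect_gt(res$p_value, 0.99)
})

test_that("fully separated samples give rank-biserial r = 1", {
  res <- two_group_compare(11:20, 1:10, test = "mann-whitney")
  expect_equal(res$effect_size, 1)
  expect_equal(res$effect_type, "rank_biserial_r")
  res2 <- two_group_compare(1:10, 11:20, test = "mann-whitney")
  expect_equal(res2$effect_size, -1)
})

test_that("Cohen's d equals the pooled-SD hand formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  res <- two_group_compare(x, y, test = "t")
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(res$effect_size, (mean(x) - mean(y)) / sp)
  expect_equal(res$delta_mean, -1)
  expect_equal(res$sem_delta, sqrt(var(x) / 4 + var(y) / 4))
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(62)
  x <- stats::rexp(15); y <- stats::rexp(20) + 0.3
  p1 <- two_group_compare(x, y, test = "mann-whitney")$p_value
  p2 <- two_group_compare(exp(x), exp(y), test = "mann-whitney")$p_value
  p3 <- two_group_compare(x^3, y^3, test = "mann-whitney")$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("all-tied samples warn as degenerate", {
  expect_warning(res <- two_group_compare(rep(1, 5), rep(1, 6),
                                          test = "mann-whitney"),
                 "degenerate")
  expect_equal(res$effect_size, 0)
})

test_that("Kruskal-Wallis requires three groups of n >= 3", {
  expect_error(kruskal_wallis_test(1:10, rep(c("a", "b"), 5)),
               "two_group_compare")
  expect_error(kruskal_wallis_test(1:9, c("a", "a", "a", "b", "b", "b", "c", "c", "d")),
               "insufficient")
})

test_that("Kruskal-Wallis H matches the rank-arithmetic formula", {
  vals <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis_test(vals, grp)
  # tie-corrected H computed from first principles
  r <- rank(vals)
  n <- 9
  H <- (12 / (n * (n + 1))) * sum(tapply(r, grp, sum)^2 / 3) - 3 * (n + 1)
  ties <- table(vals)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(res$statistic_H, H)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 6L)
})

test_that("a 3-SD shifted group is detected", {
  set.seed(63)
  for (r in 1:3) {
    vals <- c(stats::rnorm(10), stats::rnorm(10), stats::rnorm(10, 3))
    expect_lt(kruskal_wallis_test(vals, rep(c("a", "b", "c"), each = 10))$p_value,
              0.01)
  }
})

test_that("Kruskal-Wallis holds its size under the null", {
  set.seed(64)
  rej <- mean(replicate(200, {
    kruskal_wallis_test(stats::rnorm(30), rep(c("a", "b", "c"), 10))$p_value < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})

test_that("mixed ANOVA df follow the between-subjects design", {
  set.seed(65)
  a <- mixed_anova(make_counts(161, 145))
  g <- a$table[a$table$effect == "group", ]
  expect_equal(c(g$df1, g$df2), c(1, 304))
  w <- a$table[a$table$effect == "window", ]
  expect_equal(c(w$df1, w$df2), c(3, 912))    # (w-1), (N-g)(w-1)
  b <- mixed_anova(make_counts(15, 24))
  expect_equal(b$table$df2[1], 37)
})

test_that("identical groups carry a near-zero group effect", {
  set.seed(66)
  a <- mixed_anova(make_counts(100, 100))
  g <- a$table[a$table$effect == "group", ]
  expect_lt(g$partial_eta_sq, 0.05)
  expect_true(all(a$table$partial_eta_sq >= 0 & a$table$partial_eta_sq <= 1))
})

test_that("mixed ANOVA matches an explicit sums-of-squares decomposition", {
  set.seed(67)
  n_per <- 10; nw <- 3
  d <- make_counts(n_per, n_per, rates1 = c(4, 6, 8), rates2 = c(4, 4, 4))[
    , c("cell_id", "group", "window", "count")]
  a <- mixed_anova(d)

  # textbook balanced mixed-design decomposition
  y <- d$count
  grand <- mean(y)
  cell_means <- tapply(y, d$cell_id, mean)
  group_means <- tapply(y, d$group, mean)
  win_means <- tapply(y, d$window, mean)
  cw_means <- tapply(y, list(d$group, d$window), mean)
  n_cells <- 2 * n_per
  ss_between_cells <- nw * sum((cell_means - grand)^2)
  ss_group <- nw * n_per * sum((group_means - grand)^2)
  ss_subj_within <- ss_between_cells - ss_group
  ss_window <- n_cells * sum((win_means - grand)^2)
  ss_inter <- n_per * sum((cw_means - grand)^2) - ss_group - ss_window
  ss_total <- sum((y - grand)^2)
  ss_err_within <- ss_total - ss_between_cells - ss_window - ss_inter

  f_group <- (ss_group / 1) / (ss_subj_within / (n_cells - 2))
  f_window <- (ss_window / (nw - 1)) / (ss_err_within / ((n_cells - 2) * (nw - 1)))

  g <- a$table[a$table$effect == "group", ]
  w <- a$table[a$table$effect == "window", ]
  i <- a$table[a$table$effect == "group:window", ]
  expect_equal(g$statistic, f_group, tolerance = 1e-10)
  expect_equal(w$statistic, f_window, tolerance = 1e-10)
  expect_equal(g$partial_eta_sq, ss_group / (ss_group + ss_subj_within),
               tolerance = 1e-10)
  expect_equal(w$partial_eta_sq, ss_window / (ss_window + ss_err_within),
               tolerance = 1e-10)
  expect_equal(i$partial_eta_sq, ss_inter / (ss_inter + ss_err_within),
               tolerance = 1e-10)
  # components add back to the total in the balanced case
  expect_equal(ss_group + ss_subj_within + ss_window + ss_inter + ss_err_within,
               ss_total, tolerance = 1e-10)
})

test_that("incomplete designs are rejected", {
  set.seed(68)
  d <- make_counts(5, 5)
  expect_error(mixed_anova(d[-1, ]), "exactly one count per window")
  d2 <- make_counts(5, 5)
  d2$group <- NA_character_
  expect_error(mixed_anova(d2), "group label")
})

test_that("percent change is plain mean arithmetic per window", {
  d <- tibble::tibble(cell_id = rep(1:4, each = 2),
                      group = rep(c("BDK", "PBS"), each = 4),
                      window = rep(1:2, 4),
                      count = c(3, 3, 3, 3, 2, 2, 2, 2))
  pc <- percent_change(d, "PBS")
  expect_equal(pc$pct_change, c(50, 50))
  d$count <- rep(2, 8)
  expect_equal(percent_change(d, "PBS")$pct_change, c(0, 0))
  d$count[d$group == "PBS"] <- 0
  expect_error(percent_change(d, "PBS"), "undefined percentage")
})

test_that("a simulated 2x rate ratio appears as ~+100% in ground-truth counts", {
  set.seed(69)
  d <- make_counts(100, 100, rates1 = c(6, 6, 12, 6), rates2 = rep(6, 4))
  pc <- percent_change(d, "PBS")
  expect_lt(abs(pc$pct_change[pc$window == 3] - 100), 25)
  expect_true(all(abs(pc$pct_change[pc$window != 3]) < 25))
})

test_that("cumulative dose sums the schedule up to the triggering injection", {
  s <- ptz_schedule()
  expect_equal(cumulative_dose(s, 1), 40)
  expect_equal(cumulative_dose(s, 3), 50)
  expect_equal(cumulative_dose(s, 5), 70)      # 40 + 5 + 5 + 10 + 10
  # brute-force summation oracle on arbitrary schedules
  set.seed(70)
  for (r in 1:5) {
    doses <- stats::runif(6, 1, 20)
    sch <- dose_schedule(doses[1], doses[-1], cumsum(stats::runif(5, 1, 10)))
    k <- sample(1:6, 1)
    expect_equal(cumulative_dose(sch, k), sum(doses[1:k]))
  }
  expect_error(cumulative_dose(s, 0), "invalid index")
  expect_error(cumulative_dose(s, nrow(s) + 1), "invalid index")
  expect_error(dose_schedule(40, c(5, 5), c(10, 10)), "strictly increasing")
  expect_error(dose_schedule(-1, 5, 10), "positive")
})
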