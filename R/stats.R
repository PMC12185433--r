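#' Choose the two-group test by normality and variance gating
#'
#' Mirrors the conventional decision tree: Shapiro-Wilk normality on both
#' samples; if both look normal, an F-test of variances decides between the
#' pooled-variance t-test and the Welch t-test; if either sample is
#' non-normal, the Mann-Whitney U test is used.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param alpha Significance level for the gating tests (default 0.05).
#' @return One of `"t"`, `"welch"`, `"mann-whitney"`.
#' @export
choose_two_group_test <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("insufficient sample: each group needs n >= 3", call. = FALSE)
  }
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  if (!normal(x) || !normal(y)) return("mann-whitney")
  if (stats::var.test(x, y)$p.value > alpha) "t" else "welch"
}

#' Compare two groups with the gated test and an effect size
#'
#' Runs the test selected by [choose_two_group_test()] (or a caller-supplied
#' one), two-tailed and unpaired. Effect size is Cohen's d (pooled SD) for
#' the t-family and the rank-biserial correlation \code{r = 2U/(n1 n2) - 1}
#' for Mann-Whitney.
#'
#' @param x,y Numeric samples.
#' @param alpha Gating level passed to [choose_two_group_test()].
#' @param test Optional override: `"t"`, `"welch"` or `"mann-whitney"`.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `delta_mean`
#'   (`mean(x) - mean(y)`), `sem_delta`, `n1`, `n2`, `effect_size`,
#'   `effect_type`.
#' @export
two_group_compare <- function(x, y, alpha = 0.05, test = NULL) {
  test <- test %||% choose_two_group_test(x, y, alpha)
  test <- match.arg(test, c("t", "welch", "mann-whitney"))
  n1 <- length(x); n2 <- length(y)
  delta <- mean(x) - mean(y)
  sem <- sqrt(stats::var(x) / n1 + stats::var(y) / n2)
  if (test == "mann-whitney") {
    if (stats::sd(c(x, y)) == 0) {
      warning("degenerate data: all pooled values are tied")
      stat <- n1 * n2 / 2; p <- 1
    } else {
      wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
      stat <- unname(wt$statistic)   # U for x over y
      p <- wt$p.value
    }
    eff <- 2 * stat / (n1 * n2) - 1
    eff_type <- "rank_biserial_r"
  } else {
    tt <- stats::t.test(x, y, var.equal = (test == "t"))
    stat <- unname(tt$statistic)
    p <- tt$p.value
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    eff <- if (sp == 0) 0 else delta / sp
    eff_type <- "cohen_d"
  }
  tibble(test = test, statistic = stat, p_value = p, delta_mean = delta,
         sem_delta = sem, n1 = n1, n2 = n2,
         effect_size = eff, effect_type = eff_type)
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected Kruskal-Wallis H with its eta-squared effect size
#' `(H - k + 1) / (n - k)`. Because software sometimes reports an F for
#' heteroscedastic multi-group designs, the Welch one-way ANOVA F is also
#' returned alongside H; neither is derived from the other.
#'
#' @param values Numeric response.
#' @param group Group labels (coerced to factor; >= 3 levels, each n >= 3).
#' @return A one-row tibble: `statistic_H`, `df_between` (k - 1),
#'   `df_within` (n - k), `p_value`, `eta_sq`, and the Welch one-way F
#'   (`welch_F`, `welch_df1`, `welch_df2`, `welch_p`).
#' @export
kruskal_wallis_test <- function(values, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 3) {
    stop("fewer than 3 groups: use two_group_compare()", call. = FALSE)
  }
  if (any(table(group) < 3)) {
    stop("insufficient sample: each group needs n >= 3", call. = FALSE)
  }
  n <- length(values)
  kw <- stats::kruskal.test(values, group)
  H <- unname(kw$statistic)
  welch <- tryCatch(stats::oneway.test(values ~ group, var.equal = FALSE),
                    error = function(e) NULL)
  tibble(
    statistic_H = H,
    df_between = k - 1L,
    df_within = n - k,
    p_value = kw$p.value,
    eta_sq = (H - k + 1) / (n - k),
    welch_F = if (is.null(welch)) NA_real_ else unname(welch$statistic),
    welch_df1 = if (is.null(welch)) NA_real_ else unname(welch$parameter[1]),
    welch_df2 = if (is.null(welch)) NA_real_ else unname(welch$parameter[2]),
    welch_p = if (is.null(welch)) NA_real_ else welch$p.value
  )
}

#' Mixed two-way ANOVA on an event-count table
#'
#' Fits the group comparison used for windowed event counts: group is the
#' between-subjects factor, window (timepoint) the within-subjects factor,
#' and each cell is a subject measured once per window. The between-subjects
#' group effect is tested against subject-within-group variation with
#' degrees of freedom `(g - 1, N - g)` for N cells in g groups; window and
#' the group x window interaction are tested within subjects. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` with the error term of
#' the stratum the effect is tested in.
#'
#' @param counts A [count_events()] table, or any data frame with columns
#'   `cell_id`, `group`, `window`, `count` (complete: every cell has one
#'   count in every window).
#' @return An object of class `ca_anova`; see [tidy.ca_anova()] and
#'   [glance.ca_anova()].
#' @export
mixed_anova <- function(counts) {
  d <- as.data.frame(counts)[, c("cell_id", "group", "window", "count")]
  if (any(is.na(d$group))) stop("every cell needs a group label", call. = FALSE)
  d$cell_id <- factor(d$cell_id)
  d$group <- factor(d$group)
  d$window <- factor(d$window)
  if (nlevels(d$group) < 2 || nlevels(d$window) < 2) {
    stop("invalid design: need >= 2 groups and >= 2 windows", call. = FALSE)
  }
  tab <- table(d$cell_id, d$window)
  if (any(tab != 1L)) {
    stop("invalid design: every cell must have exactly one count per window",
         call. = FALSE)
  }
  if (any(rowSums(table(d$cell_id, d$group) > 0) != 1L)) {
    stop("invalid design: each cell must belong to exactly one group",
         call. = FALSE)
  }

  fit <- stats::aov(count ~ group * window + Error(cell_id), data = d)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: cell_id"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  rn <- function(df) trimws(rownames(df))
  pick <- function(df, term) df[rn(df) == term, , drop = FALSE]
  res_b <- pick(btw, "Residuals"); res_w <- pick(wth, "Residuals")
  eff <- function(df, term, res) {
    e <- pick(df, term)
    tibble(effect = term, df1 = e$Df, df2 = res$Df,
           sumsq = e$`Sum Sq`, sumsq_error = res$`Sum Sq`,
           statistic = e$`F value`, p_value = e$`Pr(>F)`,
           partial_eta_sq = e$`Sum Sq` / (e$`Sum Sq` + res$`Sum Sq`))
  }
  table_out <- dplyr::bind_rows(
    eff(btw, "group", res_b),
    eff(wth, "window", res_w),
    eff(wth, "group:window", res_w)
  )
  structure(
    list(table = table_out,
         n_cells = nlevels(d$cell_id), n_groups = nlevels(d$group),
         n_windows = nlevels(d$window), fit = fit),
    class = "ca_anova"
  )
}

#' @export
print.ca_anova <- function(x, ...) {
  g <- x$table[x$table$effect == "group", ]
  cat(sprintf("<ca_anova> mixed two-way ANOVA: %d cells, %d groups, %d windows\n",
              x$n_cells, x$n_groups, x$n_windows))
  cat(sprintf("  group: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              g$df1, g$df2, g$statistic, g$p_value, g$partial_eta_sq))
  print(as.data.frame(x$table[, c("effect", "df1", "df2", "statistic",
                                  "p_value", "partial_eta_sq")]),
        row.names = FALSE)
  invisible(x)
}

#' Percent change in mean event counts relative to a reference group
#'
#' For every counting window and every non-reference group, reports
#' `100 * (mean_test - mean_ref) / mean_ref` of the per-cell counts.
#'
#' @param counts A [count_events()] table (or compatible data frame).
#' @param reference_group Label of the reference (e.g. vehicle) group.
#' @return A tibble with `window`, `window_label` (when available), `group`
#'   and `pct_change`.
#' @export
percent_change <- function(counts, reference_group) {
  d <- as_tibble(as.data.frame(counts))
  stopifnot(all(c("group", "window", "count") %in% names(d)))
  if (!reference_group %in% d$group) {
    stop("`reference_group` not present in the table", call. = FALSE)
  }
  means <- dplyr::summarise(dplyr::group_by(d, .data$group, .data$window),
                            mean_count = mean(.data$count), .groups = "drop")
  ref <- means[means$group == reference_group, c("window", "mean_count")]
  names(ref)[2] <- "ref_mean"
  if (any(ref$ref_mean == 0)) {
    stop("undefined percentage: reference mean is zero in window(s) ",
         paste(ref$window[ref$ref_mean == 0], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::inner_join(means[means$group != reference_group, ], ref,
                           by = "window")
  out$pct_change <- 100 * (out$mean_count - out$ref_mean) / out$ref_mean
  if ("window_label" %in% names(d)) {
    lab <- unique(d[, c("window", "window_label")])
    out <- dplyr::left_join(out, lab, by = "window")
  }
  out[, intersect(c("window", "window_label", "group", "pct_change"),
                  names(out))]
}
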