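#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mixed ANOVA result
#'
#' @param x A [mixed_anova()] object.
#' @param ... Unused.
#' @return A tibble with one row per effect (`group`, `window`,
#'   `group:window`): `effect`, `df1`, `df2`, `sumsq`, `sumsq_error`,
#'   `statistic`, `p_value`, `partial_eta_sq`.
#' @export
tidy.ca_anova <- function(x, ...) x$table

#' One-row summary of a mixed ANOVA
#'
#' @param x A [mixed_anova()] object.
#' @param ... Unused.
#' @return A one-row tibble with the between-subjects group test
#'   (`F_group`, `df1`, `df2`, `p_group`) and the three partial eta-squared
#'   values, plus the design size.
#' @export
glance.ca_anova <- function(x, ...) {
  g <- x$table[x$table$effect == "group", ]
  w <- x$table[x$table$effect == "window", ]
  i <- x$table[x$table$effect == "group:window", ]
  tibble(
    F_group = g$statistic, df1 = g$df1, df2 = g$df2, p_group = g$p_value,
    partial_eta_sq_group = g$partial_eta_sq,
    partial_eta_sq_window = w$partial_eta_sq,
    partial_eta_sq_interaction = i$partial_eta_sq,
    n_cells = x$n_cells, n_groups = x$n_groups, n_windows = x$n_windows
  )
}

#' Tidy a detection result into its event table
#'
#' @param x A [run_detection()] object.
#' @param ... Unused.
#' @return The candidate-event tibble (without the `local_trace` column).
#' @export
tidy.ca_detection <- function(x, ...) {
  x$events[, setdiff(names(x$events), "local_trace")]
}

#' One-row summary of a detection result
#'
#' @param x A [run_detection()] object.
#' @param ... Unused.
#' @return A one-row tibble: candidate and validated event totals, number of
#'   cells and windows, and mean validated events per cell per window.
#' @export
glance.ca_detection <- function(x, ...) {
  n_cells <- length(unique(x$counts$cell_id))
  n_windows <- max(x$counts$window)
  tibble(
    n_candidates = nrow(x$events),
    n_validated = sum(x$events$validated),
    n_cells = n_cells, n_windows = n_windows,
    mean_count = mean(x$counts$count)
  )
}
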