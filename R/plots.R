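#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar geom_hline labs position_dodge facet_wrap
#' @export
ggplot2::autoplot

#' Plot dF/F traces with detected events
#'
#' Stacks a few cells' dF/F traces against time and, when a detection result
#' is supplied, marks validated event onsets.
#'
#' @param dff A [compute_dff()] object.
#' @param cells Which cells to draw (indices or ids; default first 5).
#' @param detection Optional [run_detection()] result for onset markers.
#' @param spacing Vertical offset between stacked traces in dF/F units.
#' @return A ggplot object.
#' @export
plot_traces <- function(dff, cells = head(rownames(dff$dff), 5),
                        detection = NULL, spacing = 1.5) {
  stopifnot(inherits(dff, "ca_dff"))
  if (is.numeric(cells)) cells <- rownames(dff$dff)[cells]
  dt <- dff$frame_duration_s
  long <- purrr::map_dfr(seq_along(cells), function(i) {
    tibble(cell_id = cells[i],
           time_s = (seq_len(ncol(dff$dff)) - 1) * dt,
           dff = dff$dff[cells[i], ] + (i - 1) * spacing)
  })
  p <- ggplot(long, aes(x = .data$time_s, y = .data$dff,
                        group = .data$cell_id)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = sprintf("dF/F (offset %.1f per cell)", spacing))
  if (!is.null(detection)) {
    ev <- detection$events
    ev <- ev[ev$validated & ev$cell_id %in% cells, ]
    if (nrow(ev)) {
      ev$offset <- (match(ev$cell_id, cells) - 1) * spacing
      p <- p + geom_point(data = ev,
                          aes(x = .data$onset_time_s, y = .data$offset),
                          inherit.aes = FALSE, colour = "red", shape = 17)
    }
  }
  p
}

#' Mean event counts per window by group
#'
#' Bar chart of the mean validated event count per cell in each counting
#' window, with standard-error bars, split by group.
#'
#' @param object A [count_events()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_counts <- function(object, ...) {
  d <- as_tibble(as.data.frame(object))
  sm <- dplyr::summarise(dplyr::group_by(d, .data$group, .data$window_label),
                         mean = mean(.data$count),
                         sem = stats::sd(.data$count) / sqrt(dplyr::n()),
                         .groups = "drop")
  ggplot(sm, aes(x = .data$window_label, y = .data$mean, fill = .data$group)) +
    geom_col(position = position_dodge(0.9)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(0.9), width = 0.3) +
    labs(x = NULL, y = "mean events / cell / window", fill = NULL)
}

#' Estimated rigid shifts over time
#'
#' @param object A shift table from [estimate_shifts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_shifts <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), c("dx_px", "dy_px"),
                           names_to = "axis", values_to = "shift_px")
  ggplot(d, aes(x = .data$frame, y = .data$shift_px, colour = .data$axis)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "frame", y = "shift (px)", colour = NULL)
}
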