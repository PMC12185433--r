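#' Define a PTZ titration schedule
#'
#' A seizure-susceptibility titration is an initial intraperitoneal PTZ dose
#' followed by scheduled booster doses until a Grade V (generalized
#' tonic-clonic) seizure is observed; the readout compared between groups is
#' the cumulative dose at that point.
#'
#' @param initial_dose Initial dose in mg/kg (> 0), given at time 0.
#' @param booster_doses Numeric vector of booster doses in mg/kg (> 0).
#' @param booster_offsets_min Minutes after the initial dose at which each
#'   booster is given; strictly increasing, same length as `booster_doses`.
#' @return An object of class `ca_dose_schedule`: a tibble with one row per
#'   injection (`injection`, `dose_mg_kg`, `offset_min`).
#' @seealso [ptz_schedule()] for the standard titration, [cumulative_dose()]
#' @export
dose_schedule <- function(initial_dose, booster_doses, booster_offsets_min) {
  stopifnot(length(booster_doses) == length(booster_offsets_min))
  doses <- c(initial_dose, booster_doses)
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    stop("all doses must be positive", call. = FALSE)
  }
  offs <- c(0, booster_offsets_min)
  if (any(diff(offs) <= 0)) {
    stop("booster offsets must be strictly increasing", call. = FALSE)
  }
  out <- tibble(injection = seq_along(doses), dose_mg_kg = doses,
                offset_min = offs)
  class(out) <- c("ca_dose_schedule", class(out))
  out
}

#' Standard PTZ titration schedule
#'
#' The titration used for seizure-threshold comparisons: an initial dose
#' (40 mg/kg by default; 30 mg/kg for more susceptible cohorts), then two
#' 5 mg/kg boosters 10 min apart, then 10 mg/kg boosters every 5 min.
#'
#' @param initial_dose Initial dose in mg/kg (default 40).
#' @param n_top_up Number of trailing 10 mg/kg boosters to schedule
#'   (default 10).
#' @return A [dose_schedule()].
#' @export
ptz_schedule <- function(initial_dose = 40, n_top_up = 10) {
  dose_schedule(initial_dose,
                booster_doses = c(5, 5, rep(10, n_top_up)),
                booster_offsets_min = c(10, 20, 20 + 5 * seq_len(n_top_up)))
}

#' Cumulative dose at the Grade V seizure
#'
#' Sums the scheduled doses up to and including the injection at which the
#' Grade V seizure was observed.
#'
#' @param schedule A [dose_schedule()].
#' @param grade5_at_injection 1-based index of the triggering injection.
#' @return Cumulative dose in mg/kg.
#' @examples
#' cumulative_dose(ptz_schedule(), 3)  # 40 + 5 + 5 = 50 mg/kg
#' @export
cumulative_dose <- function(schedule, grade5_at_injection) {
  stopifnot(inherits(schedule, "ca_dose_schedule"))
  k <- grade5_at_injection
  if (!is.numeric(k) || length(k) != 1L || k != round(k) ||
      k < 1 || k > nrow(schedule)) {
    stop("invalid index: `grade5_at_injection` must name a scheduled injection",
         call. = FALSE)
  }
  sum(schedule$dose_mg_kg[seq_len(k)])
}
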