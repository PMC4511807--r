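#' Glucose depletion schedule
#'
#' Piecewise-linear extracellular glucose concentration over a depletion
#' assay: glucose is held at `g_s` for `hold` minutes, ramped linearly to
#' zero over the depletion time `Td`, then held at zero for the remainder of
#' the run. Galactose is constant throughout (recorded for bookkeeping; it
#' does not enter the schedule's value).
#'
#' @param Td Depletion time in minutes, `>= 0` (0 gives a step).
#' @param hold Hold duration at `g_s` before depletion starts (minutes).
#' @param g_s Initial glucose concentration (% w/v).
#' @param total Total assay duration (minutes); must cover `hold + Td`.
#' @param galactose Constant galactose concentration (% w/v).
#' @return An object of class `"glucose_schedule"`.
#' @examples
#' s <- make_schedule(Td = 240)
#' glucose_at(s, c(100, 360, 10000))
#' @export
make_schedule <- function(Td, hold = 240, g_s = 2, total = 900,
                          galactose = 2) {
  if (Td < 0) stop("Td must be >= 0 (minutes)")
  if (hold < 0) stop("hold must be >= 0 (minutes)")
  if (g_s <= 0) stop("g_s must be > 0")
  if (total < hold + Td)
    stop("total assay duration must be at least hold + Td")
  structure(list(hold = hold, Td = Td, g_s = g_s, total = total,
                 galactose = galactose),
            class = "glucose_schedule")
}

#' Evaluate a glucose schedule
#'
#' @param schedule A [make_schedule()] object.
#' @param t Time(s) in minutes, `>= 0`.
#' @return Glucose concentration(s) (% w/v).
#' @export
glucose_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "glucose_schedule"))
  if (any(t < 0)) stop("t must be >= 0 (minutes)")
  u <- t - schedule$hold
  g <- ifelse(u <= 0, schedule$g_s,
              ifelse(schedule$Td <= 0 | u >= schedule$Td, 0,
                     schedule$g_s * (1 - u / schedule$Td)))
  as.numeric(g)
}

#' @export
print.glucose_schedule <- function(x, ...) {
  cat(sprintf(
    "Glucose schedule: %.3g%% held %g min, ramp to 0%% over %g min, total %g min (galactose %.3g%%)\n",
    x$g_s, x$hold, x$Td, x$total, x$galactose))
  invisible(x)
}

#' Standard grid of depletion times
#'
#' Ten depletion times evenly spanning 0 to 8 hours — the conditions of the
#' reference depletion assays.
#'
#' @param n Number of conditions.
#' @param max_hr Longest depletion time (hours).
#' @return Numeric vector of depletion times in hours.
#' @export
depletion_grid <- function(n = 10, max_hr = 8) {
  seq(0, max_hr, length.out = n)
}

#' The preset depletion schedules
#'
#' One [make_schedule()] per depletion time of [depletion_grid()], with a
#' 4-hour hold at 2% glucose.
#'
#' @inheritParams make_schedule
#' @param Td_hr Depletion times in hours.
#' @return Named list of `"glucose_schedule"` objects.
#' @export
schedule_presets <- function(Td_hr = depletion_grid(), hold = 240, g_s = 2,
                             total = 900) {
  out <- lapply(Td_hr, function(td)
    make_schedule(Td = td * 60, hold = hold, g_s = g_s,
                  total = max(total, hold + td * 60)))
  names(out) <- sprintf("Td%0.3fhr", Td_hr)
  out
}

#' Write a schedule as a sampled CSV
#'
#' @param schedule A [make_schedule()] object.
#' @param path File path.
#' @param cadence Sampling cadence in minutes.
#' @export
write_schedule_csv <- function(schedule, path, cadence = 5) {
  t <- seq(0, schedule$total, by = cadence)
  write.csv(data.frame(time_min = t, glucose_pct = glucose_at(schedule, t)),
            path, row.names = FALSE)
  invisible(path)
}
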