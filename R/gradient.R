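# Thermal-gradient assay: cubic position-to-temperature calibration per
# runway, substrate temperatures at sightings, and the preferred-temperature
# summary over minutes 30-60.

#' Fit a runway's position-to-temperature calibration
#'
#' Least-squares degree-3 polynomial in position (cm), fitted to the five
#' temperatures measured at 0, 20, 40, 60 and 80 cm before each session.
#'
#' @param positions Numeric vector of measurement positions (cm).
#' @param temperatures Matching temperatures (degC).
#' @param runway_id Identifier carried through to tracks.
#' @param tol Maximum admissible residual RMS (degC).
#' @return A `gradient_calibration`: runway id, the data, the four cubic
#'   coefficients (intercept first) and the residual RMS.
#' @examples
#' cal <- fit_calibration(c(0, 20, 40, 60, 80), c(10, 18, 27, 38, 51))
#' position_to_temperature(cal, 40)
#' @export
fit_calibration <- function(positions, temperatures, runway_id = "runway1",
                            tol = 5) {
  if (length(positions) != length(temperatures))
    stopf("positions and temperatures must have equal length")
  if (length(unique(positions)) < 4L)
    stopf("need >= 4 distinct positions to fit a cubic")
  if (any(!is.finite(temperatures))) stopf("temperatures must be finite")
  fit <- lm(temperatures ~ poly(positions, 3L, raw = TRUE))
  rms <- sqrt(mean(resid(fit)^2))
  if (rms > tol)
    stopf("calibration residual RMS %.2f degC exceeds tolerance %.2f", rms, tol)
  structure(list(runway_id = runway_id, positions = positions,
                 temperatures = temperatures,
                 coefficients = unname(coef(fit)), resid_rms = rms),
            class = "gradient_calibration")
}

#' @export
print.gradient_calibration <- function(x, ...) {
  cat("<gradient_calibration> ", x$runway_id, ": ",
      sprintf("%.1f", min(x$temperatures)), "-",
      sprintf("%.1f", max(x$temperatures)), " degC, resid RMS ",
      sprintf("%.3f", x$resid_rms), "\n", sep = "")
  invisible(x)
}

#' Convert runway position to substrate temperature
#'
#' Evaluates the fitted cubic; no extrapolation beyond the calibrated span.
#'
#' @param cal A [fit_calibration()] result.
#' @param position Position(s) in cm within the calibrated range; `NA`
#'   propagates to `NA`.
#' @return Temperature(s) in degC.
#' @export
position_to_temperature <- function(cal, position) {
  stopifnot(inherits(cal, "gradient_calibration"))
  rng <- range(cal$positions)
  ok <- is.na(position) | (position >= rng[1] & position <= rng[2])
  if (!all(ok))
    stopf("position %s cm outside calibrated range [%g, %g]",
          paste(position[!ok], collapse = ", "), rng[1], rng[2])
  b <- cal$coefficients
  b[1] + position * (b[2] + position * (b[3] + position * b[4]))
}

#' Invert a calibration: position whose temperature is closest to a target
#'
#' Grid search at 0.01 cm over the calibrated span (robust to mild
#' non-monotonicity of the fitted cubic). Targets outside the achievable
#' range clamp to the nearest end and are flagged.
#' @param cal A [gradient_calibration].
#' @param temp Target temperature (degC).
#' @param length Runway length (cm); defaults to the calibrated span.
#' @return List with `position` (cm) and `clamped` (logical).
#' @export
invert_calibration <- function(cal, temp, length = NULL) {
  rng <- range(cal$positions)
  if (!is.null(length)) rng <- c(0, length)
  grid <- seq(rng[1], rng[2], by = 0.01)
  tg <- position_to_temperature(cal, grid)
  clamped <- temp < min(tg) || temp > max(tg)
  list(position = grid[which.min(abs(tg - temp))], clamped = clamped)
}

#' Construct a gradient occupancy track
#'
#' @param individual_id Individual identifier.
#' @param runway_id Runway whose calibration applies.
#' @param time_min Sighting times in minutes (default 10, 20, ..., 60).
#' @param position_cm Positions in cm; `NA` marks a missing sighting (animal
#'   perching on wall or lid).
#' @param runway_length Runway length (cm) for range validation.
#' @return A `gradient_track` list.
#' @export
gradient_track <- function(individual_id, runway_id, time_min = seq(10, 60, 10),
                           position_cm, runway_length = 80) {
  if (length(time_min) != length(position_cm))
    stopf("time_min and position_cm must have equal length")
  obs <- !is.na(position_cm)
  if (any(position_cm[obs] < 0 | position_cm[obs] > runway_length))
    stopf("positions must lie in [0, %g] cm", runway_length)
  structure(list(individual_id = as.character(individual_id),
                 runway_id = as.character(runway_id),
                 time_min = as.numeric(time_min),
                 position_cm = as.numeric(position_cm)),
            class = "gradient_track")
}

#' Substrate temperatures along a track
#'
#' @param track A [gradient_track()].
#' @param cal The runway's [gradient_calibration].
#' @return Numeric vector of substrate temperatures (degC), `NA` where the
#'   sighting is missing.
#' @export
track_temperatures <- function(track, cal) {
  stopifnot(inherits(track, "gradient_track"))
  if (!identical(track$runway_id, cal$runway_id))
    stopf("track runway '%s' does not match calibration '%s'",
          track$runway_id, cal$runway_id)
  position_to_temperature(cal, track$position_cm)
}

#' Preferred temperature of an individual
#'
#' Mean substrate temperature over sightings at minutes 30-60 inclusive
#' (4 of the 6 sightings); missing sightings are dropped, and the result is
#' `NA` when all four are missing.
#'
#' @param track A [gradient_track()].
#' @param cal The matching [gradient_calibration]; alternatively pass
#'   precomputed `temperatures`.
#' @param temperatures Optional substrate temperatures aligned with
#'   `track$time_min` (bypasses `cal`).
#' @param window Inclusive time window in minutes (default `c(30, 60)`).
#' @return List with `preferred_temp` (degC or `NA`) and `n_used`.
#' @export
preferred_temperature <- function(track, cal = NULL, temperatures = NULL,
                                  window = c(30, 60)) {
  stopifnot(inherits(track, "gradient_track"))
  if (is.null(temperatures)) {
    if (is.null(cal)) stopf("supply either a calibration or temperatures")
    temperatures <- track_temperatures(track, cal)
  }
  sel <- track$time_min >= window[1] & track$time_min <= window[2]
  vals <- temperatures[sel]
  vals <- vals[!is.na(vals)]
  list(preferred_temp = if (length(vals)) mean(vals) else NA_real_,
       n_used = length(vals))
}
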