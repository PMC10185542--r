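# Ventricular drive: the piston volume-time curve and its flow rate, with
# aortic-valve gating. Diastolic refill is routed through the reservoir and
# never appears as aortic flow.

#' Create a cardiac drive profile
#'
#' Heart rate and stroke volume of the ventricular pump, plus the ejection
#' template, which occupies a fixed `systolic_fraction` of the beat (0.35,
#' i.e. 0.28 s at 75 BPM). Scaling the ejection with the beat keeps the
#' peak flow proportional to cardiac output, which is how the piston drive
#' behaves; a fixed ejection time in seconds can be requested instead via
#' `systolic_time`.
#'
#' Two ejection templates are shipped:
#' \describe{
#'   \item{`"early_peak"` (default)}{a beta-shaped pulse
#'     `Q = 12 sv/ts * u (1-u)^2` with `u` the ejection phase: rapid
#'     upstroke peaking at one third of ejection then a long decline, the
#'     shape of human aortic flow that the piston drive replays.}
#'   \item{`"half_sine"`}{symmetric half-sine of area `sv`, peak flow
#'     `pi * sv / (2 ts)`.}
#' }
#'
#' @param hr heart rate, beats/min.
#' @param sv stroke volume, mL per beat.
#' @param systolic_fraction fraction of the beat spent in ejection, in
#'   (0, 1).
#' @param systolic_time optional ejection duration in s; overrides
#'   `systolic_fraction` and must be shorter than the beat period `60/hr`.
#' @param shape ejection-flow template label.
#' @return an object of class `cardiac_profile`.
#' @export
#' @examples
#' cardiac_profile(75, 70)  # the human standard drive (ejection 0.28 s)
cardiac_profile <- function(hr = 75, sv = 70, systolic_fraction = 0.35,
                            systolic_time = NULL,
                            shape = c("early_peak", "half_sine")) {
  stop_if_not_positive(hr = hr, sv = sv)
  shape <- match.arg(shape)
  period <- 60 / hr
  if (!is.null(systolic_time)) {
    stop_if_not_positive(systolic_time = systolic_time)
    if (systolic_time >= period) {
      stop("`systolic_time` must be shorter than the beat period 60/hr",
           call. = FALSE)
    }
    systolic_fraction <- systolic_time / period
  } else {
    if (!is.numeric(systolic_fraction) || length(systolic_fraction) != 1L ||
        systolic_fraction <= 0 || systolic_fraction >= 1) {
      stop("`systolic_fraction` must lie in (0, 1)", call. = FALSE)
    }
    systolic_time <- systolic_fraction * period
  }
  structure(
    list(hr = hr, sv = sv, systolic_time = systolic_time,
         systolic_fraction = systolic_fraction,
         period = period, shape = shape),
    class = "cardiac_profile"
  )
}

#' @export
print.cardiac_profile <- function(x, ...) {
  cat(sprintf("<cardiac_profile> HR %.0f BPM, SV %.0f mL, ejection %.2f s (%.0f%% of beat), %s\n",
              x$hr, x$sv, x$systolic_time, 100 * x$systolic_fraction,
              x$shape))
  invisible(x)
}

#' Cumulative ejected volume
#'
#' Volume ejected into the aorta up to time `t`: periodic-incremental with
#' the beat, monotone non-decreasing, rising by exactly `sv` during each
#' systole and flat in diastole (the one-way aortic valve isolates the
#' aorta while the piston refills from the reservoir).
#'
#' @param profile a [cardiac_profile()].
#' @param t time(s), s, `>= 0`.
#' @return cumulative ejected volume, mL.
#' @export
volume_curve <- function(profile, t) {
  stopifnot(inherits(profile, "cardiac_profile"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  T <- profile$period
  ts <- profile$systolic_time
  n_done <- floor(t / T)
  phase <- t - n_done * T
  u <- pmin(phase / ts, 1)
  within <- profile$sv * switch(profile$shape,
    half_sine = (1 - cos(pi * u)) / 2,
    early_peak = 6 * u^2 - 8 * u^3 + 3 * u^4
  )
  n_done * profile$sv + within
}

#' Aortic root flow rate
#'
#' Time derivative of [volume_curve()]: an ejection pulse of area `sv`
#' over the systolic duration, zero throughout diastole (the valve
#' prevents backflow, so flow is never negative). For the `"half_sine"`
#' template the peak flow is `pi * sv / (2 * systolic_time)`; for
#' `"early_peak"` it is `16/9 * sv / systolic_time` at one third of
#' ejection.
#'
#' @inheritParams volume_curve
#' @return flow rate, mL/s.
#' @export
#' @examples
#' p <- cardiac_profile(75, 70, shape = "half_sine")
#' flow_rate(p, 0.14)  # peak, ~392.7 mL/s
flow_rate <- function(profile, t) {
  stopifnot(inherits(profile, "cardiac_profile"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  T <- profile$period
  ts <- profile$systolic_time
  phase <- t %% T
  u <- phase / ts
  ifelse(phase < ts,
         switch(profile$shape,
                half_sine = pi * profile$sv / (2 * ts) * sin(pi * u),
                early_peak = 12 * profile$sv / ts * u * (1 - u)^2),
         0)
}
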