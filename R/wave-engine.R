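# Simulator core. The aorta is a single effective conduit from the root to
# the aortic bifurcation, modelled as a linear lossless delay line with the
# Moens wave speed. The root launches a forward wave Zc * Q(t) riding on a
# lumped Windkessel relaxation; the bifurcation reflects against the
# peripheral load; the closed valve partially re-reflects returning waves
# during diastole. Pressure at a sensor is the superposition of the delayed
# forward and backward wave trains on top of the reservoir pressurisation.

#' Peripheral load behind the aortic bifurcation
#'
#' The two peripheral-resistance (PR) ball valves and the reservoir, lumped
#' into (i) a local wave-termination resistance at the bifurcation that
#' sets the reflection coefficient, and (ii) a total hydraulic resistance
#' and compliance (Windkessel) that set the mean pressure and diastolic
#' decay. Both resistances follow the orifice law
#' `R(o) = R_ref * (0.85 / (1 - o))^2`, anchored so that the calibrated
#' baseline is recovered at the 15 % occlusion standard setting.
#'
#' @param occlusion_ratio PR ball-valve occlusion ratio in `[0, 1)`.
#' @param r_total_ref total (Windkessel) resistance at 15 % occlusion,
#'   mmHg·s/mL.
#' @param windkessel_compliance lumped compliance, mL/mmHg.
#' @param r_terminal_ref wave-termination resistance at 15 % occlusion,
#'   mmHg·s/mL.
#' @param inertance blood-column inertance of the outflow branch,
#'   mmHg·s^2/mL; the shipped default is the physical estimate
#'   `rho * path length / area` of the standard aorta. Set 0 for a pure
#'   two-element Windkessel.
#' @return an object of class `peripheral_load` with derived
#'   `terminal_resistance` and `r_total` at the requested occlusion.
#' @export
#' @examples
#' peripheral_load(0.15)  # the calibrated standard load
peripheral_load <- function(occlusion_ratio = 0.15,
                            r_total_ref = aortasim_defaults()$r_total_ref,
                            windkessel_compliance = aortasim_defaults()$windkessel_compliance,
                            r_terminal_ref = aortasim_defaults()$r_terminal_ref,
                            inertance = aortasim_defaults()$inertance) {
  if (!is.numeric(occlusion_ratio) || length(occlusion_ratio) != 1L ||
      occlusion_ratio < 0 || occlusion_ratio >= 1) {
    stop("`occlusion_ratio` must lie in [0, 1); complete closure is unbounded",
         call. = FALSE)
  }
  stop_if_not_positive(r_total_ref = r_total_ref,
                       windkessel_compliance = windkessel_compliance,
                       r_terminal_ref = r_terminal_ref)
  if (inertance < 0) stop("`inertance` must be >= 0", call. = FALSE)
  structure(
    list(occlusion_ratio = occlusion_ratio,
         terminal_resistance = terminal_resistance(occlusion_ratio,
                                                   r_terminal_ref),
         r_total = terminal_resistance(occlusion_ratio, r_total_ref),
         windkessel_compliance = windkessel_compliance,
         inertance = inertance),
    class = "peripheral_load"
  )
}

#' @export
print.peripheral_load <- function(x, ...) {
  cat(sprintf("<peripheral_load> occlusion %.0f%%: R_term %.3f, R_total %.3f mmHg.s/mL, C %.2f mL/mmHg, L %.4f mmHg.s^2/mL\n",
              100 * x$occlusion_ratio, x$terminal_resistance, x$r_total,
              x$windkessel_compliance, x$inertance))
  invisible(x)
}

#' Orifice law for the PR ball valve
#'
#' Terminal resistance as a function of occlusion ratio:
#' `R(o) = calibration * (0.85 / (1 - o))^2`, the simplest hydraulic orifice
#' law with the correct limits. It is monotone increasing in the occlusion
#' ratio and equals the calibrated baseline at the standard 15 % setting;
#' at full opening it reaches its minimum `calibration * 0.85^2`.
#'
#' @param occlusion_ratio valve occlusion in `[0, 1)`; full closure is
#'   rejected as unbounded.
#' @param calibration baseline resistance at 15 % occlusion, mmHg·s/mL.
#' @return resistance, mmHg·s/mL.
#' @export
terminal_resistance <- function(occlusion_ratio, calibration) {
  if (!is.numeric(occlusion_ratio) || any(occlusion_ratio < 0) ||
      any(occlusion_ratio >= 1)) {
    stop("`occlusion_ratio` must lie in [0, 1); complete closure is unbounded",
         call. = FALSE)
  }
  stop_if_not_positive(calibration = calibration)
  calibration * (0.85 / (1 - occlusion_ratio))^2
}

#' Characteristic impedance of the conduit
#'
#' Transmission-line closure `Zc = rho * c / A` with `A = pi (D/2)^2`,
#' converting the root flow input into its pressure output; returned in
#' mmHg·s/mL. Doubling the lumen area halves the impedance.
#'
#' @param diameter inner diameter, m.
#' @param pwv wave speed, m/s.
#' @param rho fluid density, kg/m^3.
#' @return characteristic impedance, mmHg·s/mL.
#' @export
#' @examples
#' characteristic_impedance(0.028, 6.54, 1000)  # ~0.0797 mmHg.s/mL
characteristic_impedance <- function(diameter, pwv, rho = 1000) {
  stop_if_not_positive(diameter = diameter, pwv = pwv, rho = rho)
  si_impedance_to_mmhg_ml(rho * pwv / (pi * (diameter / 2)^2))
}

#' Reflection coefficient at the bifurcation
#'
#' Pressure reflection coefficient of a resistive termination on a line of
#' characteristic impedance `zc`: `Gamma = (R - Zc) / (R + Zc)`. It is 0
#' for a matched load, tends to 1 for a closed end (`R -> Inf`) and to -1
#' for an open end, so it always lies in `(-1, 1]`.
#'
#' @param zc characteristic impedance, mmHg·s/mL (> 0).
#' @param r_terminal terminal resistance, mmHg·s/mL (>= 0; `Inf` allowed).
#' @return dimensionless reflection coefficient.
#' @export
reflection_coefficient <- function(zc, r_terminal) {
  stop_if_not_positive(zc = zc)
  if (!is.numeric(r_terminal) || length(r_terminal) != 1L ||
      is.na(r_terminal) || r_terminal < 0) {
    stop("`r_terminal` must be >= 0", call. = FALSE)
  }
  if (is.infinite(r_terminal)) return(1)
  (r_terminal - zc) / (r_terminal + zc)
}

#' Simulation settings
#'
#' @param sample_rate waveform sampling rate, Hz (>= 200 so the 30 Hz
#'   content of the pressure signal is resolved with margin). The default
#'   4 kHz keeps foot-timing quantisation well below a millisecond.
#' @param n_beats number of beats simulated (>= 3); the first
#'   `n_transient` are discarded so the retained beats are periodic.
#' @param n_transient beats discarded as start-up transient.
#' @param n_reflections retained-reflection budget used for the stability
#'   diagnostic `|Gamma * Gamma_root|^n_reflections`; the delay-line
#'   recursion itself retains all reflections exactly.
#' @param root_reflection_coefficient re-reflection coefficient at the
#'   closed aortic valve during diastole.
#' @param root_reflection_systolic reflection coefficient at the root while
#'   the valve is open. The open valve faces the low-impedance ventricle,
#'   so the default is negative (partial open-end inversion).
#' @param wave_scale dimensionless scale of the forward wave `Zc * Q(t)`
#'   launched at the root (calibrated).
#' @param terminal_smoothing time constant, s, of the first-order lag
#'   applied to the bifurcation reflection (the compliant terminal load
#'   reflects low-pass, not instantaneously; DC reflection stays `Gamma`).
#'   0 disables the smoothing.
#' @param rho working-fluid density, kg/m^3 (distilled water).
#' @param d_eff single pulse-averaged effective diameter entering the
#'   Moens relation and the characteristic impedance for the tapered path,
#'   m (calibrated inside the physical 16-28 mm taper range).
#' @return an object of class `simulation_settings`.
#' @export
simulation_settings <- function(sample_rate = 4000, n_beats = 10,
                                n_transient = 7, n_reflections = 10,
                                root_reflection_coefficient = aortasim_defaults()$root_reflection_diastolic,
                                root_reflection_systolic = aortasim_defaults()$root_reflection_systolic,
                                wave_scale = aortasim_defaults()$wave_scale,
                                terminal_smoothing = aortasim_defaults()$terminal_smoothing,
                                rho = 1000,
                                d_eff = aortasim_defaults()$d_eff) {
  stop_if_not_positive(sample_rate = sample_rate, rho = rho, d_eff = d_eff)
  if (terminal_smoothing < 0) {
    stop("`terminal_smoothing` must be >= 0", call. = FALSE)
  }
  if (sample_rate < 200) {
    stop("`sample_rate` must be >= 200 Hz to resolve 30 Hz content",
         call. = FALSE)
  }
  if (n_beats < 3) stop("`n_beats` must be >= 3", call. = FALSE)
  if (n_transient < 0 || n_transient >= n_beats) {
    stop("`n_transient` must be in [0, n_beats)", call. = FALSE)
  }
  structure(
    list(sample_rate = sample_rate, n_beats = as.integer(n_beats),
         n_transient = as.integer(n_transient),
         n_reflections = as.integer(n_reflections),
         root_reflection_coefficient = root_reflection_coefficient,
         root_reflection_systolic = root_reflection_systolic,
         wave_scale = wave_scale, terminal_smoothing = terminal_smoothing,
         rho = rho, d_eff = d_eff),
    class = "simulation_settings"
  )
}

#' Pressure waveform container
#'
#' A uniformly sampled pressure time series (mmHg) at one sensor position.
#'
#' @param samples pressure samples, mmHg; must be finite.
#' @param sample_rate sampling rate, Hz.
#' @param sensor_position path coordinate of the sensor, m.
#' @param t0 time of the first sample, s.
#' @return an object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(samples, sample_rate, sensor_position = 0,
                              t0 = 0) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("waveform samples must be finite numeric", call. = FALSE)
  }
  stop_if_not_positive(sample_rate = sample_rate)
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         sensor_position = sensor_position, t0 = t0),
    class = "pressure_waveform"
  )
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("<pressure_waveform> %d samples @ %g Hz (%.2f s) at s = %.3f m; range %.1f-%.1f mmHg\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$sensor_position,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of a waveform
#' @param w a [pressure_waveform()].
#' @return numeric vector of times, s.
#' @export
waveform_time <- function(w) {
  w$t0 + (seq_along(w$samples) - 1L) / w$sample_rate
}

#' @export
plot.pressure_waveform <- function(x, ...) {
  plot(waveform_time(x), x$samples, type = "l",
       xlab = "time [s]", ylab = "pressure [mmHg]", ...)
  invisible(x)
}

# linear-interpolating fractional delay; out-of-range past treated as zero
frac_shift <- function(x, lag) {
  n <- length(x)
  pos <- seq_len(n) - lag
  i0 <- floor(pos)
  w <- pos - i0
  v0 <- numeric(n)
  v1 <- numeric(n)
  ok0 <- i0 >= 1 & i0 <= n
  ok1 <- i0 + 1 >= 1 & i0 + 1 <= n
  v0[ok0] <- x[i0[ok0]]
  v1[ok1] <- x[i0[ok1] + 1]
  (1 - w) * v0 + w * v1
}

# closed-form 2x2 matrix exponential (complex-safe)
expm2 <- function(M) {
  tr2 <- (M[1, 1] + M[2, 2]) / 2
  dt2 <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  mu <- sqrt(as.complex(tr2^2 - dt2))
  coshm <- cosh(mu)
  sinhc <- if (Mod(mu) < 1e-10) 1 + 0i else sinh(mu) / mu
  E <- exp(tr2) * (coshm * diag(2) + sinhc * (M - tr2 * diag(2)))
  Re(E)
}

# Windkessel pressure above reservoir: C x' = Q - q, L q' = x - R q.
# Discretised exactly (piecewise-constant flow over a sample) and run as a
# second-order recursive filter. With zero inertance it reduces to the
# two-element Windkessel.
windkessel_pressure <- function(Q, dt, r, cap, inertance) {
  if (inertance <= 0) {
    a <- exp(-dt / (r * cap))
    return(as.numeric(stats::filter(r * (1 - a) * Q, a,
                                    method = "recursive")))
  }
  M <- matrix(c(0, 1 / inertance, -1 / cap, -r / inertance), 2, 2)
  Ad <- expm2(M * dt)
  Bd <- solve(M, (Ad - diag(2)) %*% c(1 / cap, 0))
  a1 <- Ad[1, 1] + Ad[2, 2]
  a2 <- -(Ad[1, 1] * Ad[2, 2] - Ad[1, 2] * Ad[2, 1])
  b1 <- Bd[1]
  b2 <- Ad[1, 2] * Bd[2] - Ad[2, 2] * Bd[1]
  u1 <- c(0, Q[-length(Q)])
  u2 <- c(0, 0, Q[-((length(Q) - 1):length(Q))])
  v <- b1 * u1 + b2 * u2
  as.numeric(stats::filter(v, c(a1, a2), method = "recursive"))
}

#' Simulate central aortic pressure waveforms
#'
#' Runs the delay-line/Windkessel model: the wave speed is the Moens speed
#' at the effective modulus for the current transmural pressure, the root
#' launches `wave_scale * Zc * Q(t)` riding on the Windkessel relaxation,
#' the bifurcation reflects with `Gamma = (R_term - Zc)/(R_term + Zc)`, and
#' the valve re-reflects returning waves (negative partial open-end
#' reflection during ejection, strong positive closed-end reflection in
#' diastole). Raising the transmural pressure above zero softens the wall
#' and slows every wave; with `tp = 0`, changing IVP and EVP together only
#' shifts the waveforms by a constant.
#'
#' The first `n_transient` beats are discarded; the returned waveforms
#' cover the final periodic beats.
#'
#' @param geometry an [aorta_geometry()]; the delay line runs from the
#'   root to its `reflection_site`.
#' @param material a [wall_material()].
#' @param profile a [cardiac_profile()].
#' @param load a [peripheral_load()].
#' @param pressures a [chamber_pressures()].
#' @param settings a [simulation_settings()].
#' @param sensors named numeric vector of sensor path coordinates, m; must
#'   not lie beyond the reflection site. Default: the root (`aa`) and the
#'   bifurcation sensor (`ab`) of the geometry.
#' @return an object of class `aorta_simulation`: list with `waveforms`
#'   (named list of [pressure_waveform()]), `wave_speed` (m/s),
#'   `effective_modulus` (Pa), `zc`, `gamma_ab`, and the input objects.
#' @export
#' @examples
#' sim <- simulate_aorta()
#' sim$wave_speed
#' extract_features(sim$waveforms$aa)
simulate_aorta <- function(geometry = build_standard_aorta(),
                           material = standard_wall_material(),
                           profile = cardiac_profile(),
                           load = peripheral_load(),
                           pressures = chamber_pressures(aortasim_defaults()$ivp_offset),
                           settings = simulation_settings(),
                           sensors = NULL) {
  stopifnot(inherits(geometry, "aorta_geometry"),
            inherits(material, "wall_material"),
            inherits(profile, "cardiac_profile"),
            inherits(load, "peripheral_load"),
            inherits(pressures, "chamber_pressures"),
            inherits(settings, "simulation_settings"))
  if (is.null(sensors)) {
    sensors <- c(aa = 0, ab = geometry$sensor_distance_aa_ab)
  }
  L <- geometry$reflection_site
  if (any(sensors < 0 | sensors > L)) {
    stop("sensors must lie between the root and the reflection site",
         call. = FALSE)
  }
  if (is.null(names(sensors))) {
    names(sensors) <- sprintf("s%03.0f", 1000 * sensors)
  }
  h <- geometry$segments[[1]]$wall_thickness
  E_eff <- effective_modulus(material, pressures$tp,
                             diameter = settings$d_eff, wall_thickness = h)
  cc <- moens_pwv(E_eff, h, settings$rho, settings$d_eff,
                  material$poisson_ratio)
  zc <- characteristic_impedance(settings$d_eff, cc, settings$rho)
  gamma_ab <- reflection_coefficient(zc, load$terminal_resistance)
  g_root_max <- max(abs(settings$root_reflection_coefficient),
                    abs(settings$root_reflection_systolic))
  if (abs(gamma_ab) * g_root_max >= 1) {
    stop("unstable configuration: |Gamma_ab * Gamma_root| >= 1", call. = FALSE)
  }

  fs <- settings$sample_rate
  dt <- 1 / fs
  T <- profile$period
  n <- round(settings$n_beats * T * fs)
  t <- (seq_len(n) - 1L) * dt
  Q <- flow_rate(profile, t)

  x_wk <- windkessel_pressure(Q, dt, load$r_total,
                              load$windkessel_compliance, load$inertance)

  m <- 2 * L / cc * fs           # round-trip delay in samples
  if (m < 2) {
    stop("sample rate too low to resolve the round-trip reflection delay",
         call. = FALSE)
  }
  # classify valve state with a quarter-sample guard so the boundary
  # sample falls on the same side in every beat (t %% T jitters by one ulp)
  phase <- t %% T
  phase <- ifelse(phase > T - dt / 4, phase - T, phase)
  g_root <- ifelse(phase < profile$systolic_time - dt / 4,
                   settings$root_reflection_systolic,
                   settings$root_reflection_coefficient)
  # only the pulsatile flow component travels as a wave; the steady
  # (cardiac-output) component's pressure lives in the Windkessel term
  co_mls <- profile$sv * profile$hr / 60
  src <- settings$wave_scale * zc * (Q - co_mls) + x_wk
  gb <- gamma_ab * g_root
  a_sm <- if (settings$terminal_smoothing > 0)
    exp(-dt / settings$terminal_smoothing) else 0

  # forward wave emitted at the root, including valve re-reflections:
  # f0(t) = src(t) + Gamma_root(t) * Gamma_ab * sm(f0)(t - 2L/c)
  # where sm() is the first-order compliant-termination lag (z below)
  f0 <- src
  z <- numeric(n)
  block <- max(1L, floor(m) - 1L)
  i <- 1L
  while (i <= n) {
    j <- min(i + block - 1L, n)
    idx <- i:j
    pos <- idx - m
    i0 <- floor(pos)
    w <- pos - i0
    v0 <- numeric(length(idx))
    v1 <- numeric(length(idx))
    ok0 <- i0 >= 1
    ok1 <- i0 + 1 >= 1
    v0[ok0] <- z[i0[ok0]]
    v1[ok1] <- z[i0[ok1] + 1]
    f0[idx] <- src[idx] + gb[idx] * ((1 - w) * v0 + w * v1)
    z[idx] <- if (a_sm > 0) {
      as.numeric(stats::filter((1 - a_sm) * f0[idx], a_sm,
                               method = "recursive",
                               init = if (i == 1L) 0 else z[i - 1L]))
    } else f0[idx]
    i <- j + 1L
  }

  keep_from <- round(settings$n_transient * T * fs) + 1L
  t0 <- (keep_from - 1L) * dt
  waveforms <- lapply(seq_along(sensors), function(k) {
    s <- sensors[[k]]
    p <- pressures$ivp_offset +
      frac_shift(f0, s / cc * fs) +
      gamma_ab * frac_shift(z, (2 * L - s) / cc * fs)
    if (any(!is.finite(p))) {
      stop("simulation produced non-finite samples", call. = FALSE)
    }
    pressure_waveform(p[keep_from:n], fs, sensor_position = s, t0 = t0)
  })
  names(waveforms) <- names(sensors)

  structure(
    list(waveforms = waveforms, wave_speed = cc, effective_modulus = E_eff,
         zc = zc, gamma_ab = gamma_ab,
         geometry = geometry, material = material, profile = profile,
         load = load, pressures = pressures, settings = settings),
    class = "aorta_simulation"
  )
}

#' @export
print.aorta_simulation <- function(x, ...) {
  cat(sprintf("<aorta_simulation> HR %.0f, SV %.0f, occlusion %.0f%%, TP %.1f mmHg\n",
              x$profile$hr, x$profile$sv, 100 * x$load$occlusion_ratio,
              x$pressures$tp))
  cat(sprintf("  wave speed %.3f m/s (E_eff %.0f kPa), Zc %.4f mmHg.s/mL, Gamma_ab %.3f\n",
              x$wave_speed, x$effective_modulus / 1000, x$zc, x$gamma_ab))
  for (nm in names(x$waveforms)) {
    cat(sprintf("  %s: ", nm)); print(x$waveforms[[nm]])
  }
  invisible(x)
}

#' Foot-to-foot pulse transit time between two sensors
#'
#' Detects the foot of every beat in both waveforms (per-beat lowest point
#' preceding the upstroke, see [foot_times()]), pairs each foot in `a`
#' with the first later foot in `b` within half a beat, and averages the
#' per-beat delays. The wave speed is `distance / PTT`.
#'
#' @param waveform_a,waveform_b [pressure_waveform()]s with the same
#'   sample rate and beat count; `a` is the upstream (earlier) sensor.
#' @param distance path distance between the sensors, m.
#' @param foot_method foot definition passed to [foot_times()].
#' @return an object of class `ptt_measurement`: list with `distance`,
#'   `ptt` (s), `pwv` (m/s) and the per-beat delays.
#' @export
#' @examples
#' fx <- generate_fixture("shifted_pair", seed = 1)
#' measure_ptt(fx$a, fx$b, distance = 0.5)$pwv  # 10 m/s
measure_ptt <- function(waveform_a, waveform_b, distance,
                        foot_method = c("lowest", "tangent")) {
  stopifnot(inherits(waveform_a, "pressure_waveform"),
            inherits(waveform_b, "pressure_waveform"))
  foot_method <- match.arg(foot_method)
  if (waveform_a$sample_rate != waveform_b$sample_rate) {
    stop("waveforms must share a sample rate", call. = FALSE)
  }
  stop_if_not_positive(distance = distance)
  fa <- foot_times(waveform_a, method = foot_method)
  fb <- foot_times(waveform_b, method = foot_method)
  if (length(fa) == 0L || length(fb) == 0L) {
    stop("feet not detectable in one of the waveforms", call. = FALSE)
  }
  period <- if (length(fa) > 1L) stats::median(diff(fa)) else
    diff(range(waveform_time(waveform_a)))
  dts <- c()
  for (f in fa) {
    cand <- fb[fb > f & fb - f < 0.5 * period]
    if (length(cand)) dts <- c(dts, min(cand) - f)
  }
  if (length(dts) == 0L) {
    stop("no causal foot pairing found (delay <= 0 or feet unmatched)",
         call. = FALSE)
  }
  ptt <- mean(dts)
  structure(
    list(distance = distance, ptt = ptt, pwv = distance / ptt,
         per_beat = dts, n_beats = length(dts)),
    class = "ptt_measurement"
  )
}

#' @export
print.ptt_measurement <- function(x, ...) {
  cat(sprintf("<ptt_measurement> distance %.3f m, PTT %.4f s (%d beats), PWV %.2f m/s\n",
              x$distance, x$ptt, x$n_beats, x$pwv))
  invisible(x)
}

#' Wave speed from distance and transit time
#'
#' @param distance path distance, m.
#' @param ptt pulse transit time(s), s.
#' @return wave speed(s), m/s.
#' @export
#' @examples
#' pwv_from_ptt(0.551, c(0.0838, 0.1079, 0.1763))  # 6.58, 5.11, 3.13
pwv_from_ptt <- function(distance, ptt) {
  stop_if_not_positive(distance = distance)
  if (any(ptt <= 0)) stop("`ptt` must be positive", call. = FALSE)
  distance / ptt
}
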