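# Calibrated defaults. The hardware the model mirrors was itself tuned to
# the human standard (SBP 120, DBP 80, AIx 13.3 %, aPWV near 6.54 m/s at
# HR 75, SV 70, 15 % occlusion, TP 0); the model's free lumped constants
# are fixed the same way, once, by a deterministic least-squares fit
# against those anchors, and the fitted values ship as frozen defaults so
# every downstream computation is deterministic.

# frozen constants (see calibrate_simulator(); re-running it reproduces
# these values from the anchors)
.frozen_defaults <- new.env(parent = emptyenv())
.frozen_defaults$values <- list(
  r_total_ref = 0.1400963,       # mmHg.s/mL, Windkessel resistance @15%
  windkessel_compliance = 1.8034351, # mL/mmHg
  r_terminal_ref = 0.2285606,    # mmHg.s/mL, wave termination @15%
  wave_scale = 0.3939974,        # forward-wave amplitude scale
  inertance = 0.025,             # mmHg.s^2/mL, rho*l/A of the outflow line
  ivp_offset = 83,               # mmHg, reservoir pressurisation level
  root_reflection_diastolic = 0.8,
  root_reflection_systolic = 0,
  terminal_smoothing = 0.045,    # s, compliant-termination reflection lag
  d_eff = 0.0218                 # m, pulse-averaged effective diameter
)

#' Shipped model defaults
#'
#' The frozen lumped constants of the simulator: the four calibrated
#' constants (`r_total_ref`, `windkessel_compliance`, `r_terminal_ref`,
#' `wave_scale`; see [calibrate_simulator()]), the physically derived
#' inertance `rho * L / A` of the conduit, the reservoir pressurisation
#' level, the valve reflection coefficients and the pulse-averaged
#' effective diameter `d_eff` (21.8 mm, inside the 16-28 mm taper range,
#' chosen so that inverting the Moens relation at the 6.54 m/s target
#' yields the 350 kPa target modulus).
#'
#' @return named list of constants.
#' @export
aortasim_defaults <- function() {
  .frozen_defaults$values
}

#' Calibrate the simulator's free constants
#'
#' Deterministic least-squares fit of the four free lumped constants
#' (Windkessel resistance and compliance, wave-termination resistance,
#' forward-wave scale) against the human-standard anchors at the standard
#' configuration (HR 75, SV 70, 15 % occlusion, TP 0): SBP 120 mmHg,
#' DBP 80 mmHg, AIx 13.3 %. A weak quadratic pull toward the physical
#' starting values pins the directions the anchors leave free, so the fit
#' is fully reproducible. Nelder-Mead in log-parameter space.
#'
#' @param anchors named numeric vector of targets.
#' @param start named list of starting constants (defaults: the shipped
#'   values).
#' @param maxit iteration budget for the deterministic optimiser.
#' @param settings base [simulation_settings()] used during fitting.
#' @return list with the fitted constants (`values`), the achieved
#'   features (`achieved`) and the final objective (`objective`).
#' @export
calibrate_simulator <- function(anchors = c(sbp = 120, dbp = 80, aix = 13.3),
                                start = aortasim_defaults(),
                                maxit = 300,
                                settings = simulation_settings()) {
  par0 <- log(c(start$r_total_ref, start$windkessel_compliance,
                start$r_terminal_ref, start$wave_scale))
  eval_pars <- function(par) {
    vals <- exp(par)
    load <- peripheral_load(0.15, r_total_ref = vals[1],
                            windkessel_compliance = vals[2],
                            r_terminal_ref = vals[3],
                            inertance = start$inertance)
    st <- settings
    st$wave_scale <- vals[4]
    sim <- simulate_aorta(load = load,
                          pressures = chamber_pressures(start$ivp_offset),
                          settings = st)
    extract_features(sim$waveforms$aa)
  }
  objective <- function(par) {
    ft <- tryCatch(eval_pars(par), error = function(e) NULL)
    if (is.null(ft)) return(1e6)
    aix_val <- if (is.na(ft$aix)) 40 else ft$aix
    sum(c(ft$sbp - anchors[["sbp"]],
          ft$dbp - anchors[["dbp"]],
          0.5 * (aix_val - anchors[["aix"]]))^2) +
      0.2 * sum((par - par0)^2)
  }
  fit <- stats::optim(par0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  vals <- exp(fit$par)
  out <- start
  out$r_total_ref <- vals[1]
  out$windkessel_compliance <- vals[2]
  out$r_terminal_ref <- vals[3]
  out$wave_scale <- vals[4]
  list(values = out, achieved = eval_pars(fit$par), objective = fit$value)
}

#' Standard simulation configuration
#'
#' Convenience bundle of the standard study conditions: standard aorta and
#' silicone wall, HR 75 BPM, SV 70 mL, 15 % occlusion, TP = 0 at the
#' default reservoir level.
#'
#' @param ... overrides passed to [simulate_aorta()] (e.g. `profile`,
#'   `load`, `pressures`, `settings`, `sensors`).
#' @return the result of [simulate_aorta()].
#' @export
simulate_standard <- function(...) {
  simulate_aorta(...)
}
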