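# Structured configuration files. One YAML file holds the geometry,
# material, cardiac, load, chamber-pressure and settings sections. File
# units follow bench convention -- lengths in millimetres, moduli in kPa --
# and are converted to SI at this boundary.

#' Write a simulation configuration to YAML
#'
#' Serialises the six component objects into one structured file. Lengths
#' are written in millimetres and moduli in kPa (bench units); pressures
#' in mmHg; times in seconds.
#'
#' @param config list with elements `geometry`, `material`, `profile`,
#'   `load`, `pressures`, `settings` (any subset; missing parts are
#'   omitted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list()
  if (!is.null(config$geometry)) {
    g <- config$geometry
    out$geometry <- list(
      segments = lapply(g$segments, function(s) list(
        name = s$name, length_mm = 1000 * s$length,
        diameter_proximal_mm = 1000 * s$diameter_proximal,
        diameter_distal_mm = 1000 * s$diameter_distal,
        wall_thickness_mm = 1000 * s$wall_thickness)),
      bifurcation_angle_deg = g$bifurcation_angle,
      sensor_positions_mm = 1000 * g$sensor_positions,
      sensor_distance_aa_ab_mm = 1000 * g$sensor_distance_aa_ab,
      reflection_site_mm = 1000 * g$reflection_site)
  }
  if (!is.null(config$material)) {
    m <- config$material
    out$material <- list(
      E0_kpa = m$E0 / 1000,
      poisson_ratio = m$poisson_ratio,
      behavior = m$behavior)
    if (!is.null(m$tp_table)) {
      out$material$tp_table <- list(
        tp_mmhg = as.numeric(m$tp_table[, 1]),
        E_kpa = as.numeric(m$tp_table[, 2]) / 1000)
    }
  }
  if (!is.null(config$profile)) {
    p <- config$profile
    out$cardiac <- list(hr_bpm = p$hr, sv_ml = p$sv,
                        systolic_time_s = p$systolic_time, shape = p$shape)
  }
  if (!is.null(config$load)) {
    l <- config$load
    out$load <- list(occlusion_ratio = l$occlusion_ratio,
                     windkessel_compliance_ml_mmhg = l$windkessel_compliance,
                     inertance_mmhg_s2_ml = l$inertance)
  }
  if (!is.null(config$pressures)) {
    out$pressures <- list(ivp_offset_mmhg = config$pressures$ivp_offset,
                          evp_mmhg = config$pressures$evp)
  }
  if (!is.null(config$settings)) {
    s <- config$settings
    out$settings <- list(sample_rate_hz = s$sample_rate,
                         n_beats = s$n_beats, n_transient = s$n_transient,
                         n_reflections = s$n_reflections,
                         root_reflection_coefficient = s$root_reflection_coefficient,
                         root_reflection_systolic = s$root_reflection_systolic,
                         wave_scale = s$wave_scale, rho_kg_m3 = s$rho,
                         d_eff_mm = 1000 * s$d_eff)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Inverse of [write_config()]: reads the bench-unit file and rebuilds the
#' component objects in SI/internal units. Missing sections come back as
#' the shipped defaults.
#'
#' @param path YAML file written by [write_config()] (or hand-authored in
#'   the same layout).
#' @return list with `geometry`, `material`, `profile`, `load`,
#'   `pressures`, `settings`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  out$geometry <- if (!is.null(raw$geometry)) {
    g <- raw$geometry
    aorta_geometry(
      segments = lapply(g$segments, function(s) vessel_segment(
        s$name, s$length_mm / 1000, s$diameter_proximal_mm / 1000,
        s$diameter_distal_mm / 1000, s$wall_thickness_mm / 1000)),
      bifurcation_angle = g$bifurcation_angle_deg,
      sensor_positions = unlist(g$sensor_positions_mm) / 1000,
      sensor_distance_aa_ab = g$sensor_distance_aa_ab_mm / 1000,
      reflection_site = if (!is.null(g$reflection_site_mm))
        g$reflection_site_mm / 1000 else NULL)
  } else build_standard_aorta()
  out$material <- if (!is.null(raw$material)) {
    m <- raw$material
    if (!is.null(m$tp_table)) {
      softening_curve_from_table(
        cbind(unlist(m$tp_table$tp_mmhg), 1000 * unlist(m$tp_table$E_kpa)),
        poisson_ratio = m$poisson_ratio)
    } else {
      wall_material(E0 = 1000 * m$E0_kpa, poisson_ratio = m$poisson_ratio,
                    behavior = m$behavior)
    }
  } else standard_wall_material()
  out$profile <- if (!is.null(raw$cardiac)) {
    cardiac_profile(raw$cardiac$hr_bpm, raw$cardiac$sv_ml,
                    systolic_time = raw$cardiac$systolic_time_s,
                    shape = raw$cardiac$shape %||% "early_peak")
  } else cardiac_profile()
  out$load <- if (!is.null(raw$load)) {
    peripheral_load(
      occlusion_ratio = raw$load$occlusion_ratio,
      windkessel_compliance = raw$load$windkessel_compliance_ml_mmhg %||%
        aortasim_defaults()$windkessel_compliance,
      inertance = raw$load$inertance_mmhg_s2_ml %||%
        aortasim_defaults()$inertance)
  } else peripheral_load()
  out$pressures <- if (!is.null(raw$pressures)) {
    chamber_pressures(raw$pressures$ivp_offset_mmhg, raw$pressures$evp_mmhg)
  } else chamber_pressures(aortasim_defaults()$ivp_offset)
  out$settings <- if (!is.null(raw$settings)) {
    s <- raw$settings
    simulation_settings(
      sample_rate = s$sample_rate_hz %||% 4000,
      n_beats = s$n_beats %||% 10,
      n_transient = s$n_transient %||% 7,
      n_reflections = s$n_reflections %||% 10,
      root_reflection_coefficient = s$root_reflection_coefficient %||%
        aortasim_defaults()$root_reflection_diastolic,
      root_reflection_systolic = s$root_reflection_systolic %||%
        aortasim_defaults()$root_reflection_systolic,
      wave_scale = s$wave_scale %||% aortasim_defaults()$wave_scale,
      rho = s$rho_kg_m3 %||% 1000,
      d_eff = if (!is.null(s$d_eff_mm)) s$d_eff_mm / 1000 else
        aortasim_defaults()$d_eff)
  } else simulation_settings()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export waveforms as tidy CSV
#'
#' Long-format table with columns `time_s`, `sensor_position_m`,
#' `pressure_mmhg`.
#'
#' @param sim an `aorta_simulation` (or named list of
#'   [pressure_waveform()]s).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(sim, path) {
  wfs <- if (inherits(sim, "aorta_simulation")) sim$waveforms else sim
  tabs <- lapply(wfs, function(w) data.frame(
    time_s = waveform_time(w),
    sensor_position_m = w$sensor_position,
    pressure_mmhg = w$samples))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform CSV
#'
#' Accepts either a two-column file (`time_s`, `pressure_mmhg`) or the
#' tidy three-column export of [write_waveforms_csv()] (one sensor per
#' distinct `sensor_position_m`).
#'
#' @param path CSV file.
#' @return a [pressure_waveform()] or, for multi-sensor files, a named
#'   list of them.
#' @export
read_waveform_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_mmhg") %in% names(tab))) {
    stop("CSV must have columns time_s and pressure_mmhg", call. = FALSE)
  }
  build <- function(sub, pos) {
    dt <- diff(sub$time_s)
    if (diff(range(dt)) > 1e-6 * mean(dt)) {
      stop("waveform CSV must be uniformly sampled", call. = FALSE)
    }
    pressure_waveform(sub$pressure_mmhg, 1 / mean(dt), pos, sub$time_s[1])
  }
  if ("sensor_position_m" %in% names(tab) &&
      length(unique(tab$sensor_position_m)) > 1L) {
    pos <- sort(unique(tab$sensor_position_m))
    out <- lapply(pos, function(p)
      build(tab[tab$sensor_position_m == p, ], p))
    names(out) <- sprintf("s%03.0f", 1000 * pos)
    return(out)
  }
  pos <- if ("sensor_position_m" %in% names(tab))
    tab$sensor_position_m[1] else 0
  build(tab, pos)
}
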