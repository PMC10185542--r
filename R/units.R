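# Unit boundary. The mmHg <-> Pa conversion factor lives here and nowhere
# else; every other file converts through these helpers.

#' Unit conversion between mmHg and pascal
#'
#' All internal wall mechanics are in SI (Pa, m, kg/m^3); pressures at the
#' user surface are in mmHg, the unit clinical waveforms are printed in.
#' `1 mmHg = 133.322 Pa`.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

# hydraulic impedance: Pa.s/m^3 -> mmHg.s/mL
# 1 mmHg.s/mL = 133.322 Pa.s / 1e-6 m^3
si_impedance_to_mmhg_ml <- function(z) pa_to_mmhg(z) * 1e-6

stop_if_not_positive <- function(...) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
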