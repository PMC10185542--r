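# Wall mechanics: Moens-Korteweg wave speed (forward and inverse), the
# strain-softening effective modulus of the silicone wall under transmural
# pressure, and the compliance-chamber pressure bookkeeping.

#' Moens-Korteweg pulse wave velocity
#'
#' Pressure-wave speed in a thin-walled elastic tube filled with
#' incompressible, inviscid fluid:
#' \deqn{PWV = \sqrt{E h / (\rho_f D (1 - \nu^2))}}
#' with wall elastic modulus `E`, wall thickness `h`, fluid density `rho`,
#' inner diameter `D` and Poisson ratio `nu`. The speed scales as
#' `sqrt(E)` and `1/sqrt(D)`.
#'
#' @param E wall elastic modulus, Pa.
#' @param h wall thickness, m.
#' @param rho fluid density, kg/m^3.
#' @param D inner diameter, m.
#' @param nu Poisson ratio, in `[0, 1)`; 0.5 for an incompressible
#'   elastomer.
#' @return wave speed, m/s.
#' @export
#' @examples
#' moens_pwv(346e3, 0.002, 1000, 0.0218, 0.5)  # ~6.51 m/s
moens_pwv <- function(E, h, rho, D, nu = 0.5) {
  stop_if_not_positive(E = E, h = h, rho = rho, D = D)
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu >= 1) {
    stop("`nu` must lie in [0, 1)", call. = FALSE)
  }
  sqrt(E * h / (rho * D * (1 - nu^2)))
}

#' Inverse Moens-Korteweg relation: modulus from wave speed
#'
#' Exact algebraic inverse of [moens_pwv()]:
#' `E = pwv^2 * rho * D * (1 - nu^2) / h`. The round trip
#' `moens_pwv(moens_inverse_e(v, ...), ...)` recovers `v` to machine
#' precision.
#'
#' @param pwv target wave speed, m/s.
#' @inheritParams moens_pwv
#' @return wall elastic modulus, Pa.
#' @export
#' @examples
#' moens_inverse_e(6.54, 0.002, 1000, 0.0218, 0.5) / 1000  # ~350 kPa
moens_inverse_e <- function(pwv, h, rho, D, nu = 0.5) {
  stop_if_not_positive(pwv = pwv, h = h, rho = rho, D = D)
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu >= 1) {
    stop("`nu` must lie in [0, 1)", call. = FALSE)
  }
  pwv^2 * rho * D * (1 - nu^2) / h
}

#' Create a wall material
#'
#' Describes the elastic behaviour of the vessel wall. Three behaviours are
#' supported: `"constant"` (modulus independent of strain),
#' `"strain_softening"` (modulus decreases with strain, as for biomimetic
#' silicones) and `"strain_hardening"` (modulus increases with strain, as
#' for real arteries; accepted but not used by the shipped simulator).
#'
#' For strain-dependent behaviours, `softening_curve` maps tensile strain
#' (dimensionless) to modulus (Pa) and must satisfy `curve(0) == E0`; for
#' `"strain_softening"` it must be monotone non-increasing.
#'
#' As an alternative anchored directly in bench measurements, a material may
#' carry a `tp_table`: measured (transmural pressure mmHg, modulus Pa) knots
#' interpolated by [effective_modulus()]. See
#' [softening_curve_from_table()].
#'
#' @param E0 zero-strain elastic modulus, Pa.
#' @param poisson_ratio Poisson ratio in `[0, 0.5]`.
#' @param behavior one of `"constant"`, `"strain_softening"`,
#'   `"strain_hardening"`.
#' @param softening_curve function strain -> modulus Pa, required for
#'   strain-dependent behaviours.
#' @param tp_table optional two-column matrix/data.frame of (tp mmHg, E Pa)
#'   knots; when present it takes precedence in [effective_modulus()].
#' @return an object of class `wall_material`.
#' @export
wall_material <- function(E0, poisson_ratio = 0.5,
                          behavior = c("constant", "strain_softening",
                                       "strain_hardening"),
                          softening_curve = NULL, tp_table = NULL) {
  behavior <- match.arg(behavior)
  stop_if_not_positive(E0 = E0)
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("`poisson_ratio` must lie in [0, 0.5]", call. = FALSE)
  }
  if (behavior != "constant") {
    if (!is.function(softening_curve)) {
      stop("strain-dependent behaviour needs a `softening_curve` function",
           call. = FALSE)
    }
    if (abs(softening_curve(0) - E0) > 1e-6 * E0) {
      stop("softening_curve(0) must equal E0", call. = FALSE)
    }
    if (behavior == "strain_softening") {
      eps <- seq(0, 0.5, length.out = 51)
      if (any(diff(softening_curve(eps)) > 1e-9 * E0)) {
        stop("strain-softening curve must be monotone non-increasing",
             call. = FALSE)
      }
    }
  }
  if (!is.null(tp_table)) {
    tp_table <- as.matrix(tp_table)
    if (ncol(tp_table) != 2L) stop("`tp_table` needs two columns (tp, E)",
                                   call. = FALSE)
    tp_table <- tp_table[order(tp_table[, 1]), , drop = FALSE]
    if (tp_table[1, 1] != 0) {
      stop("`tp_table` must include a knot at tp = 0", call. = FALSE)
    }
    if (any(tp_table[, 2] <= 0)) stop("moduli must be positive", call. = FALSE)
    if (any(diff(tp_table[, 2]) > 0)) {
      stop("`tp_table` moduli must be non-increasing in tp", call. = FALSE)
    }
    if (abs(tp_table[1, 2] - E0) > 1e-6 * E0) {
      stop("`tp_table` knot at tp = 0 must equal E0", call. = FALSE)
    }
  }
  structure(
    list(E0 = E0, poisson_ratio = poisson_ratio, behavior = behavior,
         softening_curve = softening_curve, tp_table = tp_table),
    class = "wall_material"
  )
}

#' @export
print.wall_material <- function(x, ...) {
  cat(sprintf("<wall_material> E0 = %.0f kPa, nu = %.2f, behaviour: %s%s\n",
              x$E0 / 1000, x$poisson_ratio, x$behavior,
              if (!is.null(x$tp_table))
                sprintf(" (tabulated at %d TP knots)", nrow(x$tp_table))
              else ""))
  invisible(x)
}

#' Material from measured (transmural pressure, modulus) knots
#'
#' Builds a strain-softening material whose [effective_modulus()]
#' interpolates measured bench knots exactly (monotone cubic interpolation
#' for three or more knots, linear for two, constant for one). Beyond the
#' last knot the modulus is clamped at the last measured value.
#'
#' @param points two-column matrix or data.frame: transmural pressure in
#'   mmHg (must include 0) and modulus in Pa, non-increasing in pressure.
#' @param poisson_ratio Poisson ratio, default 0.5.
#' @return a `wall_material` with an attached `tp_table`.
#' @export
#' @examples
#' m <- softening_curve_from_table(cbind(c(0, 10, 20), c(346e3, 248e3, 80e3)))
#' effective_modulus(m, 10)  # 248000 exactly at the knot
softening_curve_from_table <- function(points, poisson_ratio = 0.5) {
  points <- as.matrix(points)
  wall_material(E0 = points[order(points[, 1])[1], 2],
                poisson_ratio = poisson_ratio,
                behavior = "strain_softening",
                softening_curve = flat_curve_for_table(points),
                tp_table = points)
}

# constant placeholder curve so the constructor's curve checks pass for
# table-backed materials (the table takes precedence in effective_modulus)
flat_curve_for_table <- function(points) {
  E0 <- points[order(points[, 1])[1], 2]
  function(strain) rep(E0, length(strain))
}

#' Standard silicone wall material
#'
#' The shipped default: a biomimetic silicone with zero-strain modulus
#' 346 kPa and the measured strain-softening knots at transmural pressures
#' 0, 10 and 20 mmHg (346, 248 and 80 kPa). Poisson ratio 0.5
#' (incompressible elastomer).
#'
#' @return a `wall_material`.
#' @export
standard_wall_material <- function() {
  softening_curve_from_table(cbind(c(0, 10, 20), c(346e3, 248e3, 80e3)))
}

#' Chamber pressures: intravascular, extravascular, transmural
#'
#' The reservoir pressurises the vessel from the inside (IVP offset) and the
#' compliance chamber from the outside (EVP); the transmural pressure is
#' their difference, `tp = ivp_offset - evp`, held exactly. With `tp = 0`
#' the wall stays at zero strain and keeps its zero-strain modulus.
#'
#' @param ivp_offset reservoir pressurisation, mmHg.
#' @param evp compliance-chamber pressure, mmHg.
#' @return an object of class `chamber_pressures` with fields `ivp_offset`,
#'   `evp` and derived `tp`.
#' @export
chamber_pressures <- function(ivp_offset, evp = ivp_offset) {
  stopifnot(is.numeric(ivp_offset), length(ivp_offset) == 1L,
            is.numeric(evp), length(evp) == 1L,
            is.finite(ivp_offset), is.finite(evp))
  structure(
    list(ivp_offset = ivp_offset, evp = evp, tp = ivp_offset - evp),
    class = "chamber_pressures"
  )
}

#' @export
print.chamber_pressures <- function(x, ...) {
  cat(sprintf("<chamber_pressures> IVP %.1f, EVP %.1f, TP %.1f mmHg\n",
              x$ivp_offset, x$evp, x$tp))
  invisible(x)
}

#' Effective wall modulus under transmural pressure
#'
#' At `tp = 0` the wall is at zero strain and the modulus is exactly `E0`.
#' For a strain-softening material under positive transmural pressure the
#' modulus decreases:
#' - if the material carries measured `tp_table` knots (the shipped
#'   default), the modulus is the monotone interpolant through them,
#'   clamped beyond the last knot;
#' - otherwise, a thin-wall Laplace closure is used: hoop stress
#'   `sigma = TP * r / h`, strain `eps = sigma / E`, and
#'   `E = curve(eps)` solved self-consistently by damped fixed-point
#'   iteration (damping 0.5, tolerance 1e-8 on strain, at most 100
#'   iterations).
#'
#' Negative transmural pressure (chamber over-pressurisation) is outside the
#' modelled range and rejected.
#'
#' @param material a [wall_material()].
#' @param tp transmural pressure, mmHg, `>= 0`.
#' @param diameter vessel inner diameter, m (Laplace closure only).
#' @param wall_thickness wall thickness, m (Laplace closure only).
#' @return effective modulus, Pa.
#' @export
effective_modulus <- function(material, tp, diameter = 0.0218,
                              wall_thickness = 0.002) {
  stopifnot(inherits(material, "wall_material"))
  if (!is.numeric(tp) || length(tp) != 1L || !is.finite(tp)) {
    stop("`tp` must be a single finite number", call. = FALSE)
  }
  if (tp < 0) {
    stop("negative transmural pressure (chamber over-pressurisation) is not modelled",
         call. = FALSE)
  }
  if (tp == 0) return(material$E0)
  if (!is.null(material$tp_table)) {
    tab <- material$tp_table
    if (nrow(tab) == 1L) return(tab[1, 2])
    tp_clamped <- min(tp, max(tab[, 1]))
    if (nrow(tab) == 2L) {
      return(stats::approx(tab[, 1], tab[, 2], xout = tp_clamped)$y)
    }
    f <- stats::splinefun(tab[, 1], tab[, 2], method = "hyman")
    return(f(tp_clamped))
  }
  if (material$behavior == "constant") return(material$E0)
  # Laplace-law fixed point: sigma = TP r / h, eps = sigma / E, E = curve(eps)
  sigma <- mmhg_to_pa(tp) * (diameter / 2) / wall_thickness
  eps <- sigma / material$E0
  for (i in seq_len(100)) {
    E_new <- material$softening_curve(eps)
    if (!is.finite(E_new) || E_new <= 0) {
      stop("softening curve returned a non-positive modulus", call. = FALSE)
    }
    eps_new <- sigma / E_new
    if (abs(eps_new - eps) <= 1e-8 * max(1, abs(eps))) {
      return(E_new)
    }
    eps <- eps + 0.5 * (eps_new - eps)
  }
  stop("effective_modulus: fixed-point iteration did not converge",
       call. = FALSE)
}
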