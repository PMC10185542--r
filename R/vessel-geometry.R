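# Geometry of the artificial aorta: a 1-D path of tapered segments followed
# from the aortic root through one iliac branch. The geometry exists to
# supply path lengths and diameters for wave timing and impedance; there is
# no 3-D meshing and no secondary flow.

#' Create a vessel segment
#'
#' A straight or curved conduit with a linear diameter taper. Lengths and
#' diameters are in metres.
#'
#' @param name segment label.
#' @param length path length in m (> 0).
#' @param diameter_proximal inner diameter at the upstream end, m.
#' @param diameter_distal inner diameter at the downstream end, m; defaults
#'   to `diameter_proximal` (uniform segment).
#' @param wall_thickness wall thickness in m (> 0).
#' @return an object of class `vessel_segment`.
#' @export
#' @examples
#' vessel_segment("abdominal", 0.512, 0.026, 0.016, 0.002)
vessel_segment <- function(name, length, diameter_proximal,
                           diameter_distal = diameter_proximal,
                           wall_thickness) {
  stopifnot(is.character(name), length(name) == 1L)
  stop_if_not_positive(length = length,
                       diameter_proximal = diameter_proximal,
                       diameter_distal = diameter_distal,
                       wall_thickness = wall_thickness)
  structure(
    list(name = name, length = length,
         diameter_proximal = diameter_proximal,
         diameter_distal = diameter_distal,
         wall_thickness = wall_thickness),
    class = "vessel_segment"
  )
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %s: L = %.1f mm, D = %.1f -> %.1f mm, h = %.1f mm\n",
              x$name, 1000 * x$length, 1000 * x$diameter_proximal,
              1000 * x$diameter_distal, 1000 * x$wall_thickness))
  invisible(x)
}

#' Assemble an aorta geometry from segments
#'
#' The path coordinate `s` is arc length from the aortic root (s = 0 at the
#' valve outlet), following a single branch through the bifurcation. The two
#' iliac branches are symmetric; one is modelled and the terminal load
#' represents their parallel combination.
#'
#' @param segments list of [vessel_segment()] objects, ordered root to
#'   periphery.
#' @param bifurcation_angle angle between the iliac branches, degrees.
#' @param sensor_positions path coordinates of the pressure sensors, m.
#' @param sensor_distance_aa_ab path distance between the aortic-arch (AA)
#'   and aortic-bifurcation (AB) sensors used for transit-time measurements,
#'   m.
#' @param reflection_site path coordinate of the wave reflection site
#'   (the aortic bifurcation); defaults to the end of the second-to-last
#'   segment, i.e. the start of the post-bifurcation branch.
#' @return an object of class `aorta_geometry`.
#' @export
aorta_geometry <- function(segments, bifurcation_angle,
                           sensor_positions, sensor_distance_aa_ab,
                           reflection_site = NULL) {
  stopifnot(is.list(segments), length(segments) >= 1L,
            all(vapply(segments, inherits, logical(1), "vessel_segment")))
  stop_if_not_positive(bifurcation_angle = bifurcation_angle,
                       sensor_distance_aa_ab = sensor_distance_aa_ab)
  lens <- vapply(segments, `[[`, numeric(1), "length")
  total <- sum(lens)
  if (!is.numeric(sensor_positions) || any(!is.finite(sensor_positions))) {
    stop("`sensor_positions` must be finite numeric", call. = FALSE)
  }
  if (any(sensor_positions < 0 | sensor_positions > total)) {
    stop("all sensor positions must lie in [0, total length]", call. = FALSE)
  }
  if (is.null(reflection_site)) {
    reflection_site <- if (length(segments) > 1L) sum(lens[-length(lens)]) else total
  }
  if (reflection_site <= 0 || reflection_site > total) {
    stop("`reflection_site` must lie in (0, total length]", call. = FALSE)
  }
  structure(
    list(segments = segments,
         bifurcation_angle = bifurcation_angle,
         sensor_positions = sort(sensor_positions),
         sensor_distance_aa_ab = sensor_distance_aa_ab,
         reflection_site = reflection_site,
         total_length = total,
         segment_starts = cumsum(c(0, lens[-length(lens)]))),
    class = "aorta_geometry"
  )
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat(sprintf("<aorta_geometry> %d segments, total length %.1f mm\n",
              length(x$segments), 1000 * x$total_length))
  for (seg in x$segments) print(seg)
  cat(sprintf("  bifurcation angle %.0f deg, reflection site at %.1f mm\n",
              x$bifurcation_angle, 1000 * x$reflection_site))
  cat(sprintf("  %d sensors, AA-AB sensor distance %.0f mm\n",
              length(x$sensor_positions), 1000 * x$sensor_distance_aa_ab))
  invisible(x)
}

#' Standard artificial aorta
#'
#' The 1:1 human-scale artificial aorta: total path length 743 mm made of an
#' aortic arch (half-circle of 50 mm radius of curvature, arc length
#' pi * 50 mm, inner diameter 28 mm), an abdominal aorta (512 mm, tapering
#' linearly from 26 to 16 mm), and the remainder as a femoral branch beyond
#' the 80 degree bifurcation (14 mm diameter). Wall thickness is 2 mm
#' throughout. Pressure sensors sit every 100 mm from the root; the AA-AB
#' sensor pair used for transit-time measurements is 551 mm apart.
#'
#' @return an `aorta_geometry`.
#' @seealso [standard_aorta_lengths()] for the distinct path-length
#'   constants of this geometry.
#' @export
#' @examples
#' geo <- build_standard_aorta()
#' geo$total_length          # 0.743
#' diameter_at(geo, 0)       # 0.028
build_standard_aorta <- function() {
  arch_len <- pi * 0.050
  abdominal_len <- 0.512
  total <- standard_aorta_lengths()[["total"]]
  femoral_len <- total - arch_len - abdominal_len
  segs <- list(
    vessel_segment("aortic_arch", arch_len, 0.028, 0.028, 0.002),
    vessel_segment("abdominal_aorta", abdominal_len, 0.026, 0.016, 0.002),
    vessel_segment("femoral_branch", femoral_len, 0.014, 0.014, 0.002)
  )
  aorta_geometry(
    segments = segs,
    bifurcation_angle = 80,
    sensor_positions = seq(0, 0.7, by = 0.1),
    sensor_distance_aa_ab = standard_aorta_lengths()[["sensor_aa_ab"]]
  )
}

#' Named path-length constants of the standard aorta
#'
#' Three distinct lengths are attached to the standard geometry and must not
#' be conflated: the total fabricated path length (743 mm), the aortic
#' reference length quoted for transit-time error statements (712 mm), and
#' the AA-AB sensor distance used to convert transit times to wave speed
#' (551 mm).
#'
#' @return named numeric vector in metres with elements `total`,
#'   `ptt_reference` and `sensor_aa_ab`.
#' @export
standard_aorta_lengths <- function() {
  c(total = 0.743, ptt_reference = 0.712, sensor_aa_ab = 0.551)
}

#' Inner diameter at a path coordinate
#'
#' Piecewise-linear diameter along the vessel path: linear taper within each
#' segment, discontinuities allowed at segment joins. A join coordinate
#' belongs to the upstream segment (its distal diameter is returned), so
#' the end of the abdominal taper reads as its distal diameter.
#'
#' @param geometry an [aorta_geometry()].
#' @param s path coordinate(s) from the aortic root, m; must lie in
#'   `[0, total_length]`.
#' @return inner diameter(s) in m.
#' @export
diameter_at <- function(geometry, s) {
  stopifnot(inherits(geometry, "aorta_geometry"))
  if (!is.numeric(s) || any(!is.finite(s))) {
    stop("`s` must be finite numeric", call. = FALSE)
  }
  if (any(s < 0 | s > geometry$total_length)) {
    stop("path coordinate out of range [0, total length]", call. = FALSE)
  }
  starts <- geometry$segment_starts
  lens <- vapply(geometry$segments, `[[`, numeric(1), "length")
  ends <- starts + lens
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    # joins belong to the upstream segment; s = 0 to the first
    k <- if (s[i] <= 0) 1L else max(which(starts < s[i] - 1e-12), 1L)
    seg <- geometry$segments[[k]]
    frac <- (s[i] - starts[k]) / lens[k]
    frac <- min(max(frac, 0), 1)
    out[i] <- seg$diameter_proximal +
      frac * (seg$diameter_distal - seg$diameter_proximal)
  }
  out
}

#' Length-weighted mean diameter over a path interval
#'
#' The Moens-Korteweg relation takes a single diameter, but the path tapers;
#' this returns the length-weighted mean of [diameter_at()] over
#' `[s0, s1]`, computed exactly from the piecewise-linear taper (trapezoid
#' per overlapped segment). The result always lies between the minimum and
#' maximum diameter on the interval.
#'
#' @param geometry an [aorta_geometry()].
#' @param s0,s1 interval endpoints, m, with `0 <= s0 < s1 <= total_length`.
#' @return mean inner diameter, m.
#' @export
effective_diameter <- function(geometry, s0, s1) {
  stopifnot(inherits(geometry, "aorta_geometry"))
  if (!is.numeric(s0) || !is.numeric(s1) || length(s0) != 1L ||
      length(s1) != 1L || !is.finite(s0) || !is.finite(s1)) {
    stop("`s0` and `s1` must be single finite numbers", call. = FALSE)
  }
  if (s0 < 0 || s1 > geometry$total_length || s0 >= s1) {
    stop("need 0 <= s0 < s1 <= total length (degenerate interval rejected)",
         call. = FALSE)
  }
  starts <- geometry$segment_starts
  lens <- vapply(geometry$segments, `[[`, numeric(1), "length")
  ends <- starts + lens
  acc <- 0
  for (k in seq_along(lens)) {
    a <- max(s0, starts[k])
    b <- min(s1, ends[k])
    if (b <= a) next
    seg <- geometry$segments[[k]]
    d_a <- seg$diameter_proximal +
      (a - starts[k]) / lens[k] * (seg$diameter_distal - seg$diameter_proximal)
    d_b <- seg$diameter_proximal +
      (b - starts[k]) / lens[k] * (seg$diameter_distal - seg$diameter_proximal)
    acc <- acc + (b - a) * (d_a + d_b) / 2
  }
  acc / (s1 - s0)
}
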