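#' Inverse patchy particle geometry
#'
#' Construct the triblock interaction-sphere layout of an inverse patchy
#' particle (IPP): a hard sphere of radius `sigma_c` carrying a central
#' interaction site of radius `sigma_c + delta/2` (the equatorial belt) and
#' two identical off-centre sites (the polar patches) of radius `sigma_p`
#' displaced by `a` along the particle symmetry axis.
#'
#' The screening conditions of the implicit solvent impose
#' `sigma_p + a = sigma_c + delta/2`, so that all interaction spheres reach
#' equally far from the particle surface. Together with the patch
#' half-opening angle
#' `gamma = acos((sigma_c^2 + a^2 - sigma_p^2) / (2 a sigma_c))`
#' this fixes the off-centre displacement uniquely:
#' `a = (R^2 - sigma_c^2) / (2 (R - sigma_c cos(gamma)))` with
#' `R = sigma_c + delta/2`.
#'
#' Reduced units: the hard-core diameter `2 sigma_c = 1` sets the length
#' scale, so the defaults are `sigma_c = 0.5` and `delta = 0.2 * sigma_c`.
#'
#' @param gamma_deg Patch half-opening angle in degrees. Must lie in the
#'   solvable interval where `0 < a < sigma_c` (for the default geometry,
#'   roughly above 5.74 degrees and below 90).
#' @param sigma_c Hard-core radius (default 0.5, reduced units).
#' @param delta Interaction range beyond the hard core (default
#'   `0.2 * sigma_c`).
#' @return An object of class `ipp_geometry`: a list with fields `sigma_c`,
#'   `delta`, `a`, `sigma_p`, `gamma_deg`, and the derived radii
#'   `r_core = 2 sigma_c` (hard-core contact distance), `r_cut = 2 sigma_c +
#'   delta` (interaction cutoff) and `R_c = sigma_c + delta/2` (central-site
#'   radius).
#' @examples
#' g <- ipp_geometry(55)
#' g$a        # off-centre site displacement
#' g$sigma_p  # patch interaction radius
#' @export
ipp_geometry <- function(gamma_deg, sigma_c = 0.5, delta = 0.2 * sigma_c) {
  stopifnot(is.numeric(gamma_deg), length(gamma_deg) == 1L, is.finite(gamma_deg))
  if (sigma_c <= 0) stop("`sigma_c` must be positive", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (gamma_deg <= 0 || gamma_deg >= 90) {
    stop("`gamma_deg` must lie strictly between 0 and 90 degrees", call. = FALSE)
  }
  R <- sigma_c + delta / 2
  cg <- cos(gamma_deg * pi / 180)
  a <- (R^2 - sigma_c^2) / (2 * (R - sigma_c * cg))
  sigma_p <- R - a
  if (a <= 0 || a >= sigma_c) {
    # boundary of the admissible interval: a = sigma_c
    cg_min <- (R - (R^2 - sigma_c^2) / (2 * sigma_c)) / sigma_c
    g_min <- acos(min(1, max(-1, cg_min))) * 180 / pi
    stop(sprintf(
      "gamma = %g deg gives off-centre displacement a = %.4f outside (0, sigma_c); admissible gamma interval is (%.3f, 90) degrees",
      gamma_deg, a, g_min
    ), call. = FALSE)
  }
  g <- structure(
    list(
      sigma_c = sigma_c, delta = delta, a = a, sigma_p = sigma_p,
      gamma_deg = gamma_deg,
      r_core = 2 * sigma_c, r_cut = 2 * sigma_c + delta, R_c = R
    ),
    class = "ipp_geometry"
  )
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "ipp_geometry"))
  if (abs(g$sigma_p + g$a - (g$sigma_c + g$delta / 2)) > 1e-12) {
    stop("geometry violates sigma_p + a = sigma_c + delta/2", call. = FALSE)
  }
  lhs <- cos(g$gamma_deg * pi / 180)
  rhs <- (g$sigma_c^2 + g$a^2 - g$sigma_p^2) / (2 * g$a * g$sigma_c)
  if (abs(lhs - rhs) > 1e-10) {
    stop("geometry violates the half-opening-angle relation", call. = FALSE)
  }
  if (g$sigma_p <= g$delta / 2) {
    stop("patch interaction sphere does not protrude beyond the hard core", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.ipp_geometry <- function(x, ...) {
  cat("<ipp_geometry>\n")
  cat(sprintf("  gamma  : %g deg\n", x$gamma_deg))
  cat(sprintf("  sigma_c: %.6f   delta: %.6f\n", x$sigma_c, x$delta))
  cat(sprintf("  a      : %.6f   sigma_p: %.6f\n", x$a, x$sigma_p))
  cat(sprintf("  range  : [%.3f, %.3f]\n", x$r_core, x$r_cut))
  invisible(x)
}

#' Sphere-sphere overlap (lens) volume
#'
#' Volume of the intersection of two spheres of radii `R1` and `R2` whose
#' centres are a distance `d` apart. Full containment returns the volume of
#' the smaller sphere; separated spheres return 0. Vectorised over all three
#' arguments; continuous in `d`.
#'
#' @param R1,R2 Sphere radii (positive).
#' @param d Centre-centre distance (non-negative).
#' @return Overlap volume(s).
#' @examples
#' overlap_volume(0.55, 0.55, 0)    # contained: (4/3) pi 0.55^3
#' overlap_volume(0.55, 0.55, 1.1)  # tangent: 0
#' @export
overlap_volume <- function(R1, R2, d) {
  if (any(R1 <= 0) || any(R2 <= 0)) stop("radii must be positive", call. = FALSE)
  if (any(d < 0)) stop("distance must be non-negative", call. = FALSE)
  n <- max(length(R1), length(R2), length(d))
  R1 <- rep_len(R1, n); R2 <- rep_len(R2, n); d <- rep_len(d, n)
  v <- numeric(n)
  contained <- d <= abs(R1 - R2)
  v[contained] <- (4 / 3) * pi * pmin(R1[contained], R2[contained])^3
  lens <- !contained & d < R1 + R2
  if (any(lens)) {
    r1 <- R1[lens]; r2 <- R2[lens]; dd <- d[lens]
    v[lens] <- pi * (r1 + r2 - dd)^2 *
      (dd^2 + 2 * dd * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * dd)
  }
  v
}
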