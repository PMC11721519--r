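#' Contact energy set
#'
#' The set `u = (u_EE, u_EP, u_PP)` of pair energies at hard-core contact
#' (`r = 2 sigma_c`) in the three reference mutual orientations:
#' equator-equator (EE, both symmetry axes perpendicular to the
#' centre-centre vector and parallel to each other), equator-pole (EP, one
#' axis along the centre-centre vector, the other perpendicular) and
#' pole-pole (PP, both axes along the centre-centre vector). Energies are
#' expressed in units of |u_EP|, and the EP attraction is fixed at
#' `u_EP = -1` by convention, so only the two repulsions are free.
#'
#' @param u_EE Equator-equator contact energy (>= 0 for the systems studied).
#' @param u_PP Pole-pole contact energy (>= 0).
#' @param u_EP Equator-pole contact energy; fixed at -1 (supplying any other
#'   value is an error, since it would change the unit of energy).
#' @return An object of class `ipp_energy_set`.
#' @examples
#' energy_set(0, 0)      # "repulsions off" (ro) system
#' energy_set(0.5, 2)    # reference (ref) system, u_PP/u_EE = 4
#' @export
energy_set <- function(u_EE, u_PP, u_EP = -1) {
  stopifnot(is.numeric(u_EE), is.numeric(u_PP), length(u_EE) == 1L, length(u_PP) == 1L)
  if (!identical(as.numeric(u_EP), -1)) {
    stop("u_EP is fixed at -1: contact energies are expressed in units of |u_EP|",
      call. = FALSE
    )
  }
  if (u_EE < 0 || u_PP < 0) {
    stop("u_EE and u_PP must be non-negative (repulsive or null)", call. = FALSE)
  }
  structure(list(u_EE = u_EE, u_EP = -1, u_PP = u_PP), class = "ipp_energy_set")
}

#' @export
print.ipp_energy_set <- function(x, ...) {
  cat(sprintf("<ipp_energy_set> u = {%g, %g, %g}  (EE, EP, PP; units |u_EP|)\n",
    x$u_EE, x$u_EP, x$u_PP))
  invisible(x)
}

#' Pair configuration
#'
#' A pair of IPPs described by the centre-centre displacement vector and the
#' two unit symmetry axes. Axes are normalised to unit length; the triblock
#' pattern has head-tail symmetry, so `n` and `-n` are equivalent.
#'
#' @param r_vec Numeric length-3 displacement vector from particle 1 to 2.
#' @param n1,n2 Numeric length-3 symmetry axes (normalised internally; an
#'   axis whose norm differs from 1 by more than 1e-6 is an error).
#' @return An object of class `ipp_pair`.
#' @export
pair_config <- function(r_vec, n1, n2) {
  stopifnot(length(r_vec) == 3L, length(n1) == 3L, length(n2) == 3L)
  nn1 <- sqrt(sum(n1^2)); nn2 <- sqrt(sum(n2^2))
  if (abs(nn1 - 1) > 1e-6 || abs(nn2 - 1) > 1e-6) {
    stop("axes must be unit vectors", call. = FALSE)
  }
  structure(
    list(r_vec = as.numeric(r_vec), n1 = as.numeric(n1 / nn1), n2 = as.numeric(n2 / nn2)),
    class = "ipp_pair"
  )
}

#' Reference pair configurations at contact
#'
#' The EE, EP and PP mutual orientations at separation `r` along the x axis.
#' EE: both axes along z (perpendicular to r, parallel to each other; the
#' azimuthal degeneracy is resolved by the axial symmetry of the pattern).
#' EP: axis 1 along x, axis 2 along z. PP: both axes along x.
#'
#' @param kind One of "EE", "EP", "PP".
#' @param r Centre-centre separation (default contact, `r = 1`).
#' @return An `ipp_pair`.
#' @export
reference_pair <- function(kind = c("EE", "EP", "PP"), r = 1) {
  kind <- match.arg(kind)
  ex <- c(1, 0, 0); ez <- c(0, 0, 1)
  switch(kind,
    EE = pair_config(r * ex, ez, ez),
    EP = pair_config(r * ex, ex, ez),
    PP = pair_config(r * ex, ex, ex)
  )
}

# Site layout of a pair: central sites at 0 and r_vec, patch sites at
# +/- a n1 and r_vec +/- a n2. Returns the distances entering each weight.
pair_site_distances <- function(pc, g) {
  rv <- pc$r_vec
  a <- g$a
  d_cc <- sqrt(sum(rv^2))
  d_cp <- c(
    sqrt(colSums((rv + a * cbind(pc$n2, -pc$n2))^2)), # centre 1 - patches 2
    sqrt(colSums((rv - a * cbind(pc$n1, -pc$n1))^2))  # centre 2 - patches 1
  )
  pp <- expand.grid(s1 = c(1, -1), s2 = c(1, -1))
  d_pp <- vapply(seq_len(4), function(k) {
    sqrt(sum((rv + a * pp$s2[k] * pc$n2 - a * pp$s1[k] * pc$n1)^2))
  }, numeric(1))
  list(d_cc = d_cc, d_cp = d_cp, d_pp = d_pp)
}

#' Geometric overlap weights of a pair configuration
#'
#' The three geometric weights entering the IPP pair energy: the
#' belt-belt weight `omega_cc` (overlap volume of the two central
#' interaction spheres of radius `sigma_c + delta/2`), the belt-patch weight
#' `omega_cp` (sum of the four centre-patch overlap volumes) and the
#' patch-patch weight `omega_pp` (sum of the four patch-patch overlap
#' volumes). All weights vanish beyond the cutoff `2 sigma_c + delta`.
#' Weights are raw overlap volumes (length cubed); any proportionality
#' constant is absorbed by the contact-energy calibration.
#'
#' @param pc An `ipp_pair`.
#' @param g An `ipp_geometry`.
#' @return Named numeric vector `c(omega_cc, omega_cp, omega_pp)`.
#' @export
geometric_weights <- function(pc, g) {
  stopifnot(inherits(pc, "ipp_pair"), inherits(g, "ipp_geometry"))
  r <- sqrt(sum(pc$r_vec^2))
  if (r < g$r_core - 1e-12) {
    stop("hard-core overlap: |r_vec| < 2 sigma_c", call. = FALSE)
  }
  if (r > g$r_cut) {
    return(c(omega_cc = 0, omega_cp = 0, omega_pp = 0))
  }
  d <- pair_site_distances(pc, g)
  c(
    omega_cc = overlap_volume(g$R_c, g$R_c, d$d_cc),
    omega_cp = sum(overlap_volume(g$R_c, g$sigma_p, d$d_cp)),
    omega_pp = sum(overlap_volume(g$sigma_p, g$sigma_p, d$d_pp))
  )
}

#' Contact-weight matrix
#'
#' The 3x3 matrix of geometric weights evaluated at hard-core contact in the
#' three reference orientations: rows EE, EP, PP; columns `omega_cc`,
#' `omega_cp`, `omega_pp`. Solving this linear system against a contact
#' energy set `u` yields the site-pair energy strengths `epsilon`.
#'
#' @param g An `ipp_geometry`.
#' @return A 3x3 numeric matrix with dimnames.
#' @export
contact_weight_matrix <- function(g) {
  W <- t(vapply(
    c("EE", "EP", "PP"),
    function(k) geometric_weights(reference_pair(k, r = g$r_core), g),
    numeric(3)
  ))
  dimnames(W) <- list(c("EE", "EP", "PP"), c("omega_cc", "omega_cp", "omega_pp"))
  W
}

#' Site-pair energy strengths from contact energies
#'
#' Inverts the linear system `W %*% eps = u`, where `W` is the
#' [contact_weight_matrix()] of the geometry and `u = (u_EE, u_EP, u_PP)`,
#' to obtain the energy strengths `eps = (eps_cc, eps_cp, eps_pp)` of the
#' belt-belt, belt-patch and patch-patch site interactions. The round trip
#' (re-evaluating the pair energy at the three reference contacts)
#' reproduces `u` to numerical precision.
#'
#' @param u An `ipp_energy_set`.
#' @param g An `ipp_geometry`.
#' @return An object of class `ipp_epsilon_set`: list with `eps_cc`,
#'   `eps_cp`, `eps_pp`, plus the geometry and the source `u` attached.
#' @examples
#' g <- ipp_geometry(55)
#' epsilon_from_u(energy_set(0.5, 2), g)
#' @export
epsilon_from_u <- function(u, g) {
  stopifnot(inherits(u, "ipp_energy_set"), inherits(g, "ipp_geometry"))
  W <- contact_weight_matrix(g)
  if (rcond(W) < 1e-10) {
    stop(paste0(
      "contact-weight matrix is numerically singular for gamma = ", g$gamma_deg,
      " deg: the EE/EP/PP reference configurations do not distinguish the three site pairs"
    ), call. = FALSE)
  }
  eps <- solve(W, c(u$u_EE, u$u_EP, u$u_PP))
  structure(
    list(
      eps_cc = eps[[1]], eps_cp = eps[[2]], eps_pp = eps[[3]],
      geometry = g, u = u
    ),
    class = "ipp_epsilon_set"
  )
}

#' @export
print.ipp_epsilon_set <- function(x, ...) {
  cat(sprintf(
    "<ipp_epsilon_set> eps = {cc: %.4f, cp: %.4f, pp: %.4f}  (gamma = %g deg, u = {%g, %g, %g})\n",
    x$eps_cc, x$eps_cp, x$eps_pp, x$geometry$gamma_deg, x$u$u_EE, x$u$u_EP, x$u$u_PP
  ))
  invisible(x)
}

#' Define an IPP model (geometry + calibrated energies)
#'
#' Convenience constructor tying a patch size and a contact energy set into
#' a calibrated model: `ipp_model(gamma_deg, u_EE, u_PP)` is
#' `epsilon_from_u(energy_set(u_EE, u_PP), ipp_geometry(gamma_deg, ...))`.
#'
#' @inheritParams ipp_geometry
#' @inheritParams energy_set
#' @return An `ipp_epsilon_set`.
#' @export
ipp_model <- function(gamma_deg, u_EE, u_PP, sigma_c = 0.5, delta = 0.2 * sigma_c) {
  epsilon_from_u(energy_set(u_EE, u_PP), ipp_geometry(gamma_deg, sigma_c, delta))
}

#' IPP pair interaction energy
#'
#' The anisotropic pair energy
#' `U(r, Omega) = eps_cc omega_cc + eps_cp omega_cp + eps_pp omega_pp`:
#' infinitely repulsive for `r < 2 sigma_c` (returned as `Inf`, a sentinel
#' that never enters arithmetic - the sampler treats it as unconditional
#' rejection), zero beyond `2 sigma_c + delta`, and the weighted sum of
#' overlap volumes in between. Invariant under swapping the two particles,
#' under negating either axis, and under any global rotation.
#'
#' @param pc An `ipp_pair`.
#' @param eps An `ipp_epsilon_set` (from [epsilon_from_u()] or [ipp_model()]).
#' @param g Geometry; defaults to the geometry stored in `eps`.
#' @return Scalar energy in units of |u_EP| (`Inf` on hard-core overlap).
#' @examples
#' m <- ipp_model(55, 0.5, 2)
#' pair_energy(reference_pair("EP"), m)  # -1 by calibration
#' @export
pair_energy <- function(pc, eps, g = eps$geometry) {
  stopifnot(inherits(pc, "ipp_pair"), inherits(eps, "ipp_epsilon_set"))
  r <- sqrt(sum(pc$r_vec^2))
  if (r < g$r_core - 1e-12) return(Inf)
  if (r > g$r_cut) return(0)
  w <- geometric_weights(pc, g)
  sum(w * c(eps$eps_cc, eps$eps_cp, eps$eps_pp))
}

#' Contact rotation scan
#'
#' Pair energy at contact while one particle's axis rotates in the plane
#' containing the centre-centre vector: from EE through EP back to EE
#' (`scan = "EE-EP-EE"`, the rotating axis starts perpendicular to r with
#' the partner axis fixed perpendicular), or from PP through EP to PP
#' (`scan = "PP-EP-PP"`, partner axis fixed along r). Reproduces the
#' characteristic contact-energy curves of the model.
#'
#' @param eps An `ipp_epsilon_set`.
#' @param scan Which rotation path, `"EE-EP-EE"` or `"PP-EP-PP"`.
#' @param n Number of angles sampled over \[0, 180\] degrees.
#' @param r Separation (default contact).
#' @return A tibble with columns `angle_deg` and `energy`.
#' @export
contact_rotation_scan <- function(eps, scan = c("EE-EP-EE", "PP-EP-PP"),
                                  n = 181, r = 1) {
  scan <- match.arg(scan)
  g <- eps$geometry
  ex <- c(1, 0, 0); ez <- c(0, 0, 1)
  ang <- seq(0, pi, length.out = n)
  fixed <- if (scan == "EE-EP-EE") ez else ex
  # rotating axis sweeps the x-z plane; at angle 0 it matches the scan label
  e <- vapply(ang, function(th) {
    ct <- cos(th); st <- sin(th)
    nrot <- if (scan == "EE-EP-EE") {
      c(st, 0, ct)   # z -> x -> -z : EE -> EP -> EE
    } else {
      c(ct, 0, st)   # x -> z -> -x : PP -> EP -> PP
    }
    pair_energy(pair_config(r * ex, nrot, fixed), eps, g)
  }, numeric(1))
  tibble::tibble(angle_deg = ang * 180 / pi, energy = e)
}
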