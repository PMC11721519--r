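# Deterministic fixture generation for tests and examples: reference
# dimers, rotation scans, random gases and toy trimers.

#' Generate a deterministic test fixture
#'
#' Small, seeded inputs used throughout the test suite and examples:
#' \describe{
#'   \item{`ep_dimer`, `ee_dimer`, `pp_dimer`}{A contact pair (`r = 1`) in
#'     the corresponding reference orientation, as an `ipp_configuration`
#'     of two particles centred in a box.}
#'   \item{`rotation_scan`}{A list of `ipp_pair` configurations sweeping
#'     the contact rotation EE -> EP -> EE and PP -> EP -> PP.}
#'   \item{`random_gas`}{`n` random non-overlapping particles with uniform
#'     random axes in a box of edge `L` (deterministic under `seed`).}
#'   \item{`trimer_linear`}{Three collinear particles at unit bond length.}
#'   \item{`trimer_compact`}{An equilateral triangle at unit bond length.}
#' }
#'
#' @param kind Fixture name (see above).
#' @param seed Integer seed (used by the random kinds).
#' @param n,L Particle count and box edge for `random_gas`.
#' @param gamma_deg Patch size for `rotation_scan` pair geometry checks
#'   (unused by the purely positional fixtures).
#' @return An `ipp_configuration`, or a list of `ipp_pair` for
#'   `rotation_scan`.
#' @export
generate_fixture <- function(kind, seed = 1L, n = 50, L = 8, gamma_deg = 55) {
  kinds <- c(
    "ep_dimer", "ee_dimer", "pp_dimer", "rotation_scan",
    "random_gas", "trimer_linear", "trimer_compact"
  )
  if (!kind %in% kinds) {
    stop(sprintf(
      "unknown fixture kind '%s'; available: %s", kind, paste(kinds, collapse = ", ")
    ), call. = FALSE)
  }
  centre <- L / 2
  dimer <- function(n1, n2) {
    configuration(
      positions = rbind(c(centre - 0.5, centre, centre), c(centre + 0.5, centre, centre)),
      axes = rbind(n1, n2), L = L
    )
  }
  ex <- c(1, 0, 0); ez <- c(0, 0, 1)
  switch(kind,
    ep_dimer = dimer(ex, ez),
    ee_dimer = dimer(ez, ez),
    pp_dimer = dimer(ex, ex),
    rotation_scan = {
      ang <- seq(0, pi, length.out = 37)
      c(
        lapply(ang, function(th) pair_config(ex, c(sin(th), 0, cos(th)), ez)),
        lapply(ang, function(th) pair_config(ex, c(cos(th), 0, sin(th)), ex))
      )
    },
    random_gas = {
      set.seed(seed)
      pos <- matrix(NA_real_, n, 3)
      placed <- 0L
      for (attempt in seq_len(20000 * n)) {
        p <- stats::runif(3, 0, L)
        ok <- TRUE
        if (placed > 0) {
          d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, p)
          d <- d - L * round(d / L)
          ok <- all(rowSums(d^2) >= 1)
        }
        if (ok) {
          placed <- placed + 1L
          pos[placed, ] <- p
          if (placed == n) break
        }
      }
      if (placed < n) stop("could not place the requested gas without overlap", call. = FALSE)
      axes <- matrix(stats::rnorm(3 * n), n, 3)
      axes <- axes / sqrt(rowSums(axes^2))
      configuration(pos, axes, L)
    },
    trimer_linear = configuration(
      positions = rbind(
        c(centre - 1, centre, centre), c(centre, centre, centre),
        c(centre + 1, centre, centre)
      ),
      axes = rbind(ez, ez, ez), L = L
    ),
    trimer_compact = {
      h <- sqrt(3) / 2
      configuration(
        positions = rbind(
          c(centre - 0.5, centre - h / 3, centre),
          c(centre + 0.5, centre - h / 3, centre),
          c(centre, centre + 2 * h / 3, centre)
        ),
        axes = rbind(ez, ez, ez), L = L
      )
    }
  )
}
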