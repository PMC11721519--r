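# Automated critical-point search: coexistence scan in mu, bisection in T
# on the hysteresis branch gap, then simulate-fit-restart iterations with
# the mixed-field Ising matching.

#' Bisect the coexistence chemical potential at fixed temperature
#'
#' Short grand-canonical runs started from an intermediate density relax
#' into the gas branch below the coexistence chemical potential and into
#' the liquid branch above it. Bisection on the mean density of such scout
#' runs brackets `mu_coex(T)`.
#'
#' @param eps An `ipp_epsilon_set`.
#' @param T Temperature.
#' @param mu_bracket Length-2 initial bracket.
#' @param sched Scout schedule (short; its `seed` seeds each scout run,
#'   incremented per iteration).
#' @param rho_split Density separating "gas-like" from "liquid-like" means.
#' @param iters Number of bisection steps.
#' @return List with `mu` (bracket midpoint), `history` tibble.
#' @export
scan_coexistence_mu <- function(eps, T, mu_bracket = c(-1.2, -0.1),
                                sched = gc_schedule(
                                  total_steps = 2000, equil_steps = 600,
                                  sample_every = 5, config_every = 1e9,
                                  N_max = 400, N0 = 140, L = 8
                                ),
                                rho_split = 0.15, iters = 7) {
  lo <- mu_bracket[1]
  hi <- mu_bracket[2]
  hist <- list()
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    sk <- sched
    sk$seed <- sched$seed + k
    s <- run_gcmc(state_point(T, mid), sk, eps)
    rho <- mean(s$records$N) / sk$L^3
    dense <- rho > rho_split
    hist[[k]] <- tibble::tibble(iter = k, mu = mid, rho = rho, dense = dense)
    if (dense) hi <- mid else lo <- mid
  }
  list(mu = (lo + hi) / 2, history = dplyr::bind_rows(hist))
}

# gas-start / dense-start branch densities at the bisected coexistence mu;
# the gap between them vanishes at and above the critical temperature
.branch_gap <- function(eps, T, mu_bracket, scout, medium, seed_shift = 0) {
  sc <- scout
  sc$seed <- scout$seed + seed_shift
  cx <- scan_coexistence_mu(eps, T, mu_bracket, sc)
  rho <- vapply(c(1L, 2L), function(b) {
    sk <- medium
    sk$seed <- medium$seed + seed_shift + b
    sk$N0 <- if (b == 1L) 15L else as.integer(0.85 * medium$N_max)
    s <- run_gcmc(state_point(T, cx$mu), sk, eps)
    mean(s$records$N) / sk$L^3
  }, numeric(1))
  list(mu = cx$mu, rho_gas = rho[1], rho_dense = rho[2], gap = rho[2] - rho[1])
}

#' Locate the liquid-liquid critical point of an IPP model
#'
#' Three-stage search. (1) Temperature bisection on the hysteresis gap: at
#' each trial temperature the coexistence chemical potential is bracketed
#' by [scan_coexistence_mu()], then one gas-started and one dense-started
#' run are compared; below the critical temperature they relax to distinct
#' branches, above it they merge. Bisection finds the branch-merging
#' temperature, a finite-run-length estimate from above of `T_c`. (2) A
#' production run is performed at the merging point. (3) `(T_c, mu_c, s)`
#' are fitted by histogram reweighting against the universal Ising
#' order-parameter distribution ([fit_critical_point()]); when the fitted
#' state moves materially away from the simulated one (beyond `restart_dT`
#' relative in T or `restart_dmu` in units of T in mu), the production run
#' is repeated at the fitted state, up to `max_restarts` times.
#'
#' @param eps An `ipp_epsilon_set`.
#' @param T_bracket Temperature bracket: hysteretic at the lower end,
#'   merged at the upper.
#' @param mu_bracket Initial bracket for the coexistence scans.
#' @param production Production schedule (its seed is offset per restart).
#' @param scout Short schedule for the mu bisections.
#' @param medium Medium schedule for the branch runs of the T bisection.
#' @param t_iters Temperature bisection iterations.
#' @param gap_tol Branch-density gap below which branches count as merged.
#' @param rho_merged_max Upper bound on the gas-started branch density for
#'   a "merged" classification: when both branch runs condense, the
#'   coexistence scan has overshot the chemical potential (a subcritical
#'   signature), not evidence of criticality.
#' @param max_restarts Maximum simulate-fit restarts.
#' @param restart_dT,restart_dmu Movement thresholds triggering a restart.
#' @param error_max Acceptance threshold passed to [fit_critical_point()].
#' @param verbose Print progress lines.
#' @return A `critical_fit` with the final production `gc_series` attached
#'   as `$series` and the search path as `$path` (tibble).
#' @export
locate_critical_point <- function(eps,
                                  T_bracket,
                                  mu_bracket = c(-1.2, -0.1),
                                  production = gc_schedule(
                                    total_steps = 5e4, equil_steps = 1e4,
                                    sample_every = 5, config_every = 2500,
                                    N_max = 400, N0 = 100, L = 8
                                  ),
                                  scout = gc_schedule(
                                    total_steps = 2000, equil_steps = 600,
                                    sample_every = 5, config_every = 1e9,
                                    N_max = 400, N0 = 140, L = 8
                                  ),
                                  medium = gc_schedule(
                                    total_steps = 2e4, equil_steps = 6e3,
                                    sample_every = 5, config_every = 1e9,
                                    N_max = 400, N0 = 100, L = 8
                                  ),
                                  t_iters = 4, gap_tol = 0.06,
                                  rho_merged_max = 0.30,
                                  max_restarts = 1,
                                  restart_dT = 0.01, restart_dmu = 0.015,
                                  error_max = 0.140,
                                  verbose = FALSE) {
  stopifnot(inherits(eps, "ipp_epsilon_set"), length(T_bracket) == 2)
  T_lo <- T_bracket[1]
  T_hi <- T_bracket[2]

  # stage 1: bisect the branch-merging temperature
  merged <- NULL
  for (k in seq_len(t_iters)) {
    T_mid <- (T_lo + T_hi) / 2
    bg <- .branch_gap(eps, T_mid, mu_bracket, scout, medium, seed_shift = 10 * k)
    if (verbose) {
      message(sprintf(
        "  T-bisect %d: T = %.4f, mu* = %.4f, rho = %.3f / %.3f (gap %.3f)",
        k, T_mid, bg$mu, bg$rho_gas, bg$rho_dense, bg$gap
      ))
    }
    if (bg$gap < gap_tol && bg$rho_gas < rho_merged_max) {
      T_hi <- T_mid
      merged <- c(T_mid, bg$mu, (bg$rho_gas + bg$rho_dense) / 2)
    } else {
      T_lo <- T_mid
    }
  }
  if (is.null(merged)) {
    # no merged point seen inside the bracket: fall back to the upper end
    bg <- .branch_gap(eps, T_bracket[2], mu_bracket, scout, medium, seed_shift = 999)
    merged <- c(T_bracket[2], bg$mu, (bg$rho_gas + bg$rho_dense) / 2)
  }

  # stages 2-3: production + mixed-field fit with restarts
  T_run <- merged[1]
  mu_run <- merged[2]
  path <- list()
  fit <- NULL
  series <- NULL
  for (it in seq_len(max_restarts + 1)) {
    ps <- production
    ps$seed <- production$seed + it
    ps$N0 <- as.integer(max(10, round(merged[3] * ps$L^3)))
    series <- run_gcmc(state_point(T_run, mu_run), ps, eps)
    fit <- fit_critical_point(series, error_max = error_max)
    path[[it]] <- tibble::tibble(
      iter = it, T_run = T_run, mu_run = mu_run,
      T_c = fit$T_c, mu_c = fit$mu_c, s = fit$s,
      fit_error = fit$fit_error, ess = fit$ess
    )
    if (verbose) {
      message(sprintf(
        "  run %d at (T = %.4f, mu = %.4f) -> T_c = %.4f, mu_c = %.4f, rho_c = %.3f, err = %.3f, ESS = %.0f",
        it, T_run, mu_run, fit$T_c, fit$mu_c, fit$rho_c, fit$fit_error, fit$ess
      ))
    }
    moved_T <- abs(fit$T_c - T_run) / T_run > restart_dT
    moved_mu <- abs(fit$mu_c - mu_run) / T_run > restart_dmu
    if (!(moved_T || moved_mu) || it == max_restarts + 1) break
    T_run <- fit$T_c
    mu_run <- fit$mu_c
  }
  fit$series <- series
  fit$path <- dplyr::bind_rows(path)
  fit
}
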