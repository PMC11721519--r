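#' Thermodynamic state point
#'
#' Temperature and chemical potential of the grand-canonical ensemble, both
#' in units of |u_EP| (k_B = 1). The thermal wavelength is folded into the
#' chemical potential (Lambda = 1), so the activity is `z = exp(mu / T)`.
#'
#' @param T Temperature (> 0).
#' @param mu Chemical potential.
#' @return An object of class `ipp_state`.
#' @export
state_point <- function(T, mu) {
  stopifnot(is.numeric(T), is.numeric(mu), length(T) == 1L, length(mu) == 1L)
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  structure(list(T = T, mu = mu), class = "ipp_state")
}

#' @export
print.ipp_state <- function(x, ...) {
  cat(sprintf("<ipp_state> T = %g, mu = %g  (z = %.4g)\n", x$T, x$mu, exp(x$mu / x$T)))
  invisible(x)
}

#' Sampling schedule for a grand-canonical run
#'
#' One MC step is `N_max` elementary moves. Defaults are the production
#' protocol used throughout: box edge `L = 8`, `N0 = 180` initial
#' particles, `5e7` total steps with `2.5e6` discarded as equilibration,
#' one observable record every `1e3` steps and one configuration snapshot
#' every `5e4` steps (47,500 records and 950 snapshots per run).
#'
#' @param total_steps Total MC steps.
#' @param equil_steps Equilibration steps (discarded; must be < total).
#' @param sample_every Record (N, E) every this many post-equilibration steps.
#' @param config_every Snapshot the configuration every this many steps.
#' @param N_max Maximum particle number (also the moves-per-step unit).
#' @param N0 Initial particle count (random non-overlapping placement).
#' @param L Cubic box edge.
#' @param seed Integer RNG seed; every run is bit-reproducible given it.
#' @return An object of class `ipp_schedule`.
#' @export
gc_schedule <- function(total_steps = 5e7, equil_steps = 2.5e6,
                        sample_every = 1e3, config_every = 5e4,
                        N_max = 1000, N0 = 180, L = 8, seed = 1L) {
  stopifnot(total_steps > 0, equil_steps >= 0, sample_every > 0, config_every > 0)
  if (equil_steps >= total_steps) {
    stop("equil_steps must be smaller than total_steps", call. = FALSE)
  }
  if (N0 > N_max) stop("N0 cannot exceed N_max", call. = FALSE)
  structure(
    list(
      total_steps = total_steps, equil_steps = equil_steps,
      sample_every = sample_every, config_every = config_every,
      N_max = as.integer(N_max), N0 = as.integer(N0), L = L,
      seed = as.integer(seed)
    ),
    class = "ipp_schedule"
  )
}

#' Record and snapshot bookkeeping of a schedule
#'
#' Number of observable records and configuration snapshots a schedule
#' produces: records are collected every `sample_every` steps after
#' equilibration, snapshots every `config_every` steps.
#'
#' @param sched An `ipp_schedule`.
#' @return A tibble with `n_records`, `n_configs`, `production_steps`,
#'   `moves_per_step`.
#' @examples
#' schedule_summary(gc_schedule())  # 47500 records, 950 snapshots
#' @export
schedule_summary <- function(sched) {
  stopifnot(inherits(sched, "ipp_schedule"))
  prod <- sched$total_steps - sched$equil_steps
  tibble::tibble(
    n_records = floor(prod / sched$sample_every),
    n_configs = floor(prod / sched$config_every),
    production_steps = prod,
    moves_per_step = sched$N_max
  )
}

#' @export
print.ipp_schedule <- function(x, ...) {
  s <- schedule_summary(x)
  cat(sprintf(
    "<ipp_schedule> %g steps (%g equil), L = %g, N_max = %d, N0 = %d, seed = %d\n",
    x$total_steps, x$equil_steps, x$L, x$N_max, x$N0, x$seed
  ))
  cat(sprintf("  -> %d records, %d snapshots\n", s$n_records, s$n_configs))
  invisible(x)
}

#' Particle configuration
#'
#' Positions and unit symmetry axes of N particles in a cubic periodic box.
#'
#' @param positions N x 3 matrix of positions in `[0, L)`.
#' @param axes N x 3 matrix of unit axis vectors.
#' @param L Box edge.
#' @param step Optional MC step label.
#' @return An object of class `ipp_configuration`.
#' @export
configuration <- function(positions, axes, L, step = NA_real_) {
  positions <- as.matrix(positions)
  axes <- as.matrix(axes)
  stopifnot(ncol(positions) == 3L, ncol(axes) == 3L, nrow(positions) == nrow(axes))
  if (nrow(positions) > 0) {
    if (any(positions < 0) || any(positions >= L)) {
      stop("positions must lie in [0, L)", call. = FALSE)
    }
    norms <- sqrt(rowSums(axes^2))
    if (any(abs(norms - 1) > 1e-10)) {
      stop("axes must be unit vectors (norm within 1e-10 of 1)", call. = FALSE)
    }
  }
  structure(
    list(positions = positions, axes = axes, L = L,
         N = nrow(positions), step = step),
    class = "ipp_configuration"
  )
}

#' @export
print.ipp_configuration <- function(x, ...) {
  cat(sprintf("<ipp_configuration> N = %d, L = %g", x$N, x$L))
  if (!is.na(x$step)) cat(sprintf(", step = %g", x$step))
  cat("\n")
  invisible(x)
}

#' Total potential energy of a configuration
#'
#' Sum of the IPP pair energies over all pairs within the interaction
#' cutoff, under minimum-image periodic boundaries, via cell lists.
#'
#' @param cfg An `ipp_configuration`.
#' @param eps An `ipp_epsilon_set`.
#' @param g Geometry (defaults to the one in `eps`).
#' @return Scalar energy; hard-core overlap raises an error.
#' @export
total_energy <- function(cfg, eps, g = eps$geometry) {
  stopifnot(inherits(cfg, "ipp_configuration"), inherits(eps, "ipp_epsilon_set"))
  if (cfg$N == 0) return(0)
  res <- .total_energy_cpp(cfg$positions, cfg$axes, cfg$L,
    unclass(g), c(eps$eps_cc, eps$eps_cp, eps$eps_pp))
  if (res$overlap) {
    stop("configuration contains a hard-core overlap", call. = FALSE)
  }
  res$energy
}

#' Run a grand-canonical Monte Carlo simulation
#'
#' Metropolis GCMC of the IPP model: with probability `p_exchange` (0.01) an
#' exchange move (insertion or deletion, chosen 50/50), otherwise a single
#' particle rototranslation (per-component displacement uniform in +/-
#' `max_disp` = 0.05, axis rotated by an angle uniform in (0, `max_rot` =
#' 0.1] radians about a uniformly random direction). Step sizes are tuned so
#' the rototranslation acceptance is near 0.3 close to the critical point.
#' An MC step is `N_max` elementary moves; observables (N, E) and
#' configuration snapshots are collected post-equilibration at the
#' schedule's cadence. Runs are deterministic given `sched$seed`.
#'
#' @param state An `ipp_state` (temperature and chemical potential).
#' @param sched An `ipp_schedule`.
#' @param eps An `ipp_epsilon_set` defining the model.
#' @param p_exchange Probability of attempting an exchange move.
#' @param max_disp Maximum per-component displacement.
#' @param max_rot Maximum rotation angle (radians).
#' @param hard_core Set `FALSE` to disable the hard core (ideal/penetrable
#'   reference systems for validation).
#' @param drift_check_every If > 0, recompute the total energy from scratch
#'   every this many steps, record the worst relative deviation of the
#'   incremental bookkeeping, and resynchronise.
#' @return An object of class `gc_series`: list with `records` (tibble
#'   `step`, `N`, `E`), `configs` (list of `ipp_configuration`), `state`,
#'   `schedule`, `model`, `acceptance` (per move type), `counters`,
#'   `max_drift`, and `final` configuration.
#' @export
run_gcmc <- function(state, sched, eps,
                     p_exchange = 0.01, max_disp = 0.05, max_rot = 0.1,
                     hard_core = TRUE, drift_check_every = 0) {
  stopifnot(inherits(state, "ipp_state"), inherits(sched, "ipp_schedule"),
    inherits(eps, "ipp_epsilon_set"))
  g <- eps$geometry
  set.seed(sched$seed)
  res <- .run_gcmc_cpp(
    L = sched$L, T = state$T, mu = state$mu,
    N_max = sched$N_max, N0 = sched$N0,
    total_steps = sched$total_steps, equil_steps = sched$equil_steps,
    sample_every = sched$sample_every, config_every = sched$config_every,
    geom = unclass(g), eps = c(eps$eps_cc, eps$eps_cp, eps$eps_pp),
    p_exchange = p_exchange, max_disp = max_disp, max_rot = max_rot,
    hard_core = hard_core, drift_check_every = drift_check_every
  )
  rec <- res$records
  records <- tibble::tibble(step = rec[, 1], N = rec[, 2], E = rec[, 3])
  configs <- purrr::map(res$configs, function(fr) {
    configuration(fr$positions, fr$axes, L = sched$L, step = fr$step)
  })
  att <- res$counters$attempted
  acc <- res$counters$accepted
  acceptance <- ifelse(att > 0, acc / att, NA_real_)
  names(acceptance) <- names(att)
  structure(
    list(
      records = records, configs = configs,
      state = state, schedule = sched, model = eps,
      acceptance = acceptance,
      counters = res$counters,
      max_drift = res$max_drift,
      final = configuration(res$final$positions, res$final$axes,
        L = sched$L, step = sched$total_steps)
    ),
    class = "gc_series"
  )
}

#' @export
print.gc_series <- function(x, ...) {
  cat(sprintf(
    "<gc_series> %d records, %d snapshots at T = %g, mu = %g\n",
    nrow(x$records), length(x$configs), x$state$T, x$state$mu
  ))
  cat(sprintf(
    "  <N> = %.2f, <E> = %.2f, RT acceptance = %.3f\n",
    mean(x$records$N), mean(x$records$E), x$acceptance[["rt"]]
  ))
  invisible(x)
}

#' @rdname run_gcmc
#' @param object,x A `gc_series`.
#' @param ... Unused.
#' @export
glance.gc_series <- function(x, ...) {
  tibble::tibble(
    T = x$state$T, mu = x$state$mu,
    n_records = nrow(x$records), n_configs = length(x$configs),
    N_mean = mean(x$records$N), N_var = stats::var(x$records$N),
    E_mean = mean(x$records$E),
    rho_mean = mean(x$records$N) / x$schedule$L^3,
    acc_rt = x$acceptance[["rt"]],
    max_drift = x$max_drift
  )
}

#' Trace plot of a grand-canonical series
#'
#' Particle number and total energy versus MC step.
#'
#' @param object A `gc_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_series <- function(object, ...) {
  d <- tidyr::pivot_longer(object$records, c("N", "E"),
    names_to = "observable", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~observable, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "MC step", y = NULL,
      title = sprintf("GCMC trace (T = %g, mu = %g)", object$state$T, object$state$mu)
    )
}
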