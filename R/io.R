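# File formats: structured run configs (YAML key-value), extended-XYZ
# trajectories with per-particle axis vectors, and TSV observable series.

#' Parse a run configuration file
#'
#' Reads a structured key-value (YAML) file with three blocks:
#' `model` (`gamma_deg`, `delta`, `u_EE`, `u_PP`), `ensemble` (`T`, `mu`,
#' `L`, `N_max`, `N0`) and `schedule` (`total_steps`, `equil_steps`,
#' `sample_every`, `config_every`, `seed`, `replicates`). Omitted schedule
#' and ensemble fields default to the production protocol (`L = 8`,
#' `N0 = 180`, `5e7` total steps, `2.5e6` equilibration, sampling every
#' `1e3`, snapshots every `5e4`, 12 replicates). `sigma_c` is fixed at 0.5
#' by the reduced-unit convention and `u_EP` at -1; a config supplying
#' `u_EP` is rejected.
#'
#' @param path Path to the YAML file.
#' @return A list of class `ipp_run_config` with elements `model`
#'   (`ipp_epsilon_set`), `state` (`ipp_state`), `schedule`
#'   (`ipp_schedule`), `replicates`, and `raw` (the resolved key-values).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model <- raw$model
  if (is.null(model$gamma_deg)) stop("config: model$gamma_deg is required", call. = FALSE)
  if (!is.null(model$u_EP) && !identical(as.numeric(model$u_EP), -1)) {
    stop("config: u_EP must not be set; it is fixed at -1 by the unit convention",
      call. = FALSE
    )
  }
  if (!is.null(model$delta) && model$delta <= 0) {
    stop("config: model$delta must be positive", call. = FALSE)
  }
  g <- ipp_geometry(model$gamma_deg,
    sigma_c = 0.5,
    delta = if (is.null(model$delta)) 0.1 else model$delta
  )
  eps <- epsilon_from_u(
    energy_set(model$u_EE %||% 0, model$u_PP %||% 0), g
  )
  ens <- raw$ensemble
  if (is.null(ens$T) || is.null(ens$mu)) {
    stop("config: ensemble$T and ensemble$mu are required", call. = FALSE)
  }
  st <- state_point(ens$T, ens$mu)
  sc <- raw$schedule
  sched <- gc_schedule(
    total_steps = sc$total_steps %||% 5e7,
    equil_steps = sc$equil_steps %||% 2.5e6,
    sample_every = sc$sample_every %||% 1e3,
    config_every = sc$config_every %||% 5e4,
    N_max = ens$N_max %||% 1000,
    N0 = ens$N0 %||% 180,
    L = ens$L %||% 8,
    seed = sc$seed %||% 1L
  )
  resolved <- list(
    model = list(
      gamma_deg = g$gamma_deg, delta = g$delta, sigma_c = g$sigma_c,
      u_EE = eps$u$u_EE, u_EP = -1, u_PP = eps$u$u_PP
    ),
    ensemble = list(T = st$T, mu = st$mu, L = sched$L,
      N_max = sched$N_max, N0 = sched$N0),
    schedule = list(
      total_steps = sched$total_steps, equil_steps = sched$equil_steps,
      sample_every = sched$sample_every, config_every = sched$config_every,
      seed = sched$seed, replicates = sc$replicates %||% 12L
    )
  )
  structure(
    list(model = eps, state = st, schedule = sched,
      replicates = as.integer(sc$replicates %||% 12L), raw = resolved),
    class = "ipp_run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Echo a resolved run configuration
#'
#' Writes the fully resolved configuration (all defaults filled in) as YAML
#' so any run can be re-launched exactly from its run directory.
#'
#' @param cfg An `ipp_run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ipp_run_config"))
  yaml::write_yaml(cfg$raw, path)
  invisible(path)
}

#' Replicate seed derivation
#'
#' Deterministic per-replicate seeds from a master seed: replicate `k` gets
#' an independent sub-stream seed derived by a fixed integer mix, keeping
#' all values in the 32-bit integer range.
#'
#' @param master Master integer seed.
#' @param k Replicate index (1-based); vectorised.
#' @return Integer seed(s).
#' @export
replicate_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 30269) %% 2147483563) + 1L
}

# ---------------------------------------------------------------- XYZ I/O

#' Write a trajectory in extended-XYZ format
#'
#' One frame per configuration: the first line is the particle count, the
#' comment line carries `step=... T=... mu=... L=... E=... N=...` and the
#' column layout, and each particle line has `x y z ax ay az` (position and
#' unit symmetry axis).
#'
#' @param frames A list of `ipp_configuration` (or a single one).
#' @param path Output path.
#' @param state Optional `ipp_state` recorded in the comment lines.
#' @param energies Optional numeric vector of frame energies.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, state = NULL, energies = NULL) {
  if (inherits(frames, "ipp_configuration")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    stopifnot(inherits(fr, "ipp_configuration"))
    meta <- sprintf(
      "step=%s T=%s mu=%s L=%.12g E=%s N=%d Properties=pos:R:3:axis:R:3",
      format(fr$step), format(if (is.null(state)) NA else state$T),
      format(if (is.null(state)) NA else state$mu), fr$L,
      format(if (is.null(energies)) NA else energies[k]), fr$N
    )
    writeLines(as.character(fr$N), con)
    writeLines(meta, con)
    if (fr$N > 0) {
      m <- cbind(fr$positions, fr$axes)
      writeLines(apply(m, 1, function(v) paste(sprintf("%.15g", v), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory()]. Each frame is validated: axis vectors
#' must have unit norm (to 1e-6) and positions must lie in `[0, L)`;
#' violations raise an error naming the frame and particle.
#'
#' @param path Trajectory path.
#' @return A list of `ipp_configuration`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop(sprintf("malformed frame header at line %d", i), call. = FALSE)
    k <- k + 1L
    meta <- lines[i + 1L]
    L <- .xyz_meta_num(meta, "L")
    step <- .xyz_meta_num(meta, "step")
    if (is.na(L)) stop(sprintf("frame %d: missing box size L in comment line", k), call. = FALSE)
    if (n > 0) {
      body <- lines[(i + 2L):(i + 1L + n)]
      m <- do.call(rbind, lapply(body, function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]])))
      if (ncol(m) != 6) {
        stop(sprintf("frame %d: expected 6 columns (x y z ax ay az)", k), call. = FALSE)
      }
      norms <- sqrt(rowSums(m[, 4:6, drop = FALSE]^2))
      bad <- which(abs(norms - 1) > 1e-6)
      if (length(bad) > 0) {
        stop(sprintf("frame %d, particle %d: axis is not a unit vector (norm %.6g)",
          k, bad[1], norms[bad[1]]), call. = FALSE)
      }
      bad_pos <- which(m[, 1:3, drop = FALSE] < 0 | m[, 1:3, drop = FALSE] >= L, arr.ind = TRUE)
      if (nrow(bad_pos) > 0) {
        stop(sprintf("frame %d, particle %d: position outside [0, L)", k, bad_pos[1, 1]),
          call. = FALSE)
      }
      frames[[k]] <- configuration(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], L, step)
    } else {
      frames[[k]] <- configuration(matrix(numeric(), 0, 3), matrix(numeric(), 0, 3), L, step)
    }
    i <- i + 2L + n
  }
  frames
}

.xyz_meta_num <- function(meta, key) {
  m <- regmatches(meta, regexec(paste0(key, "=([^ ]+)"), meta))[[1]]
  if (length(m) < 2) return(NA_real_)
  suppressWarnings(as.numeric(m[2]))
}

#' Write / read an observable series as TSV
#'
#' Plain tab-separated storage of the `(step, N, E)` records of a run.
#'
#' @param series A `gc_series` (or its `records` tibble).
#' @param path File path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_observables <- function(series, path) {
  rec <- if (inherits(series, "gc_series")) series$records else series
  readr::write_tsv(rec, path)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
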