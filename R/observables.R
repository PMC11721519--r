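# Connectivity and structure observables: geometric/energetic bonds,
# functionality, bonded-pair energy distributions, cluster morphology,
# bonding volume and the reduced second virial coefficient.

#' Bond graph of a configuration
#'
#' Two particles form a geometric bond when their minimum-image separation
#' lies within the interaction shell, `2 sigma_c <= r <= 2 sigma_c +
#' delta`. A geometric bond is additionally energetic when the pair energy
#' is strictly negative. Energetic bonds are therefore a subset of
#' geometric ones.
#'
#' @param cfg An `ipp_configuration`.
#' @param eps An `ipp_epsilon_set`.
#' @param g Geometry (defaults to the one stored in `eps`).
#' @return An object of class `bond_graph`: list with `edges` (tibble `i`,
#'   `j`, `r`, `energy`, `energetic`), `N`, `L`.
#' @export
bond_graph <- function(cfg, eps, g = eps$geometry) {
  stopifnot(inherits(cfg, "ipp_configuration"), inherits(eps, "ipp_epsilon_set"))
  if (cfg$N == 0) {
    edges <- tibble::tibble(
      i = integer(), j = integer(), r = numeric(),
      energy = numeric(), energetic = logical()
    )
  } else {
    m <- .bond_table_cpp(cfg$positions, cfg$axes, cfg$L,
      unclass(g), c(eps$eps_cc, eps$eps_cp, eps$eps_pp))
    edges <- tibble::tibble(
      i = as.integer(m[, "i"]), j = as.integer(m[, "j"]),
      r = as.numeric(m[, "r"]), energy = as.numeric(m[, "energy"]),
      energetic = as.numeric(m[, "energy"]) < 0
    )
  }
  structure(list(edges = edges, N = cfg$N, L = cfg$L), class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf(
    "<bond_graph> N = %d: %d geometric bonds, %d energetic\n",
    x$N, nrow(x$edges), sum(x$edges$energetic)
  ))
  invisible(x)
}

#' Geometric and energetic functionality
#'
#' Average number of bonds per particle, split by bond kind: `f_G` counts
#' all geometric bonds, `f_E` only those with negative pair energy. Since
#' energetic bonds are a subset of geometric ones, `f_E <= f_G` always.
#'
#' @param graph A `bond_graph`.
#' @return A tibble with columns `f_G`, `f_E`, `n_particles`.
#' @export
functionality <- function(graph) {
  stopifnot(inherits(graph, "bond_graph"))
  if (graph$N == 0) {
    return(tibble::tibble(f_G = 0, f_E = 0, n_particles = 0L))
  }
  tibble::tibble(
    f_G = 2 * nrow(graph$edges) / graph$N,
    f_E = 2 * sum(graph$edges$energetic) / graph$N,
    n_particles = graph$N
  )
}

#' Bonded-pair energy distribution
#'
#' Normalised probability density of the pair interaction energy over all
#' geometrically bonded pairs in a set of configurations (typically
#' snapshots sampled at the critical point). Also reports the location of
#' the negative-energy mode, estimated by a kernel smoother over energies
#' below `peak_below`.
#'
#' @param configs A list of `ipp_configuration` (e.g. `series$configs`) or
#'   a single configuration.
#' @param eps An `ipp_epsilon_set`.
#' @param bins Number of histogram bins.
#' @param range Energy range of the histogram (energies outside are kept in
#'   the closing bins' count but the density is reported on this range).
#' @param peak_below Upper energy bound of the window in which the
#'   negative-energy mode is located (separates it from the zero-energy
#'   peak).
#' @return A tibble with `energy` (bin centres) and `density`; attributes
#'   `peak_negative` (mode location), `n_bonds`.
#' @export
bonded_energy_histogram <- function(configs, eps, bins = 75,
                                    range = c(-1.5, 1), peak_below = -0.2) {
  if (inherits(configs, "ipp_configuration")) configs <- list(configs)
  stopifnot(length(configs) >= 1)
  u <- unlist(lapply(configs, function(cf) bond_graph(cf, eps)$edges$energy))
  if (length(u) == 0) {
    stop("no geometric bonds in any supplied configuration", call. = FALSE)
  }
  u_cl <- pmin(pmax(u, range[1]), range[2])
  h <- graphics::hist(u_cl,
    breaks = seq(range[1], range[2], length.out = bins + 1), plot = FALSE
  )
  out <- tibble::tibble(energy = h$mids, density = h$density)
  neg <- u[u < peak_below]
  peak <- NA_real_
  if (length(neg) >= 10) {
    d <- stats::density(neg, bw = 0.02, n = 512)
    peak <- d$x[which.max(d$y)]
  }
  attr(out, "peak_negative") <- peak
  attr(out, "n_bonds") <- length(u)
  out
}

#' Cluster statistics of the geometric bond network
#'
#' Connected components of the geometric bond graph with per-cluster radius
#' of gyration. Positions are unwrapped across the periodic boundaries
#' along a spanning tree of each component (each bond displacement taken
#' under minimum image), after which
#' `Rg^2 = mean(|x_i - centroid|^2)`. Components whose unwrapped extent
#' exceeds half the box in any dimension are flagged (`spanning = TRUE`),
#' since the unwrapping is then ambiguous.
#'
#' @param graph A `bond_graph`.
#' @param cfg The `ipp_configuration` the graph was built from.
#' @return A tibble with one row per cluster: `cluster`, `size`, `rg`,
#'   `spanning`, `members` (list column of particle indices).
#' @export
cluster_stats <- function(graph, cfg) {
  stopifnot(inherits(graph, "bond_graph"), inherits(cfg, "ipp_configuration"))
  n <- cfg$N
  if (n == 0) {
    return(tibble::tibble(
      cluster = integer(), size = integer(), rg = numeric(),
      spanning = logical(), members = list()
    ))
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$i, to = graph$edges$j),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(ig)
  L <- cfg$L
  pos <- cfg$positions
  out <- vector("list", comp$no)
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    m <- length(members)
    if (m == 1) {
      out[[k]] <- tibble::tibble(
        cluster = k, size = 1L, rg = 0, spanning = FALSE, members = list(members)
      )
      next
    }
    sub <- igraph::induced_subgraph(ig, members)
    bfs <- igraph::bfs(sub, root = 1, father = TRUE)
    order <- as.integer(bfs$order)
    father <- as.integer(bfs$father)
    unw <- matrix(NA_real_, m, 3)
    unw[order[1], ] <- pos[members[order[1]], ]
    for (v in order[-1]) {
      f <- father[v]
      d <- pos[members[v], ] - pos[members[f], ]
      d <- d - L * round(d / L)
      unw[v, ] <- unw[f, ] + d
    }
    cen <- colMeans(unw)
    rg <- sqrt(mean(rowSums(sweep(unw, 2, cen)^2)))
    extent <- apply(unw, 2, function(z) diff(range(z)))
    out[[k]] <- tibble::tibble(
      cluster = k, size = m, rg = rg,
      spanning = any(extent > L / 2), members = list(members)
    )
  }
  dplyr::bind_rows(out)
}

#' Bonding volume
#'
#' Orientation-averaged positional volume available to a pair for forming a
#' geometric bond with negative energy: `V_b = V_shell * P(U < 0)`, where
#' the probability is estimated by Monte Carlo with the separation sampled
#' uniformly in shell volume (r^3-uniform over `[2 sigma_c, 2 sigma_c +
#' delta]`) and both symmetry axes independent and uniform on the sphere.
#' `V_shell = (4 pi / 3) [(2 sigma_c + delta)^3 - (2 sigma_c)^3]` (about
#' 1.3865 in reduced units).
#'
#' @param eps An `ipp_epsilon_set`.
#' @param n_samples Number of Monte Carlo samples (>= 1e5 recommended).
#' @param seed RNG seed (runs are deterministic given it).
#' @return A tibble with `V_b`, `se` (standard error), `p_bond`,
#'   `V_shell`, `n_samples`.
#' @examples
#' \donttest{
#' bonding_volume(ipp_model(55, 0, 0), n_samples = 1e5, seed = 1)
#' }
#' @export
bonding_volume <- function(eps, n_samples = 1e6, seed = 1L) {
  stopifnot(inherits(eps, "ipp_epsilon_set"), n_samples >= 1)
  set.seed(seed)
  r <- .bonding_volume_cpp(
    unclass(eps$geometry), c(eps$eps_cc, eps$eps_cp, eps$eps_pp), n_samples
  )
  tibble::tibble(
    V_b = r$V_b, se = r$se, p_bond = r$p_bond,
    V_shell = r$V_shell, n_samples = r$n_samples
  )
}

#' Reduced second virial coefficient
#'
#' `B2(T) = -1/2 INT (<exp(-U(r, Omega)/T)>_Omega - 1) 4 pi r^2 dr`,
#' including the hard core, normalised by the hard-sphere value
#' `B2_HS = (2 pi / 3)(2 sigma_c)^3` to give the dimensionless stickiness
#' measure `b2* = B2 / B2_HS` (1 for pure hard spheres; increasingly
#' negative the stickier the attraction). The orientational average is a
#' Monte Carlo estimate over independent uniform axes; the radial integral
#' over the interaction shell uses fixed Gauss-Legendre quadrature.
#'
#' If `potential` is supplied (a function `U(r)` of separation only, may
#' return `Inf` inside a hard core of diameter `2 sigma_c`), the
#' orientational average is bypassed and the same quadrature machinery is
#' applied to the isotropic potential — used to validate against
#' closed-form references such as the square well.
#'
#' @param T Temperature (> 0); vectorised.
#' @param eps An `ipp_epsilon_set` (ignored when `potential` is given,
#'   except for its geometry).
#' @param g Geometry (defaults to the one in `eps`).
#' @param n_orient Orientation samples per radial node.
#' @param n_r Radial Gauss-Legendre nodes over the shell.
#' @param seed RNG seed for the orientational sampling.
#' @param potential Optional isotropic potential `function(r)`.
#' @param tol Relative standard-error tolerance on `b2*`; exceeded ->
#'   error reporting the achieved estimate.
#' @return A tibble with one row per temperature: `T`, `b2_star`, `se`.
#' @export
second_virial <- function(T, eps = NULL, g = eps$geometry,
                          n_orient = 4e4, n_r = 24, seed = 1L,
                          potential = NULL, tol = 0.02) {
  stopifnot(all(T > 0))
  if (is.null(potential)) stopifnot(inherits(eps, "ipp_epsilon_set"))
  gq <- pracma::gaussLegendre(n_r, g$r_core, g$r_cut)
  B2_hs <- (2 * pi / 3) * g$r_core^3
  out <- vector("list", length(T))
  for (k in seq_along(T)) {
    beta <- 1 / T[k]
    if (is.null(potential)) {
      set.seed(seed + k - 1)
      mv <- .boltzmann_orient_avg_cpp(
        gq$x, beta, unclass(g), c(eps$eps_cc, eps$eps_cp, eps$eps_pp), n_orient
      )
      f_mean <- mv[, 1] - 1
      f_se <- mv[, 2]
    } else {
      u <- vapply(gq$x, potential, numeric(1))
      f_mean <- ifelse(is.infinite(u), -1, expm1(-beta * u))
      f_se <- rep(0, n_r)
    }
    shell <- -0.5 * sum(gq$w * 4 * pi * gq$x^2 * f_mean)
    shell_se <- 0.5 * sqrt(sum((gq$w * 4 * pi * gq$x^2)^2 * f_se^2))
    B2 <- B2_hs + shell
    b2s <- B2 / B2_hs
    se <- shell_se / B2_hs
    if (se > tol * max(1, abs(b2s))) {
      stop(sprintf(
        "second virial not converged at T = %g: b2* = %.4f with se %.4f (tolerance %.4f); increase n_orient",
        T[k], b2s, se, tol * max(1, abs(b2s))
      ), call. = FALSE)
    }
    out[[k]] <- tibble::tibble(T = T[k], b2_star = b2s, se = se)
  }
  dplyr::bind_rows(out)
}
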