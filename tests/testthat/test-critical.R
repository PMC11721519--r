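# histogram reweighting and Ising-distribution matching

# synthetic replicate whose ordering operator M = N + s_true * E follows
# the universal Ising density exactly (up to sampling), with E independent
# Gaussian; used for parameter-recovery checks
make_ising_series <- function(n, s_true, m_mean = 150, m_sd = 30,
                              e_mean = -200, e_sd = 40, T = 0.15, mu = -0.4,
                              seed = 1) {
  set.seed(seed)
  # inverse-CDF sampling of the Ising reference on a fine grid
  x <- seq(-5, 5, length.out = 4001)
  p <- ising_reference(x)
  cdf <- cumsum(p) / sum(p)
  keep <- !duplicated(cdf)
  xi <- approx(cdf[keep], x[keep], runif(n), rule = 2)$y
  E <- rnorm(n, e_mean, e_sd)
  M <- m_mean + m_sd * xi
  N <- M - s_true * E
  structure(
    list(
      records = tibble::tibble(step = seq_len(n), N = N, E = E),
      configs = list(),
      state = state_point(T, mu),
      schedule = gc_schedule(
        total_steps = n * 10 + 1000, equil_steps = 1000,
        sample_every = 10, config_every = 1e9, N_max = 450, N0 = 100, L = 8
      ),
      acceptance = c(rt = NA_real_), max_drift = 0
    ),
    class = "gc_series"
  )
}

test_that("the Ising reference density is normalised, symmetric and bimodal", {
  x <- seq(-6, 6, length.out = 4801)
  p <- ising_reference(x)
  dx <- x[2] - x[1]
  expect_equal(sum(p) * dx, 1, tolerance = 1e-8)
  expect_equal(sum(x^2 * p) * dx, 1, tolerance = 1e-8) # unit variance
  expect_equal(p, rev(p)) # exact symmetry
  # exactly two maxima at +/- x*
  dp <- diff(p)
  turning <- which(diff(sign(dp)) == -2)
  expect_identical(length(turning), 2L)
  xstar <- x[turning + 1]
  expect_equal(xstar[2], -xstar[1], tolerance = 1e-6)
  expect_gt(xstar[2], 1) # peaks beyond one standard deviation
  expect_gt(ising_reference(xstar[2]), ising_reference(0))
})

test_that("identity reweighting gives uniform weights summing to one", {
  s <- make_ising_series(5000, 0.5, seed = 3)
  w <- reweight_samples(s, s$state)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(max(w), min(w))
  expect_equal(attr(w, "ess"), 5000, tolerance = 1e-6)
})

test_that("reweighting ideal-gas samples reproduces the shifted Poisson mean", {
  m0 <- model_ro_55
  m0$eps_cc <- m0$eps_cp <- m0$eps_pp <- 0
  lam0 <- 20
  st0 <- state_point(1, log(lam0 / 512))
  sch <- gc_schedule(
    total_steps = 10000, equil_steps = 1500, sample_every = 3,
    config_every = 1e9, N_max = 120, N0 = 20, L = 8, seed = 21
  )
  s <- run_gcmc(st0, sch, m0, hard_core = FALSE, p_exchange = 0.3)
  lam1 <- 24
  st1 <- state_point(1, log(lam1 / 512))
  w <- reweight_samples(s, st1)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w * s$records$N), lam1, tolerance = 0.04)

  # reweighted distribution matches a direct simulation at the target
  # (Kolmogorov-Smirnov at the 1% level, effective-sample-size corrected)
  sch2 <- sch
  sch2$seed <- 22
  s2 <- run_gcmc(st1, sch2, m0, hard_core = FALSE, p_exchange = 0.3)
  grid <- 0:60
  cdf_rw <- vapply(grid, function(k) sum(w[s$records$N <= k]), numeric(1))
  cdf_dir <- stats::ecdf(s2$records$N)(grid)
  D <- max(abs(cdf_rw - cdf_dir))
  ac <- acf(s$records$N, lag.max = 1, plot = FALSE)$acf[2]
  neff <- attr(w, "ess") * (1 - ac) / (1 + ac)
  # asymptotic KS critical value at alpha = 0.01 (two samples, n ~ neff)
  crit <- 1.63 * sqrt(2 / neff)
  expect_lt(D, crit)
})

test_that("ordering distribution is standardised and reduces to N when s = 0", {
  s <- make_ising_series(20000, 0.7, seed = 5)
  d <- ordering_distribution(s, s = 0.7)
  dx <- diff(d$x[1:2])
  # standardisation holds up to the (tiny) out-of-range truncated mass
  expect_lt(abs(sum(d$x * d$density) * dx), 5e-3)
  expect_equal(sum(d$x^2 * d$density) * dx, 1, tolerance = 0.05)
  # s = 0 reproduces the standardised N histogram (up to bin-edge ties)
  d0 <- ordering_distribution(s, s = 0)
  zN <- scale(s$records$N)[, 1]
  h <- hist(zN[abs(zN) <= 4], breaks = seq(-4, 4, length.out = 101), plot = FALSE)
  expect_lt(max(abs(d0$density - h$density * mean(abs(zN) <= 4))), 0.01)
  # degenerate variance errors
  sdeg <- s
  sdeg$records$N <- 1
  sdeg$records$E <- 0
  expect_error(ordering_distribution(sdeg, s = 0), "degenerate")
})

test_that("a near-critical two-phase mixture yields a bimodal ordering operator", {
  set.seed(8)
  n <- 20000
  phase <- runif(n) < 0.5
  N <- ifelse(phase, rnorm(n, 40, 12), rnorm(n, 160, 12))
  E <- rnorm(n, -2 * N, 10) # energy correlated with density
  s <- make_ising_series(10, 1)
  s$records <- tibble::tibble(step = seq_len(n), N = N, E = E)
  d <- ordering_distribution(s, s = 0)
  dens <- d$density
  turning <- which(diff(sign(diff(dens))) == -2)
  peaks <- turning[dens[turning + 1] > 0.1 * max(dens)]
  expect_identical(length(peaks), 2L)
})

test_that("the fit recovers the generating mixing parameter on synthetic data", {
  s_grid <- c(0.25, 0.5, 1, 2)
  rel_err <- vapply(seq_along(s_grid), function(i) {
    s <- make_ising_series(30000, s_grid[i], seed = 40 + i)
    f <- fit_critical_point(s, fix_state = TRUE)
    expect_lt(f$fit_error, 0.05) # constructed to match the reference
    abs(f$s - s_grid[i]) / s_grid[i]
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
  expect_lt(min(rel_err), 0.05)
})

test_that("supercritical (unimodal Gaussian) samples are rejected by the fit", {
  set.seed(77)
  n <- 20000
  s <- make_ising_series(10, 1)
  N <- rnorm(n, 100, 20)
  E <- -1.5 * N + rnorm(n, 0, 10)
  s$records <- tibble::tibble(step = seq_len(n), N = N, E = E)
  f <- fit_critical_point(s, fix_state = TRUE)
  expect_gt(f$fit_error, 0.140)
  expect_false(f$accepted)
})

test_that("replicate pooling reduces the fit-error spread", {
  errs_single <- vapply(1:6, function(k) {
    fit_critical_point(make_ising_series(4000, 0.8, seed = 100 + k),
      fix_state = TRUE)$fit_error
  }, numeric(1))
  errs_pooled <- vapply(1:3, function(k) {
    reps <- lapply(1:4, function(j) make_ising_series(4000, 0.8, seed = 200 + 10 * k + j))
    fit_critical_point(reps, fix_state = TRUE)$fit_error
  }, numeric(1))
  expect_lt(mean(errs_pooled), mean(errs_single))
})

test_that("reweighting far outside the trust region warns about sample size", {
  s <- make_ising_series(3000, 0.5, seed = 9)
  expect_warning(
    reweight_samples(s, state_point(s$state$T * 0.8, s$state$mu - 0.5)),
    "effective sample size"
  )
})
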