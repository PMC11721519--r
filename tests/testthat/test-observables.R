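# bonds, functionality, clusters, bonding volume, second virial

test_that("bond classification follows the distance rule and the energy sign", {
  # EP contact dimer: geometric and energetic
  d_ep <- generate_fixture("ep_dimer")
  bg <- bond_graph(d_ep, model_ref_55)
  expect_identical(nrow(bg$edges), 1L)
  expect_true(bg$edges$energetic)
  expect_equal(bg$edges$energy, -1, tolerance = 1e-10)

  # EE contact dimer in the reference system: geometric but U > 0
  d_ee <- generate_fixture("ee_dimer")
  bg2 <- bond_graph(d_ee, model_ref_55)
  expect_identical(nrow(bg2$edges), 1L)
  expect_false(bg2$edges$energetic)

  # beyond the shell: no edges
  far <- configuration(
    rbind(c(3, 4, 4), c(4.2, 4, 4)),
    rbind(c(0, 0, 1), c(0, 0, 1)), L = 8
  )
  expect_identical(nrow(bond_graph(far, model_ref_55)$edges), 0L)

  # r = 1.05 in EP orientation: both kinds
  mid <- configuration(
    rbind(c(3, 4, 4), c(4.05, 4, 4)),
    rbind(c(1, 0, 0), c(0, 0, 1)), L = 8
  )
  bg3 <- bond_graph(mid, model_ref_55)
  expect_identical(nrow(bg3$edges), 1L)
  expect_true(bg3$edges$energetic)
})

test_that("functionality is the mean bond count per particle, f_E <= f_G", {
  expect_equal(
    functionality(bond_graph(generate_fixture("ep_dimer"), model_ro_55))[, c("f_G", "f_E")],
    tibble::tibble(f_G = 1, f_E = 1)
  )
  gas <- generate_fixture("random_gas", seed = 2, n = 30, L = 10)
  bgas <- bond_graph(gas, model_ref_55)
  fg <- functionality(bgas)
  expect_gte(fg$f_G, fg$f_E)
  # random near-critical-density snapshot: subset property on many frames
  set.seed(9)
  sch <- gc_schedule(
    total_steps = 1500, equil_steps = 500, sample_every = 100,
    config_every = 250, N_max = 150, N0 = 80, L = 8, seed = 14
  )
  s <- run_gcmc(state_point(0.15, -0.5), sch, model_ro_55)
  for (cf in s$configs) {
    f <- functionality(bond_graph(cf, model_ro_55))
    expect_gte(f$f_G, f$f_E)
  }
  empty <- configuration(matrix(numeric(), 0, 3), matrix(numeric(), 0, 3), L = 8)
  expect_equal(functionality(bond_graph(empty, model_ro_55))$f_G, 0)
})

test_that("bonded-energy histogram is normalised and finds the attractive mode", {
  d_ep <- generate_fixture("ep_dimer")
  h <- bonded_energy_histogram(replicate(30, d_ep, simplify = FALSE), model_ro_55)
  dx <- diff(h$energy[1:2])
  expect_equal(sum(h$density) * dx, 1, tolerance = 1e-8)
  expect_equal(attr(h, "peak_negative"), -1, tolerance = 0.05)
  expect_identical(attr(h, "n_bonds"), 30L)
  empty <- configuration(matrix(numeric(), 0, 3), matrix(numeric(), 0, 3), L = 8)
  expect_error(bonded_energy_histogram(empty, model_ro_55), "no geometric bonds")
})

test_that("cluster radii of gyration match direct coordinate values", {
  m <- model_ro_55
  dimer <- generate_fixture("ep_dimer")
  cs <- cluster_stats(bond_graph(dimer, m), dimer)
  expect_identical(nrow(cs), 1L)
  expect_equal(cs$rg, 0.5, tolerance = 1e-12)

  lin <- generate_fixture("trimer_linear")
  # linear trimer bonds exceed the shell (r = 1 exactly at both bonds)
  cl <- cluster_stats(bond_graph(lin, m), lin)
  one <- cl[cl$size == 3, ]
  expect_equal(one$rg, sqrt(2 / 3), tolerance = 1e-12)

  tri <- generate_fixture("trimer_compact")
  ct <- cluster_stats(bond_graph(tri, m), tri)
  expect_equal(ct$rg[ct$size == 3], 1 / sqrt(3), tolerance = 1e-12)

  # branched-vs-compact contrast
  expect_gt(one$rg, ct$rg[ct$size == 3])

  # singletons have zero radius
  gas <- configuration(rbind(c(1, 1, 1), c(5, 5, 5)), rbind(c(0, 0, 1), c(0, 0, 1)), L = 8)
  cg <- cluster_stats(bond_graph(gas, m), gas)
  expect_identical(cg$size, c(1L, 1L))
  expect_identical(cg$rg, c(0, 0))
  expect_equal(sum(cg$size), gas$N)
})

test_that("cluster unwrapping crosses periodic boundaries correctly", {
  m <- model_ro_55
  # dimer straddling the boundary: positions 0.1 and 7.15 along x (r = 0.95+0.1... )
  cf <- configuration(
    rbind(c(0.05, 4, 4), c(7.0, 4, 4)),
    rbind(c(1, 0, 0), c(1, 0, 0)), L = 8
  )
  bg <- bond_graph(cf, m)
  expect_identical(nrow(bg$edges), 1L) # minimum-image distance 1.05
  cs <- cluster_stats(bg, cf)
  expect_equal(cs$rg[cs$size == 2], 1.05 / 2, tolerance = 1e-12)
  expect_false(any(cs$spanning))
})

test_that("bonding volume is bounded by the shell and vanishes without attraction", {
  # purely repulsive model: no negative-energy states
  m_rep <- model_ro_55
  m_rep$eps_cc <- abs(m_rep$eps_cc)
  m_rep$eps_cp <- abs(m_rep$eps_cp)
  m_rep$eps_pp <- abs(m_rep$eps_pp)
  v0 <- bonding_volume(m_rep, n_samples = 2e4, seed = 1)
  expect_identical(v0$V_b, 0)

  v <- bonding_volume(model_ro_55, n_samples = 1e5, seed = 2)
  expect_gt(v$V_b, 0)
  expect_lt(v$V_b, v$V_shell)
  expect_equal(v$V_shell, (4 * pi / 3) * (1.1^3 - 1), tolerance = 1e-12)
})

test_that("bonding-volume error scales as 1/sqrt(n) and seeds agree", {
  v1 <- bonding_volume(model_ref_55, n_samples = 4e4, seed = 5)
  v2 <- bonding_volume(model_ref_55, n_samples = 4e5, seed = 6)
  expect_equal(v1$se / v2$se, sqrt(10), tolerance = 0.2)
  v3 <- bonding_volume(model_ref_55, n_samples = 4e5, seed = 7)
  expect_lt(abs(v2$V_b - v3$V_b), 3 * sqrt(v2$se^2 + v3$se^2))
})

test_that("second virial reduces to the hard-sphere and square-well values", {
  # all interactions off: pure hard sphere
  hs <- second_virial(1, model_ro_55, potential = function(r) 0)
  expect_equal(hs$b2_star, 1, tolerance = 1e-10)
  # square well of depth 1, width delta: closed-form reference
  lam3 <- 1.1^3
  for (T in c(0.25, 0.4, 1)) {
    sw <- second_virial(T, model_ro_55, potential = function(r) if (r <= 1.1) -1 else 0)
    expect_equal(sw$b2_star, 1 - (lam3 - 1) * expm1(1 / T), tolerance = 1e-6)
  }
})

test_that("model second virial washes out at high T and grows sticky when cold", {
  b <- second_virial(c(0.12, 0.2, 5, 100), model_ro_55, n_orient = 8000, seed = 3)
  expect_true(all(diff(b$b2_star) > 0)) # monotone in T
  expect_equal(b$b2_star[4], 1, tolerance = 0.01) # attraction washed out
  expect_lt(b$b2_star[1], -1) # strongly sticky near the critical regime
})

test_that("unconverged virial quadrature raises with the achieved error", {
  expect_error(
    second_virial(0.1, model_ro_55, n_orient = 50, seed = 1, tol = 1e-4),
    "not converged"
  )
})
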