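test_that("pathway permeability coefficients follow the hindered-diffusion chain", {
  geom <- tj_geometry()
  mol <- tj_molecule(547)
  l_cb <- 0.525e6
  oracle <- (2 * geom$w_TJ * l_cb) * mol$D0 *
    hindrance_slit(mol$radius / geom$w_TJ) / geom$h_strand
  expect_equal(tj_break_permeability(geom, mol, l_cb), oracle)
  expect_equal(tj_break_permeability(geom, mol, 0), 0)
  expect_equal(tj_break_permeability(geom, mol, 2 * l_cb), 2 * oracle)

  ttj <- tj_tricellular(rho_tTJ = 0.078e12)
  o2 <- pi * ttj$r_tTJ^2 * ttj$rho_tTJ * mol$D0 *
    hindrance_pore(mol$radius / ttj$r_tTJ) / ttj$h_tTJ
  expect_equal(tj_ttj_permeability(ttj, mol), o2)
  # MDCK C7 tricellular pores alone reach the measured 1.0 nm/s
  expect_gte(tj_ttj_permeability(ttj, mol), 1.0e-9)
  # linear in pore density
  expect_equal(tj_ttj_permeability(tj_tricellular(0.156e12), mol), 2 * o2)
  # big molecules are excluded
  expect_error(tj_ttj_permeability(ttj, tj_molecule(2e5)), "excluded")
})

test_that("rate constants vanish when intact and balance fluxes when broken", {
  geom <- tj_geometry()
  P <- 3e-4
  expect_equal(tj_rate_constant(0, geom, P, 1e-14), 0)
  k_ij <- tj_rate_constant(1, geom, P, 1e-14)
  k_ji <- tj_rate_constant(1, geom, P, 0.5e-14)
  expect_equal(k_ij * 1e-14, k_ji * 0.5e-14)  # flux balance across areas
  expect_equal(k_ij, geom$l_break * P / 1e-14)
})

test_that("total permeability adds the two parallel pathways", {
  expect_equal(tj_total_permeability(0, 3e-9), 3e-9)
  expect_equal(tj_total_permeability(3e-9, 0), 3e-9)
  expect_equal(tj_total_permeability(1e-9, 2e-9),
               tj_total_permeability(2e-9, 1e-9))
  expect_error(tj_total_permeability(-1e-9, 0), "non-negative")
})

test_that("a sealed network passes nothing", {
  set.seed(1)
  sim <- tj_permeability("Caco-2", geom = tj_geometry(width = 5),
                         dyn = tj_dynamics(0), horizon = 60, reps = 2)
  expect_equal(sim$P_bTJ, 0)
  expect_true(all(sim$qa_mean == 0))
  expect_equal(sim$P_TJ, sim$P_tTJ)
})

test_that("a permanently broken network reproduces the static linear solve", {
  epi <- tj_preset("Caco-2")
  geom <- tj_geometry(n_strand = 2, width = 4)
  net <- tj_network(geom)
  mol <- tj_molecule(547)
  Pb <- tj_break_permeability(geom, mol, epi$l_cb)
  oracle <- static_permeability(net, geom, Pb,
                                rep(1L, nrow(net$sections)))
  dyn_broken <- tj_dynamics(1 / max(net$sections$length), p_seal = 1e-12)
  set.seed(7)
  sim <- tj_permeability(epi, geom = geom, dyn = dyn_broken, horizon = 200,
                         reps = 2, init = "zero")
  expect_equal(sim$P_bTJ, oracle, tolerance = 1e-4)
})

test_that("the ODE bookkeeping conserves mass and apical gain is monotone", {
  set.seed(11)
  sim <- tj_permeability("Caco-2", geom = tj_geometry(width = 20),
                         horizon = 400, reps = 4, record = "all")
  expect_lt(sim$cons_err, 1e-9)
  expect_true(all(apply(sim$qa, 2, function(q) all(diff(q) >= -1e-12))))
})

test_that("results are invariant to the basal concentration scale", {
  set.seed(5)
  a <- tj_permeability("MDCK IIa", geom = tj_geometry(width = 10),
                       horizon = 300, reps = 4, c_basal = 1)
  set.seed(5)
  b <- tj_permeability("MDCK IIa", geom = tj_geometry(width = 10),
                       horizon = 300, reps = 4, c_basal = 7.3)
  expect_equal(a$P_bTJ, b$P_bTJ, tolerance = 1e-12)
})

test_that("seeded permeability runs are bit-reproducible", {
  set.seed(123)
  a <- tj_permeability("Caco-2", geom = tj_geometry(width = 8),
                       horizon = 120, reps = 3)
  set.seed(123)
  b <- tj_permeability("Caco-2", geom = tj_geometry(width = 8),
                       horizon = 120, reps = 3)
  expect_identical(a$qa_mean, b$qa_mean)
})

test_that("permeability increases with p_break under common random numbers", {
  geom <- tj_geometry(width = 20)
  res <- vapply(c(0.02e6, 0.05e6, 0.09e6), function(p) {
    set.seed(31)
    tj_permeability("MDCK II mean", geom = geom, dyn = tj_dynamics(p),
                    horizon = 900, reps = 12)$P_bTJ
  }, 0)
  expect_true(all(diff(res) > 0))
})

test_that("equilibrium row profile is linear inside with boundary jumps", {
  for (n in c(2, 4, 6)) {
    net <- tj_network(tj_geometry(n_strand = n, width = 3))
    prof <- tj_equilibrium_profile(net)
    R <- n - 1L
    expect_equal(prof, (2 * R + 1 - 2 * seq_len(R)) / (2 * R))
    expect_true(all(diff(prof) < 0))
    expect_true(all(prof > 0 & prof < 1))
    if (R >= 3) expect_equal(diff(diff(prof)), rep(0, R - 2))
  }
})

test_that("simulated equilibrium profile matches the closed form and is
           insensitive to the break probability", {
  epi <- tj_preset("MDCK II mean")
  geom <- tj_geometry(n_strand = 4, width = 15)
  net <- tj_network(geom)
  mol <- tj_molecule(547)
  Pb <- tj_break_permeability(geom, mol, epi$l_cb)
  mf <- tj_equilibrium_profile(net)
  set.seed(17)
  s1 <- tj_equilibrium_profile(net, tj_dynamics(0.036e6), Pb,
                               method = "simulate", horizon = 2400,
                               reps = 24)
  set.seed(18)
  s2 <- tj_equilibrium_profile(net, tj_dynamics(0.09e6), Pb,
                               method = "simulate", horizon = 1200,
                               reps = 24)
  expect_equal(s1, mf, tolerance = 0.08)
  expect_equal(s2, mf, tolerance = 0.08)
  expect_equal(max(abs(s1 - s2)), 0, tolerance = 0.08)
})

test_that("single-row equilibrium lies strictly between basal and apical", {
  net <- tj_network(tj_geometry(n_strand = 2, width = 3))
  prof <- tj_equilibrium_profile(net)
  expect_length(prof, 1)
  expect_true(prof > 0 && prof < 1)
})

test_that("zero-init runs report a lag and both estimators see the same
           asymptote on a fast system", {
  epi <- tj_preset("MDCK II mean")
  geom <- tj_geometry(n_strand = 2, width = 15)
  set.seed(23)
  lag_paired <- tj_lag_time(epi, geom = geom, horizon = 600, reps = 24,
                            method = "paired")
  expect_true(is.finite(lag_paired))
  expect_lt(abs(lag_paired), 30)  # near-zero lag for a 2-strand system
  set.seed(23)
  sim <- tj_permeability(epi, geom = geom, horizon = 600, reps = 24,
                         init = "zero")
  expect_true(is.finite(sim$lag_time))
})

test_that("lag time increases with strand number", {
  epi <- tj_preset("MDCK II mean")
  lags <- vapply(2:4, function(n) {
    set.seed(29)
    tj_lag_time(epi, geom = tj_geometry(n_strand = n, width = 20),
                horizon = 1800, reps = 16, method = "paired")
  }, 0)
  expect_true(all(diff(lags) > 0))
})
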