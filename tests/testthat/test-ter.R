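test_that("break resistance follows the printed geometry formula", {
  geom <- tj_geometry()
  elec <- tj_electrical(7.65e3)
  oracle <- 0.537 * 6e-9 / (2 * 4e-9 * 20e-9)
  expect_equal(tj_break_resistance(geom, elec), oracle)
  # halving the break area doubles the resistance
  g2 <- tj_geometry(l_break = 10e-9)
  expect_equal(tj_break_resistance(g2, elec), 2 * oracle)
  # the calibration-consistent default override is 0.2 GOhm
  expect_equal(elec$R_break, 0.2e9)
})

test_that("section resistance: intact division, broken parallel combination", {
  elec <- tj_electrical(7.65e3)  # Caco-2, 7.65 GOhm um
  expect_equal(tj_section_resistance(0, 0.05e-6, elec), 153e9)
  # MDCK C7: a 20-nm length of strand has 531 GOhm
  expect_equal(tj_section_resistance(0, 20e-9, tj_electrical(10.62e3)),
               531e9)
  # broken: remaining strand in parallel with the break
  rb <- tj_section_resistance(1, 0.05e-6, elec)
  expect_equal(rb, 1 / ((0.05e-6 - 20e-9) / 7.65e3 + 1 / 0.2e9))
  # with a non-conducting strand only the break conducts
  expect_equal(tj_section_resistance(1, 0.05e-6, tj_electrical(1e30)),
               0.2e9, tolerance = 1e-6)
  # breaking always lowers the resistance
  lens <- c(50e-9, 100e-9)
  expect_true(all(tj_section_resistance(1, lens, elec) <
                    tj_section_resistance(0, lens, elec)))
})

test_that("strand-to-break resistance ratios span the reported range", {
  r20 <- function(R_strand) R_strand / 20e-9
  expect_equal(r20(0.36e3) / 0.2e9, 90)     # average MDCK II
  expect_equal(r20(10.62e3) / 0.2e9, 2655)  # MDCK C7
})

test_that("the intact network solves to the series closed form exactly", {
  for (n in c(2, 4, 5)) {
    for (W in c(3, 10)) {
      geom <- tj_geometry(n_strand = n, width = W)
      net <- tj_network(geom)
      elec <- tj_electrical(0.46e3)
      Rs <- tj_section_resistance(0, net$sections$length, elec)
      sol <- tj_solve_network(net, Rs)
      closed <- n * elec$R_strand / (W * geom$w_comp)
      expect_equal(sol$R_2D, closed, tolerance = 1e-9)
    }
  }
})

test_that("loop analysis agrees with an independent nodal solve on random
           break patterns", {
  geom <- tj_geometry(n_strand = 3, width = 3)
  net <- tj_network(geom)
  elec <- tj_electrical(0.46e3)
  set.seed(99)
  for (i in 1:100) {
    st <- stats::rbinom(nrow(net$sections), 1, 0.3)
    Rs <- tj_section_resistance(st, net$sections$length, elec)
    mesh <- tj_solve_network(net, Rs)$R_2D
    expect_equal(mesh, nodal_r2d(net, Rs), tolerance = 1e-9)
  }
})

test_that("the source voltage is a pure scaling parameter", {
  net <- tj_network(tj_geometry(n_strand = 3, width = 3))
  elec <- tj_electrical(0.46e3)
  set.seed(1)
  st <- stats::rbinom(nrow(net$sections), 1, 0.2)
  Rs <- tj_section_resistance(st, net$sections$length, elec)
  a <- tj_solve_network(net, Rs, V_s = 1)
  b <- tj_solve_network(net, Rs, V_s = 2)
  expect_equal(b$I_outer, 2 * a$I_outer)
  expect_equal(b$R_2D, a$R_2D)
})

test_that("tricellular resistance follows Ohmic pore geometry", {
  elec <- tj_electrical(0.46e3)
  ttj <- tj_tricellular(0.106e12)  # MDCK IIa
  oracle <- 0.537 * 1e-6 / (pi * (5e-9)^2 * 0.106e12)
  expect_equal(tj_ttj_resistance(ttj, elec), oracle)
  expect_equal(tj_ttj_resistance(tj_tricellular(0.053e12), elec),
               2 * oracle)
  # measured MDCK IIa TER of 28 Ohm cm^2 puts the tTJ share at a few percent
  expect_equal(28 / (oracle * 1e4), 0.043, tolerance = 0.01)
})

test_that("a break-free epithelium has the static parallel TER", {
  epi <- tj_preset("Caco-2")
  geom <- tj_geometry(width = 10)
  set.seed(2)
  sim <- tj_ter(epi, geom = geom, dyn = tj_dynamics(0), horizon = 20)
  R_b <- 4 * epi$R_strand / epi$l_cb
  R_t <- tj_ttj_resistance(tj_tricellular(epi$rho_tTJ),
                           tj_electrical(epi$R_strand))
  expect_equal(sim$TER_mean, 1 / (1 / R_b + 1 / R_t), tolerance = 1e-9)
  expect_equal(diff(range(sim$TER)), 0)
})

test_that("the TER trace stays between the all-broken and all-intact limits", {
  epi <- tj_preset("Caco-2")
  geom <- tj_geometry(width = 10)
  net <- tj_network(geom)
  elec <- tj_electrical(epi$R_strand)
  scale <- net$w_model / epi$l_cb
  R_t <- tj_ttj_resistance(tj_tricellular(epi$rho_tTJ), elec)
  lims <- vapply(c(0, 1), function(s) {
    Rs <- tj_section_resistance(s, net$sections$length, elec)
    Rb <- tj_solve_network(net, Rs)$R_2D * scale
    1 / (1 / Rb + 1 / R_t)
  }, 0)
  set.seed(3)
  sim <- tj_ter(epi, geom = geom, horizon = 600)
  expect_gte(min(sim$TER), lims[2] * (1 - 1e-9))
  expect_lte(max(sim$TER), lims[1] * (1 + 1e-9))
})

test_that("TER falls with p_break and rises with strand number", {
  epi <- tj_preset("MDCK II mean")
  ters_p <- vapply(c(0.01e6, 0.05e6, 0.12e6), function(p) {
    set.seed(8)
    tj_ter(epi, geom = tj_geometry(width = 20), dyn = tj_dynamics(p),
           horizon = 1500)$TER_mean
  }, 0)
  expect_true(all(diff(ters_p) < 0))
  ters_n <- vapply(c(2, 4, 6), function(n) {
    set.seed(9)
    tj_ter(epi, geom = tj_geometry(n_strand = n, width = 20),
           horizon = 1500)$TER_mean
  }, 0)
  expect_true(all(diff(ters_n) > 0))
})

test_that("seeded TER runs are bit-reproducible", {
  set.seed(77)
  a <- tj_ter("MDCK IIa", geom = tj_geometry(width = 8), horizon = 100)
  set.seed(77)
  b <- tj_ter("MDCK IIa", geom = tj_geometry(width = 8), horizon = 100)
  expect_identical(a$TER, b$TER)
})
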