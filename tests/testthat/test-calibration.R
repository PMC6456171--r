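test_that("hexagonal cell arrays give the textbook junction densities", {
  hex <- tj_hexagonal_geometry(20e-6)
  expect_equal(hex$l_cb / 1e6, 0.050, tolerance = 1e-9)
  hex15 <- tj_hexagonal_geometry(15e-6)
  expect_equal(hex15$l_cb / 1e6, 0.067, tolerance = 0.01)
  # densities within the reported band for 15-20 um cells
  for (a in c(15e-6, 17.5e-6, 20e-6)) {
    h <- tj_hexagonal_geometry(a)
    expect_true(h$l_cb / 1e6 >= 0.049 && h$l_cb / 1e6 <= 0.068)
    expect_true(h$rho_tTJ / 1e12 >= 0.001 && h$rho_tTJ / 1e12 <= 0.003)
    # two tricellular vertices per cell
    cell_area <- 2 * sqrt(3) * a^2
    expect_equal(h$rho_tTJ * cell_area, 2)
  }
  expect_error(tj_hexagonal_geometry(-1), "positive")
})

test_that("calibration is rejected when tricellular pores already explain the
           measurement", {
  expect_error(tj_fit_p_break("MDCK C7"), "infeasible")
})

test_that("p_break calibration recovers a self-generated target", {
  geom <- tj_geometry(n_strand = 3, width = 20)
  base <- tj_preset("MDCK IIa")
  p_true <- 0.030e6
  set.seed(55)
  crn <- sample.int(2^30, 1)
  set.seed(crn)
  P_target <- tj_permeability(base, geom = geom, dyn = tj_dynamics(p_true),
                              horizon = 1200, reps = 16)$P_bTJ
  epi <- tj_epithelium("synthetic", l_cb = base$l_cb,
                       rho_tTJ = base$rho_tTJ,
                       P_exp = P_target +
                         tj_ttj_permeability(tj_tricellular(base$rho_tTJ),
                                             tj_molecule(547)))
  fit <- tj_fit_p_break(epi, geom = geom, reps = 16, horizon = 1200,
                        coarse_reps = 16, coarse_horizon = 1200,
                        crn_seed = crn)
  expect_s3_class(fit, "tj_fit")
  expect_equal(fit$value, p_true, tolerance = 0.001e6 / p_true + 1e-9)
  expect_named(coef(fit), "p_break")
  # reported value sits on the calibration grid
  expect_equal(fit$value %% 0.001e6, 0)
})

test_that("R_strand calibration recovers a self-generated target", {
  geom <- tj_geometry(width = 15)
  base <- tj_preset("MDCK IIa")
  R_true <- 0.46e3
  set.seed(66)
  crn <- sample.int(2^30, 1)
  set.seed(crn)
  TER_target <- tj_ter(base, geom = geom, elec = tj_electrical(R_true),
                       horizon = 2500)$TER_mean
  epi <- tj_epithelium("synthetic", l_cb = base$l_cb,
                       rho_tTJ = base$rho_tTJ, TER_exp = TER_target,
                       p_break = base$p_break)
  fit <- tj_fit_r_strand(epi, geom = geom, horizon = 2500, crn_seed = crn)
  expect_equal(fit$value, R_true, tolerance = 0.05)
  expect_equal(fit$value %% 10, 0)  # 0.01 GOhm um grid
  expect_lt(fit$achieved, 0.05)
})

test_that("pathway shares decompose measured barrier properties", {
  sh <- tj_pathway_shares("MDCK C7")
  expect_equal(sh$perm_tTJ, 1)  # C7 leak pathway is fully tricellular
  expect_equal(sh$perm_bTJ + sh$perm_tTJ, 1)
  expect_equal(sh$ter_bTJ + sh$ter_tTJ, 1)
  sh2 <- tj_pathway_shares("MDCK IIa")
  expect_true(sh2$perm_bTJ > 0 && sh2$perm_bTJ < 1)
  expect_lt(sh2$ter_tTJ, 0.1)
})

test_that("strand sweep and sensitivity return well-formed effects on a desk
           scale", {
  sw <- tj_strand_sweep("MDCK II mean", n_strand = c(2, 4), width = 12,
                        reps = 8, horizon_perm = 600, horizon_ter = 500)
  expect_equal(nrow(sw), 2)
  expect_lt(sw$P_TJ[2], sw$P_TJ[1])     # permeability falls with strands
  expect_gt(sw$TER[2], sw$TER[1])       # TER rises with strands
  expect_gt(sw$perm_share_tTJ[2], sw$perm_share_tTJ[1])
  expect_equal(sw$P_rel[sw$n_strand == 4], 1)

  sens <- tj_sensitivity("MDCK II mean", params = c("R_strand", "rho_tTJ"),
                         geom = tj_geometry(width = 12), reps = 8,
                         horizon_perm = 600, horizon_ter = 500,
                         crn_seed = 4242)
  expect_equal(nrow(sens), 4)
  # TER tracks R_strand nearly proportionally for MDCK II
  r_down <- sens$TER_rel[sens$parameter == "R_strand" & sens$change < 0]
  r_up <- sens$TER_rel[sens$parameter == "R_strand" & sens$change > 0]
  expect_equal(r_down, 0.75, tolerance = 0.08)
  expect_equal(r_up, 1.25, tolerance = 0.08)
  # permeability is proportional to the pore density through the tTJ term
  expect_true(all(is.finite(sens$P_rel)))
})
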