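test_that("stationary broken probability matches the matrix-power oracle", {
  dyn <- tj_dynamics(p_break = 0.047e6, p_seal = 0.033)
  len <- 0.05e-6
  v <- chain_power(0.047e6 * len, 0.033)
  expect_equal(tj_stationary_broken(dyn, len), v[2], tolerance = 1e-9)
  # degenerate and symmetric cases
  expect_equal(tj_stationary_broken(tj_dynamics(0), len), 0)
  dyn_sym <- tj_dynamics(p_break = 0.033 / len, p_seal = 0.033)
  expect_equal(tj_stationary_broken(dyn_sym, len), 0.5)
  expect_error(tj_stationary_broken(dyn, -1e-9), "non-negative")
})

test_that("initial-state sampling follows the stationary distribution", {
  net <- tj_network(tj_geometry(n_strand = 2, width = 1))
  dyn <- tj_dynamics(p_break = 0.033 / 100e-9 * 0.0707, p_seal = 0.033)
  p <- tj_stationary_broken(dyn, net$sections$length[1])
  set.seed(1)
  n <- 5000
  draws <- replicate(n, tj_sample_states(net, dyn)[1])
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / n))
  # all intact when breaks cannot form
  expect_equal(tj_sample_states(net, tj_dynamics(0)), rep(0L, 2))
})

test_that("longer sections are broken at least as often as shorter ones", {
  net <- tj_network(tj_geometry(n_strand = 3, width = 4))
  dyn <- tj_dynamics(p_break = 0.05e6)
  p <- tj_stationary_broken(dyn, net$sections$length)
  long <- net$sections$length == 100e-9
  short <- net$sections$length == 50e-9
  expect_true(min(p[long]) > max(p[short]))
})

test_that("state stepping reproduces the transition probabilities and is ergodic", {
  net <- tj_network(tj_geometry(n_strand = 2, width = 25))
  dyn <- tj_dynamics(p_break = 0.06e6, p_seal = 0.033)
  pb <- dyn$p_break * net$sections$length
  set.seed(2)
  n_steps <- 4000
  states <- tj_sample_states(net, dyn)
  n_sec <- length(states)
  breaks <- seals <- intact_expo <- broken_expo <- 0
  occ <- numeric(n_sec)
  for (i in seq_len(n_steps)) {
    new <- tj_step_states(states, net, dyn)
    breaks <- breaks + sum(states == 0 & new == 1)
    seals <- seals + sum(states == 1 & new == 0)
    intact_expo <- intact_expo + sum(states == 0)
    broken_expo <- broken_expo + sum(states == 1)
    states <- new
    occ <- occ + states
  }
  # transition frequencies within 3 binomial SDs
  p_b <- mean(pb)
  expect_lt(abs(breaks / intact_expo - p_b),
            3 * sqrt(p_b * (1 - p_b) / intact_expo))
  expect_lt(abs(seals / broken_expo - dyn$p_seal),
            3 * sqrt(dyn$p_seal * (1 - dyn$p_seal) / broken_expo))
  # ergodic occupancy vs Eq-3 stationary value (pooled over sections)
  p_stat <- tj_stationary_broken(dyn, net$sections$length)
  expect_equal(mean(occ / n_steps), mean(p_stat), tolerance = 0.05)
})

test_that("deterministic limits of the step rule hold", {
  net <- tj_network(tj_geometry(n_strand = 2, width = 3))
  all_broken <- rep(1L, nrow(net$sections))
  dyn <- tj_dynamics(p_break = 0, p_seal = 1)
  expect_equal(tj_step_states(all_broken, net, dyn),
               rep(0L, nrow(net$sections)))
})

test_that("broken spells last about 1/p_seal updates on average", {
  net <- tj_network(tj_geometry(n_strand = 2, width = 25))
  dyn <- tj_dynamics(p_break = 0.2e6, p_seal = 0.033)
  set.seed(3)
  states <- tj_sample_states(net, dyn)
  dur <- numeric(0)
  open_since <- rep(NA_real_, length(states))
  for (t in seq_len(6000)) {
    new <- tj_step_states(states, net, dyn)
    opened <- states == 0 & new == 1
    closed <- states == 1 & new == 0
    open_since[opened] <- t
    dur <- c(dur, t - open_since[closed & !is.na(open_since)])
    states <- new
  }
  expect_gt(length(dur), 300)
  expect_equal(mean(dur), 1 / dyn$p_seal, tolerance = 0.15)
})

test_that("seeded runs are bit-reproducible", {
  net <- tj_network(tj_geometry(n_strand = 3, width = 5))
  dyn <- tj_dynamics(p_break = 0.05e6)
  set.seed(42); a <- tj_sample_states(net, dyn)
  set.seed(42); b <- tj_sample_states(net, dyn)
  expect_identical(a, b)
})
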