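test_that("pool construction follows the quadratic size distribution", {
  pool <- motor_pool(n = 300)
  expect_equal(pool$soma_um[1], 50)
  expect_equal(pool$soma_um[300], 100)
  expect_lt(median(pool$soma_um), 75)
  expect_equal(median(pool$soma_um), 62.5, tolerance = 0.01)
  expect_equal(pool$s_fac[1], 1)
  expect_true(all(pool$s_fac <= 1))
  expect_true(all(diff(pool$gamma_star) > 0))
  expect_true(all(pool$i_rheo > 0))
  expect_true(all(pool$t_refr > 0 & pool$r_kohm > 0 & pool$c_mss > 0))
})

test_that("input generation obeys the mixing rules", {
  spec3 <- scenario_spec("ii")
  expect_equal(unique(as.vector(muflex:::mixing_weights(10, 3, "homogeneous"))),
               1 / 3)

  set.seed(2)
  w <- muflex:::mixing_weights(1000, 3, "heterogeneous")
  expect_equal(rowSums(w), rep(1, 1000), tolerance = 1e-12)
  # temperature 0.1 concentrates each row's mass on its dominant source
  # (Monte-Carlo mean of the max weight is ~0.82 for uniform draws, k = 3)
  expect_gt(mean(apply(w, 1, max)), 0.75)
  expect_gt(mean(apply(w, 1, max) > 0.5), 0.9)

  inp <- generate_inputs(spec3, n_per_pool = 20, duration = 20, seed = 3)
  expect_equal(dim(inp$gamma_e), c(20, 20 * 500))
  expect_true(all(inp$gamma_i == 0))

  # correlated pool sources in the three-pool scenario
  inp7 <- generate_inputs(scenario_spec("vii"), n_per_pool = 5,
                          duration = 60, seed = 4)
  cm <- cor(t(inp7$sources))
  expect_equal(mean(cm[upper.tri(cm)]), 0.7, tolerance = 0.05)

  expect_error(scenario_spec("viii"), "Unknown scenario")
})

test_that("subthreshold drive is silent; constant drive matches the closed-form period", {
  pool <- motor_pool(n = 20)
  t_n <- 5 * 500
  ge_low <- matrix(0.3, 20, t_n) # below every recruitment threshold
  sim0 <- simulate_pool(pool, ge_low, NULL, 500, 5, dt = 5e-5)
  expect_equal(nrow(sim0$mn_spikes), 0)

  gamma <- 0.55
  ge <- matrix(gamma, 20, t_n)
  sim <- simulate_pool(pool, ge, NULL, 500, 5, dt = 5e-5)
  active <- unique(sim$mn_spikes$unit_id)
  expect_gt(length(active), 0)
  for (u in active[c(1, length(active))]) {
    j <- as.integer(sub("mn", "", u))
    isi <- diff(sim$mn_spikes$time_s[sim$mn_spikes$unit_id == u])
    expect_gt(length(isi), 3)
    # perfectly periodic firing
    expect_lt(diff(range(isi)), 2e-4 + 1e-12)
    expect_true(all(isi >= pool$t_refr[j] - 1e-12))
    # closed-form LIF period: t* = tau_eff log(vinf / (vinf - vth)) + t_refr
    b <- 1 / pool$r_kohm[j] + gamma * pool$s_fac[j]
    vinf <- (25 * gamma * pool$s_fac[j] - pool$i_rheo[j]) / b
    t_star <- pool$c_mss[j] / b * log(vinf / (vinf - 10))
    expect_equal(mean(isi), t_star + pool$t_refr[j], tolerance = 0.02)
  }

  # firing rate is non-decreasing in drive
  rates <- vapply(c(0.5, 0.55, 0.6), function(g) {
    s <- simulate_pool(pool, matrix(g, 20, t_n), NULL, 500, 5, dt = 5e-5)
    nrow(s$mn_spikes)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("halving dt changes firing rates by less than 2%", {
  pool <- motor_pool(n = 30)
  inp <- generate_inputs(scenario_spec("i"), n_per_pool = 30, duration = 6,
                         seed = 5)
  n1 <- nrow(simulate_pool(pool, inp$gamma_e, NULL, 500, 6, dt = 1e-4)$mn_spikes)
  n2 <- nrow(simulate_pool(pool, inp$gamma_e, NULL, 500, 6, dt = 5e-5)$mn_spikes)
  expect_lt(abs(n1 - n2) / n2, 0.02)
})

test_that("simulation is reproducible and deterministic given identical inputs", {
  pool <- motor_pool(n = 10)
  inp <- generate_inputs(scenario_spec("i"), n_per_pool = 10, duration = 4,
                         seed = 6)
  s1 <- simulate_pool(pool, inp$gamma_e, NULL, 500, 4, dt = 1e-4)
  s2 <- simulate_pool(pool, inp$gamma_e, NULL, 500, 4, dt = 1e-4)
  expect_identical(s1$mn_spikes, s2$mn_spikes)
})

test_that("Renshaw connectivity densities match the scenario definitions", {
  spec6 <- scenario_spec("vi")
  rsh <- build_renshaw(spec6, duration = 1, seed = 7)
  expect_equal(rsh$m, 60)
  in_deg <- rowSums(rsh$c_mn2rc)
  expect_true(all(in_deg == round(0.17 * 300)))
  out_deg <- rowSums(rsh$c_rc2mn) # per motor neuron, cells inhibiting it
  expect_equal(mean(out_deg) / 60, 0.40, tolerance = 0.05)

  rsh_b <- build_renshaw(spec6, duration = 1, seed = 7)
  expect_identical(rsh_b$c_mn2rc, rsh$c_mn2rc)
  expect_identical(rsh_b$c_rc2mn, rsh$c_rc2mn)

  spec7 <- scenario_spec("vii")
  rsh7 <- build_renshaw(spec7, duration = 1, seed = 8)
  expect_equal(rsh7$m, 180)
  # no motor neuron excites a heteronymous Renshaw cell
  for (p in 1:3) {
    mn <- (p - 1) * 300 + 1:300
    rc_het <- setdiff(1:180, (p - 1) * 60 + 1:60)
    expect_true(all(!rsh7$c_mn2rc[rc_het, mn]))
    expect_true(all(rowSums(rsh7$c_mn2rc[(p - 1) * 60 + 1:60, mn]) ==
                      round(0.5 * 300)))
  }
  # each motor neuron: homonymous inhibition from ~60% of its own cells
  own <- rowSums(rsh7$c_rc2mn[1:300, 1:60])
  expect_equal(mean(own) / 60, 0.60, tolerance = 0.05)
  # exactly two thirds of each pool receive heteronymous inhibition
  het <- rowSums(rsh7$c_rc2mn[1:300, 61:180] > 0)
  expect_equal(sum(het > 0), 200)
})

test_that("recruitment follows the size principle under a slow ramp", {
  pool <- motor_pool(n = 60)
  rec <- simulate_ramp(pool, gamma_range = c(0.3, 1.2), duration = 10,
                       seed = 9)
  got <- rec[!is.na(rec$first_spike_s), ]
  expect_gt(nrow(got), 40)
  rho <- cor(got$soma_um, got$first_spike_s, method = "spearman")
  expect_gte(rho, 0.95)
})
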