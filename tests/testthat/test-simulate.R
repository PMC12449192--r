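test_that("vde KO never forms de-epoxidized pigments", {
  p <- noise_free_params()
  reg <- light_regime()
  s <- simulate_pigments(p, genotype("vde_ko"), reg)
  expect_true(all(s$dt == 0))
  expect_true(all(s$zx == 0))
  expect_true(all(s$ax == 0))
  # also from an explicit de-epoxidized-free initial state
  s2 <- simulate_pigments(p, genotype("vde_ko"), reg,
                          initial = c(dd = 0.05, dt = 0, vx = 0.05, ax = 0,
                                      zx = 0, fx = 0.6))
  expect_true(all(s2$dt == 0) && all(s2$zx == 0))
})

test_that("total pigment is conserved when de novo synthesis is off", {
  p <- noise_free_params(s_denovo = 0)
  reg <- light_regime()
  for (g in c("wt", "zep2_ko", "zep3_ko")) {
    s <- simulate_pigments(p, genotype(g), reg)
    tot <- s$dd + s$dt + s$vx + s$ax + s$zx
    expect_lt(diff(range(tot)) / tot[1], 1e-6)
  }
})

test_that("wild type triples its pool over the HL block; fucoxanthin is constant", {
  s <- simulate_pigments(noise_free_params(), genotype("wt"), light_regime())
  tot <- function(r) r$dd + r$dt + r$vx + r$ax + r$zx
  ratio <- tot(s[s$time_min == 360, ]) / tot(s[s$time_min == 0, ])
  expect_equal(ratio, 3, tolerance = 0.001)
  expect_equal(diff(range(s$fx)), 0)
})

test_that("ODE solution matches the consecutive-chain closed form", {
  # source off, de-epoxidation off, ZEP3 chain only: pure Zx -> Ax -> Vx
  p <- noise_free_params(s_denovo = 0, v_dd = 0, v_vx = 0, k3_dt = 0, k2 = 0)
  reg <- regime_from_segments(
    data.frame(start_min = 0, duration_min = 60, irradiance = 25))
  init <- c(dd = 0, dt = 0, vx = 0, ax = 0.1, zx = 0.8, fx = 0.6)
  s <- simulate_pigments(p, genotype("wt"), reg, initial = init,
                         times = seq(0, 60, by = 2.5), window_start = 0)
  cf <- bateman(s$time_min, kz = p$k3_zx, ka = p$k3_ax, z0 = 0.8, a0 = 0.1)
  expect_lt(max(abs(s$zx - cf$zx) / pmax(cf$zx, 1e-12)), 1e-6)
  expect_lt(max(abs(s$ax - cf$ax) / pmax(cf$ax, 1e-12)), 1e-6)
  # mass balance: vx picks up exactly what the chain loses
  expect_equal(s$vx + s$ax + s$zx, rep(0.9, nrow(s)), tolerance = 1e-9)
})

test_that("zep3 KO retains Dt through recovery but loses it overnight", {
  reg <- light_regime()
  t0 <- analysis_window_start(reg)
  s <- simulate_pigments(noise_free_params(), genotype("zep3_ko"), reg,
                         times = t0 + c(0, 360, 390, 1440))
  dt6 <- s$dt[s$time_min == 360]
  expect_lt(abs(s$dt[s$time_min == 390] - dt6) / dt6, 0.30)
  expect_lt(s$dt[s$time_min == 1440] / dt6, 0.01)
})

test_that("trajectories stay nonnegative across random parameter draws", {
  reg <- light_regime()
  set.seed(202)
  for (i in 1:5) {
    p <- noise_free_params(
      v_dd = runif(1, 0, 1), v_vx = runif(1, 0, 0.5),
      k3_dt = runif(1, 0, 0.3), k3_zx = runif(1, 0, 0.3),
      k3_ax = runif(1, 0, 0.2), k2 = runif(1, 0, 0.05),
      s_denovo = runif(1, 0, 0.002)
    )
    g <- sample(c("wt", "vde_ko", "zep2_ko", "zep3_ko"), 1)
    s <- simulate_pigments(p, genotype(g), reg)
    expect_true(all(as.matrix(s[c("dd", "dt", "vx", "ax", "zx")]) >= 0))
  }
})

test_that("invalid inputs are rejected", {
  expect_error(scenario_params(v_dd = -1), "nonnegative")
  expect_error(scenario_params(w_ax = 2), "w_ax")
  expect_error(scenario_params(n_replicates = 0), "n_replicates")
  expect_error(scenario_params(not_a_param = 1), "unknown")
  expect_error(
    simulate_pigments(noise_free_params(), genotype("wt"), light_regime(),
                      initial = c(dd = -0.1, dt = 0, vx = 0, ax = 0, zx = 0,
                                  fx = 0.6)),
    "nonnegative")
})

test_that("fluorescence emulation inverts exactly and scales with gamma", {
  p <- noise_free_params()
  reg <- light_regime()
  pig <- simulate_pigments(p, genotype("wt"), reg,
                           times = analysis_window_start(reg) + sampling_grid())
  fl <- simulate_fluorescence(pig, p, reg)
  # algebraic inversion recovers the emitted NPQ_total
  npq_back <- (p$fm_ref - fl$fm_prime) / fl$fm_prime
  q <- pig$dt + pig$zx + p$w_ax * pig$ax
  qi <- qi_at(p, reg, pig$time_min + analysis_window_start(reg),
              analysis_window_start(reg))
  expect_equal(npq_back, p$gamma * q + qi, tolerance = 1e-12)
  # no quenching: vde KO with photoinhibition off emits fm_ref everywhere
  p0 <- noise_free_params(qi_max = 0)
  pig0 <- simulate_pigments(p0, genotype("vde_ko"), reg,
                            times = analysis_window_start(reg) + sampling_grid())
  fl0 <- simulate_fluorescence(pig0, p0, reg)
  expect_equal(fl0$fm_prime, rep(p0$fm_ref, nrow(fl0)))
  # doubling gamma doubles fm_ref/F'm - 1 when qI = 0
  p1 <- noise_free_params(qi_max = 0)
  p2 <- noise_free_params(qi_max = 0, gamma = 50)
  fl1 <- simulate_fluorescence(pig, p1, reg)
  fl2 <- simulate_fluorescence(pig, p2, reg)
  expect_equal(p1$fm_ref / fl2$fm_prime - 1,
               2 * (p1$fm_ref / fl1$fm_prime - 1), tolerance = 1e-12)
  # missing reference points are refused
  expect_error(simulate_fluorescence(pig[pig$time_min > 0, ], p, reg),
               "reference")
})

test_that("replicate generation is seeded, truncated and sized as configured", {
  p <- scenario_params(seed = 123)
  d1 <- generate_dataset(p, genotypes = c("wt", "zep2_ko"))
  d2 <- generate_dataset(p, genotypes = c("wt", "zep2_ko"))
  expect_identical(d1, d2)
  # default replication: exactly 3 rows per strain x time
  cnt <- dplyr::count(d1$pigments, strain, time_min)
  expect_true(all(cnt$n == 3))
  expect_true(all(as.matrix(d1$pigments[c("dd", "dt", "vx", "ax", "zx")]) >= 0))
  expect_true(all(d1$fluorescence$fm_prime > 0))
  # zero noise reproduces the mean trajectory in every replicate
  d0 <- generate_dataset(noise_free_params(n_replicates = 3),
                         genotypes = "wt")
  by_rep <- split(d0$pigments$dt, d0$pigments$replicate)
  expect_equal(by_rep[[1]], by_rep[[2]])
  expect_equal(by_rep[[2]], by_rep[[3]])
  # a different seed changes the draws
  d3 <- generate_dataset(scenario_params(seed = 124),
                         genotypes = c("wt", "zep2_ko"))
  expect_false(identical(d1$pigments$dd, d3$pigments$dd))
})
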