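test_that("pool normalization gives per-time-point fractions", {
  d <- data.frame(dd = c(0.05, 0.08), dt = c(0.05, 0.02),
                  vx = c(0.2, 0.1), ax = c(0, 0.1), zx = c(0.2, 0.2))
  expect_equal(normalize_to_pool(d, "dd")$dt_frac, c(0.5, 0.2))
  nv <- normalize_to_pool(d, "vx")
  expect_equal(nv$zx_frac, c(0.5, 0.5))
  expect_equal(nv$zx_frac + nv$ax_frac + nv$vx_frac, c(1, 1))
  # constant pool: halving the pigment halves the fraction
  d2 <- data.frame(dd = c(0.06, 0.08), dt = c(0.04, 0.02),
                   vx = 0, ax = 0, zx = 0)
  expect_equal(normalize_to_pool(d2, "dd")$dt_frac, c(0.4, 0.2))
  # empty pools are dropped with a warning
  d3 <- data.frame(dd = c(0.1, 0), dt = c(0.1, 0), vx = 0, ax = 0, zx = 0)
  expect_warning(out <- normalize_to_pool(d3, "dd"), "dropped")
  expect_equal(nrow(out), 1)
})

test_that("per-time-point and fixed-pool normalization coincide in recovery", {
  # LL recovery has no de novo input, so each cycle's pool is closed
  ds <- mean_dataset()
  rec <- ds$pigments[ds$pigments$strain == "zep2_ko" &
                       ds$pigments$time_min >= 360, ]
  pool_t <- rec$vx + rec$ax + rec$zx
  expect_equal(pool_t, rep(pool_t[1], length(pool_t)), tolerance = 1e-7)
  frac_fixed <- rec$zx / pool_t[1]
  expect_equal(normalize_to_pool(rec, "vx")$zx_frac, frac_fixed,
               tolerance = 1e-7)
})

test_that("single-exponential fit is exact on self-generated data", {
  t <- recovery_grid()
  fit <- fit_single_exponential(t, 0.4 * exp(-0.12 * t))
  expect_equal(unname(fit$rates["k"]), 0.12, tolerance = 1e-6)
  expect_equal(unname(fit$amplitudes["y0"]), 0.4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # prediction is strictly decreasing and residual-free
  expect_true(all(diff(fit$fitted) < 0))
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # degenerate inputs
  expect_warning(f0 <- fit_single_exponential(t, rep(0.3, length(t))),
                 "boundary")
  expect_true(f0$boundary)
  expect_error(fit_single_exponential(t, rep(0, length(t))), "nothing to fit")
  expect_error(fit_single_exponential(t[1:2], c(1, 2)), "at least 3")
  expect_error(fit_single_exponential(t, -abs(exp(-t))), "nonnegative")
})

test_that("consecutive-chain fit recovers rates to four significant digits", {
  t <- recovery_grid()
  b <- bateman(t, kz = 0.165, ka = 0.055, z0 = 0.8, a0 = 0)
  fit <- fit_consecutive(t, b$zx, b$ax)
  expect_equal(unname(fit$rates["kz"]), 0.165, tolerance = 5e-5)
  expect_equal(unname(fit$rates["ka"]), 0.055, tolerance = 5e-5)
  expect_equal(unname(fit$amplitudes["z0"]), 0.8, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # equal-rate data generated via the limit branch round-trips within 1 %
  b2 <- bateman(t, kz = 0.1, ka = 0.1, z0 = 0.5, a0 = 0.05)
  fit2 <- fit_consecutive(t, b2$zx, b2$ax)
  expect_equal(unname(fit2$rates["kz"]), 0.1, tolerance = 0.01)
  expect_equal(unname(fit2$rates["ka"]), 0.1, tolerance = 0.01)
  expect_error(fit_consecutive(t, rep(0, length(t)), b$ax), "nothing to fit")
  expect_error(fit_consecutive(t[1:3], b$zx[1:3], b$ax[1:3]), "at least 4")
})

test_that("Bateman fractions respect mass balance at all times", {
  t <- seq(0, 30, by = 0.5)
  b <- bateman(t, 0.165, 0.055, z0 = 0.7, a0 = 0.3)
  vx <- 1 - b$zx - b$ax # closed chain starting from fractions summing to 1
  expect_true(all(vx >= -1e-12))
  expect_equal(b$zx + b$ax + vx, rep(1, length(t)))
  # limit branch is continuous against the generic branch
  near <- bateman(t, 0.1 + 5e-7, 0.1, z0 = 0.5, a0 = 0)
  lim <- bateman(t, 0.1, 0.1, z0 = 0.5, a0 = 0)
  expect_equal(near$ax, lim$ax, tolerance = 1e-4)
})

test_that("the Ax transient peak time follows the closed form", {
  expect_equal(ax_peak_time(0.165, 0.055), log(3) / 0.11, tolerance = 1e-12)
  expect_equal(ax_peak_time(0.165, 0.055), 9.99, tolerance = 0.001)
  expect_equal(ax_peak_time(0.1, 0.1), 10)
  # continuity at the branch point
  expect_equal(ax_peak_time(0.2, 0.2 - 1e-9), ax_peak_time(0.2, 0.2),
               tolerance = 1e-6)
  expect_error(ax_peak_time(-0.1, 0.05), "> 0")
  # the simulated Ax transient actually peaks there (dense noise-free grid)
  p <- noise_free_params()
  reg <- light_regime()
  t0 <- analysis_window_start(reg)
  s <- simulate_pigments(p, genotype("zep2_ko"), reg,
                         times = t0 + seq(360, 390, by = 0.25))
  t_peak <- s$time_min[which.max(s$ax)] - 360
  expect_equal(t_peak, ax_peak_time(p$k3_zx, p$k3_ax), tolerance = 0.3)
})

test_that("recovery fits on noise-free simulations recover generating rates", {
  ds <- mean_dataset()
  q <- compute_quenching(ds$fluorescence)
  fits <- fit_recovery_kinetics(ds$pigments, q)
  gen <- c(wt.kT = 0.12, wt.kZ = 0.165, wt.kA = 0.055,
           zep2_ko.kT = 0.11, zep2_ko.kZ = 0.155, zep2_ko.kA = 0.045)
  for (nm in names(gen)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    est <- fits$estimate[fits$strain == parts[1] &
                           fits$parameter == parts[2]]
    expect_equal(unname(est), unname(gen[nm]), tolerance = 0.05)
  }
  # qE relaxation tracks the Dt-pool rate; the end-anchored offsetless
  # model inflates it slightly (see the methods vignette)
  r0 <- fits$estimate[fits$strain == "wt" & fits$parameter == "R0"]
  expect_equal(unname(r0), 0.12, tolerance = 0.10)
  expect_true(all(fits$r_squared[fits$parameter != "R0"] > 0.999))
})

test_that("rate comparison contrasts strains and honours missing data", {
  ds <- mean_dataset()
  fits <- fit_recovery_kinetics(ds$pigments)
  # single replicate: intervals suppressed with warning
  w <- capture_warnings(cmp <- compare_rates(fits, n_boot = 50))
  expect_true(any(grepl("suppressed", w)))
  expect_true(all(is.na(cmp$conf_low)))
  for (par in c("kT", "kZ", "kA")) {
    expect_lt(cmp$diff_vs_ref[cmp$strain == "zep2_ko" & cmp$parameter == par], 0)
  }
  # identical inputs for both strains: contrasts collapse to zero
  same <- dplyr::bind_rows(
    dplyr::mutate(fits[fits$strain == "wt", ], strain = "wt"),
    dplyr::mutate(fits[fits$strain == "wt", ], strain = "mirror"))
  suppressWarnings(cmp0 <- compare_rates(same, n_boot = 50))
  expect_equal(cmp0$diff_vs_ref, rep(0, nrow(cmp0)))
  # a strain with missing Vx-cycle fits keeps flagged NA rows
  miss <- fits
  miss$estimate[miss$strain == "zep2_ko" & miss$parameter %in% c("kZ", "kA")] <- NA
  suppressWarnings(cmpm <- compare_rates(miss, n_boot = 50))
  expect_true(all(is.na(
    cmpm$estimate[cmpm$strain == "zep2_ko" & cmpm$parameter %in% c("kZ", "kA")])))
  expect_error(compare_rates(fits[fits$strain == "wt", ]), "2 strains")
})

test_that("tidy and glance summarize kinetic fits", {
  t <- recovery_grid()
  fit <- fit_single_exponential(t, 0.4 * exp(-0.12 * t))
  td <- tidy(fit)
  expect_equal(td$term, c("k", "y0"))
  gl <- glance(fit)
  expect_equal(gl$model, "single_exp")
  expect_equal(gl$n, length(t))
})
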