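test_that("delta pools are weighted sums vanishing at the endpoint", {
  pig <- data.frame(strain = "wt", replicate = 1,
                    time_min = c(0, 360, 370, 390),
                    dt = c(0.01, 0.25, 0.10, 0.05),
                    ax = c(0, 0.02, 0.08, 0.06),
                    zx = c(0, 0.15, 0.08, 0.05))
  dp <- build_delta_pools(pig)
  # the 0 h induction sample is excluded, the HL endpoint kept
  expect_equal(sort(unique(dp$time_min)), c(360, 370, 390))
  expect_equal(dp$delta_pool[dp$formula == "dt" & dp$time_min == 360], 0.20)
  expect_equal(
    dp$delta_pool[dp$formula == "dt_zx_half_ax" & dp$time_min == 360],
    0.20 + 0.10 + 0.5 * (-0.04))
  expect_equal(dp$delta_pool[dp$time_min == 390], rep(0, 5))
  dp2 <- build_delta_pools(pig, include_hl_endpoint = FALSE)
  expect_false(360 %in% dp2$time_min)
  expect_error(build_delta_pools(pig[pig$time_min != 390, ]), "endpoint")
})

test_that("hand-weighted deltas match the formula table", {
  # delta_dt = 0.1, delta_zx = 0.1, delta_ax = 0.04 -> half-Ax pool 0.22
  pig <- data.frame(strain = "wt", replicate = 1, time_min = c(360, 390),
                    dt = c(0.15, 0.05), zx = c(0.12, 0.02),
                    ax = c(0.05, 0.01))
  dp <- build_delta_pools(pig)
  expect_equal(
    dp$delta_pool[dp$formula == "dt_zx_half_ax" & dp$time_min == 360], 0.22)
  expect_equal(
    dp$delta_pool[dp$formula == "dt_zx_ax" & dp$time_min == 360], 0.24)
})

test_that("the generating formula attains a perfect combined fit", {
  ds <- mean_dataset()
  qe <- linear_qe(ds$pigments, gamma = 25, w_ax = 0.5)
  dp <- build_delta_pools(ds$pigments)
  fits <- suppressWarnings(fit_pool_models(qe, dp))
  comb <- fits[fits$group == "combined", ]
  r2 <- function(id) comb$r_squared[comb$formula == id]
  expect_equal(r2("dt_zx_half_ax"), 1, tolerance = 1e-9)
  expect_equal(comb$slope[comb$formula == "dt_zx_half_ax"], 25,
               tolerance = 1e-6)
  # misspecified Ax weight strictly degrades the fit when delta-Ax varies
  expect_lt(r2("dt_zx_ax"), 1 - 1e-6)
  expect_lt(r2("dt_zx"), 1 - 1e-6)
  expect_identical(as.character(select_best_pool(fits)), "dt_zx_half_ax")
})

test_that("a full-Ax generator selects the full-Ax formula", {
  ds <- mean_dataset()
  qe <- linear_qe(ds$pigments, gamma = 25, w_ax = 1)
  fits <- suppressWarnings(fit_pool_models(qe, build_delta_pools(ds$pigments)))
  expect_identical(as.character(select_best_pool(fits)), "dt_zx_ax")
})

test_that("shuffled qE shows no pool correlation", {
  ds <- mean_dataset()
  qe <- linear_qe(ds$pigments)
  set.seed(99)
  qe$qe <- sample(qe$qe)
  fits <- suppressWarnings(fit_pool_models(qe, build_delta_pools(ds$pigments)))
  expect_lt(max(fits$r_squared[fits$group == "combined"]), 0.3)
})

test_that("selection handles single formulas and inputs validation", {
  ds <- mean_dataset()
  qe <- linear_qe(ds$pigments)
  dp <- build_delta_pools(ds$pigments, formulas = pool_formulas()[4, ])
  fits <- suppressWarnings(fit_pool_models(qe, dp))
  expect_identical(as.character(select_best_pool(fits)), "dt_zx_half_ax")
  expect_error(select_best_pool(fits[fits$group != "combined", ]),
               "combined")
  expect_error(fit_pool_models(qe[0, ], dp), "no paired")
})

test_that("the continuous Ax weight is recovered and its profile is smooth", {
  ds <- mean_dataset()
  qe <- linear_qe(ds$pigments, w_ax = 0.5)
  aw <- suppressWarnings(estimate_ax_weight(qe, ds$pigments))
  expect_true(aw$identifiable)
  expect_lt(abs(aw$w - 0.5), 1e-3)
  # profile is continuous: no jumps between adjacent grid points
  expect_lt(max(abs(diff(aw$profile$r_squared))), 0.05)
  # profile agrees with the discrete five-formula comparison at w = 0, 1/2, 1
  fits <- suppressWarnings(fit_pool_models(qe, build_delta_pools(ds$pigments)))
  comb <- fits[fits$group == "combined", ]
  for (id_w in list(c("dt_zx", 0), c("dt_zx_half_ax", 0.5), c("dt_zx_ax", 1))) {
    expect_equal(
      aw$profile$r_squared[abs(aw$profile$w - as.numeric(id_w[2])) < 1e-9],
      comb$r_squared[comb$formula == id_w[1]], tolerance = 1e-9)
  }
})

test_that("a vanishing Ax delta leaves the weight unidentifiable", {
  pig <- data.frame(strain = "wt", replicate = 1,
                    time_min = c(360, 370, 375, 390),
                    dt = c(0.25, 0.12, 0.08, 0.05),
                    zx = c(0.10, 0.05, 0.03, 0.02),
                    ax = rep(0.04, 4))
  qe <- tibble::tibble(strain = "wt", replicate = 1,
                       time_min = c(360, 370, 375, 390),
                       qe = c(2, 1, 0.5, 0))
  aw <- estimate_ax_weight(qe, pig)
  expect_false(aw$identifiable)
  expect_true(is.na(aw$w))
})
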