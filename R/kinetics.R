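#' Normalize cycle pigments to their per-time-point pool size
#'
#' Expresses each xanthophyll-cycle pigment as a fraction of its own cycle's
#' total pool, computed per time point: `dt_frac = Dt / (Dd + Dt)` for the
#' Dd cycle, and `zx_frac`, `ax_frac`, `vx_frac` as fractions of
#' `Vx + Ax + Zx` for the Vx cycle. During LL recovery (no de novo input)
#' each cycle's pool is closed, so per-time-point and fixed-pool
#' normalization coincide. Time points with an empty pool are dropped with a
#' warning.
#'
#' @param pigments Data frame with the five cycle pigment columns.
#' @param cycle `"dd"` or `"vx"`.
#' @return Tibble with the fraction column(s) appended; empty-pool rows
#'   removed.
#' @export
normalize_to_pool <- function(pigments, cycle = c("dd", "vx")) {
  cycle <- match.arg(cycle)
  out <- tibble::as_tibble(pigments)
  if (cycle == "dd") {
    pool <- out$dd + out$dt
    keep <- pool > 0
    if (!all(keep)) warning(sum(!keep), " time point(s) dropped: empty Dd-cycle pool")
    out <- out[keep, ]
    out$dt_frac <- out$dt / (out$dd + out$dt)
  } else {
    pool <- out$vx + out$ax + out$zx
    keep <- pool > 0
    if (!all(keep)) warning(sum(!keep), " time point(s) dropped: empty Vx-cycle pool")
    out <- out[keep, ]
    pool <- out$vx + out$ax + out$zx
    out$zx_frac <- out$zx / pool
    out$ax_frac <- out$ax / pool
    out$vx_frac <- out$vx / pool
  }
  out
}

#' Single-exponential first-order decay fit
#'
#' Least-squares fit of `y(t) = y0 * exp(-k * (t - t0))` to recovery data,
#' with `t0` the start of the recovery window. There is no additive offset:
#' both qE and the end-anchored pigment deltas are structurally zero at full
#' recovery, so the asymptote is fixed at zero.
#'
#' @param times Times in minutes (recovery points only).
#' @param values Nonnegative observations (pool fractions or qE).
#' @param t0 Recovery start; default `min(times)`.
#' @return An object of class `xq_kinfit` with fields `model`
#'   (`"single_exp"`), `rates` (named `k`), `amplitudes` (named `y0`),
#'   `r_squared`, `residuals`, `fitted`, `boundary` (TRUE when the decay
#'   rate collapsed to the k = 0 boundary).
#' @examples
#' t <- c(0, 1, 3, 5, 7.5, 10, 15, 30)
#' fit <- fit_single_exponential(t, 0.4 * exp(-0.12 * t))
#' tidy(fit)
#' @export
fit_single_exponential <- function(times, values, t0 = min(times)) {
  if (length(times) < 3) stop("need at least 3 recovery time points")
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(values < 0)) stop("values must be nonnegative")
  tt <- times - t0
  if (all(values == 0)) stop("all values are zero: nothing to fit")

  # log-linear initial guess on the strictly positive points
  pos <- values > 0
  if (sum(pos) >= 2 && stats::sd(tt[pos]) > 0) {
    co <- unname(stats::coef(stats::lm(log(values[pos]) ~ tt[pos])))
    k0 <- max(-co[2], 1e-6)
    y00 <- exp(co[1])
  } else {
    k0 <- 0.1
    y00 <- max(values)
  }
  res_fn <- function(par) par["y0"] * exp(-par["k"] * tt) - values
  fit <- minpack.lm::nls.lm(
    par = c(y0 = y00, k = k0), fn = res_fn,
    lower = c(y0 = 0, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!lm_converged(fit, values)) {
    stop("single-exponential fit did not converge (info = ", fit$info,
         "); initial guess was y0 = ", signif(y00, 4), ", k = ", signif(k0, 4))
  }
  par <- fit$par
  boundary <- par["k"] < 1e-8
  if (boundary) {
    warning("decay rate collapsed to the k = 0 boundary (constant series?)")
  }
  fitted <- par["y0"] * exp(-par["k"] * tt)
  new_kinfit(
    model = "single_exp",
    rates = c(k = unname(par["k"])),
    amplitudes = c(y0 = unname(par["y0"])),
    observed = values, fitted = unname(fitted),
    boundary = boundary
  )
}

#' Closed-form consecutive first-order (Bateman) time courses
#'
#' For the epoxidation chain Zx -> Ax -> Vx with rates `kz`, `ka`:
#' `Zx(t) = z0 exp(-kz t)` and
#' `Ax(t) = a0 exp(-ka t) + z0 kz / (ka - kz) * (exp(-kz t) - exp(-ka t))`,
#' with the `kz = ka` degeneracy handled by its analytic limit
#' `a0 exp(-k t) + z0 k t exp(-k t)`. `Vx` follows by mass balance.
#'
#' @param t Times (min) since recovery start.
#' @param kz,ka Rate constants (min-1).
#' @param z0,a0 Initial amplitudes.
#' @param tol Relative rate difference below which the equal-rate limit
#'   branch is used.
#' @return List with numeric vectors `zx` and `ax`.
#' @export
bateman <- function(t, kz, ka, z0, a0 = 0, tol = 1e-8) {
  zx <- z0 * exp(-kz * t)
  ax <- if (abs(kz - ka) <= tol * max(kz, ka, 1e-300)) {
    k <- (kz + ka) / 2
    a0 * exp(-k * t) + z0 * k * t * exp(-k * t)
  } else {
    a0 * exp(-ka * t) + z0 * kz / (ka - kz) * (exp(-kz * t) - exp(-ka * t))
  }
  list(zx = zx, ax = ax)
}

#' Fit the consecutive Zx -> Ax -> Vx epoxidation chain
#'
#' Joint least squares of the Bateman closed form (see [bateman()]) on the
#' zeaxanthin and antheraxanthin pool fractions over the recovery window,
#' over parameters `(kz, ka, z0, a0)`. Initialization takes `kz` from a
#' log-linear fit of the Zx decay and `ka` from a conditional scan.
#'
#' @param times Recovery times (min); at least 4 points.
#' @param zx_frac,ax_frac Pool fractions of Zx and Ax.
#' @param t0 Recovery start; default `min(times)`.
#' @return An `xq_kinfit` with `model = "consecutive"`, rates `kz`, `ka` and
#'   amplitudes `z0`, `a0`.
#' @examples
#' t <- c(0, 1, 3, 5, 7.5, 10, 15, 30)
#' b <- bateman(t, 0.165, 0.055, z0 = 0.8)
#' tidy(fit_consecutive(t, b$zx, b$ax))
#' @export
fit_consecutive <- function(times, zx_frac, ax_frac, t0 = min(times)) {
  if (length(times) < 4) stop("need at least 4 recovery time points")
  if (length(zx_frac) != length(times) || length(ax_frac) != length(times)) {
    stop("times, zx_frac and ax_frac must have equal length")
  }
  if (all(zx_frac == 0)) stop("all Zx fractions are zero: nothing to fit")
  tt <- times - t0

  pos <- zx_frac > 0
  if (sum(pos) >= 2 && stats::sd(tt[pos]) > 0) {
    co <- unname(stats::coef(stats::lm(log(zx_frac[pos]) ~ tt[pos])))
    kz0 <- max(-co[2], 1e-4)
    z00 <- exp(co[1])
  } else {
    kz0 <- 0.1
    z00 <- max(zx_frac)
  }
  # conditional scan for ka given the kz guess
  ka_grid <- kz0 * c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 3)
  a00 <- max(ax_frac[1], 0)
  sse <- vapply(ka_grid, function(ka) {
    m <- bateman(tt, kz0, ka, z00, a00)
    sum((m$zx - zx_frac)^2 + (m$ax - ax_frac)^2)
  }, numeric(1))
  ka0 <- ka_grid[which.min(sse)]

  res_fn <- function(par) {
    m <- bateman(tt, par["kz"], par["ka"], par["z0"], par["a0"])
    c(m$zx - zx_frac, m$ax - ax_frac)
  }
  fit <- minpack.lm::nls.lm(
    par = c(kz = kz0, ka = ka0, z0 = z00, a0 = a00), fn = res_fn,
    lower = c(kz = 0, ka = 0, z0 = 0, a0 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!lm_converged(fit, c(zx_frac, ax_frac))) {
    stop("consecutive-chain fit did not converge (info = ", fit$info,
         "); initial guess was kz = ", signif(kz0, 4), ", ka = ",
         signif(ka0, 4))
  }
  par <- fit$par
  m <- bateman(tt, par["kz"], par["ka"], par["z0"], par["a0"])
  new_kinfit(
    model = "consecutive",
    rates = c(kz = unname(par["kz"]), ka = unname(par["ka"])),
    amplitudes = c(z0 = unname(par["z0"]), a0 = unname(par["a0"])),
    observed = c(zx_frac, ax_frac), fitted = c(m$zx, m$ax),
    boundary = any(par[c("kz", "ka")] < 1e-8)
  )
}

# Levenberg-Marquardt termination codes 1-4 are all convergence criteria
# (ftol/xtol/both/gtol); runs that exhaust evaluations at an essentially
# perfect fit (residual norm at numerical noise) are accepted too.
lm_converged <- function(fit, observed) {
  if (fit$info %in% 1:4) return(TRUE)
  sqrt(fit$deviance) <= 1e-8 * max(1, sqrt(sum(observed^2)))
}

new_kinfit <- function(model, rates, amplitudes, observed, fitted, boundary) {
  resid <- observed - fitted
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(
    list(model = model, rates = rates, amplitudes = amplitudes,
         r_squared = r2, residuals = resid, fitted = fitted,
         boundary = boundary),
    class = "xq_kinfit"
  )
}

#' @export
print.xq_kinfit <- function(x, ...) {
  cat("<", x$model, " kinetic fit>\n", sep = "")
  cat("  rates (min-1): ",
      paste(names(x$rates), signif(x$rates, 4), sep = " = ", collapse = ", "),
      "\n  amplitudes: ",
      paste(names(x$amplitudes), signif(x$amplitudes, 4), sep = " = ",
            collapse = ", "),
      "\n  r-squared: ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.xq_kinfit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$rates), names(x$amplitudes)),
    estimate = c(unname(x$rates), unname(x$amplitudes))
  )
}

#' @export
glance.xq_kinfit <- function(x, ...) {
  tibble::tibble(model = x$model, r_squared = x$r_squared,
                 boundary = x$boundary, n = length(x$residuals))
}

#' Time of the transient antheraxanthin maximum
#'
#' For the chain Zx -> Ax -> Vx starting with no Ax, the Ax transient peaks
#' at `t = ln(kz/ka) / (kz - ka)`, with limit `1/kz` as the two rates
#' coincide.
#'
#' @param kz,ka Positive rate constants (min-1).
#' @param tol Relative difference below which the limit branch is used.
#' @return Peak time in minutes.
#' @examples
#' ax_peak_time(0.165, 0.055) # about 10 min
#' @export
ax_peak_time <- function(kz, ka, tol = 1e-8) {
  if (any(c(kz, ka) <= 0)) stop("rate constants must be > 0")
  if (abs(kz - ka) <= tol * max(kz, ka)) return(2 / (kz + ka))
  log(kz / ka) / (kz - ka)
}

#' Per-replicate recovery kinetics for a whole dataset
#'
#' Fits, for each strain x replicate and using LL recovery points only
#' (HL-induction samples are excluded): the qE relaxation rate `R0`
#' (single exponential, when a quenching table is supplied), the Dt -> Dd
#' epoxidation rate `kT` (single exponential on the Dt pool fraction), and
#' the consecutive Zx -> Ax -> Vx rates `kZ`, `kA` (Bateman fit on the Zx
#' and Ax pool fractions). The sample taken at the HL -> LL transition is
#' the recovery's t = 0 point.
#'
#' @param pigments Replicate-level pigment table (`strain`, `replicate`,
#'   `time_min`, pigment columns).
#' @param quenching Optional output of [compute_quenching()] (adds `R0`).
#' @param recovery_start Minute of the HL -> LL transition (default 360).
#' @return Tibble with columns `strain`, `replicate`, `parameter`
#'   (`R0`/`kT`/`kZ`/`kA`), `estimate`, `r_squared`.
#' @examples
#' ds <- generate_dataset(scenario_params(seed = 2, cv_pigment = 0,
#'                                        cv_fluor = 0, n_replicates = 1),
#'                        genotypes = "wt")
#' fit_recovery_kinetics(ds$pigments, compute_quenching(ds$fluorescence))
#' @export
fit_recovery_kinetics <- function(pigments, quenching = NULL,
                                  recovery_start = 360) {
  rec <- dplyr::filter(tibble::as_tibble(pigments),
                       .data$time_min >= recovery_start - 1e-9)
  groups <- dplyr::distinct(rec, .data$strain, .data$replicate)
  out <- purrr::pmap(groups, function(strain, replicate) {
    g <- rec[rec$strain == strain & rec$replicate == replicate, ]
    g <- g[order(g$time_min), ]
    rows <- list()
    f_dd <- try_fit(function() {
      gd <- normalize_to_pool(g, "dd")
      fit_single_exponential(gd$time_min, gd$dt_frac, t0 = recovery_start)
    })
    rows$kT <- f_dd
    f_vx <- try_fit(function() {
      gv <- normalize_to_pool(g, "vx")
      fit_consecutive(gv$time_min, gv$zx_frac, gv$ax_frac,
                      t0 = recovery_start)
    })
    rows$vx <- f_vx
    pick <- function(fit, field, nm = NULL) {
      if (is.null(fit)) return(NA_real_)
      v <- if (is.null(nm)) fit[[field]] else fit[[field]][[nm]]
      if (is.null(v)) NA_real_ else unname(v)
    }
    res <- tibble::tibble(
      strain = strain, replicate = replicate,
      parameter = c("kT", "kZ", "kA"),
      estimate = c(pick(f_dd, "rates", "k"),
                   pick(f_vx, "rates", "kz"),
                   pick(f_vx, "rates", "ka")),
      r_squared = c(pick(f_dd, "r_squared"),
                    pick(f_vx, "r_squared"),
                    pick(f_vx, "r_squared"))
    )
    if (!is.null(quenching)) {
      q <- quenching[quenching$strain == strain &
                       quenching$replicate == replicate &
                       quenching$time_min >= recovery_start - 1e-9, ]
      q <- q[order(q$time_min), ]
      f_qe <- try_fit(function() {
        fit_single_exponential(q$time_min, pmax(q$qe, 0),
                               t0 = recovery_start)
      })
      res <- dplyr::bind_rows(
        tibble::tibble(
          strain = strain, replicate = replicate, parameter = "R0",
          estimate = if (is.null(f_qe)) NA_real_ else f_qe$rates["k"],
          r_squared = if (is.null(f_qe)) NA_real_ else f_qe$r_squared
        ),
        res
      )
    }
    res
  })
  dplyr::bind_rows(out)
}

try_fit <- function(f) {
  tryCatch(suppressWarnings(f()), error = function(e) NULL)
}

#' Summarize and contrast fitted rates across strains
#'
#' Per strain and parameter: mean and SD of the per-replicate estimates plus
#' a bootstrap (replicate-resampled) percentile interval; and, against the
#' reference strain, the difference of means. Strains fitted with a single
#' replicate get no interval (with a warning); parameters missing for a
#' strain are kept as flagged `NA` rows.
#'
#' @param rates Output of [fit_recovery_kinetics()].
#' @param reference Reference strain (default `"wt"`).
#' @param n_boot Bootstrap resamples (default 999).
#' @param conf Interval coverage (default 0.95).
#' @param seed Seed for the bootstrap stream.
#' @return Tibble with `strain`, `parameter`, `n`, `estimate` (mean), `sd`,
#'   `conf_low`, `conf_high`, `diff_vs_ref`.
#' @export
compare_rates <- function(rates, reference = "wt", n_boot = 999,
                          conf = 0.95, seed = 1L) {
  if (dplyr::n_distinct(rates$strain) < 2) {
    stop("need fits for at least 2 strains to compare")
  }
  set.seed(seed)
  alpha <- (1 - conf) / 2
  summ <- rates |>
    dplyr::group_by(.data$strain, .data$parameter) |>
    dplyr::summarise(
      n = sum(!is.na(.data$estimate)),
      estimate = mean(.data$estimate[!is.na(.data$estimate)]),
      sd = stats::sd(.data$estimate[!is.na(.data$estimate)]),
      .groups = "drop"
    )
  summ$estimate[summ$n == 0] <- NA_real_
  ci <- purrr::pmap(summ, function(strain, parameter, n, estimate, sd) {
    est <- rates$estimate[rates$strain == strain &
                            rates$parameter == parameter]
    est <- est[!is.na(est)]
    if (length(est) < 2) {
      if (length(est) == 1) {
        warning("single replicate for ", strain, "/", parameter,
                ": bootstrap interval suppressed")
      }
      return(c(NA_real_, NA_real_))
    }
    bm <- vapply(seq_len(n_boot), function(i) {
      mean(sample(est, replace = TRUE))
    }, numeric(1))
    stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
  })
  summ$conf_low <- vapply(ci, `[`, numeric(1), 1)
  summ$conf_high <- vapply(ci, `[`, numeric(1), 2)
  ref <- summ[summ$strain == reference, c("parameter", "estimate")]
  names(ref)[2] <- "ref_estimate"
  summ <- dplyr::left_join(summ, ref, by = "parameter")
  summ$diff_vs_ref <- summ$estimate - summ$ref_estimate
  summ$ref_estimate <- NULL
  summ
}
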