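#' Simulate xanthophyll-cycle pigment dynamics for one genotype
#'
#' Integrates the light-gated mass-action model of the diadinoxanthin (Dd)
#' and violaxanthin (Vx) cycles over a regime. State variables are the
#' pigment:chlorophyll a ratios (dd, dt, vx, ax, zx) plus a constant
#' fucoxanthin pool (fx). Fluxes:
#'
#' * VDE (HL only, `vde_active`): Dd->Dt at `v_dd`; Vx->Ax and Ax->Zx at
#'   `v_vx`.
#' * ZEP3 (LL only, `zep3_active`, blocked in darkness when
#'   `dark_blocks_zep3`): Dt->Dd at `k3_dt`, Zx->Ax at `k3_zx`, Ax->Vx at
#'   `k3_ax`.
#' * ZEP2 (all irradiances, `zep2_active`): Dt->Dd, Zx->Ax, Ax->Vx at `k2`.
#' * De novo synthesis (HL only): a flux of `s_denovo` enters the pool from
#'   beta-carotene through the biosynthetic arm
#'   (nascent Zx -ZEP2-> Vx -Dd synthase-> Dd). The arm's transit time
#'   (~1/`kd`) is negligible against the HL block, so the flux is delivered
#'   at the arm's terminus: into Dd when ZEP2 is active, into free Zx when
#'   ZEP2 is knocked out and the arm is severed. The standing thylakoid
#'   pools are not substrates of the arm, which is what keeps each cycle
#'   closed during LL recovery.
#'
#' Gating is a hard 0/1 switch at `hl_threshold`; because gates change only
#' at segment boundaries the system is integrated segment by segment with a
#' stiff-capable adaptive solver (relative tolerance 1e-8).
#'
#' @param params An [scenario_params()] object.
#' @param genotype An [genotype()] object or genotype name.
#' @param regime An [light_regime()] object.
#' @param initial Named numeric initial state `c(dd, dt, vx, ax, zx, fx)`;
#'   defaults to [initial_pigments()] for the genotype.
#' @param times Absolute regime minutes at which to report the trajectory.
#'   Default: a dense 1-min grid over the day-5 analysis window (final HL
#'   block plus 30 min recovery) united with [sampling_grid()].
#' @param window_start Absolute minute of the 0 h sample; defaults to the
#'   start of the final HL block. Reported `time_min` is relative to it.
#'
#' @return Tibble with columns `strain`, `time_min` (minutes since
#'   `window_start`), `phase`, `dd`, `dt`, `vx`, `ax`, `zx`, `fx`.
#' @examples
#' sim <- simulate_pigments(scenario_params(), genotype("wt"), light_regime())
#' sim[sim$time_min %in% sampling_grid(), ]
#' @export
simulate_pigments <- function(params, genotype, regime,
                              initial = NULL, times = NULL,
                              window_start = NULL) {
  validate_params(params)
  if (!inherits(genotype, "xq_genotype")) genotype <- genotype(genotype)
  if (is.null(window_start)) window_start <- analysis_window_start(regime)
  if (is.null(times)) {
    times <- window_start + sort(unique(c(seq(0, 390, by = 1), sampling_grid())))
  }
  times <- sort(unique(times))
  if (is.null(initial)) initial <- initial_pigments(genotype)
  state <- initial[c("dd", "dt", "vx", "ax", "zx", "fx")]
  if (anyNA(state)) stop("initial state must name dd, dt, vx, ax, zx, fx")
  if (any(state < 0)) stop("initial pigment state must be nonnegative")

  traj <- integrate_segments(params, genotype, regime, state, times)
  tibble::tibble(
    strain = genotype$name,
    time_min = times - window_start,
    phase = phase_at(regime, times, side = "left"),
    dd = traj[, "dd"], dt = traj[, "dt"], vx = traj[, "vx"],
    ax = traj[, "ax"], zx = traj[, "zx"], fx = traj[, "fx"]
  )
}

# Right-hand side coefficients for one regime segment. Returns list(A, b)
# of the linear system dx/dt = A x + b on state (dd, dt, vx, ax, zx, fx).
segment_system <- function(params, genotype, irradiance) {
  p <- params
  hl <- irradiance >= p$hl_threshold
  dark <- irradiance <= 0
  vde_on <- genotype$vde_active == 1 && hl
  zep3_on <- genotype$zep3_active == 1 && !hl &&
    !(dark && isTRUE(p$dark_blocks_zep3))
  zep2_on <- genotype$zep2_active == 1
  r_dt <- (if (zep3_on) p$k3_dt else 0) + (if (zep2_on) p$k2 else 0)
  r_zx <- (if (zep3_on) p$k3_zx else 0) + (if (zep2_on) p$k2 else 0)
  r_ax <- (if (zep3_on) p$k3_ax else 0) + (if (zep2_on) p$k2 else 0)
  v_dd <- if (vde_on) p$v_dd else 0
  v_vx <- if (vde_on) p$v_vx else 0

  A <- matrix(0, 6, 6, dimnames = list(PIGS, PIGS))
  A["dd", "dd"] <- -v_dd;          A["dd", "dt"] <- r_dt
  A["dt", "dd"] <- v_dd;           A["dt", "dt"] <- -r_dt
  A["vx", "vx"] <- -v_vx;          A["vx", "ax"] <- r_ax
  A["ax", "vx"] <- v_vx;           A["ax", "zx"] <- r_zx
  A["ax", "ax"] <- -(r_ax + v_vx)
  A["zx", "ax"] <- v_vx;           A["zx", "zx"] <- -r_zx

  b <- stats::setNames(numeric(6), PIGS)
  if (hl && p$s_denovo > 0) {
    target <- if (genotype$zep2_active == 1) "dd" else "zx"
    b[target] <- p$s_denovo
  }
  list(A = A, b = b)
}

PIGS <- c("dd", "dt", "vx", "ax", "zx", "fx")

integrate_segments <- function(params, genotype, regime, state, times) {
  starts <- regime$start_min
  ends <- starts + regime$duration_min
  if (times[1] < starts[1] - 1e-9 || times[length(times)] > max(ends) + 1e-9) {
    stop("requested times fall outside the regime")
  }
  out <- matrix(NA_real_, nrow = length(times), ncol = 6,
                dimnames = list(NULL, PIGS))
  t_cur <- times[1]
  out[1, ] <- state
  # march over the segments intersecting [times[1], max(times)]
  for (i in seq_len(nrow(regime))) {
    seg_a <- max(starts[i], t_cur)
    seg_b <- ends[i]
    if (seg_b <= t_cur + 1e-12) next
    if (seg_a > times[length(times)]) break
    t_stop <- min(seg_b, times[length(times)])
    inner <- times[times > seg_a + 1e-12 & times <= t_stop + 1e-12]
    tt <- sort(unique(c(seg_a, inner, t_stop)))
    sys <- segment_system(params, genotype, regime$irradiance[i])
    sol <- deSolve::lsoda(
      y = state, times = tt,
      func = function(t, y, parms) list(parms$A %*% y + parms$b),
      parms = sys, rtol = 1e-8, atol = 1e-12
    )
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed in segment ", i, " (t = ", seg_a, "..", t_stop,
           " min); istate = ", attr(sol, "istate")[1])
    }
    keep <- match(round(inner, 9), round(sol[, "time"], 9))
    out[match(round(inner, 9), round(times, 9)), ] <-
      as.matrix(sol[keep, PIGS, drop = FALSE])
    state <- as.numeric(sol[nrow(sol), PIGS])
    names(state) <- PIGS
    t_cur <- t_stop
    if (t_cur >= times[length(times)] - 1e-12) break
  }
  # mass-action dynamics are nonnegative up to solver round-off
  out[out < 0 & out > -1e-12] <- 0
  out
}

#' Cumulative high-light exposure and photoinhibition
#'
#' qI rises linearly with accumulated HL exposure to `qi_max` over
#' `qi_rise_min` minutes and does not relax on the recovery timescale
#' (its relaxation time is taken as much longer than 30 min).
#'
#' @param params An `xq_params`.
#' @param regime An `xq_regime`.
#' @param time_abs Absolute regime minutes.
#' @param window_start Minute from which HL exposure is accumulated.
#' @return Numeric vector of qI values.
#' @export
qi_at <- function(params, regime, time_abs, window_start) {
  starts <- regime$start_min
  ends <- starts + regime$duration_min
  hl <- regime$phase == "HL"
  sapply(time_abs, function(t) {
    a <- pmax(starts, window_start)
    b <- pmin(ends, t)
    expo <- sum(pmax(0, b - a)[hl])
    params$qi_max * min(1, expo / params$qi_rise_min)
  })
}

#' Emulate maximum-fluorescence traces from pigment trajectories
#'
#' Couples the quenching-active pigment pool Q = Dt + Zx + `w_ax` * Ax to an
#' emitted maximum fluorescence via
#' `NPQ_total(t) = gamma * Q(t) + qI(t)` and
#' `F'm(t) = fm_ref / (1 + NPQ_total(t))`. The Fm reference is the 0 h LL
#' sample and the F''m reference the end-of-recovery sample; both must be
#' present.
#'
#' @param pigments Pigment tibble as returned by [simulate_pigments()]
#'   (one or more strains; `time_min` relative to the 0 h sample).
#' @param params An [scenario_params()] object.
#' @param regime The regime used for the pigment simulation (needed for qI).
#' @param fm_time,recovery_time Times (min) of the Fm and F''m references
#'   (defaults 0 and 390).
#' @return Tibble `strain`, `time_min`, `fm_prime`, with attributes
#'   `fm_time` and `recovery_time`.
#' @export
simulate_fluorescence <- function(pigments, params, regime,
                                  fm_time = 0, recovery_time = 390) {
  validate_params(params)
  for (tm in c(fm_time, recovery_time)) {
    ok <- stats::aggregate(pigments$time_min,
                           by = list(strain = pigments$strain),
                           FUN = function(v) any(abs(v - tm) < 1e-9))
    if (!all(ok$x)) {
      stop("pigment table lacks the ", tm,
           " min reference point for strain(s): ",
           paste(ok$strain[!ok$x], collapse = ", "))
    }
  }
  window_start <- analysis_window_start(regime)
  q <- pigments$dt + pigments$zx + params$w_ax * pigments$ax
  qi <- qi_at(params, regime, pigments$time_min + window_start, window_start)
  npq_total <- params$gamma * q + qi
  out <- tibble::tibble(
    strain = pigments$strain,
    time_min = pigments$time_min,
    fm_prime = params$fm_ref / (1 + npq_total)
  )
  attr(out, "fm_time") <- fm_time
  attr(out, "recovery_time") <- recovery_time
  out
}

#' Generate a replicate-level synthetic dataset
#'
#' Runs the noise-free simulator for every genotype on the day-5 sampling
#' grid, emulates the fluorescence trace, and adds multiplicative Gaussian
#' replicate noise (coefficient of variation `cv_pigment` / `cv_fluor`,
#' truncated at zero) to produce `n_replicates` biological replicates per
#' strain. A single seeded RNG stream makes the output reproducible:
#' identical seeds give identical tables.
#'
#' @param params An [scenario_params()] object (holds noise CVs,
#'   `n_replicates` and `seed`).
#' @param genotypes Character vector or list of [genotype()] objects
#'   (default: wt, vde KO, zep2 KO, zep3 KO).
#' @param regime An [light_regime()] (default the 5-day standard regime).
#' @return List with tibbles `pigments` (strain, replicate, time_min, phase,
#'   dd..fx) and `fluorescence` (strain, replicate, time_min, fm_prime).
#' @examples
#' ds <- generate_dataset(scenario_params(seed = 7))
#' dplyr::count(ds$pigments, strain)
#' @export
generate_dataset <- function(params = scenario_params(),
                             genotypes = c("wt", "vde_ko", "zep2_ko", "zep3_ko"),
                             regime = light_regime()) {
  validate_params(params)
  if (params$n_replicates < 1) stop("n_replicates must be >= 1")
  genos <- lapply(genotypes, function(g) {
    if (inherits(g, "xq_genotype")) g else genotype(g)
  })
  window_start <- analysis_window_start(regime)
  times <- window_start + sampling_grid()

  set.seed(as.integer(params$seed))
  pig_list <- list()
  flu_list <- list()
  for (g in genos) {
    mean_pig <- simulate_pigments(params, g, regime, times = times,
                                  window_start = window_start)
    mean_flu <- simulate_fluorescence(mean_pig, params, regime)
    for (r in seq_len(params$n_replicates)) {
      pg <- mean_pig
      vals <- as.matrix(pg[PIGS])
      noise <- matrix(stats::rnorm(length(vals), mean = 1,
                                   sd = params$cv_pigment),
                      nrow = nrow(vals))
      vals <- pmax(vals * noise, 0)
      pg[PIGS] <- as.data.frame(vals)
      pg <- tibble::add_column(pg, replicate = r, .after = "strain")
      pig_list[[length(pig_list) + 1]] <- pg

      fl <- mean_flu
      fl$fm_prime <- pmax(
        fl$fm_prime * stats::rnorm(nrow(fl), 1, params$cv_fluor),
        .Machine$double.eps
      )
      fl <- tibble::add_column(fl, replicate = r, .after = "strain")
      flu_list[[length(flu_list) + 1]] <- fl
    }
  }
  list(
    pigments = dplyr::bind_rows(pig_list),
    fluorescence = dplyr::bind_rows(flu_list)
  )
}
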