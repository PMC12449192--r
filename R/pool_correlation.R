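#' Candidate de-epoxidized pigment pool formulas
#'
#' The five candidate definitions of the quenching-active pigment pool
#' compared against qE: Dt alone, Zx alone, Dt + Zx, Dt + Zx + 1/2 Ax, and
#' Dt + Zx + Ax. Each is a weighted sum of the de-epoxidized (and
#' half-de-epoxidized) pigments.
#'
#' @param w_ax Optional extra weight to include as a `custom_w` formula.
#' @return Tibble with columns `id`, `w_dt`, `w_zx`, `w_ax`.
#' @examples
#' pool_formulas()
#' @export
pool_formulas <- function(w_ax = NULL) {
  f <- tibble::tribble(
    ~id,              ~w_dt, ~w_zx, ~w_ax,
    "dt",             1,     0,     0,
    "zx",             0,     1,     0,
    "dt_zx",          1,     1,     0,
    "dt_zx_half_ax",  1,     1,     0.5,
    "dt_zx_ax",       1,     1,     1
  )
  if (!is.null(w_ax)) {
    stopifnot(w_ax >= 0, w_ax <= 1)
    f <- dplyr::bind_rows(
      f, tibble::tibble(id = "custom_w", w_dt = 1, w_zx = 1, w_ax = w_ax))
  }
  f
}

#' End-of-recovery pool deltas for each candidate formula
#'
#' For every candidate pool formula computes
#' `delta_pool(t) = sum(w_p * (p(t) - p(390 min)))` per strain x replicate.
#' The 0 h HL-induction sample is excluded; the 6 h HL sample (the recovery
#' starting point) is included by default since both endpoints of each
#' recovery trajectory carry information about the quenching-pool range.
#'
#' @param pigments Replicate-level pigment table.
#' @param formulas Tibble as from [pool_formulas()].
#' @param recovery_time End-of-recovery minute (default 390).
#' @param recovery_start HL -> LL transition minute (default 360).
#' @param include_hl_endpoint Keep the sample taken at `recovery_start`
#'   (default TRUE).
#' @return Long tibble `strain`, `replicate`, `time_min`, `formula`,
#'   `delta_pool`.
#' @export
build_delta_pools <- function(pigments, formulas = pool_formulas(),
                              recovery_time = 390, recovery_start = 360,
                              include_hl_endpoint = TRUE) {
  dp <- delta_pigment(pigments, cols = c("dt", "ax", "zx"),
                      recovery_time = recovery_time)
  lo <- if (include_hl_endpoint) recovery_start - 1e-9 else recovery_start + 1e-9
  dp <- dplyr::filter(dp, .data$time_min > lo)
  out <- purrr::pmap(formulas, function(id, w_dt, w_zx, w_ax) {
    tibble::tibble(
      strain = dp$strain, replicate = dp$replicate, time_min = dp$time_min,
      formula = id,
      delta_pool = w_dt * dp$delta_dt + w_zx * dp$delta_zx + w_ax * dp$delta_ax
    )
  })
  dplyr::bind_rows(out)
}

#' Linear models of qE against each candidate pool
#'
#' Ordinary least squares with intercept of `qe ~ delta_pool`, per strain
#' and for all strains pooled (`group = "combined"`), for every candidate
#' formula. Each point is one replicate x time measurement. Results are
#' ordered by decreasing combined r-squared.
#'
#' @param quenching Output of [compute_quenching()] (or any table with
#'   `strain`, `replicate`, `time_min`, `qe`).
#' @param delta_pools Output of [build_delta_pools()].
#' @return Tibble of class `xq_pool_models`: `formula`, `group` (strain or
#'   `"combined"`), `slope`, `intercept`, `r_squared`, `n_points`.
#' @examples
#' ds <- generate_dataset(scenario_params(seed = 5),
#'                        genotypes = c("wt", "zep2_ko"))
#' qe <- compute_quenching(ds$fluorescence)
#' fits <- fit_pool_models(qe, build_delta_pools(ds$pigments))
#' select_best_pool(fits)
#' @export
fit_pool_models <- function(quenching, delta_pools) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(quenching), "strain", "replicate",
                  "time_min", "qe"),
    tibble::as_tibble(delta_pools),
    by = c("strain", "replicate", "time_min")
  )
  if (nrow(joined) == 0) stop("no paired qE / delta-pool measurements")
  one_fit <- function(d, group) {
    if (nrow(d) < 3) stop("fewer than 3 points for group '", group, "'")
    m <- stats::lm(qe ~ delta_pool, data = d)
    tibble::tibble(
      group = group,
      slope = unname(stats::coef(m)[2]),
      intercept = unname(stats::coef(m)[1]),
      r_squared = summary(m)$r.squared,
      n_points = nrow(d)
    )
  }
  res <- joined |>
    dplyr::group_by(.data$formula) |>
    dplyr::group_modify(function(d, key) {
      per_strain <- d |>
        dplyr::group_by(.data$strain) |>
        dplyr::group_modify(~ one_fit(.x, .y$strain)) |>
        dplyr::ungroup() |>
        dplyr::select(-"strain")
      dplyr::bind_rows(per_strain, one_fit(d, "combined"))
    }) |>
    dplyr::ungroup()
  comb <- res[res$group == "combined", c("formula", "r_squared")]
  res$formula <- factor(res$formula,
                        levels = comb$formula[order(-comb$r_squared)])
  res <- res[order(res$formula), ]
  res$formula <- as.character(res$formula)
  class(res) <- c("xq_pool_models", class(res))
  res
}

#' Select the candidate pool that best explains qE
#'
#' Picks the formula with the maximal combined r-squared; exact ties are
#' broken toward the formula with fewer (then smaller-weighted) terms, i.e.
#' in the order dt, zx, dt_zx, dt_zx_half_ax, dt_zx_ax.
#'
#' @param results Output of [fit_pool_models()].
#' @return The winning formula id (character scalar), with the combined
#'   r-squared as attribute `r_squared`.
#' @export
select_best_pool <- function(results) {
  comb <- results[results$group == "combined", ]
  if (nrow(comb) == 0) stop("no combined fits in input")
  simplicity <- c(dt = 1, zx = 2, dt_zx = 3, dt_zx_half_ax = 4,
                  dt_zx_ax = 5, custom_w = 6)
  ord <- order(-comb$r_squared,
               simplicity[match(comb$formula, names(simplicity))])
  best <- comb[ord[1], ]
  structure(best$formula, r_squared = best$r_squared)
}

#' Continuous antheraxanthin-weight estimate
#'
#' Generalizes the discrete five-formula comparison: finds the weight
#' `w in [0, 1]` maximizing the combined r-squared of
#' `qe ~ delta(Dt + Zx + w * Ax)`, and returns the r-squared profile over a
#' grid of weights. If the Ax delta carries no variation the weight is
#' unidentifiable and flagged.
#'
#' @param quenching Output of [compute_quenching()].
#' @param pigments Replicate-level pigment table.
#' @param grid Weights at which to evaluate the profile (default
#'   `seq(0, 1, 0.01)`).
#' @inheritParams build_delta_pools
#' @return List with `w` (the optimum), `r_squared` (at the optimum),
#'   `profile` (tibble `w`, `r_squared`), `identifiable` (logical).
#' @export
estimate_ax_weight <- function(quenching, pigments, grid = seq(0, 1, 0.01),
                               recovery_time = 390, recovery_start = 360,
                               include_hl_endpoint = TRUE) {
  dp <- delta_pigment(pigments, cols = c("dt", "ax", "zx"),
                      recovery_time = recovery_time)
  lo <- if (include_hl_endpoint) recovery_start - 1e-9 else recovery_start + 1e-9
  dp <- dplyr::filter(dp, .data$time_min > lo)
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(quenching), "strain", "replicate",
                  "time_min", "qe"),
    dplyr::select(dp, "strain", "replicate", "time_min",
                  "delta_dt", "delta_zx", "delta_ax"),
    by = c("strain", "replicate", "time_min")
  )
  if (nrow(joined) < 3) stop("too few paired points")
  if (stats::var(joined$delta_ax) < 1e-20) {
    return(list(w = NA_real_, r_squared = NA_real_,
                profile = tibble::tibble(w = grid, r_squared = NA_real_),
                identifiable = FALSE))
  }
  r2_at <- function(w) {
    x <- joined$delta_dt + joined$delta_zx + w * joined$delta_ax
    summary(stats::lm(joined$qe ~ x))$r.squared
  }
  profile <- tibble::tibble(w = grid,
                            r_squared = vapply(grid, r2_at, numeric(1)))
  opt <- stats::optimize(r2_at, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-6)
  cand_w <- c(opt$maximum, 0, 1)
  cand_r <- c(opt$objective, r2_at(0), r2_at(1))
  best <- which.max(cand_r)
  list(w = cand_w[best], r_squared = cand_r[best], profile = profile,
       identifiable = TRUE)
}
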