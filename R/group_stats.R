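#' Per-time-point Welch tests of a mutant against the reference strain
#'
#' For one metric (a pigment, pool or quenching column) and one mutant
#' strain, runs a Welch two-sample t-test against the reference at every
#' time point and applies the Holm step-down correction within the declared
#' family. The default family is all time points of one metric x one mutant
#' contrast, mirroring per-panel significance marks; pass a `family` factor
#' to redefine it. Welch (unequal variance) is used deliberately: with n = 3
#' replicates and heteroscedastic pigment pools the pooled-variance t is not
#' defensible.
#'
#' When both groups have zero variance the t statistic is undefined; equal
#' means then give p = 1 and unequal means a flagged zero p-value
#' (`degenerate = TRUE`).
#'
#' @param data Replicate-level table with `strain`, `replicate`, `time_min`
#'   and the metric column.
#' @param metric Name of the value column to test.
#' @param mutant Mutant strain name.
#' @param reference Reference strain (default `"wt"`).
#' @param alpha_levels Significance thresholds reported as indicator
#'   columns (defaults 0.05 and 0.005).
#' @return Tibble with `metric`, `mutant`, `time_min`, `t_statistic`, `df`,
#'   `p_raw`, `p_holm`, `significant_05`, `significant_005`, `degenerate`.
#' @examples
#' ds <- generate_dataset(scenario_params(seed = 11),
#'                        genotypes = c("wt", "zep3_ko"))
#' welch_tests(pool_sums(ds$pigments), "deepoxidized", "zep3_ko")
#' @export
welch_tests <- function(data, metric, mutant, reference = "wt",
                        alpha_levels = c(0.05, 0.005)) {
  stopifnot(metric %in% names(data))
  d <- tibble::as_tibble(data)
  d <- d[d$strain %in% c(mutant, reference), ]
  times <- sort(unique(d$time_min))
  rows <- purrr::map(times, function(tm) {
    x <- d[[metric]][d$strain == mutant & abs(d$time_min - tm) < 1e-9]
    y <- d[[metric]][d$strain == reference & abs(d$time_min - tm) < 1e-9]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      stop("need >= 2 replicates per group at t = ", tm, " min")
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(tibble::tibble(
        time_min = tm, t_statistic = NA_real_, df = NA_real_,
        p_raw = if (eq) 1 else 0, degenerate = TRUE
      ))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tibble::tibble(
      time_min = tm, t_statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_raw = tt$p.value, degenerate = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  tibble::tibble(
    metric = metric, mutant = mutant,
    out[c("time_min", "t_statistic", "df", "p_raw", "p_holm")],
    significant_05 = out$p_holm < alpha_levels[1],
    significant_005 = out$p_holm < alpha_levels[2],
    degenerate = out$degenerate
  )
}

#' Shapiro-Wilk normality screen per group
#'
#' Advisory normality check run before the t-tests; it reports the W
#' statistic and p-value per group and never gates the tests. Groups with
#' fewer than 3 observations or zero variance are skipped with a warning.
#'
#' @param data Table with the value column and grouping columns.
#' @param metric Name of the value column.
#' @param group_cols Columns defining the groups (default `strain`).
#' @return Tibble with the group columns, `n`, `W`, `p_value`, `skipped`.
#' @export
shapiro_check <- function(data, metric, group_cols = "strain") {
  stopifnot(metric %in% names(data))
  d <- tibble::as_tibble(data)
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(g, key) {
      v <- g[[metric]][!is.na(g[[metric]])]
      if (length(v) < 3 || stats::sd(v) == 0) {
        warning("group skipped in Shapiro-Wilk check (n < 3 or constant)")
        return(tibble::tibble(n = length(v), W = NA_real_,
                              p_value = NA_real_, skipped = TRUE))
      }
      sw <- stats::shapiro.test(v)
      tibble::tibble(n = length(v), W = unname(sw$statistic),
                     p_value = sw$p.value, skipped = FALSE)
    }) |>
    dplyr::ungroup()
}
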