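#' Non-photochemical quenching from maximum-fluorescence traces
#'
#' `NPQ(t) = (Fm - F'm(t)) / F'm(t)`, with Fm taken per strain x replicate
#' as the maximum fluorescence at the first LL pulse (the 0 h sample). No
#' dark-adapted reference exists anywhere in this analysis: low light is the
#' condition in which the maximum number of reaction centers are open, since
#' diatom NPQ does not relax in darkness.
#'
#' @param fluorescence Data frame with `strain`, `replicate`, `time_min`,
#'   `fm_prime`.
#' @param fm_time Time (min) of the Fm reference pulse (default 0).
#' @return Input tibble with an `npq` column appended.
#' @examples
#' tr <- data.frame(strain = "wt", replicate = 1,
#'                  time_min = c(0, 360), fm_prime = c(1, 0.25))
#' compute_npq(tr)
#' @export
compute_npq <- function(fluorescence, fm_time = 0) {
  quench_ratio(fluorescence, ref_time = fm_time, col = "npq")
}

#' Rapidly relaxing quenching (qE) from maximum-fluorescence traces
#'
#' `qE(t) = (F''m - F'm(t)) / F'm(t)`, where F''m is the maximum
#' fluorescence at the end of the 30 min recovery, taken per strain x
#' replicate. Because the slowly relaxing photoinhibition component is
#' common to F''m and F'm, it cancels and qE isolates the xanthophyll-cycle
#' driven component; qE is exactly zero at the recovery endpoint.
#'
#' @param fluorescence Data frame with `strain`, `replicate`, `time_min`,
#'   `fm_prime`.
#' @param recovery_time Time (min) of the F''m reference (default 390).
#' @return Input tibble with a `qe` column appended.
#' @export
compute_qe <- function(fluorescence, recovery_time = 390) {
  quench_ratio(fluorescence, ref_time = recovery_time, col = "qe")
}

#' NPQ and qE in one pass
#'
#' @inheritParams compute_npq
#' @inheritParams compute_qe
#' @return Tibble with both `npq` and `qe` columns.
#' @examples
#' ds <- generate_dataset(scenario_params(seed = 3), genotypes = "wt")
#' compute_quenching(ds$fluorescence)
#' @export
compute_quenching <- function(fluorescence, fm_time = 0, recovery_time = 390) {
  compute_qe(compute_npq(fluorescence, fm_time), recovery_time)
}

quench_ratio <- function(fluorescence, ref_time, col) {
  need <- c("strain", "replicate", "time_min", "fm_prime")
  miss <- setdiff(need, names(fluorescence))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(fluorescence$fm_prime <= 0)) {
    stop("fm_prime must be strictly positive")
  }
  out <- tibble::as_tibble(fluorescence) |>
    dplyr::group_by(.data$strain, .data$replicate)
  has_ref <- out |>
    dplyr::summarise(ok = any(abs(.data$time_min - ref_time) < 1e-9),
                     .groups = "drop")
  if (!all(has_ref$ok)) {
    bad <- has_ref[!has_ref$ok, ]
    stop("missing ", ref_time, " min reference pulse for ",
         paste(bad$strain, bad$replicate, sep = "/", collapse = ", "))
  }
  out <- dplyr::mutate(
    out,
    !!col := (.data$fm_prime[abs(.data$time_min - ref_time) < 1e-9][1] -
                .data$fm_prime) / .data$fm_prime
  )
  dplyr::ungroup(out)
}
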