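#' Normalize a raw pigment table to chlorophyll a molar ratios
#'
#' Applies the two preprocessing rules used throughout the analysis: any
#' chlorophyllide a is summed into chlorophyll a, and pigment contents are
#' divided by the (summed) chlorophyll a to give mol/mol ratios. Tables that
#' are already normalized (no chlorophyll columns) pass through unchanged
#' when `normalized = TRUE`.
#'
#' @param raw Data frame with pigment columns (`dd`, `dt`, `vx`, `ax`, `zx`,
#'   optionally `fx`) and, for absolute contents, `chl_a` (and optionally
#'   `chlide_a`).
#' @param normalized Set `TRUE` to declare the table already in mol/mol
#'   units; chlorophyll columns must then be absent.
#' @return Tibble with pigment columns as mol/mol ratios; chlorophyll
#'   columns are dropped.
#' @examples
#' preprocess_pigment_table(
#'   data.frame(strain = "wt", replicate = 1, time_min = 0,
#'              chl_a = 1.5, chlide_a = 0.5, dd = 0.2, dt = 0, vx = 0,
#'              ax = 0, zx = 0)
#' )
#' @export
preprocess_pigment_table <- function(raw, normalized = FALSE) {
  out <- tibble::as_tibble(raw)
  pig_cols <- intersect(c("dd", "dt", "vx", "ax", "zx", "fx"), names(out))
  if (length(pig_cols) == 0) stop("no pigment columns found")
  if (any(vapply(out[pig_cols], function(v) any(v < 0, na.rm = TRUE), TRUE))) {
    stop("pigment contents must be nonnegative")
  }
  if (normalized) {
    if (any(c("chl_a", "chlide_a") %in% names(out))) {
      stop("table declared normalized but carries chlorophyll columns")
    }
    return(out)
  }
  if (!"chl_a" %in% names(out)) {
    stop("normalization requires a 'chl_a' column (or set normalized = TRUE)")
  }
  chl <- out$chl_a
  if ("chlide_a" %in% names(out)) chl <- chl + out$chlide_a
  if (any(chl <= 0)) stop("chlorophyll a (+ chlorophyllide a) must be > 0")
  for (cc in pig_cols) out[[cc]] <- out[[cc]] / chl
  out$chl_a <- NULL
  out$chlide_a <- NULL
  out
}

#' Pigment pool sums and de-epoxidation states
#'
#' Adds the standard pool summaries to a pigment table:
#' `dd_pool = Dd + Dt`, `vx_pool = Vx + Ax + Zx`, `total` (sum of the five
#' cycle pigments), `epoxidized = Dd + Vx + Ax`, `deepoxidized = Dt + Zx`,
#' and the two de-epoxidation states `des_dd` and `des_vx` (see [des_dd()],
#' [des_vx()]). Antheraxanthin counts fully in the epoxidized pool but at
#' one half in the Vx-cycle DES; both conventions are applied exactly as
#' defined.
#'
#' @param pigments Data frame with columns `dd`, `dt`, `vx`, `ax`, `zx`.
#' @return The input tibble with the seven summary columns appended.
#' @examples
#' pool_sums(data.frame(dd = 0.01, dt = 0.02, vx = 0.03, ax = 0.04, zx = 0.05))
#' @export
pool_sums <- function(pigments) {
  need <- c("dd", "dt", "vx", "ax", "zx")
  miss <- setdiff(need, names(pigments))
  if (length(miss)) stop("missing pigment column(s): ", paste(miss, collapse = ", "))
  if (any(vapply(pigments[need], function(v) any(v < 0, na.rm = TRUE), TRUE))) {
    stop("pigment contents must be nonnegative")
  }
  out <- tibble::as_tibble(pigments)
  out |>
    dplyr::mutate(
      dd_pool = .data$dd + .data$dt,
      vx_pool = .data$vx + .data$ax + .data$zx,
      total = .data$dd_pool + .data$vx_pool,
      epoxidized = .data$dd + .data$vx + .data$ax,
      deepoxidized = .data$dt + .data$zx,
      des_dd = des_dd(.data$dd, .data$dt),
      des_vx = des_vx(.data$vx, .data$ax, .data$zx)
    )
}

#' Dd-cycle de-epoxidation state
#'
#' `DES = Dt / (Dd + Dt)`. An empty cycle pool leaves the DES undefined and
#' yields `NA` (not zero) so that downstream statistics skip it.
#'
#' @param dd,dt Diadinoxanthin and diatoxanthin ratios (vectorized).
#' @return Fraction in `[0, 1]`, or `NA` where `dd + dt == 0`.
#' @export
des_dd <- function(dd, dt) {
  if (any(dd < 0 | dt < 0, na.rm = TRUE)) stop("pigments must be nonnegative")
  pool <- dd + dt
  ifelse(pool > 0, dt / pool, NA_real_)
}

#' Vx-cycle de-epoxidation state
#'
#' `DES = (Zx + Ax/2) / (Vx + Ax + Zx)`: the mono-epoxidized antheraxanthin
#' counts at one half. Empty pools yield `NA`.
#'
#' @param vx,ax,zx Violaxanthin, antheraxanthin, zeaxanthin ratios
#'   (vectorized).
#' @return Fraction in `[0, 1]`, or `NA` where the pool is empty.
#' @export
des_vx <- function(vx, ax, zx) {
  if (any(vx < 0 | ax < 0 | zx < 0, na.rm = TRUE)) stop("pigments must be nonnegative")
  pool <- vx + ax + zx
  ifelse(pool > 0, (zx + ax / 2) / pool, NA_real_)
}

#' End-of-recovery deltas of pigments or pools
#'
#' For each strain x replicate trajectory, subtracts the value at the end of
#' the recovery phase: `delta = value(t) - value(recovery_time)`, so the
#' delta is exactly zero at the recovery endpoint and negative for pigments
#' that rise during recovery. This removes the slowly relaxing
#' (photoinhibition-associated) baseline the same way the qE convention does
#' for fluorescence.
#'
#' @param pigments Data frame with `strain`, `replicate`, `time_min` and the
#'   requested columns.
#' @param cols Character vector of columns to difference (default the five
#'   cycle pigments present).
#' @param recovery_time End-of-recovery time in minutes (default 390).
#' @return Input tibble with `delta_<col>` columns appended.
#' @export
delta_pigment <- function(pigments,
                          cols = intersect(c("dd", "dt", "vx", "ax", "zx"),
                                           names(pigments)),
                          recovery_time = 390) {
  if (!all(c("strain", "replicate", "time_min") %in% names(pigments))) {
    stop("pigment table must have strain, replicate and time_min columns")
  }
  out <- tibble::as_tibble(pigments) |>
    dplyr::group_by(.data$strain, .data$replicate)
  has_end <- out |>
    dplyr::summarise(ok = any(abs(.data$time_min - recovery_time) < 1e-9),
                     .groups = "drop")
  if (!all(has_end$ok)) {
    bad <- has_end[!has_end$ok, ]
    stop("missing ", recovery_time, " min recovery endpoint for ",
         paste(bad$strain, bad$replicate, sep = "/", collapse = ", "))
  }
  for (cc in cols) {
    out <- dplyr::mutate(
      out,
      !!paste0("delta_", cc) :=
        .data[[cc]] - .data[[cc]][abs(.data$time_min - recovery_time) < 1e-9][1]
    )
  }
  dplyr::ungroup(out)
}
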