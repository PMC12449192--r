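#' Genotype definitions
#'
#' A genotype is a set of activity flags for the three xanthophyll-cycle
#' enzymes: VDE (the de-epoxidase acting on both cycles), ZEP2 (the slow,
#' always-on epoxidase of the de novo biosynthesis arm) and ZEP3 (the fast,
#' strictly low-light-gated photoprotective epoxidase). The complemented line
#' is functionally wild type.
#'
#' @param name One of `"wt"`, `"vde_ko"`, `"zep2_ko"`, `"zep3_ko"`,
#'   `"complemented"`.
#' @return A list of class `xq_genotype` with fields `name`, `vde_active`,
#'   `zep2_active`, `zep3_active`.
#' @examples
#' genotype("zep3_ko")
#' @export
genotype <- function(name = c("wt", "vde_ko", "zep2_ko", "zep3_ko",
                              "complemented")) {
  name <- match.arg(name)
  flags <- c(vde = 1, zep2 = 1, zep3 = 1)
  ko <- switch(name, vde_ko = "vde", zep2_ko = "zep2", zep3_ko = "zep3", NULL)
  if (!is.null(ko)) flags[ko] <- 0
  structure(
    list(name = name, vde_active = unname(flags["vde"]),
         zep2_active = unname(flags["zep2"]), zep3_active = unname(flags["zep3"])),
    class = "xq_genotype"
  )
}

#' @export
print.xq_genotype <- function(x, ...) {
  cat("<genotype ", x$name, "> vde=", x$vde_active, " zep2=", x$zep2_active,
      " zep3=", x$zep3_active, "\n", sep = "")
  invisible(x)
}

#' Simulation scenario parameters
#'
#' All rate constants are first-order and in min-1; fluxes are in
#' mol pigment (mol chl a)-1 min-1. The defaults are the package's calibrated
#' study conditions (see the methods vignette for their provenance):
#'
#' * `v_dd`, `v_vx`: VDE de-epoxidation rates (Dd->Dt, and Vx->Ax / Ax->Zx),
#'   active in HL only.
#' * `k3_dt`, `k3_zx`, `k3_ax`: ZEP3 epoxidation rates (Dt->Dd, Zx->Ax,
#'   Ax->Vx), active in LL only (and blocked in darkness when
#'   `dark_blocks_zep3` is set).
#' * `k2`: ZEP2 epoxidation rate applied to Dt, Zx and Ax at all irradiances.
#'   The effective wild-type LL recovery rates are therefore
#'   kT = k3_dt + k2 = 0.12, kZ = k3_zx + k2 = 0.165 and
#'   kA = k3_ax + k2 = 0.055 min-1 (Ax transient peaking near 10 min).
#' * `kd`: Dd-synthase step (Vx->Dd) of the biosynthetic arm. With
#'   kd = 0.2 min-1 the arm's transit time (~5 min) is negligible against the
#'   6 h HL block, so de novo flux is delivered at the arm's terminus
#'   (see `simulate_pigments`).
#' * `s_denovo`: HL-gated de novo synthesis flux entering the xanthophyll
#'   pool from beta-carotene; default 2 * 0.10 / 360 so that 6 h of HL adds
#'   0.20 mol/mol and triples a 0.10 mol/mol pool.
#' * `qi_max`, `qi_rise_min`: photoinhibition (qI) plateau and linear rise
#'   time under HL; qI does not relax within the 30 min recovery.
#' * `gamma`: NPQ units per mol/mol of quenching-active pigment; `w_ax`: the
#'   antheraxanthin quenching weight; `fm_ref`: unquenched maximum
#'   fluorescence.
#' * `cv_pigment`, `cv_fluor`: replicate noise coefficients of variation;
#'   `n_replicates`; `seed`.
#'
#' @param ... Named overrides of any default listed above, plus
#'   `hl_threshold` and `dark_blocks_zep3`.
#' @return A list of class `xq_params`.
#' @examples
#' scenario_params(cv_pigment = 0, n_replicates = 1)
#' @export
scenario_params <- function(...) {
  p <- list(
    v_dd = 0.5, v_vx = 0.1,
    k3_dt = 0.11, k3_zx = 0.155, k3_ax = 0.045,
    k2 = 0.01, kd = 0.2,
    s_denovo = 2 * 0.10 / 360,
    qi_max = 0.3, qi_rise_min = 360,
    gamma = 25, w_ax = 0.5, fm_ref = 1.0,
    cv_pigment = 0.05, cv_fluor = 0.05,
    n_replicates = 3L, seed = 1L,
    hl_threshold = 500, dark_blocks_zep3 = TRUE
  )
  over <- list(...)
  if (length(over) > 0) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown) > 0 || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown scenario parameter(s): ",
           paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "))
    }
    p[names(over)] <- over
  }
  validate_params(p)
  class(p) <- "xq_params"
  p
}

validate_params <- function(p) {
  rates <- c("v_dd", "v_vx", "k3_dt", "k3_zx", "k3_ax", "k2", "kd",
             "s_denovo", "qi_max", "qi_rise_min", "gamma", "fm_ref",
             "cv_pigment", "cv_fluor")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("parameter '", nm, "' must be a single nonnegative number")
    }
  }
  if (p$w_ax < 0 || p$w_ax > 1) stop("w_ax must lie in [0, 1]")
  if (p$n_replicates < 1) stop("n_replicates must be >= 1")
  invisible(p)
}

#' Default day-5 initial pigment states
#'
#' Pigment:chlorophyll a molar ratios at the 0 h sample of the fifth
#' treatment day, i.e. after four days of HL:LL acclimation. The wild type
#' (and the zep3 KO, whose acclimated morning state is indistinguishable)
#' holds 0.097 mol/mol in the Dd cycle and 0.003 in the Vx cycle, almost all
#' epoxidized. The zep2 KO starts with a substantial Vx-cycle share
#' (Dd + Dt = 0.06, Vx + Ax + Zx = 0.04). The vde KO is devoid of
#' de-epoxidized pigments at all times, so its initial state carries the same
#' pool sizes fully epoxidized.
#'
#' @param genotype An `xq_genotype` or genotype name.
#' @param fx Constant fucoxanthin ratio carried through the simulation
#'   (default 0.6).
#' @return Named numeric vector `c(dd, dt, vx, ax, zx, fx)`.
#' @export
initial_pigments <- function(genotype = "wt", fx = 0.6) {
  name <- if (inherits(genotype, "xq_genotype")) genotype$name else genotype
  st <- switch(name,
    wt = ,
    complemented = ,
    zep3_ko = c(dd = 0.095, dt = 0.002, vx = 0.002, ax = 0, zx = 0.001),
    vde_ko = c(dd = 0.097, dt = 0, vx = 0.003, ax = 0, zx = 0),
    zep2_ko = c(dd = 0.058, dt = 0.002, vx = 0.030, ax = 0.002, zx = 0.008),
    stop("unknown genotype: ", name)
  )
  c(st, fx = fx)
}
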