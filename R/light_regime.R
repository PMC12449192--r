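#' Build a high-light / low-light irradiance regime
#'
#' Constructs the piecewise-constant irradiance schedule used throughout the
#' package: `days` repetitions of a high-light (HL) block followed by a
#' low-light (LL) block. The default reproduces the standard acclimation
#' protocol of five consecutive days with 6 h HL (~1,100 umol photons m-2 s-1)
#' followed by 18 h LL; the 30 min recovery window analysed downstream is the
#' start of the day-5 LL block.
#'
#' @param days Number of HL:LL days (default 5).
#' @param hl_min Duration of the HL block in minutes (default 360).
#' @param ll_min Duration of the LL block in minutes (default 1080).
#' @param hl_irradiance HL irradiance in umol photons m-2 s-1 (default 1100).
#' @param ll_irradiance LL irradiance in umol photons m-2 s-1 (default 25).
#' @param hl_threshold Irradiance at or above which a segment is labelled HL
#'   (default 500).
#'
#' @return A tibble of class `xq_regime` with columns `start_min`,
#'   `duration_min`, `irradiance`, `phase` (`"HL"` or `"LL"`), and an
#'   `hl_threshold` attribute.
#'
#' @examples
#' reg <- light_regime()
#' # day-5 HL block ends at minute 6120
#' subset(reg, phase == "HL")
#' @export
light_regime <- function(days = 5, hl_min = 360, ll_min = 1080,
                         hl_irradiance = 1100, ll_irradiance = 25,
                         hl_threshold = 500) {
  stopifnot(days >= 1, hl_min > 0, ll_min > 0)
  start <- (seq_len(days) - 1) * (hl_min + ll_min)
  segs <- tibble::tibble(
    start_min = as.numeric(rbind(start, start + hl_min)),
    duration_min = rep(c(hl_min, ll_min), days),
    irradiance = rep(c(hl_irradiance, ll_irradiance), days)
  )
  regime_from_segments(segs, hl_threshold = hl_threshold)
}

#' Build a regime from explicit segments
#'
#' Lower-level constructor taking a data frame of segments. Segments must be
#' contiguous (each starts where the previous one ends) and non-overlapping;
#' the phase label is derived from the irradiance and `hl_threshold`.
#'
#' @param segments Data frame with columns `start_min`, `duration_min`,
#'   `irradiance` (and optionally `phase`, which is recomputed).
#' @param hl_threshold HL labelling threshold (default 500).
#' @return An `xq_regime` tibble.
#' @export
regime_from_segments <- function(segments, hl_threshold = 500) {
  req <- c("start_min", "duration_min", "irradiance")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0) {
    stop("regime segments are missing column(s): ", paste(miss, collapse = ", "))
  }
  segs <- tibble::as_tibble(segments)[req]
  segs <- segs[order(segs$start_min), ]
  if (any(segs$duration_min <= 0)) stop("segment durations must be > 0")
  if (any(segs$irradiance < 0)) stop("irradiance must be >= 0")
  ends <- segs$start_min + segs$duration_min
  if (nrow(segs) > 1) {
    gaps <- segs$start_min[-1] - ends[-nrow(segs)]
    if (any(abs(gaps) > 1e-9)) {
      stop("regime segments must be contiguous and non-overlapping")
    }
  }
  segs$phase <- ifelse(segs$irradiance >= hl_threshold, "HL", "LL")
  attr(segs, "hl_threshold") <- hl_threshold
  class(segs) <- c("xq_regime", class(segs))
  segs
}

#' Phase label and irradiance at a time point
#'
#' For sampling instants that fall exactly on a segment boundary the label of
#' the segment ending there is used (`side = "left"`, the default): a sample
#' taken at the HL onset is still an LL sample, and the sample taken at the
#' end of the HL block is an HL sample. ODE gating uses `side = "right"`
#' (the segment starting at the boundary).
#'
#' @param regime An `xq_regime`.
#' @param time_min Numeric vector of times in minutes.
#' @param side `"left"` or `"right"` boundary convention.
#' @return Character vector of `"HL"` / `"LL"` labels.
#' @export
phase_at <- function(regime, time_min, side = c("left", "right")) {
  side <- match.arg(side)
  starts <- regime$start_min
  ends <- starts + regime$duration_min
  t0 <- starts[1]
  tend <- ends[length(ends)]
  if (any(time_min < t0 - 1e-9 | time_min > tend + 1e-9)) {
    stop("time outside the regime (", t0, " to ", tend, " min)")
  }
  idx <- if (side == "left") {
    pmax(1L, findInterval(time_min, starts, left.open = TRUE))
  } else {
    pmin(nrow(regime), findInterval(time_min, starts))
  }
  regime$phase[idx]
}

regime_end <- function(regime) {
  max(regime$start_min + regime$duration_min)
}

#' Default day-5 sampling grid
#'
#' The sampling scheme applied on the fifth treatment day: immediately before
#' HL onset (0 h), after 6 h of HL, and 1, 3, 5, 7.5, 10, 15 and 30 min into
#' the LL recovery. Times are minutes since the 0 h sample.
#'
#' @return Numeric vector of sampling times (min).
#' @export
sampling_grid <- function() {
  c(0, 360, 360 + c(1, 3, 5, 7.5, 10, 15, 30))
}

#' Start of the day-5 analysis window within a regime
#'
#' @param regime An `xq_regime`.
#' @return Minute at which the final HL block starts (the 0 h sample).
#' @export
analysis_window_start <- function(regime) {
  hl <- regime[regime$phase == "HL", , drop = FALSE]
  if (nrow(hl) == 0) stop("regime contains no HL segment")
  max(hl$start_min)
}
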