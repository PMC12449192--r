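#' Plot pigment time courses
#'
#' One facet per pigment, colored by strain, with the recovery window on a
#' shared minute axis. Intended as a quick look at simulated or measured
#' tables.
#'
#' @param pigments Replicate-level pigment table.
#' @param pigs Pigment columns to show.
#' @return A ggplot object.
#' @export
plot_pigments <- function(pigments, pigs = c("dd", "dt", "vx", "ax", "zx")) {
  long <- tidyr::pivot_longer(tibble::as_tibble(pigments),
                              cols = dplyr::all_of(pigs),
                              names_to = "pigment", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$ratio,
                                     colour = .data$strain,
                                     group = interaction(.data$strain,
                                                         .data$replicate))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~pigment, scales = "free_y") +
    ggplot2::labs(x = "time (min since 0 h sample)",
                  y = "pigment : chl a (mol/mol)") +
    ggplot2::theme_minimal()
}

#' Plot NPQ and qE traces
#'
#' @param quenching Output of [compute_quenching()].
#' @return A ggplot object.
#' @export
plot_quenching <- function(quenching) {
  long <- tidyr::pivot_longer(tibble::as_tibble(quenching),
                              cols = c("npq", "qe"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     colour = .data$strain,
                                     group = interaction(.data$strain,
                                                         .data$replicate))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "time (min since 0 h sample)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot qE against each candidate de-epoxidized pool
#'
#' Scatter of qE versus the end-anchored pool delta, one facet per
#' candidate formula, with per-strain OLS lines (solid) and the combined
#' line (dashed).
#'
#' @param quenching Output of [compute_quenching()].
#' @param delta_pools Output of [build_delta_pools()].
#' @return A ggplot object.
#' @export
plot_pool_correlation <- function(quenching, delta_pools) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(quenching), "strain", "replicate",
                  "time_min", "qe"),
    tibble::as_tibble(delta_pools),
    by = c("strain", "replicate", "time_min")
  )
  ggplot2::ggplot(joined, ggplot2::aes(.data$delta_pool, .data$qe)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$strain), size = 1) +
    ggplot2::geom_smooth(ggplot2::aes(colour = .data$strain),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "black",
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~formula, scales = "free_x") +
    ggplot2::labs(x = "delta de-epoxidized pool (mol/mol)", y = "qE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.xq_pool_models <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$formula, .data$r_squared,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.xq_kinfit <- function(object, ...) {
  n <- length(object$fitted)
  d <- tibble::tibble(index = seq_len(n),
                      observed = object$fitted + object$residuals,
                      fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "observation", y = "value",
                  title = paste(object$model, "fit")) +
    ggplot2::theme_minimal()
}
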