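#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a diameter profile
#'
#' Cross-sectional diameter against arc-length position within the
#' measurement window, with the window mean overlaid.
#'
#' @param object A `vessel_measurement` from [measure_aorta()] /
#'   [measure_pa()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vessel_measurement <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position_cm, y = .data$diameter_mm)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$mean_diameter_mm,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Arc-length position (cm)", y = "Diameter (mm)",
                  title = sprintf("%s: mean %.1f mm", object$vessel_label,
                                  object$mean_diameter_mm)) +
    ggplot2::theme_minimal()
}

#' Covariate balance (love) plot
#'
#' Absolute standardized mean differences before and after matching.
#'
#' @param object An `smd_balance` tibble from [balance_smd()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smd_balance <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("smd_before", "smd_after"),
                              names_to = "stage", values_to = "smd")
  long$stage <- factor(long$stage, levels = c("smd_before", "smd_after"),
                       labels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd), y = .data$covariate,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dotted") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = "matching") +
    ggplot2::theme_minimal()
}
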