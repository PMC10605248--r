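#' Plot focal-ratio curves by condition
#'
#' Mean R(z) per condition with a +/- sd ribbon, the standard light-focusing
#' figure: a transparent, focusing spheroid shows a sharp peak well above 1.
#'
#' @importFrom ggplot2 .data
#' @param comparison a `condition_comparison` from [compare_conditions()], or
#'   a single `focal_curve`.
#' @return a ggplot object.
#' @export
plot_focal_curve <- function(comparison) {
  if (inherits(comparison, "focal_curve")) {
    df <- data.frame(condition = "stack", z = comparison$z,
                     mean_ratio = comparison$ratio, sd_ratio = 0)
  } else df <- comparison$curve_summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$mean_ratio,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ratio - .data$sd_ratio,
                                      ymax = .data$mean_ratio + .data$sd_ratio),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "z position (um)", y = "focal ratio R(z)") +
    ggplot2::theme_minimal()
}

#' Plot an overlap sweep: observed vs expected-by-chance
#'
#' @param sweep an [overlap_sweep()] result.
#' @return a ggplot object.
#' @export
plot_overlap_sweep <- function(sweep) {
  df <- rbind(data.frame(x = sweep$x * 100, genes = sweep$observed,
                         what = "observed"),
              data.frame(x = sweep$x * 100, genes = sweep$expected,
                         what = "expected by chance"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$genes,
                                   colour = .data$what)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c("observed" = "#2166ac",
                                            "expected by chance" = "grey55")) +
    ggplot2::labs(x = "top-enriched fraction (%)", y = "shared genes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param de a `de_result` from [nb_de_test()].
#' @return a ggplot object.
#' @export
plot_volcano <- function(de) {
  df <- as.data.frame(de)
  df$signif <- df$call != "ns"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$signif)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60",
                                            "TRUE" = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' Fold-change density by reference identity
#'
#' Density of DEG log2 fold changes split by reference identity (FC vs LEC):
#' concordant regional identities put FC mass at positive and LEC mass at
#' negative fold changes.
#'
#' @param overlay result of [fc_lec_overlay()].
#' @return a ggplot object.
#' @export
plot_fc_density <- function(overlay) {
  df <- overlay$genes[overlay$genes$identity != "neither", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   colour = .data$identity,
                                   fill = .data$identity)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::scale_colour_manual(values = c(FC = "#e08214", LEC = "#1b7837"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "log2 fold change", y = "density") +
    ggplot2::theme_minimal()
}
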