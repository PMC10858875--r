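#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PCoA ordination
#'
#' @param object A `phagedyn_pcoa` object.
#' @param groups Optional vector of group labels (colours), one per
#'   sample.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phagedyn_pcoa <- function(object, groups = NULL, ...) {
  df <- tibble::as_tibble(object$points[, 1:2, drop = FALSE],
                          rownames = "sample_id")
  names(df)[2:3] <- c("Axis1", "Axis2")
  pe <- 100 * object$prop_explained[1:2]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2))
  if (!is.null(groups)) {
    df$group <- groups
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2,
                                          colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2])) +
    ggplot2::theme_minimal()
}

#' Plot shared-SNP fraction against time lag by lifestyle
#'
#' @param fit A `phagedyn_snp_fit` object from [similarity_vs_lag()].
#' @return A ggplot with per-lifestyle points and OLS lines.
#' @export
plot_similarity_lag <- function(fit) {
  stopifnot(inherits(fit, "phagedyn_snp_fit"))
  ggplot2::ggplot(fit$series,
                  ggplot2::aes(.data$lag_days, .data$shared_fraction,
                               colour = .data$lifestyle)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "time lag (days)", y = "shared-SNP fraction") +
    ggplot2::theme_minimal()
}

#' Plot prevalence against mean relative abundance
#'
#' @param prev Output of [prevalence_and_mean_abundance()].
#' @param groups Optional named vector population_id -> group label.
#' @return A ggplot on a log-x scale.
#' @export
plot_prevalence_abundance <- function(prev, groups = NULL) {
  df <- prev
  if (!is.null(groups)) df$group <- unname(groups[df$population_id])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mean_rel_abundance_pct,
                                        .data$prevalence_pct))
  if (!is.null(groups)) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p + ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean relative abundance (%)",
                  y = "prevalence (%)") +
    ggplot2::theme_minimal()
}

#' Plot seasonal abundance variation per host family
#'
#' @param variation Output of [abundance_variation()].
#' @return A ggplot bar chart of per-family deltas (HL minus HF).
#' @export
plot_abundance_variation <- function(variation) {
  ggplot2::ggplot(variation$per_family,
                  ggplot2::aes(stats::reorder(.data$family, .data$delta),
                               .data$delta, fill = .data$delta > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "abundance change (HL - HF)") +
    ggplot2::theme_minimal()
}
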