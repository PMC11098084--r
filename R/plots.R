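#' Plot a pairing kymograph
#'
#' Loci on the vertical axis, recorded frames on the horizontal axis, with a
#' dark-blue (zero distance, paired) to red (maximum distance) colour map.
#'
#' @param km matrix from [kymograph()].
#' @return a ggplot object.
#' @export
plot_kymograph <- function(km) {
  steps <- attr(km, "steps")
  df <- expand.grid(node = 0:(nrow(km) - 1), frame = seq_len(ncol(km)))
  df$step <- steps[df$frame]
  df$dist <- as.vector(km)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$node,
                                   fill = .data$dist)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("darkblue", "blue", "cyan", "yellow", "red"),
      limits = c(0, 1), name = "fraction of\nmax distance") +
    ggplot2::labs(x = "simulation step", y = "position along chromosome (node)") +
    ggplot2::theme_minimal()
}

#' Plot ensemble fidelity against a numeric scan variable
#'
#' Mean with SEM error bars, one point per condition.
#'
#' @param results per-run data.frame with columns `x` and `fidelity`.
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_fidelity_curve <- function(results, xlab = "parameter") {
  agg <- stats::aggregate(fidelity ~ x, results, function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  })
  df <- data.frame(x = agg$x, mean = agg$fidelity[, "mean"],
                   sem = agg$fidelity[, "sem"])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "pairing fidelity") +
    ggplot2::theme_minimal()
}

#' Beeswarm-style plot of per-run fidelities by condition
#'
#' Jittered per-run points over boxes (median, quartiles, 1.5 IQR whiskers).
#'
#' @param results per-run data.frame with columns `label` and `fidelity`.
#' @return a ggplot object.
#' @export
plot_fidelity_swarm <- function(results) {
  results$label <- factor(results$label, levels = unique(results$label))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$label, y = .data$fidelity)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 1.5, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1, alpha = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "pairing fidelity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
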