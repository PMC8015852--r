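#' @export
autoplot.window_track <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = object$metric[1]) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of association results
#'
#' @param results Association tibble from [emmax_scan()] or [lfmm_scan()].
#' @param threshold Optional p-value threshold drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$pos / 1e6,
                                    y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  p
}

#' @export
autoplot.ammi <- function(object, ...) {
  dg <- tibble(label = object$genotype_effects$sample,
               effect = object$genotype_effects$effect,
               ipca1 = object$scores_g[, 1] * sqrt(object$lambda[1]),
               what = "accession")
  de <- tibble(label = as.character(object$year_effects$year),
               effect = object$year_effects$effect,
               ipca1 = object$scores_e[, 1] * sqrt(object$lambda[1]),
               what = "year")
  ggplot2::ggplot(dplyr::bind_rows(dg, de),
                  ggplot2::aes(x = .data$effect, y = .data$ipca1,
                               colour = .data$what)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "main effect (days)", y = "IPCA1") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lt50_fit <- function(object, ...) {
  grid <- tibble(temperature = seq(min(object$data$temperature) - 5,
                                   max(object$data$temperature) + 5,
                                   length.out = 200))
  grid$rel_conductance <-
    1 / (1 + exp(object$k * (grid$temperature - object$lt50)))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$temperature,
                               y = .data$rel_conductance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$lt50, linetype = "dashed") +
    ggplot2::labs(x = "temperature (°C)", y = "relative conductance") +
    ggplot2::theme_minimal()
}
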