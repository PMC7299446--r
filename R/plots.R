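#' Density plot of prevalence draws
#'
#' @param object An `mm_draws` table.
#' @param ... Unused.
#' @return A ggplot: one density per model label over the prevalence scale.
#' @export
autoplot.mm_draws <- function(object, ...) {
  ggplot(object, aes(x = .data$value, colour = .data$label)) +
    geom_density() +
    labs(x = "estimated hidden-population size",
         y = "density", colour = NULL) +
    theme_minimal()
}

#' Range plot of a pipeline report
#'
#' Shows, per model and for the averaged distribution, the min–max span
#' (thin line), the 10th–90th percentile span (thick line), and the mean
#' (point).
#'
#' @param object An `mm_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_report <- function(object, ...) {
  s <- mutate(object$summary,
              label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot(s, aes(y = .data$label)) +
    geom_linerange(aes(xmin = .data$min, xmax = .data$max),
                   linewidth = 0.4, colour = "grey60") +
    geom_pointrange(aes(x = .data$mean, xmin = .data$p10, xmax = .data$p90),
                    linewidth = 1.1) +
    labs(x = "estimated hidden-population size", y = NULL,
         title = object$config$region_name) +
    theme_minimal()
}
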