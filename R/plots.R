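#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot independent vs adjusted trio coefficients
#'
#' Dot-and-interval plot of the child, mother and father polygenic-score
#' coefficients in the independent and co-adjusted models (point estimate
#' +/- 1.96 SE).
#'
#' @param object A `trio_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trio_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate,
                                  colour = .data$model)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - 1.96 * .data$std.error,
                   ymax = .data$estimate + 1.96 * .data$std.error),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "PGS coefficient (SD units)",
                  colour = NULL,
                  title = sprintf("Trio attenuation: %.1f%% (SE %.1f)",
                                  object$attenuation_pct, object$se_attenuation)) +
    ggplot2::theme_minimal()
}

#' Plot heritability before and after PC adjustment
#'
#' @param object A `strat_check`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strat_check <- function(object, ...) {
  d <- object$estimates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$h2)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$h2 - 1.96 * .data$se,
                                          ymax = .data$h2 + 1.96 * .data$se)) +
    ggplot2::labs(x = NULL, y = expression(h^2),
                  title = "SNP heritability before/after PC adjustment") +
    ggplot2::theme_minimal()
}

#' Phenotype distributions by generation and subpopulation
#'
#' Quick look at a simulated cohort: per-generation density of a trait,
#' coloured by subpopulation.
#'
#' @param cohort A `cohort` with phenotypes.
#' @param trait Phenotype column (default `trait_a`).
#' @return A ggplot.
#' @export
plot_cohort_phenotypes <- function(cohort, trait = "trait_a") {
  d <- dplyr::inner_join(cohort$individuals, cohort$phenos, by = c("id", "generation"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[trait]],
                                  colour = factor(.data$subpop))) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~generation, labeller = ggplot2::label_both) +
    ggplot2::labs(colour = "subpop") +
    ggplot2::theme_minimal()
}
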