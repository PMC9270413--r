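#' Bar chart of hypothesis counts
#'
#' The analogue of the hypothesis-count figure: one bar per hypothesis
#' class, optionally stacked by red-list status.
#'
#' @param species_summary Labelled per-species tibble (from
#'   [label_comparisons()] / `run_pipeline()$species_summary`).
#' @param traits Optional trait table supplying `red_list` for the fill.
#' @return A ggplot object.
#' @export
plot_hypothesis_counts <- function(species_summary, traits = NULL) {
  df <- species_summary
  if (!is.null(traits) && !"red_list" %in% names(df)) {
    df <- dplyr::left_join(df, dplyr::select(traits, "species_id", "red_list"),
                           by = "species_id")
  }
  df$label <- factor(df$label, levels = c("HP0", "HP1", "HP2", "HP3"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label)) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "Hypothesis", y = "Number of species") +
    ggplot2::theme_minimal()
  if ("red_list" %in% names(df)) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data$red_list))
  } else {
    p + ggplot2::geom_bar()
  }
}

#' Love plot of covariate balance before and after matching
#'
#' @param balance Balance tibble from [balance_report()].
#' @return A ggplot object (absolute SMD per covariate, pre vs post).
#' @export
plot_balance <- function(balance) {
  long <- balance |>
    tidyr::pivot_longer(c("smd_before", "smd_after"),
                        names_to = "stage", values_to = "smd") |>
    dplyr::mutate(stage = dplyr::recode(.data$stage,
                                        smd_before = "before matching",
                                        smd_after = "after matching"))
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd), y = .data$covariate,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Threshold-sensitivity profile of the hypothesis counts
#'
#' @param sensitivity Tibble from [threshold_sensitivity()].
#' @return A ggplot object (count per class across thresholds).
#' @export
plot_threshold_sensitivity <- function(sensitivity) {
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = .data$threshold, y = .data$n,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Classification threshold", y = "Species count",
                  colour = "Hypothesis") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a beta mixed model
#'
#' @param object A `"beta_glmm"` fit.
#' @param ... Unused.
#' @return A ggplot object (estimates with 95% Wald intervals).
#' @export
autoplot.beta_glmm <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "Standardized coefficient (logit scale, 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
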