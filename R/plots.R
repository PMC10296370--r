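#' Plot an ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Forest plot of significant lipid associations
#'
#' Odds ratios with 95% confidence intervals for the species retained by
#' [export_forest_data()], univariate and covariate-adjusted side by side,
#' ordered by adjusted p-value.
#'
#' @param forest Output of [export_forest_data()].
#' @param max_species Cap on displayed species.
#' @return A ggplot.
#' @export
plot_forest <- function(forest, max_species = 40) {
  d <- forest |>
    head(max_species) |>
    select("species", dplyr::starts_with("odds_ratio"),
           dplyr::starts_with("ci_")) |>
    tidyr::pivot_longer(-"species",
                        names_to = c(".value", "model"),
                        names_pattern = "(odds_ratio|ci_low|ci_high)_(.*)") |>
    mutate(species = factor(.data$species, levels = rev(unique(.data$species))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$species,
                                  colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.25) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (per unit log-concentration)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Variance-explained and batch/biology R2 of the leading PCs
#'
#' @param diagnostics A [pca_diagnostics()] tibble (optionally two bound
#'   together with a `stage` column for before/after comparison).
#' @return A ggplot.
#' @export
plot_pc_diagnostics <- function(diagnostics) {
  d <- diagnostics |>
    tidyr::pivot_longer(c("r2_batch", "r2_age", "r2_sex"),
                        names_to = "variable", values_to = "r2") |>
    mutate(variable = sub("^r2_", "", .data$variable))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pc, y = .data$r2,
                                       colour = .data$variable)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Principal component", y = expression(R^2)) +
    ggplot2::theme_minimal()
  if ("stage" %in% names(diagnostics)) {
    p <- p + ggplot2::facet_wrap(~stage)
  }
  p
}

#' Individual classifiability against a clinical variable
#'
#' @param ics [compute_ics()] result.
#' @param clinical Clinical tibble.
#' @param variable Clinical column for the x axis.
#' @return A ggplot.
#' @export
plot_ics <- function(ics, clinical, variable = "bmi") {
  d <- ics |> inner_join(clinical[c("sample_id", variable)], by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[variable]], y = .data$ics)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = variable, y = "Individual classifiability score") +
    ggplot2::theme_minimal()
}
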