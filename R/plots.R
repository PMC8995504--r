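#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the load-deformation curve of an FE solution
#'
#' @param object an `fe_solution`.
#' @param ... unused.
#' @return a ggplot: reaction force (N) against nominal compressive
#'   deformation, with the femoral strength marked at the final step.
#' @export
autoplot.fe_solution <- function(object, ...) {
  h <- object$reaction_history
  ggplot2::ggplot(h, ggplot2::aes(x = 100 * .data$deformation,
                                  y = .data$reaction_N)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = h[nrow(h), ], colour = "red", size = 2) +
    ggplot2::labs(x = "compressive deformation (%)",
                  y = "reaction force (N)",
                  title = sprintf("Femoral strength %.0f N at %.0f%% deformation",
                                  object$femoral_strength,
                                  100 * object$target_deformation)) +
    ggplot2::theme_minimal()
}

#' Plot a phantom calibration fit
#'
#' @param object a `calibration_line`.
#' @param ... unused.
#' @return a ggplot of insert mean HU against known density with the
#'   fitted line.
#' @export
autoplot.calibration_line <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$hu_mean,
                                              y = .data$density)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "insert ROI mean (HU)",
                  y = expression(rho[apparent] ~ (g/cm^3)),
                  title = sprintf("Calibration: rho = %.3g HU %+.3g (r² = %.4f)",
                                  object$slope, object$intercept,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot adjusted R-squared along a model ladder
#'
#' @param object a `ladder_fit` from [fit_ladder()].
#' @param ... unused.
#' @return a ggplot of adjusted R^2 per rung, improvements highlighted.
#' @export
autoplot.ladder_fit <- function(object, ...) {
  d <- tidy(object)
  d$label <- vapply(strsplit(d$formula, " \\+ "), function(p) p[length(p)],
                    character(1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rung, y = .data$adj.r.squared)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$improved), size = 2,
                        na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3, na.rm = TRUE) +
    ggplot2::labs(x = "model rung (predictors added left to right)",
                  y = "adjusted R²", colour = "improved") +
    ggplot2::theme_minimal()
}

#' Scatter plots of femoral strength against cohort covariates
#'
#' @param cohort cohort tibble (see [generate_cohort()]).
#' @param covariates covariate names to plot against strength.
#' @return a ggplot facetted by covariate, coloured by group, with
#'   per-group least-squares lines.
#' @export
plot_strength_correlations <- function(cohort,
                                       covariates = c("fn_t_score", "pentosidine",
                                                      "age")) {
  stopifnot(all(c("group", "strength", covariates) %in% names(cohort)))
  long <- tidyr::pivot_longer(cohort[, c("group", "strength", covariates)],
                              dplyr::all_of(covariates),
                              names_to = "covariate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$strength,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "femoral strength (N)") +
    ggplot2::theme_minimal()
}
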