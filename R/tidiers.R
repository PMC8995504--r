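#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted strength regression model
#'
#' @param x a `strength_model` from [fit_ladder()].
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate` (B),
#'   `std_estimate` (beta), `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.strength_model <- function(x, ...) {
  dplyr::transmute(x$coefficients,
                   term = .data$term, estimate = .data$B,
                   std_estimate = .data$beta, p.value = .data$p_value,
                   conf.low = .data$ci_lower, conf.high = .data$ci_upper)
}

#' One-row summary of a strength regression model
#'
#' @inheritParams tidy.strength_model
#' @return tibble: `r.squared`, `adj.r.squared`, `sigma`, `nobs`,
#'   `n_predictors`.
#' @export
glance.strength_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
                 sigma = x$sigma, nobs = x$n,
                 n_predictors = length(x$predictors))
}

#' Tidy a model ladder
#'
#' @param x a `ladder_fit` from [fit_ladder()].
#' @param ... unused.
#' @return tibble with one row per rung: `rung`, `formula`,
#'   `adj.r.squared`, `r.squared`, `improved`, `fittable`, `note`.
#' @export
tidy.ladder_fit <- function(x, ...) {
  tibble::tibble(
    rung = x$rung,
    formula = vapply(x$predictors, paste, character(1), collapse = " + "),
    adj.r.squared = x$adj_r_squared,
    r.squared = x$r_squared,
    improved = x$improved,
    fittable = x$fittable,
    note = x$note)
}

#' Tidy the reaction history of an FE solution
#'
#' @param x an `fe_solution` from [solve_compression()].
#' @param ... unused.
#' @return the reaction-history tibble (`step`, `deformation`,
#'   `displacement_mm`, `reaction_N`, `iterations`, `residual`).
#' @export
tidy.fe_solution <- function(x, ...) x$reaction_history

#' One-row summary of an FE solution
#'
#' @inheritParams tidy.fe_solution
#' @return tibble: `femoral_strength_N`, `target_deformation`,
#'   `n_elements`, `n_nodes`, `equilibrium_rel`, `max_plastic_overshoot`.
#' @export
glance.fe_solution <- function(x, ...) {
  tibble::tibble(femoral_strength_N = x$femoral_strength,
                 target_deformation = x$target_deformation,
                 n_elements = x$n_elements, n_nodes = x$n_nodes,
                 equilibrium_rel = x$equilibrium_rel,
                 max_plastic_overshoot = x$max_plastic_overshoot)
}

#' Tidy a calibration line
#'
#' @param x a `calibration_line` from [fit_calibration()].
#' @param ... unused.
#' @return tibble of the insert points (`hu_mean`, `density`).
#' @export
tidy.calibration_line <- function(x, ...) x$points

#' One-row summary of a calibration line
#'
#' @inheritParams tidy.calibration_line
#' @return tibble: `slope`, `intercept`, `r.squared`, `n_points`.
#' @export
glance.calibration_line <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n_points = x$n_points)
}

#' One-row summary of a pipeline report
#'
#' @param x an `fe_report` from [run_pipeline()].
#' @param ... unused.
#' @return the report's `summary` tibble.
#' @export
glance.fe_report <- function(x, ...) x$summary
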