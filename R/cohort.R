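#' Reference multiple-regression models for femoral strength
#'
#' The best published predictive models of QCT-FE femoral strength for
#' elderly men with type 2 diabetes (T2DM) and age-matched controls:
#' unstandardized coefficients of the linear predictor
#' `FS = B0 + sum(Bi * xi)` in Newtons. The diabetic model uses femoral
#' neck T score, pentosidine (pmol/ml), age (years), HbA1c (%) and P1NP
#' (ng/ml); the control model uses femoral neck T score, BMI (kg/m^2) and
#' P1NP.
#'
#' @return named list with elements `t2dm` and `control`, each a tibble
#'   with columns `term` and `estimate` (the `(Intercept)` row first).
#' @export
#' @examples
#' reference_strength_models()$t2dm
reference_strength_models <- function() {
  list(
    t2dm = tibble::tibble(
      term = c("(Intercept)", "fn_t_score", "pentosidine", "age", "hba1c", "p1np"),
      estimate = c(29240.848, 315.404, -14.118, -153.863, -879.085, 161.406)),
    control = tibble::tibble(
      term = c("(Intercept)", "fn_t_score", "bmi", "p1np"),
      estimate = c(9584.833, 745.051, -40.206, -13.840)))
}

# Default covariate distributions per group: means chosen near the
# published cohort medians (diabetics: higher HbA1c and BMI, lower P1NP),
# SDs at plausible clinical spreads.
default_covariates <- function() {
  tibble::tribble(
    ~name,          ~mean_t2dm, ~mean_control, ~sd,
    "age",           67,         61,            6,
    "bmi",           25.7,       23.7,          2.2,
    "fn_t_score",    -0.8,       -1.6,          1.1,
    "hba1c",         8.1,        5.6,           0.9,
    "p1np",          33,         55,            12,
    "pentosidine",   560,        620,           150,
    "c_peptide",     1.2,        1.6,           0.4)
}

# Default covariate correlation structure (shared across groups):
# pentosidine rises with age and tracks C-peptide; T score falls with age.
default_correlation <- function() {
  nm <- default_covariates()$name
  r <- diag(length(nm))
  dimnames(r) <- list(nm, nm)
  set_r <- function(a, b, v) {
    r[a, b] <<- v; r[b, a] <<- v
  }
  set_r("age", "pentosidine", 0.35)
  set_r("age", "fn_t_score", -0.30)
  set_r("pentosidine", "c_peptide", 0.25)
  set_r("bmi", "fn_t_score", 0.20)
  set_r("hba1c", "p1np", -0.20)
  r
}

#' Specify a synthetic cohort
#'
#' Defines the generating model for a two-group synthetic cohort
#' (diabetic arm `t2dm` and `control`): per-group sample sizes, covariate
#' means/SDs, a shared covariate correlation matrix, per-group coefficient
#' vectors for the strength-generating linear model, and the strength
#' noise SD. Defaults emulate the published study conditions: n = 10
#' diabetics and 8 controls, the reference model coefficients of
#' [reference_strength_models()] (so strength falls with pentosidine and
#' age in the diabetic arm and rises with femoral neck T score in both),
#' and 400 N residual noise.
#'
#' @param n_t2dm,n_control per-group sample sizes (each >= 3).
#' @param covariates tibble like [default_covariates()]: columns `name`,
#'   `mean_t2dm`, `mean_control`, `sd`.
#' @param correlation covariate correlation matrix (symmetric positive
#'   semi-definite, dimnames matching `covariates$name`).
#' @param coef_t2dm,coef_control named coefficient vectors (with
#'   `(Intercept)`) for the per-group strength models; defaults are the
#'   reference models.
#' @param noise_sd strength residual SD in Newtons (default 400).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_t2dm = 10L, n_control = 8L,
                        covariates = default_covariates(),
                        correlation = default_correlation(),
                        coef_t2dm = NULL, coef_control = NULL,
                        noise_sd = 400, seed = 1L) {
  if (n_t2dm < 3 || n_control < 3) stop("n_per_group must be >= 3")
  stopifnot(is.data.frame(covariates),
            all(c("name", "mean_t2dm", "mean_control", "sd") %in% names(covariates)))
  k <- nrow(covariates)
  if (!is.matrix(correlation) || any(dim(correlation) != k)) {
    stop("correlation must be a ", k, "x", k, " matrix")
  }
  if (max(abs(correlation - t(correlation))) > 1e-12) {
    stop("correlation matrix must be symmetric")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("correlation matrix must be positive semi-definite")
  }
  ref <- reference_strength_models()
  as_named <- function(tb) stats::setNames(tb$estimate, tb$term)
  if (is.null(coef_t2dm)) coef_t2dm <- as_named(ref$t2dm)
  if (is.null(coef_control)) coef_control <- as_named(ref$control)
  for (cf in list(coef_t2dm, coef_control)) {
    if (!"(Intercept)" %in% names(cf)) stop("coefficients need an (Intercept)")
    miss <- setdiff(setdiff(names(cf), "(Intercept)"), covariates$name)
    if (length(miss)) stop("unknown coefficient covariates: ", paste(miss, collapse = ", "))
  }
  structure(list(
    n_t2dm = as.integer(n_t2dm), n_control = as.integer(n_control),
    covariates = covariates, correlation = correlation,
    coef_t2dm = coef_t2dm, coef_control = coef_control,
    noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws per-group covariates from the multivariate normal implied by the
#' spec's means/SDs/correlation and computes femoral strength as the
#' group's linear predictor plus Gaussian noise. The generating
#' coefficients are attached as `attr(, "truth")` so regression-recovery
#' tests can compare fitted against generating values.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `subject`, `group` (`"t2dm"`/`"control"`),
#'   one column per covariate, and `strength` (N); attribute `truth` holds
#'   the generating coefficient vectors and `noise_sd`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(spec$seed)
  cv <- spec$covariates
  sigma <- diag(cv$sd) %*% spec$correlation %*% diag(cv$sd)
  draw <- function(n, means, coefs, group) {
    x <- MASS::mvrnorm(n, mu = means, Sigma = sigma)
    if (n == 1) x <- matrix(x, nrow = 1)
    colnames(x) <- cv$name
    lp <- rep(coefs[["(Intercept)"]], n)
    for (nm in setdiff(names(coefs), "(Intercept)")) lp <- lp + coefs[[nm]] * x[, nm]
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, sd = spec$noise_sd) else 0
    dplyr::bind_cols(tibble::tibble(group = group),
                     tibble::as_tibble(x),
                     tibble::tibble(strength = lp + noise))
  }
  out <- dplyr::bind_rows(
    draw(spec$n_t2dm, cv$mean_t2dm, spec$coef_t2dm, "t2dm"),
    draw(spec$n_control, cv$mean_control, spec$coef_control, "control"))
  out <- dplyr::mutate(out, subject = sprintf("S%03d", dplyr::row_number()),
                       .before = 1)
  attr(out, "truth") <- list(coef_t2dm = spec$coef_t2dm,
                             coef_control = spec$coef_control,
                             noise_sd = spec$noise_sd)
  out
}
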