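#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum comparison of two groups with the small-sample policy used for
#' cohort tables of this size: exact enumeration p-value when the combined
#' sample is at most 20 and tie-free, otherwise the mid-rank normal
#' approximation with tie correction. The method actually used is recorded
#' in the result.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return tibble with one row: `U` (statistic for the first sample),
#'   `p_value` (two-sided), `method` (`"exact"`/`"normal"`), `n_x`, `n_y`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("inputs must be finite")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  tibble::tibble(U = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal",
                 n_x = length(x), n_y = length(y))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a two-sided p-value: exact for
#' tie-free samples of at most 9 pairs, the t approximation otherwise.
#' Constant input yields an undefined correlation, reported as `NA` with
#' `method = "undefined"`.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return tibble with one row: `rho`, `p_value`, `method`
#'   (`"exact"`/`"t-approximation"`/`"undefined"`), `n`.
#' @export
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs required")
  if (any(!is.finite(c(x, y)))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          method = "undefined", n = n))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 method = if (exact) "exact" else "t-approximation", n = n)
}

#' Quartile summary and group comparison of a cohort table
#'
#' Summarizes each numeric variable as median (Q1, Q3) per group (linear
#' interpolation quantiles) and compares the groups with [mann_whitney()],
#' mirroring the usual presentation of diabetic-vs-control cohort tables.
#'
#' @param cohort tibble with a `group` column (`"t2dm"`/`"control"`) and
#'   numeric variable columns.
#' @param variables variables to summarize; default all numeric columns.
#' @return tibble: `variable`, per-group `median`, `q1`, `q3`
#'   (`*_t2dm` / `*_control`), `U`, `p_value`, `method`.
#' @export
cohort_summary <- function(cohort, variables = NULL) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (is.null(variables)) {
    variables <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                         "group")
  }
  g <- cohort$group
  if (!all(g %in% c("t2dm", "control"))) stop("group must be t2dm/control")
  purrr::map_dfr(variables, function(v) {
    a <- cohort[[v]][g == "t2dm"]; b <- cohort[[v]][g == "control"]
    mw <- mann_whitney(a, b)
    qa <- unname(stats::quantile(a, c(0.25, 0.5, 0.75), type = 7))
    qb <- unname(stats::quantile(b, c(0.25, 0.5, 0.75), type = 7))
    tibble::tibble(variable = v,
                   median_t2dm = qa[2], q1_t2dm = qa[1], q3_t2dm = qa[3],
                   median_control = qb[2], q1_control = qb[1], q3_control = qb[3],
                   U = mw$U, p_value = mw$p_value, method = mw$method)
  })
}

#' Screen candidate predictors for collinearity
#'
#' When two candidate predictors correlate above `threshold` in absolute
#' value, keeps the one more correlated (Spearman) with the response and
#' drops the other - the standard pre-step that, e.g., drops femoral BMD
#' in favour of the femoral neck T score.
#'
#' @param data tibble of predictors and response.
#' @param candidates character vector of candidate predictor names.
#' @param response response column name (default `"strength"`).
#' @param threshold absolute pairwise correlation above which one of a
#'   pair is dropped (default 0.8).
#' @return list with `keep` (surviving predictors, original order) and
#'   `dropped` (tibble: `dropped`, `in_favour_of`, `r`).
#' @export
screen_collinearity <- function(data, candidates, response = "strength",
                                threshold = 0.8) {
  stopifnot(all(c(candidates, response) %in% names(data)))
  keep <- candidates
  dropped <- list()
  resp_r <- vapply(candidates, function(v) {
    abs(stats::cor(data[[v]], data[[response]], method = "spearman"))
  }, numeric(1))
  repeat {
    pair <- NULL
    for (i in seq_along(keep)) {
      for (j in seq_along(keep)) {
        if (j <= i) next
        r <- stats::cor(data[[keep[i]]], data[[keep[j]]], method = "spearman")
        if (abs(r) > threshold) { pair <- list(i = i, j = j, r = r); break }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) break
    a <- keep[pair$i]; b <- keep[pair$j]
    drop <- if (resp_r[a] >= resp_r[b]) b else a
    dropped[[length(dropped) + 1]] <-
      tibble::tibble(dropped = drop, in_favour_of = setdiff(c(a, b), drop),
                     r = pair$r)
    keep <- setdiff(keep, drop)
  }
  list(keep = keep,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                 else tibble::tibble(dropped = character(), in_favour_of = character(),
                                     r = numeric()))
}

#' Fit a hierarchical ladder of regression models
#'
#' Fits one OLS model per rung of a model ladder: the base predictor
#' alone, then the base plus the first addition, then the first two, and
#' so on. Each rung reports unstandardized coefficients with 95%
#' t-confidence intervals, standardized coefficients (from z-scored
#' response and predictors), per-coefficient p-values, and adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1); a rung is flagged when its
#' adjusted R^2 improves on the previous rung. Rungs whose design matrix
#' is rank deficient or has no residual degrees of freedom are reported
#' as unfittable rather than fitted.
#'
#' @param data tibble containing the response and all predictors.
#' @param base name of the base predictor (first rung).
#' @param additions character vector of predictors added one at a time.
#' @param response response column name (default `"strength"`).
#' @return tibble with one row per rung: `rung`, `predictors` (list
#'   column), `model` (list of `strength_model` objects or `NULL`),
#'   `adj_r_squared`, `r_squared`, `improved`, `fittable`, `note`.
#' @export
fit_ladder <- function(data, base, additions = character(),
                       response = "strength") {
  stopifnot(is.data.frame(data), base %in% names(data),
            all(additions %in% names(data)), response %in% names(data))
  rungs <- lapply(0:length(additions), function(k) c(base, additions[seq_len(k)]))
  prev_adj <- -Inf
  out <- purrr::map_dfr(seq_along(rungs), function(i) {
    preds <- rungs[[i]]
    n <- nrow(data)
    p <- length(preds)
    if (n - p - 1 <= 0) {
      return(tibble::tibble(rung = i, predictors = list(preds),
                            model = list(NULL), adj_r_squared = NA_real_,
                            r_squared = NA_real_, improved = NA,
                            fittable = FALSE,
                            note = "no residual degrees of freedom"))
    }
    fml <- stats::reformulate(preds, response)
    fit <- stats::lm(fml, data = data)
    if (fit$rank < p + 1) {
      return(tibble::tibble(rung = i, predictors = list(preds),
                            model = list(NULL), adj_r_squared = NA_real_,
                            r_squared = NA_real_, improved = NA,
                            fittable = FALSE, note = "rank-deficient design"))
    }
    sm <- strength_model(fit, data, preds, response)
    imp <- is.finite(prev_adj) && sm$adj_r_squared > prev_adj || i == 1
    prev_adj <<- sm$adj_r_squared
    tibble::tibble(rung = i, predictors = list(preds), model = list(sm),
                   adj_r_squared = sm$adj_r_squared,
                   r_squared = sm$r_squared,
                   improved = if (i == 1) NA else imp,
                   fittable = TRUE, note = NA_character_)
  })
  class(out) <- c("ladder_fit", class(out))
  out
}

# Wrap an lm fit into the package's regression-model container with
# standardized coefficients and 95% CIs.
strength_model <- function(fit, data, predictors, response) {
  # noiseless synthetic cohorts fit perfectly; that warning is expected
  s <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  co <- s$coefficients
  # standardized coefficients: refit on z-scored variables
  zd <- data[c(response, predictors)]
  zd <- tibble::as_tibble(lapply(zd, function(v) as.numeric(scale(v))))
  zfit <- stats::lm(stats::reformulate(predictors, response), data = zd)
  beta <- stats::coef(zfit)[-1]
  coefs <- tibble::tibble(
    term = rownames(co),
    B = co[, "Estimate"],
    beta = c(NA_real_, unname(beta[predictors])),
    p_value = co[, "Pr(>|t|)"],
    ci_lower = ci[, 1],
    ci_upper = ci[, 2])
  structure(list(
    response = response, predictors = predictors,
    coefficients = coefs,
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    n = nrow(data),
    fit = fit), class = "strength_model")
}

#' Predict femoral strength from a regression model
#'
#' Evaluates the linear predictor `B0 + sum(Bi * xi)` of a fitted
#' [fit_ladder()] rung or of a reference coefficient table (see
#' [reference_strength_models()]). Every predictor of the model must be
#' supplied.
#'
#' @param model a `strength_model`, or a tibble with columns `term` and
#'   `estimate` including an `(Intercept)` row.
#' @param covariates named list / one-row data frame of covariate values.
#' @return predicted strength (N), a single number.
#' @export
#' @examples
#' m <- reference_strength_models()$control
#' predict_strength(m, list(fn_t_score = -1.79, bmi = 23.72, p1np = 54.3))
predict_strength <- function(model, covariates) {
  if (inherits(model, "strength_model")) {
    terms <- model$coefficients$term
    est <- stats::setNames(model$coefficients$B, terms)
  } else if (is.data.frame(model) && all(c("term", "estimate") %in% names(model))) {
    est <- stats::setNames(model$estimate, model$term)
  } else stop("model must be a strength_model or a term/estimate table")
  if (!"(Intercept)" %in% names(est)) stop("model lacks an (Intercept) term")
  covariates <- as.list(covariates)
  needed <- setdiff(names(est), "(Intercept)")
  miss <- setdiff(needed, names(covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  val <- est[["(Intercept)"]]
  for (nm in needed) val <- val + est[[nm]] * as.numeric(covariates[[nm]])
  unname(val)
}

#' The published model ladder preset
#'
#' The hierarchical ladder used to compare predictive models of femoral
#' strength: femoral neck T score as the base, then pentosidine, age,
#' HbA1c, P1NP (and optionally BMI, C-peptide) added in order.
#'
#' @param extended include the BMI and C-peptide rungs (default FALSE).
#' @return list with `base` and `additions`, ready for [fit_ladder()].
#' @export
reference_ladder <- function(extended = FALSE) {
  adds <- c("pentosidine", "age", "hba1c", "p1np")
  if (extended) adds <- c(adds, "bmi", "c_peptide")
  list(base = "fn_t_score", additions = adds)
}

#' @export
print.strength_model <- function(x, ...) {
  cat("<strength_model> ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "),
      "  (n = ", x$n, ", adj R^2 = ", format(x$adj_r_squared, digits = 4),
      ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
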