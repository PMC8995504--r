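test_that("separated samples give U = 0 and the enumerated p", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)  # 2 / choose(6, 3)
  expect_equal(mw$method, "exact")
})

test_that("exact Mann-Whitney p equals brute-force enumeration", {
  set.seed(31)
  for (sizes in list(c(3, 3), c(4, 3), c(5, 5), c(6, 4))) {
    for (rep in 1:5) {
      pooled <- sample(100, sum(sizes))  # tie-free
      x <- pooled[seq_len(sizes[1])]
      y <- pooled[-seq_len(sizes[1])]
      mw <- mann_whitney(x, y)
      expect_equal(mw$method, "exact")
      expect_equal(mw$p_value, mw_enumerate(x, y), tolerance = 1e-12,
                   info = paste(sizes, collapse = "/"))
    }
  }
})

test_that("tied or large samples fall back to the normal approximation", {
  mw <- mann_whitney(c(1, 2, 2, 3), c(2, 4, 5))
  expect_equal(mw$method, "normal")
  big <- mann_whitney(rnorm(15), rnorm(15))
  expect_equal(big$method, "normal")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("type-I error of the exact test at n = (10, 8) is near 0.05", {
  set.seed(202)
  reject <- vapply(1:1000, function(i) {
    mann_whitney(rnorm(10), rnorm(8))$p_value <= 0.05
  }, logical(1))
  rate <- mean(reject)
  # binomial SE at p = 0.05, n = 1000 is 0.0069; allow 3 SE plus the
  # discreteness of the exact null distribution
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("spearman is rank-invariant and detects reversals", {
  x <- c(2, 5, 1, 9, 7, 3)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  cs <- spearman_cor(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(cs$rho))
  expect_equal(cs$method, "undefined")
})

test_that("exact spearman p equals full permutation enumeration", {
  set.seed(7)
  for (rep in 1:5) {
    x <- sample(50, 5)
    y <- sample(50, 5)
    sp <- spearman_cor(x, y)
    expect_equal(sp$method, "exact")
    expect_equal(sp$p_value, spearman_permute(x, y), tolerance = 1e-12)
  }
})

test_that("noiseless cohorts are recovered exactly by the ladder", {
  spec <- cohort_spec(n_t2dm = 12, n_control = 10, noise_sd = 0, seed = 3)
  co <- generate_cohort(spec)
  truth <- attr(co, "truth")$coef_t2dm
  t2 <- co[co$group == "t2dm", ]
  lad <- fit_ladder(t2, base = "fn_t_score",
                    additions = c("pentosidine", "age", "hba1c", "p1np"))
  top <- lad$model[[5]]
  expect_equal(top$adj_r_squared, 1, tolerance = 1e-10)
  got <- stats::setNames(top$coefficients$B, top$coefficients$term)
  for (nm in names(truth)) {
    expect_equal(got[[nm]], truth[[nm]], tolerance = 1e-8)
  }
})

test_that("prediction at the covariate mean equals the mean response", {
  spec <- cohort_spec(n_t2dm = 15, n_control = 10, noise_sd = 300, seed = 8)
  co <- generate_cohort(spec)
  t2 <- co[co$group == "t2dm", ]
  lad <- fit_ladder(t2, base = "fn_t_score", additions = c("age", "p1np"))
  m <- lad$model[[3]]
  at_mean <- predict_strength(m, lapply(t2[m$predictors], mean))
  expect_equal(at_mean, mean(t2$strength), tolerance = 1e-8)
})

test_that("pure-noise predictors do not raise adjusted R^2 in expectation", {
  set.seed(99)
  diffs <- vapply(1:500, function(i) {
    n <- 20
    x <- rnorm(n)
    y <- 2 * x + rnorm(n)
    z <- rnorm(n)  # pure noise
    d <- tibble::tibble(strength = y, x = x, z = z)
    lad <- fit_ladder(d, base = "x", additions = "z")
    lad$adj_r_squared[2] - lad$adj_r_squared[1]
  }, numeric(1))
  expect_lte(mean(diffs), 0.005)
})

test_that("degenerate rungs are reported as unfittable", {
  d <- tibble::tibble(strength = rnorm(4), a = rnorm(4), b = rnorm(4),
                      c = rnorm(4))
  lad <- fit_ladder(d, base = "a", additions = c("b", "c"))
  expect_true(lad$fittable[1])
  expect_false(lad$fittable[3])
  expect_match(lad$note[3], "degrees of freedom")
  # rank deficiency: duplicated predictor column
  d2 <- tibble::tibble(strength = rnorm(10), a = rnorm(10))
  d2$b <- d2$a
  lad2 <- fit_ladder(d2, base = "a", additions = "b")
  expect_false(lad2$fittable[2])
  expect_match(lad2$note[2], "rank-deficient")
})

test_that("ladder fits are invariant to row order", {
  spec <- cohort_spec(n_t2dm = 12, n_control = 8, noise_sd = 200, seed = 4)
  co <- generate_cohort(spec)
  t2 <- co[co$group == "t2dm", ]
  lad1 <- fit_ladder(t2, "fn_t_score", c("pentosidine", "age"))
  lad2 <- fit_ladder(t2[sample(nrow(t2)), ], "fn_t_score",
                     c("pentosidine", "age"))
  expect_equal(lad1$adj_r_squared, lad2$adj_r_squared, tolerance = 1e-12)
  expect_equal(lad1$model[[3]]$coefficients$B, lad2$model[[3]]$coefficients$B,
               tolerance = 1e-10)
})

test_that("parameter recovery holds within 3 SE on noisy small cohorts", {
  # 1% strength-SD noise, n = 50/group, 200 seeds: >= 95% of fitted
  # diabetic-arm coefficients within 3 SE of the generating values
  ok <- vapply(1:200, function(s) {
    spec <- cohort_spec(n_t2dm = 50, n_control = 3, noise_sd = 30, seed = s)
    co <- generate_cohort(spec)
    truth <- attr(co, "truth")$coef_t2dm
    t2 <- co[co$group == "t2dm", ]
    fit <- stats::lm(strength ~ fn_t_score + pentosidine + age + hba1c + p1np,
                     data = t2)
    est <- summary(fit)$coefficients
    nm <- c("fn_t_score", "pentosidine", "age", "hba1c", "p1np")
    all(abs(est[nm, "Estimate"] - unlist(truth[nm])) <=
          3 * est[nm, "Std. Error"])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("reference model constants and prediction contract hold", {
  ref <- reference_strength_models()
  expect_equal(predict_strength(ref$t2dm,
                                list(fn_t_score = 0, pentosidine = 0, age = 0,
                                     hba1c = 0, p1np = 0)), 29240.848)
  expect_equal(predict_strength(ref$control,
                                list(fn_t_score = 0, bmi = 0, p1np = 0)),
               9584.833)
  expect_error(predict_strength(ref$control, list(fn_t_score = 0)),
               "missing covariate")
})

test_that("collinearity screen keeps the stronger correlate of strength", {
  set.seed(12)
  n <- 40
  bmd <- rnorm(n)
  tscore <- bmd + rnorm(n, sd = 0.2)        # nearly collinear pair
  strength <- 3 * tscore + rnorm(n, sd = 0.5) # strength tracks tscore more
  d <- tibble::tibble(strength = strength, bmd = bmd, tscore = tscore,
                      age = rnorm(n))
  sc <- screen_collinearity(d, c("bmd", "tscore", "age"))
  expect_equal(sc$keep, c("tscore", "age"))
  expect_equal(sc$dropped$dropped, "bmd")
})

test_that("cohort summary reports quartiles and group comparison", {
  spec <- cohort_spec(seed = 6)
  co <- generate_cohort(spec)
  sm <- cohort_summary(co, c("hba1c", "strength"))
  expect_equal(nrow(sm), 2)
  h <- co$hba1c[co$group == "t2dm"]
  expect_equal(sm$median_t2dm[1], unname(stats::quantile(h, 0.5)))
  expect_equal(sm$q1_t2dm[1], unname(stats::quantile(h, 0.25)))
  # diabetic arm is generated with much higher HbA1c
  expect_lt(sm$p_value[1], 0.05)
})
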