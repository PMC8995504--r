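test_that("phantom insert ROI means sit on the generating line", {
  ph <- femstrength:::default_phantom(c(48, 48, 16))
  g <- generate_phantom_volume(ph, hu_slope = 1000, hu_intercept = 0,
                               noise_sd = 0)
  means <- vapply(seq_along(ph$insert_rois), function(i) {
    roi <- ph$insert_rois[[i]]
    mean(g$volume$intensities[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2],
                              roi$z[1]:roi$z[2]])
  }, numeric(1))
  expect_equal(means, c(50, 100, 200))
  expect_equal(g$truth$hu_slope, 1000)
})

test_that("recovered slope spread matches the delta-method OLS SD", {
  # 100 seeds of a noisy phantom; ROI size and noise fixed by the design
  dims <- c(36L, 24L, 14L)
  n <- 3L; w <- 10L
  rois <- lapply(1:3, function(i) {
    x0 <- (i - 1L) * 12L + 1L
    list(x = c(x0, x0 + w - 1L), y = c(1L, 10L), z = c(1L, 10L))
  })
  ph <- phantom_spec(c(0.05, 0.1, 0.2), rois)
  n_vox <- 10^3
  sigma <- 5
  slopes <- vapply(1:100, function(s) {
    g <- generate_phantom_volume(ph, dims = dims, hu_slope = 600,
                                 hu_intercept = 0, noise_sd = sigma, seed = s)
    fit_calibration(g$volume, ph)$slope
  }, numeric(1))
  expect_equal(mean(slopes), 1 / 600, tolerance = 1e-3)
  sd_theory <- slope_sd_delta(c(30, 60, 120), c(0.05, 0.1, 0.2),
                              sigma, n_vox)
  # 100 draws estimate an SD to ~7% relative; allow 3x that
  expect_equal(sd(slopes), sd_theory, tolerance = 0.25)
})

test_that("volume generation is deterministic for a fixed seed", {
  a <- generate_femur_volume(dims = c(16, 16, 32), noise_sd = 8, seed = 42)
  b <- generate_femur_volume(dims = c(16, 16, 32), noise_sd = 8, seed = 42)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$rho_apparent_field, b$truth$rho_apparent_field)
  c <- generate_femur_volume(dims = c(16, 16, 32), noise_sd = 8, seed = 43)
  expect_false(identical(a$volume$intensities, c$volume$intensities))
})

test_that("femur density field respects the requested ranges and mask", {
  g <- generate_femur_volume(dims = c(24, 24, 48), density_range = c(0.1, 1.8))
  rho <- g$truth$rho_apparent_field
  mask <- g$truth$bone_mask
  expect_true(any(mask))
  expect_gte(min(rho[mask]), 0.1)
  expect_lte(max(rho[mask]), 1.8)
  # phantom ROIs must not intersect the bone object
  for (roi in g$phantom$insert_rois) {
    expect_false(any(mask[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2],
                          roi$z[1]:roi$z[2]]))
  }
})

test_that("column preset is a rectangular prism of uniform density", {
  g <- generate_femur_volume(dims = c(12, 12, 24), preset = "column",
                             column_density = 0.5, column_halfwidth = 3,
                             phantom = NULL)
  mask <- g$truth$bone_mask
  idx <- which(mask, arr.ind = TRUE)
  # bounding box fully occupied = rectangular prism
  expect_equal(nrow(idx), prod(apply(idx, 2, function(v) diff(range(v)) + 1)))
  expect_equal(unique(g$truth$rho_apparent_field[mask]), 0.5)
})

test_that("degenerate shapes and misplaced phantoms are rejected", {
  expect_error(generate_femur_volume(dims = c(16, 16, 32), shell_voxels = 0),
               "zero-thickness")
  bad <- phantom_spec(c(0.05, 0.1, 0.2), lapply(1:3, function(i) {
    list(x = c(1L, 200L), y = c(1L, 4L), z = c(4L * i - 3L, 4L * i))
  }))
  expect_error(generate_femur_volume(dims = c(16, 16, 32), phantom = bad),
               "outside")
  expect_error(phantom_spec(c(0.2, 0.1), list(list(x = c(1, 2), y = c(1, 2),
                                                   z = c(1, 2)),
                                              list(x = c(3, 4), y = c(1, 2),
                                                   z = c(1, 2)))),
               "increasing")
  expect_error(phantom_spec(c(0.1, 0.2), list(list(x = c(1L, 4L), y = c(1L, 4L),
                                                   z = c(1L, 4L)),
                                              list(x = c(2L, 5L), y = c(1L, 4L),
                                                   z = c(1L, 4L)))),
               "overlap")
})

test_that("cohort generation honours sizes, groups and determinism", {
  spec <- cohort_spec(n_t2dm = 10, n_control = 8, seed = 5)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 18)
  expect_equal(sum(co$group == "t2dm"), 10)
  expect_equal(sum(co$group == "control"), 8)
  expect_false(anyDuplicated(co$subject) > 0)
  co2 <- generate_cohort(spec)
  expect_identical(co$strength, co2$strength)
})

test_that("noiseless cohorts are exactly linear in their covariates", {
  spec <- cohort_spec(n_t2dm = 12, n_control = 10, noise_sd = 0, seed = 2)
  co <- generate_cohort(spec)
  truth <- attr(co, "truth")
  t2 <- co[co$group == "t2dm", ]
  cf <- truth$coef_t2dm
  lp <- cf[["(Intercept)"]]
  for (nm in setdiff(names(cf), "(Intercept)")) lp <- lp + cf[[nm]] * t2[[nm]]
  expect_equal(t2$strength, unname(lp), tolerance = 1e-12)
})

test_that("negative generating slopes yield negative sample correlations", {
  # large-n sign check for the diabetic-arm structure (strength falls
  # with pentosidine and age)
  spec <- cohort_spec(n_t2dm = 5000, n_control = 3, noise_sd = 400, seed = 9)
  co <- generate_cohort(spec)
  t2 <- co[co$group == "t2dm", ]
  expect_lt(cor(t2$strength, t2$pentosidine, method = "spearman"), 0)
  expect_lt(cor(t2$strength, t2$age, method = "spearman"), 0)
  expect_gt(cor(t2$strength, t2$fn_t_score, method = "spearman"), 0)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_t2dm = 2), ">= 3")
  bad_r <- default_correlation()
  bad_r[1, 2] <- 0.5  # asymmetric
  expect_error(cohort_spec(correlation = bad_r), "symmetric")
  npsd <- default_correlation()
  npsd[1, 2] <- npsd[2, 1] <- 1.5
  expect_error(cohort_spec(correlation = npsd), "positive semi-definite")
})
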