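test_that("lattice counting: 2x2x2 mask gives 8 elements and 27 nodes", {
  rho <- array(0.5, dim = c(2, 2, 2))
  mask <- array(TRUE, dim = c(2, 2, 2))
  model <- build_mesh(rho, mask, element_size = 1.5, spacing = c(1.5, 1.5, 1.5))
  expect_equal(nrow(model$elements), 8)
  expect_equal(nrow(model$nodes), 27)
  expect_equal(model$femoral_height, 2 * 1.5)
})

test_that("single voxel gives a minimal 1-element, 8-node mesh", {
  rho <- array(0.3, dim = c(1, 1, 1))
  mask <- array(TRUE, dim = c(1, 1, 1))
  model <- build_mesh(rho, mask, element_size = 2, spacing = c(2, 2, 2))
  expect_equal(nrow(model$elements), 1)
  expect_equal(nrow(model$nodes), 8)
  expect_equal(length(unique(as.vector(model$elements))), 8)
})

test_that("L-shaped mask meshes conformingly with hand-enumerated nodes", {
  mask <- array(FALSE, dim = c(3, 1, 3))
  mask[1:3, 1, 1] <- TRUE   # horizontal arm of the L
  mask[1, 1, 2:3] <- TRUE   # vertical arm
  rho <- array(0.5, dim = dim(mask))
  model <- build_mesh(rho, mask, element_size = 1, spacing = c(1, 1, 1))
  expect_equal(nrow(model$elements), 5)
  # brute-force lattice enumeration of unique corner sites
  cells <- which(mask, arr.ind = TRUE)
  corners <- unique(do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    expand.grid(cells[i, 1] + 0:1, cells[i, 2] + 0:1, cells[i, 3] + 0:1)
  })))
  expect_equal(nrow(model$nodes), nrow(corners))
  # conformity: no duplicated node coordinates
  expect_false(anyDuplicated(model$nodes) > 0)
})

test_that("total element volume equals voxel count times element volume", {
  g <- small_femur(seed = 3)
  line <- fit_calibration(g$volume, g$phantom)
  dv <- apparent_to_ash(hu_to_apparent(g$volume, line))
  model <- build_mesh(dv, g$truth$bone_mask, element_size = 1.5)
  kept <- sum(g$truth$bone_mask) - model$n_dropped_voxels
  expect_equal(nrow(model$elements) * 1.5^3, kept * 1.5^3)
})

test_that("islands outside the largest 6-connected component are dropped", {
  mask <- array(FALSE, dim = c(8, 8, 8))
  mask[2:5, 2:5, 2:5] <- TRUE    # main blob: 64 voxels
  mask[8, 8, 8] <- TRUE          # disconnected island
  rho <- array(0.5, dim = dim(mask))
  expect_message(model <- build_mesh(rho, mask, element_size = 1,
                                     spacing = c(1, 1, 1)), "dropped 1")
  expect_equal(nrow(model$elements), 64)
  expect_equal(model$n_dropped_voxels, 1)
})

test_that("resampling supports integer refinement and coarsening", {
  rho <- array(0.5, dim = c(4, 4, 8))
  mask <- array(TRUE, dim = c(4, 4, 8))
  fine <- build_mesh(rho, mask, element_size = 0.75, spacing = c(1.5, 1.5, 1.5))
  expect_equal(nrow(fine$elements), 4 * 4 * 8 * 8)
  coarse <- build_mesh(rho, mask, element_size = 3, spacing = c(1.5, 1.5, 1.5))
  expect_equal(nrow(coarse$elements), 2 * 2 * 4)
  expect_equal(unique(coarse$element_rho), 0.5)
  expect_error(build_mesh(rho, mask, element_size = 2.1,
                          spacing = c(1.5, 1.5, 1.5)), "integer multiple")
})

test_that("pads add one cross-section of elements per layer on a column", {
  fx <- column_fixture(nx = 3, ny = 2, nz = 5)
  n <- nrow(fx$model$elements)
  padded <- attach_pads(fx$model, pad_thickness = 1L)
  expect_equal(nrow(padded$elements), n + 2 * 3 * 2)
  padded2 <- attach_pads(fx$model, pad_thickness = 2L)
  expect_equal(nrow(padded2$elements), n + 2 * 2 * 3 * 2)
  # femoral height excludes pads
  expect_equal(padded$femoral_height, fx$model$femoral_height)
  expect_error(attach_pads(fx$model, pad_thickness = 0), ">= 1")
})

test_that("pad-bone interface sites carry exactly one node (tie by merging)", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 3)
  padded <- attach_pads(fx$model, pad_thickness = 1L)
  expect_false(anyDuplicated(padded$nodes) > 0)
  # top/bottom node sets live on the flat outer pad faces
  zt <- padded$nodes[padded$node_sets$top_surface, 3]
  zb <- padded$nodes[padded$node_sets$bottom_surface, 3]
  expect_equal(length(unique(zt)), 1)
  expect_equal(length(unique(zb)), 1)
  expect_gt(min(zt), max(padded$nodes[fx$model$node_sets$top_surface, 3]) - 1e-9)
})
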