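test_that("single-element stiffness is symmetric with zero row sums", {
  fx <- column_fixture(nx = 1, ny = 1, nz = 1, E = 1, nu = 0)
  K <- as.matrix(assemble(fx$model, fx$props))
  expect_equal(K, t(K), tolerance = 1e-12)
  # rigid-body translations are zero-energy: rows sum to zero per direction
  for (d in 1:3) {
    u <- numeric(24); u[seq(d, 24, by = 3)] <- 1
    expect_equal(max(abs(K %*% u)), 0, tolerance = 1e-12)
  }
})

test_that("stiffness operator has exactly six rigid-body modes", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 2, E = 100, nu = 0.3)
  K <- as.matrix(assemble(fx$model, fx$props))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_equal(sum(ev < 1e-9 * scale), 6)
  expect_true(all(ev > -1e-9 * scale))
})

test_that("patch test: affine boundary displacement gives the exact field", {
  fx <- column_fixture(nx = 3, ny = 3, nz = 3, E = 200, nu = 0.25)
  model <- fx$model
  # affine field u = A x with a full 3x3 A (uniform strain + rotation)
  A <- matrix(c(0.002, 0.001, 0, 0.0005, -0.001, 0.002,
                0, 0.0015, -0.0005), 3, 3, byrow = TRUE)
  exact <- model$nodes %*% t(A)
  bound <- which(apply(model$nodes, 1, function(p) {
    any(abs(p - apply(model$nodes, 2, min)) < 1e-9 |
        abs(p - apply(model$nodes, 2, max)) < 1e-9)
  }))
  pdofs <- as.vector(rbind(3 * bound - 2, 3 * bound - 1, 3 * bound))
  pvals <- as.vector(t(exact[bound, ]))
  U <- femstrength:::fe_linear_solve(model, fx$props, pdofs, pvals)
  got <- matrix(U, ncol = 3, byrow = TRUE)
  expect_equal(got, unname(exact), tolerance = 1e-10)
})

test_that("two-element column compliance equals series springs", {
  # hand-computed series sum for E1, E2 in series under unit load (nu = 0)
  cells <- cbind(1L, 1L, 1:2)
  model <- femstrength:::mesh_from_cells(cells, c(0.5, 0.5),
                                         rep("bone", 2), 2)
  for (Es in list(c(100, 100), c(50, 200))) {
    props <- tibble::tibble(E_MPa = Es, nu = 0, sigma_MPa = Inf)
    sol <- solve_compression(model, props, target_deformation = 0.01,
                             n_steps = 1, bottom_mode = "roller")
    # series springs: k_i = E_i A / h per element
    A <- 4; h <- 2
    k <- 1 / sum(h / (Es * A))
    u <- 0.01 * model$femoral_height
    expect_equal(sol$femoral_strength, k * u, tolerance = 1e-8)
  }
})

test_that("uniform elastic column reaction equals E*eps*A", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 8, E = 1000, nu = 0)
  sol <- solve_compression(fx$model, fx$props, target_deformation = 0.01,
                           n_steps = 2)
  expect_equal(sol$femoral_strength, 1000 * 0.01 * fx$area, tolerance = 1e-8)
  # nu = 0.4 with roller ends is still exact uniaxial
  fx4 <- column_fixture(nx = 2, ny = 2, nz = 8, E = 1000, nu = 0.4)
  sol4 <- solve_compression(fx4$model, fx4$props, target_deformation = 0.01,
                            n_steps = 2, bottom_mode = "roller")
  expect_equal(sol4$femoral_strength, 1000 * 0.01 * fx4$area, tolerance = 1e-6)
})

test_that("perfectly plastic column strength equals sigma*A", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 6, E = 1000, nu = 0, sigy = 2)
  sol <- solve_compression(fx$model, fx$props, target_deformation = 0.04,
                           n_steps = 20, bottom_mode = "roller")
  expect_equal(sol$femoral_strength, 2 * fx$area, tolerance = 0.01)
  # reaction history is monotone non-decreasing under monotone loading,
  # up to the relative residual tolerance of the solve
  expect_true(all(diff(sol$reaction_history$reaction_N) >
                    -2e-5 * sol$femoral_strength))
  # plateau: post-yield reaction stays at the limit load
  expect_equal(sol$reaction_history$reaction_N[10], 2 * fx$area,
               tolerance = 0.01)
})

test_that("global equilibrium and plastic consistency hold at every step", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 6, E = 1000, nu = 0.3, sigy = 3)
  sol <- solve_compression(fx$model, fx$props, target_deformation = 0.04,
                           n_steps = 10)
  expect_lt(sol$equilibrium_rel, 1e-6)
  expect_lt(sol$max_plastic_overshoot, 1e-9)
})

test_that("external work equals stored energy in the elastic regime", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 6, E = 500, nu = 0.3, sigy = Inf)
  sol <- solve_compression(fx$model, fx$props, target_deformation = 0.01,
                           n_steps = 4)
  expect_equal(sol$external_work, sol$strain_energy, tolerance = 1e-6)
})

test_that("sparse and dense solves agree to 1e-8 on small meshes", {
  fx <- column_fixture(nx = 2, ny = 2, nz = 8, E = 800, nu = 0.3, sigy = Inf)
  expect_lte(fx$m, 128)
  s1 <- solve_compression(fx$model, fx$props, target_deformation = 0.01,
                          n_steps = 2, linear_solver = "sparse")
  s2 <- solve_compression(fx$model, fx$props, target_deformation = 0.01,
                          n_steps = 2, linear_solver = "dense")
  expect_equal(max(abs(s1$displacement - s2$displacement)), 0,
               tolerance = 1e-8)
  expect_equal(s1$femoral_strength, s2$femoral_strength, tolerance = 1e-8)
})

test_that("unassigned or invalid materials are rejected", {
  fx <- column_fixture(nx = 1, ny = 1, nz = 2)
  bad <- fx$props[1, ]
  expect_error(solve_compression(fx$model, bad, target_deformation = 0.01),
               "one material row per element")
  zero <- fx$props; zero$E_MPa[1] <- 0
  expect_error(assemble(fx$model, zero), "positive elastic modulus")
})
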