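# Displacement-controlled compression of a voxel hexahedral model with
# small-strain isotropic elasticity and von Mises perfect plasticity
# (associative radial return). Modified Newton: the algorithmically
# consistent tangent is assembled at the start of each displacement step
# (and refreshed if convergence stalls); linear solves reuse the sparse
# Cholesky factor.

# Vectorized stress update over all elements at one Gauss point.
# e_el: elastic strain (m x 6, engineering shear); returns stresses,
# plastic strain increments and radial-return scaling beta.
stress_update_gp <- function(eps, epsP, lam, mu, sigy) {
  e_el <- eps - epsP
  tr <- e_el[, 1] + e_el[, 2] + e_el[, 3]
  sn <- 2 * mu * e_el[, 1:3] + lam * tr
  tau <- mu * e_el[, 4:6]
  p <- (sn[, 1] + sn[, 2] + sn[, 3]) / 3
  s <- sn - p
  J2 <- 0.5 * (s[, 1]^2 + s[, 2]^2 + s[, 3]^2) + tau[, 1]^2 + tau[, 2]^2 + tau[, 3]^2
  qvm <- sqrt(3 * J2)
  yielded <- is.finite(sigy) & qvm > sigy
  beta <- ifelse(yielded, sigy / pmax(qvm, 1e-300), 1)
  s_new <- s * beta
  tau_new <- tau * beta
  sig <- cbind(s_new + p, tau_new)
  dEpsP <- cbind((1 - beta) * s / (2 * mu), (1 - beta) * tau / mu)
  list(sig = sig, dEpsP = dEpsP, beta = beta, yielded = yielded,
       s = s, tau = tau, qvm = qvm)
}

# Consistent-tangent ingredients for the radial-return update at one
# Gauss point: the radial scaling beta per element and, for yielded
# points, the rank-one dyad coefficient and unit flow direction. zeta
# keeps a tiny stiffness along the flow direction so the assembled
# tangent stays positive definite at the limit load.
consistent_tangent_gp <- function(upd, mu, zeta = 1e-6) {
  m <- length(upd$beta)
  dy <- NULL
  if (any(upd$yielded)) {
    nv <- cbind(upd$s, upd$tau)
    nrm <- sqrt(rowSums(nv[, 1:3, drop = FALSE]^2) +
                2 * rowSums(nv[, 4:6, drop = FALSE]^2))
    nv <- nv / pmax(nrm, 1e-300)
    coef <- ifelse(upd$yielded, 2 * mu * (upd$beta - zeta), 0)
    dy <- list(coef = coef, nv = nv)
  }
  list(beta = upd$beta, dyad = dy)
}

# Precompute solver context shared across steps
fe_context <- function(model, props) {
  m <- nrow(model$elements)
  ndof <- 3L * nrow(model$nodes)
  edof <- element_dofs(model$elements)
  quad <- hex_B_matrices(model$element_size)
  scatter <- Matrix::sparseMatrix(i = as.vector(edof), j = seq_len(m * 24L),
                                  x = 1, dims = c(ndof, m * 24L))
  lam <- props$E_MPa * props$nu / ((1 + props$nu) * (1 - 2 * props$nu))
  mu <- props$E_MPa / (2 * (1 + props$nu))
  list(m = m, ndof = ndof, edof = edof, quad = quad, scatter = scatter,
       lam = lam, mu = mu, kappa = lam + 2 * mu / 3, sigy = props$sigma_MPa)
}

# Internal forces and (optionally) consistent tangent at displacement U,
# trial from committed plastic strains epsP (list of 8 m x 6 matrices).
fe_internal <- function(U, ctx, epsP, want_tangent = FALSE, zeta = 1e-6) {
  fe <- matrix(0, ctx$m, 24)
  newP <- vector("list", 8)
  tang <- if (want_tangent) list(beta = vector("list", 8),
                                 dyads = vector("list", 8)) else NULL
  max_over <- 0
  energy <- 0
  Ue <- matrix(U[ctx$edof], ctx$m, 24)
  for (q in 1:8) {
    Bq <- ctx$quad$B[[q]]
    eps <- Ue %*% t(Bq)
    upd <- stress_update_gp(eps, epsP[[q]], ctx$lam, ctx$mu, ctx$sigy)
    fe <- fe + (upd$sig %*% Bq) * ctx$quad$detJ
    newP[[q]] <- epsP[[q]] + upd$dEpsP
    if (want_tangent) {
      ct <- consistent_tangent_gp(upd, ctx$mu, zeta)
      tang$beta[[q]] <- ct$beta
      tang$dyads[q] <- list(ct$dyad)  # keep NULL slots (purely elastic gp)
    }
    over <- ifelse(is.finite(ctx$sigy) & ctx$sigy > 0,
                   upd$qvm * upd$beta / ctx$sigy - 1, 0)
    max_over <- max(max_over, over, 0)
    e_el <- eps - newP[[q]]
    # engineering convention: sigma:eps = sum over normal + tau * gamma
    energy <- energy + 0.5 * sum(upd$sig * e_el) * ctx$quad$detJ
  }
  fint <- as.numeric(ctx$scatter %*% as.vector(fe))
  list(fint = fint, newP = newP, tang = tang, max_overshoot = max_over,
       strain_energy = energy)
}

#' Solve displacement-controlled compression of a hexahedral model
#'
#' Drives the top surface of the model downward to a target nominal
#' compressive deformation (displacement divided by bone-only femoral
#' height), with the bottom surface fully fixed, and integrates the
#' elastic--perfectly-plastic response in equal displacement steps.
#' Femoral strength is the reaction force on the driven surface at the
#' final (4% by default) step.
#'
#' The driven top-surface nodes have only their z displacement prescribed
#' (in-plane freedoms left free, a platen-on-pad analogy) unless
#' `top_clamped = TRUE`.
#'
#' @param model a `hex_model` (with or without pads).
#' @param materials a `material_table`, or an [element_materials()]-style
#'   tibble with columns `E_MPa`, `nu`, `sigma_MPa` (use `sigma_MPa = Inf`
#'   for purely elastic elements).
#' @param target_deformation nominal compressive strain target
#'   (default 0.04).
#' @param n_steps equal displacement increments (default 20).
#' @param tol relative residual tolerance (default 1e-6).
#' @param max_iter iteration budget per step (default 100).
#' @param top_clamped prescribe in-plane top-surface dofs to zero as well.
#' @param bottom_mode `"clamped"` (default; all bottom-surface dofs fixed,
#'   the compression-test boundary condition) or `"roller"` (only z fixed,
#'   with minimal in-plane pinning to remove rigid-body modes; used by the
#'   analytic column oracles, which assume frictionless ends).
#' @param linear_solver `"sparse"` (Cholesky, default) or `"dense"`
#'   (small-mesh reference path).
#' @param zeta regularization of the plastic tangent (default 1e-6).
#' @param verbose print per-step convergence.
#' @return object of class `fe_solution`: `displacement` (n_nodes x 3 mm),
#'   `reaction_history` (tibble: `step`, `deformation`, `displacement_mm`,
#'   `reaction_N`, `iterations`, `residual`), `femoral_strength` (N),
#'   `convergence` (tibble), `equilibrium_rel`, `external_work`,
#'   `strain_energy`, `max_plastic_overshoot`, `n_elements`, `n_nodes`.
#' @export
solve_compression <- function(model, materials,
                              target_deformation = 0.04,
                              n_steps = 20L, tol = 1e-6, max_iter = 100L,
                              top_clamped = FALSE,
                              bottom_mode = c("clamped", "roller"),
                              linear_solver = c("sparse", "dense"),
                              zeta = 1e-6, verbose = FALSE) {
  stopifnot(inherits(model, "hex_model"))
  if (target_deformation <= 0) stop("target_deformation must be positive")
  linear_solver <- match.arg(linear_solver)
  props <- if (inherits(materials, "material_table")) {
    element_materials(model, materials)
  } else materials
  if (nrow(props) != nrow(model$elements)) stop("one material row per element required")
  ctx <- fe_context(model, props)

  bottom_mode <- match.arg(bottom_mode)
  top <- model$node_sets$top_surface
  bot <- model$node_sets$bottom_surface
  if (!length(top) || !length(bot)) stop("node sets undefined")
  if (bottom_mode == "clamped") {
    fixed <- as.vector(rbind(3L * bot - 2L, 3L * bot - 1L, 3L * bot))
  } else {
    # roller: z fixed everywhere on the bottom; pin in-plane rigid modes at
    # two corner nodes (translation at one, rotation via a second)
    xy <- model$nodes[bot, 1:2, drop = FALSE]
    a <- bot[which.min(xy[, 1] + xy[, 2])]
    b <- bot[which.max(xy[, 1] - xy[, 2])]
    fixed <- c(3L * bot, 3L * a - 2L, 3L * a - 1L, 3L * b - 1L)
  }
  driven <- 3L * top
  if (top_clamped) fixed <- c(fixed, 3L * top - 2L, 3L * top - 1L)
  constrained <- c(fixed, driven)
  free <- setdiff(seq_len(ctx$ndof), constrained)

  u_total <- target_deformation * model$femoral_height
  U <- numeric(ctx$ndof)
  epsP <- replicate(8, matrix(0, ctx$m, 6), simplify = FALSE)

  hist <- vector("list", n_steps)
  conv <- vector("list", n_steps)
  Kfact <- NULL
  Kff_dense <- NULL
  refactor <- function(tang) {
    Kv <- batched_element_stiffness(ctx$kappa, ctx$mu, tang$beta, tang$dyads,
                                    ctx$quad)
    K <- assemble_global(ctx$edof, Kv, ctx$ndof)
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    if (linear_solver == "dense") {
      Kff_dense <<- as.matrix(Kff)
    } else if (is.null(Kfact)) {
      Kfact <<- Matrix::Cholesky(Kff, LDL = FALSE)
    } else {
      # sparsity pattern is fixed: reuse the symbolic factorization
      Kfact <<- Matrix::update(Kfact, Kff)
    }
  }
  lin_solve <- function(rhs) {
    if (linear_solver == "dense") solve(Kff_dense, rhs)
    else as.numeric(Matrix::solve(Kfact, rhs))
  }

  work <- 0; R_prev <- 0; u_prev <- 0
  final <- NULL
  dU_step <- NULL
  have_factor <- FALSE
  for (step in seq_len(n_steps)) {
    u_top <- -u_total * step / n_steps
    U_before <- U
    U[driven] <- u_top
    # secant predictor: repeat the previous step's converged increment
    if (!is.null(dU_step)) U[free] <- U[free] + dU_step[free]
    it <- 0
    # reuse the previous factorization; the stall rule below refreshes it
    want_t <- !have_factor
    upd <- NULL
    repeat {
      if (is.null(upd) || (want_t && is.null(upd$tang))) {
        upd <- fe_internal(U, ctx, epsP, want_tangent = want_t, zeta = zeta)
      }
      r_f <- upd$fint[free]
      ref <- max(sqrt(sum(upd$fint[constrained]^2)), 1e-8)
      res <- sqrt(sum(r_f^2)) / ref
      if (res <= tol) { final <- upd; break }
      if (it >= max_iter) {
        stop("compression step ", step, " failed to converge: relative residual ",
             format(res, digits = 4), " after ", it, " iterations")
      }
      if (want_t) { refactor(upd$tang); have_factor <- TRUE }
      delta <- lin_solve(-r_f)
      # backtracking line search: the elastic-plastic residual is only
      # piecewise smooth, so the full Newton step can overshoot
      alpha <- 1
      repeat {
        Utry <- U
        Utry[free] <- U[free] + alpha * delta
        upd_try <- fe_internal(Utry, ctx, epsP, want_tangent = FALSE)
        ref_try <- max(sqrt(sum(upd_try$fint[constrained]^2)), 1e-8)
        res_try <- sqrt(sum(upd_try$fint[free]^2)) / ref_try
        if (res_try < res || alpha <= 1 / 64) break
        alpha <- alpha / 2
      }
      U <- Utry
      upd <- upd_try
      it <- it + 1
      # keep the current factorization while it still reduces the
      # residual well; refresh the consistent tangent when it stalls
      want_t <- !(res_try < 0.7 * res)
    }
    dU_step <- U - U_before
    epsP <- final$newP
    reaction <- -sum(final$fint[driven])
    work <- work + 0.5 * (R_prev + reaction) * (abs(u_top) - u_prev)
    R_prev <- reaction; u_prev <- abs(u_top)
    hist[[step]] <- tibble::tibble(
      step = step, deformation = target_deformation * step / n_steps,
      displacement_mm = abs(u_top), reaction_N = reaction,
      iterations = it, residual = res)
    conv[[step]] <- tibble::tibble(step = step, iterations = it, residual = res)
    if (verbose) {
      message(sprintf("step %d/%d: u = %.4f mm, R = %.1f N, %d iters (res %.2e)",
                      step, n_steps, abs(u_top), reaction, it, res))
    }
  }
  hist <- dplyr::bind_rows(hist)
  # global equilibrium: z components of internal force sum to zero
  fz <- final$fint[seq(3, ctx$ndof, by = 3)]
  eq_rel <- abs(sum(fz)) / max(abs(hist$reaction_N[n_steps]), 1e-8)
  structure(list(
    displacement = matrix(U, ncol = 3, byrow = TRUE),
    reaction_history = hist,
    femoral_strength = hist$reaction_N[n_steps],
    convergence = dplyr::bind_rows(conv),
    equilibrium_rel = eq_rel,
    external_work = work,
    strain_energy = final$strain_energy,
    max_plastic_overshoot = final$max_overshoot,
    n_elements = ctx$m,
    n_nodes = nrow(model$nodes),
    target_deformation = target_deformation),
    class = "fe_solution")
}

# Linear elastic solve with arbitrary prescribed dofs (used by the patch
# test and small verification problems).
fe_linear_solve <- function(model, props, prescribed_dofs, prescribed_vals,
                            dense = FALSE) {
  ctx <- fe_context(model, props)
  K <- assemble(model, props)
  free <- setdiff(seq_len(ctx$ndof), prescribed_dofs)
  U <- numeric(ctx$ndof)
  U[prescribed_dofs] <- prescribed_vals
  rhs <- -as.numeric(K[free, prescribed_dofs, drop = FALSE] %*% U[prescribed_dofs])
  Kff <- K[free, free, drop = FALSE]
  U[free] <- if (dense) solve(as.matrix(Kff), rhs)
             else as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff), rhs))
  U
}

#' @export
print.fe_solution <- function(x, ...) {
  cat("<fe_solution> femoral strength ", format(x$femoral_strength, digits = 6),
      " N at ", 100 * x$target_deformation, "% deformation; ",
      x$n_elements, " elements, ", nrow(x$reaction_history), " steps\n", sep = "")
  invisible(x)
}
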