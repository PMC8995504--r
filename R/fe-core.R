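# Core finite element machinery: trilinear 8-node hexahedra on a regular
# lattice, 2x2x2 Gauss integration, engineering (Voigt) strain ordering
# (xx, yy, zz, xy, yz, zx).

# Corner signs matching the VTK node order used by mesh_from_cells()
hex_corner_signs <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}

# B matrices (6 x 24) and integration factor for a cube of edge h.
# Returns list(B = list of 8 matrices, detJ = (h/2)^3).
hex_B_matrices <- function(h) {
  sg <- hex_corner_signs()
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  Bs <- vector("list", 8)
  for (q in 1:8) {
    xi <- gp[q, 1]; eta <- gp[q, 2]; zeta <- gp[q, 3]
    # dN/dx = dN/dxi * 2/h on the cube
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- sg[a, ]
      dN[a, 1] <- 0.125 * s[1] * (1 + s[2] * eta) * (1 + s[3] * zeta) * 2 / h
      dN[a, 2] <- 0.125 * s[2] * (1 + s[1] * xi) * (1 + s[3] * zeta) * 2 / h
      dN[a, 3] <- 0.125 * s[3] * (1 + s[1] * xi) * (1 + s[2] * eta) * 2 / h
    }
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dN[a, 1]
      B[2, c0 + 2] <- dN[a, 2]
      B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    Bs[[q]] <- B
  }
  list(B = Bs, detJ = (h / 2)^3)
}

# Isotropic elastic 6x6 (engineering shear) from E, nu
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Element dof index matrix (m x 24): node dofs (3i-2, 3i-1, 3i)
element_dofs <- function(elements) {
  m <- nrow(elements)
  edof <- matrix(0L, m, 24)
  for (a in 1:8) {
    edof[, 3 * a - 2] <- 3L * elements[, a] - 2L
    edof[, 3 * a - 1] <- 3L * elements[, a] - 1L
    edof[, 3 * a] <- 3L * elements[, a]
  }
  edof
}

# The isotropic elastoplastic tangent decomposes as
#   D = kappa * Jn + 2 mu beta * P - coef * n n'
# with Jn the volumetric operator (ones on the normal 3x3 block), P the
# engineering deviatoric projector (2P has normals 2(delta-1/3), shears 1),
# and n the unit deviatoric flow direction. The first two pieces give
# element stiffness contributions through constant 24x24 matrices per
# Gauss point; only the rank-one dyad needs per-element vectors. This is
# what makes assembly fast in pure R.
quad_constant_blocks <- function(quad) {
  key <- format(quad$detJ, digits = 17)
  cache <- get0(".quad_blocks", envir = fe_cache_env())
  if (!is.null(cache) && identical(cache$key, key)) return(cache$blocks)
  Jn <- matrix(0, 6, 6); Jn[1:3, 1:3] <- 1
  P2 <- matrix(0, 6, 6)
  P2[1:3, 1:3] <- 2 * (diag(3) - 1 / 3)
  diag(P2)[4:6] <- 1
  JBtot <- numeric(576)
  Dev <- vector("list", 8)
  for (q in 1:8) {
    B <- quad$B[[q]]
    JBtot <- JBtot + as.vector(t(B) %*% Jn %*% B)
    Dev[[q]] <- as.vector(t(B) %*% P2 %*% B)
  }
  blocks <- list(JBtot = JBtot, Dev = Dev)
  assign(".quad_blocks", list(key = key, blocks = blocks), envir = fe_cache_env())
  blocks
}

# All m x 576 element stiffness entries for the decomposed tangent.
# kappa, mu: per-element; beta: list of 8 per-element vectors (1 = elastic);
# dyads: list of 8 NULL-or-list(coef = m-vector, nv = m x 6) entries.
batched_element_stiffness <- function(kappa, mu, beta, dyads, quad) {
  blocks <- quad_constant_blocks(quad)
  m <- length(kappa)
  Kv <- tcrossprod(kappa, blocks$JBtot)
  for (q in 1:8) {
    bq <- if (is.list(beta)) beta[[q]] else 1
    Kv <- Kv + tcrossprod(mu * bq, blocks$Dev[[q]])
    dy <- if (is.list(dyads)) dyads[[q]] else NULL
    if (!is.null(dy) && any(dy$coef != 0)) {
      W <- dy$nv %*% quad$B[[q]]          # m x 24, w = B' n per element
      iv <- rep(1:24, times = 24)
      jv <- rep(1:24, each = 24)
      Kv <- Kv - (dy$coef * W)[, iv, drop = FALSE] * W[, jv, drop = FALSE]
    }
  }
  Kv * quad$detJ
}

fe_cache_env <- local({
  e <- new.env(parent = emptyenv())
  function() e
})

# Assemble the global stiffness from per-element (per-gp) D matrices.
assemble_global <- function(edof, Kv, ndof) {
  m <- nrow(edof)
  ii <- edof[, rep(1:24, times = 24)]
  jj <- edof[, rep(1:24, each = 24)]
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(Kv), dims = c(ndof, ndof))
}

#' Assemble the elastic stiffness operator of a hexahedral model
#'
#' Builds the global sparse stiffness matrix for the model with the given
#' element materials (linear elastic branch of each material). The operator
#' is symmetric positive semi-definite with exactly six rigid-body modes
#' before constraints are applied.
#'
#' @param model a `hex_model`.
#' @param materials a `material_table`, or a tibble from
#'   [element_materials()] (columns `E_MPa`, `nu`).
#' @return a sparse symmetric `dgCMatrix` of size `3 n_nodes`.
#' @export
assemble <- function(model, materials) {
  stopifnot(inherits(model, "hex_model"))
  props <- if (inherits(materials, "material_table")) {
    element_materials(model, materials)
  } else materials
  if (nrow(props) != nrow(model$elements)) stop("one material row per element required")
  if (any(!is.finite(props$E_MPa)) || any(props$E_MPa <= 0)) {
    stop("every element needs a positive elastic modulus")
  }
  quad <- hex_B_matrices(model$element_size)
  lam <- props$E_MPa * props$nu / ((1 + props$nu) * (1 - 2 * props$nu))
  mu <- props$E_MPa / (2 * (1 + props$nu))
  Kv <- batched_element_stiffness(lam + 2 * mu / 3, mu, beta = 1,
                                  dyads = NULL, quad = quad)
  edof <- element_dofs(model$elements)
  assemble_global(edof, Kv, 3L * nrow(model$nodes))
}
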