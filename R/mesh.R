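#' Build a voxel hexahedral mesh from a bone mask
#'
#' Converts the bone voxels of a density volume into an 8-node hexahedral
#' mesh with one element per retained voxel, after (optionally) resampling
#' the grid to the requested element size and keeping only the largest
#' 6-connected component (small islands are dropped and counted). Node
#' coordinates lie on the regular lattice; shared faces share nodes, so the
#' mesh is conforming by construction.
#'
#' @param dv a `density_volume` with `rho_ash` filled (or a numeric 3D
#'   array of ash densities, in which case `spacing` must be given).
#' @param bone_mask logical 3D array marking bone voxels.
#' @param element_size target hexahedron edge length in mm (default 1.5).
#'   Must be an integer multiple or integer divisor of each voxel spacing;
#'   coarsening box-averages `rho_ash` (a coarse cell becomes bone when at
#'   least half of its voxels are bone), refinement replicates voxel values.
#' @param spacing voxel spacing, only needed when `dv` is a bare array.
#' @return object of class `hex_model`: list with `nodes` (n x 3 mm),
#'   `elements` (m x 8 node indices, VTK hexahedron corner order),
#'   `element_rho` (ash density per element, `NA` for pads),
#'   `element_kind` (`"bone"`/`"pad"`), `cells` (m x 3 lattice indices),
#'   `node_sets` (`top_surface`, `bottom_surface`), `element_size`,
#'   `femoral_height` (bone-only extent along z, mm), and
#'   `n_dropped_voxels`.
#' @export
build_mesh <- function(dv, bone_mask, element_size = 1.5, spacing = NULL) {
  if (inherits(dv, "density_volume")) {
    if (is.null(dv$rho_ash)) stop("rho_ash missing; run apparent_to_ash() first")
    rho <- dv$rho_ash
    spacing <- dv$spacing
  } else {
    rho <- dv
    if (is.null(spacing)) stop("spacing required for a bare density array")
  }
  stopifnot(is.array(rho), length(dim(rho)) == 3,
            identical(dim(rho), dim(bone_mask)))
  if (!any(bone_mask)) stop("bone mask is empty")

  rs <- resample_grid(rho, bone_mask, spacing, element_size)
  mask <- rs$mask
  rho <- rs$rho
  if (!any(mask)) stop("bone mask empty after resampling")

  keep <- largest_component6(mask)
  n_dropped <- sum(mask) - sum(keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " voxel(s) outside the largest 6-connected component")
  }
  mask <- keep
  if (!any(mask)) stop("bone mask empty after island removal")

  cells <- which(mask, arr.ind = TRUE)
  storage.mode(cells) <- "integer"
  model <- mesh_from_cells(cells, rho[mask], rep("bone", nrow(cells)),
                           element_size)
  model$n_dropped_voxels <- n_dropped
  model
}

# Resample (rho, mask) to an isotropic lattice with pitch element_size.
# Ratios must be integer multiples/divisors of the spacing per axis.
resample_grid <- function(rho, mask, spacing, element_size) {
  ratio <- element_size / spacing
  if (all(abs(ratio - 1) < 1e-9)) return(list(rho = rho, mask = mask))
  d <- dim(rho)
  up <- ratio < 1
  fac <- ifelse(up, round(1 / ratio), round(ratio))
  chk <- ifelse(up, 1 / fac, fac)
  if (any(abs(chk - ratio) > 1e-9)) {
    stop("element_size must be an integer multiple or divisor of the voxel spacing")
  }
  # refine axes first (replicate), then coarsen (block average)
  for (ax in 1:3) {
    if (up[ax] && fac[ax] > 1) {
      idx <- rep(seq_len(dim(rho)[ax]), each = fac[ax])
      rho <- index_axis(rho, ax, idx)
      mask <- index_axis(mask, ax, idx)
    }
  }
  for (ax in 1:3) {
    if (!up[ax] && fac[ax] > 1) {
      n <- dim(rho)[ax] %/% fac[ax]
      if (n < 1) stop("grid too small for requested element_size")
      take <- seq_len(n * fac[ax])
      rho <- index_axis(rho, ax, take)
      mask <- index_axis(mask, ax, take)
      rho <- block_reduce(rho, ax, fac[ax], mean)
      mask_frac <- block_reduce(mask + 0, ax, fac[ax], mean)
      mask <- mask_frac >= 0.5
    }
  }
  list(rho = rho, mask = mask)
}

index_axis <- function(a, ax, idx) {
  switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

block_reduce <- function(a, ax, fac, fun) {
  d <- dim(a)
  n <- d[ax] %/% fac
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  dim(ap) <- c(fac, n, d[perm[2]], d[perm[3]])
  out <- apply(ap, 2:4, fun)
  aperm(out, order(perm))
}

# Largest 6-connected component of a logical array, via igraph components
# on the voxel adjacency graph.
largest_component6 <- function(mask) {
  d <- dim(mask)
  lin <- array(seq_along(mask), dim = d)
  ids <- lin[mask]
  if (length(ids) <= 1) return(mask)
  pair_axis <- function(ax) {
    m1 <- index_axis(mask, ax, seq_len(d[ax] - 1))
    m2 <- index_axis(mask, ax, 2:d[ax])
    both <- m1 & m2
    a <- index_axis(lin, ax, seq_len(d[ax] - 1))[both]
    b <- index_axis(lin, ax, 2:d[ax])[both]
    cbind(a, b)
  }
  e <- do.call(rbind, lapply(1:3, function(ax) if (d[ax] > 1) pair_axis(ax)))
  em <- if (is.null(e) || nrow(e) == 0) integer(0) else
    as.vector(t(cbind(match(e[, 1], ids), match(e[, 2], ids))))
  g <- igraph::make_graph(edges = em, n = length(ids), directed = FALSE)
  comp <- igraph::components(g)
  keep_ids <- ids[comp$membership == which.max(comp$csize)]
  out <- array(FALSE, dim = d)
  out[keep_ids] <- TRUE
  out
}

# Build nodes/elements from integer lattice cell indices. Corner order is
# the VTK hexahedron convention (bottom face CCW, then top face).
mesh_from_cells <- function(cells, rho, kind, element_size) {
  stopifnot(nrow(cells) == length(rho), nrow(cells) == length(kind))
  off <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  lo <- apply(cells, 2, min)
  nxy <- apply(cells, 2, max) - lo + 2L  # corner-grid extents
  corner_key <- function(ci) {
    (ci[, 1] - lo[1]) + nxy[1] * ((ci[, 2] - lo[2]) + nxy[2] * (ci[, 3] - lo[3]))
  }
  m <- nrow(cells)
  keys <- matrix(0, m, 8)
  for (a in 1:8) {
    keys[, a] <- corner_key(cbind(cells[, 1] + off[a, 1],
                                  cells[, 2] + off[a, 2],
                                  cells[, 3] + off[a, 3]))
  }
  ukeys <- sort(unique(as.vector(keys)))
  elements <- matrix(match(as.vector(keys), ukeys), m, 8)
  # decode corner grid coordinates back from keys
  k <- ukeys
  gx <- k %% nxy[1]; k <- k %/% nxy[1]
  gy <- k %% nxy[2]; gz <- k %/% nxy[2]
  nodes <- cbind(x = (gx + lo[1] - 1) * element_size,
                 y = (gy + lo[2] - 1) * element_size,
                 z = (gz + lo[3] - 1) * element_size)
  zmax <- max(nodes[, 3]); zmin <- min(nodes[, 3])
  bone <- kind == "bone"
  fh <- (diff(range(cells[bone, 3])) + 1L) * element_size
  structure(list(
    nodes = nodes,
    elements = elements,
    element_rho = ifelse(bone, rho, NA_real_),
    element_kind = kind,
    cells = cells,
    node_sets = list(
      top_surface = which(abs(nodes[, 3] - zmax) < 1e-9),
      bottom_surface = which(abs(nodes[, 3] - zmin) < 1e-9)),
    element_size = element_size,
    femoral_height = fh,
    n_dropped_voxels = 0L),
    class = "hex_model")
}

#' Attach PMMA loading pads to a bone mesh
#'
#' Adds polymethylmethacrylate pad elements above the femoral head and
#' below the distal cut, emulating the pads used in compression tests. A
#' pad fills the gap between the bone surface and a flat platen plane:
#' within the pad footprint, cells are stacked from the local bone surface
#' up (or down) to `pad_thickness` layers beyond the global bone extreme,
#' so the outer pad face is flat. The footprint covers the columns whose
#' surface lies within `pad_span` layers of the extreme (for a flat-ended
#' column this is the full cross-section). The tie constraint between pad
#' and bone is realized as node sharing on the conforming lattice. Pad
#' elements carry E = 2500 MPa, nu = 0.3 and no yield.
#'
#' After attachment, `node_sets$top_surface` / `bottom_surface` are the
#' flat outer pad faces (the driven and fixed surfaces of the compression
#' solve). `femoral_height` remains the bone-only extent.
#'
#' @param model a `hex_model` from [build_mesh()].
#' @param pad_thickness pad layers beyond the bone extreme (default 2).
#' @param pad_span surface layers included in the pad footprint (default 3).
#' @return a `hex_model` including pad elements.
#' @export
attach_pads <- function(model, pad_thickness = 2L, pad_span = 3L) {
  stopifnot(inherits(model, "hex_model"))
  pad_thickness <- as.integer(pad_thickness)
  if (pad_thickness < 1) stop("pad thickness must be >= 1 layer")
  if (any(model$element_kind != "bone")) stop("pads already attached")
  cells <- model$cells
  key_xy <- paste(cells[, 1], cells[, 2])
  top_z <- tapply(cells[, 3], key_xy, max)
  bot_z <- tapply(cells[, 3], key_xy, min)
  zmax <- max(cells[, 3]); zmin <- min(cells[, 3])
  xy <- do.call(rbind, strsplit(names(top_z), " "))
  storage.mode(xy) <- "integer"

  stack_cells <- function(cols_xy, from_z, to_z) {
    # from_z/to_z vectors per column; build all (x, y, z) cells in range
    reps <- pmax(to_z - from_z + 1L, 0L)
    sel <- reps > 0L
    if (!any(sel)) return(NULL)
    cbind(rep(cols_xy[sel, 1], reps[sel]),
          rep(cols_xy[sel, 2], reps[sel]),
          unlist(Map(seq.int, from_z[sel], to_z[sel])))
  }
  top_cols <- top_z >= zmax - pad_span + 1L
  pad_top <- stack_cells(xy[top_cols, , drop = FALSE],
                         unname(top_z[top_cols]) + 1L,
                         rep(zmax + pad_thickness, sum(top_cols)))
  bot_cols <- bot_z <= zmin + pad_span - 1L
  pad_bot <- stack_cells(xy[bot_cols, , drop = FALSE],
                         rep(zmin - pad_thickness, sum(bot_cols)),
                         unname(bot_z[bot_cols]) - 1L)
  pad_cells <- rbind(pad_top, pad_bot)
  storage.mode(pad_cells) <- "integer"
  all_cells <- rbind(cells, pad_cells)
  kind <- c(model$element_kind, rep("pad", nrow(pad_cells)))
  rho <- c(model$element_rho, rep(NA_real_, nrow(pad_cells)))
  out <- mesh_from_cells(all_cells, rho, kind, model$element_size)
  out$n_dropped_voxels <- model$n_dropped_voxels
  out
}

#' @export
print.hex_model <- function(x, ...) {
  cat("<hex_model> ", nrow(x$elements), " hexahedra (",
      sum(x$element_kind == "bone"), " bone, ",
      sum(x$element_kind == "pad"), " pad), ",
      nrow(x$nodes), " nodes, h = ", x$element_size, " mm, bone height ",
      x$femoral_height, " mm\n", sep = "")
  invisible(x)
}
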