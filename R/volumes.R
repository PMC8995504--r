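#' Construct a CT-like volume container
#'
#' Holds a 3D grid of Hounsfield-unit intensities with voxel spacing (mm)
#' and origin. The third array index (z) is the superior-inferior loading
#' axis throughout the package.
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel edge lengths (mm), all positive.
#' @param origin numeric length-3 offset (mm), default `c(0, 0, 0)`.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  if (length(intensities) == 0) stop("empty intensity grid")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be three strictly positive lengths (mm)")
  }
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Describe a calibration phantom
#'
#' @param insert_densities strictly increasing calcium-hydroxyapatite
#'   equivalent densities (g/cm^3), default the common 0.05/0.1/0.2 set.
#' @param insert_rois list of ROI boxes, one per insert, each a list with
#'   integer ranges `x`, `y`, `z` (inclusive voxel index bounds).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(insert_densities = c(0.05, 0.1, 0.2),
                         insert_rois) {
  stopifnot(is.numeric(insert_densities), length(insert_densities) >= 1)
  if (is.unsorted(insert_densities, strictly = TRUE)) {
    stop("insert_densities must be strictly increasing")
  }
  if (length(insert_rois) != length(insert_densities)) {
    stop("one ROI required per insert density")
  }
  for (roi in insert_rois) {
    stopifnot(all(c("x", "y", "z") %in% names(roi)))
    for (ax in c("x", "y", "z")) {
      r <- roi[[ax]]
      if (length(r) != 2 || r[1] > r[2] || r[1] < 1) stop("malformed ROI range")
    }
  }
  if (rois_overlap(insert_rois)) stop("insert ROIs overlap")
  structure(list(insert_densities = insert_densities,
                 insert_rois = insert_rois),
            class = "phantom_spec")
}

rois_overlap <- function(rois) {
  n <- length(rois)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- rois[[i]]; b <- rois[[j]]
    sep <- FALSE
    for (ax in c("x", "y", "z")) {
      if (a[[ax]][2] < b[[ax]][1] || b[[ax]][2] < a[[ax]][1]) sep <- TRUE
    }
    if (!sep) return(TRUE)
  }
  FALSE
}

roi_inside <- function(roi, dims) {
  roi$x[2] <= dims[1] && roi$y[2] <= dims[2] && roi$z[2] <= dims[3]
}

# Default phantom geometry for a given grid: a slab of inserts along x at
# low y/z (the phantom sits under the hip joint in a real scan).
default_phantom <- function(dims, insert_densities = c(0.05, 0.1, 0.2)) {
  n <- length(insert_densities)
  w <- max(2L, dims[1] %/% (2L * n + 1L))
  zr <- c(1L, max(2L, dims[3] %/% 12L))
  yr <- c(1L, max(2L, dims[2] %/% 8L))
  rois <- lapply(seq_len(n), function(i) {
    x0 <- (2L * i - 1L) * w %/% 1L
    list(x = c(x0, x0 + w - 1L), y = yr, z = zr)
  })
  phantom_spec(insert_densities, rois)
}

#' Generate a synthetic phantom-only CT volume
#'
#' Builds a volume whose voxels follow a single global affine HU model
#' `HU = hu_slope * rho + hu_intercept` plus i.i.d. Gaussian noise, with the
#' phantom insert boxes at their nominal densities and zero density
#' elsewhere. The generating map and density field are returned as ground
#' truth so calibration can be tested against a known answer.
#'
#' @param phantom a `phantom_spec`; ROIs must fit inside `dims`.
#' @param dims integer length-3 grid size, default `c(48, 48, 16)`.
#' @param spacing voxel spacing (mm), default 1.5 mm isotropic.
#' @param hu_slope HU per g/cm^3 (default 600).
#' @param hu_intercept HU at zero density (default 0).
#' @param noise_sd HU noise standard deviation (default 0).
#' @param seed integer seed controlling all randomness in this call.
#' @return list with elements `volume` (a `ct_volume`) and `truth` (a
#'   `synthetic_truth`: `rho_apparent_field`, `bone_mask` (all `FALSE`),
#'   `hu_slope`, `hu_intercept`, `noise_sd`).
#' @export
generate_phantom_volume <- function(phantom,
                                    dims = c(48L, 48L, 16L),
                                    spacing = c(1.5, 1.5, 1.5),
                                    hu_slope = 600, hu_intercept = 0,
                                    noise_sd = 0, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"))
  dims <- as.integer(dims)
  for (roi in phantom$insert_rois) {
    if (!roi_inside(roi, dims)) stop("phantom ROI outside the volume")
  }
  rho <- array(0, dim = dims)
  for (i in seq_along(phantom$insert_rois)) {
    roi <- phantom$insert_rois[[i]]
    rho[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]] <-
      phantom$insert_densities[i]
  }
  hu <- hu_slope * rho + hu_intercept
  if (noise_sd > 0) {
    withr_seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = noise_sd)
  }
  truth <- structure(list(
    rho_apparent_field = rho,
    bone_mask = array(FALSE, dim = dims),
    hu_slope = hu_slope, hu_intercept = hu_intercept,
    noise_sd = noise_sd), class = "synthetic_truth")
  list(volume = ct_volume(hu, spacing), truth = truth)
}

# set.seed wrapper kept local so every generator routes its randomness
# through one explicit integer seed
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
}

#' Generate a synthetic femur-like CT volume
#'
#' Builds a parametric proximal-femur stand-in aligned with the z (loading)
#' axis: a shaft cylinder, a neck frustum and a head sphere, with a dense
#' cortical shell grading smoothly into a softer trabecular interior, plus
#' the calibration phantom placed below/beside the bone. The apparent
#' density field blends from the cortical range down to the trabecular
#' range through a distance-to-surface transition so that the full density
#' range is covered continuously. Intensities follow the same affine HU
#' model as [generate_phantom_volume()].
#'
#' `preset = "column"` replaces the femur with a uniform-density rectangular
#' column spanning fixed x/y extents: the analytic oracle geometry for the
#' FE solver.
#'
#' @param dims grid size, default `c(48, 48, 96)` voxels.
#' @param spacing voxel spacing (mm), default 1.5 mm isotropic.
#' @param preset `"femur"` (default) or `"column"`.
#' @param density_range length-2, admissible apparent-density range
#'   (g/cm^3) for bone voxels, default `c(0.1, 1.8)`.
#' @param cortical_range length-2 apparent-density range of the cortical
#'   shell, default `c(1.0, 1.8)`.
#' @param trabecular_range length-2 range of the trabecular interior,
#'   default `c(0.1, 0.6)`.
#' @param shell_voxels cortical shell thickness in voxels (default 2);
#'   must be >= 1.
#' @param blend_voxels thickness of the cortical-to-trabecular transition
#'   zone (default 4).
#' @param column_density uniform apparent density for the column preset
#'   (g/cm^3, default 0.5).
#' @param column_halfwidth half-width of the column cross-section in
#'   voxels (default a quarter of the x extent).
#' @param phantom optional `phantom_spec`; default geometry placed in the
#'   low-y/low-z slab. `NULL` omits the phantom.
#' @param hu_slope,hu_intercept,noise_sd affine HU model, as in
#'   [generate_phantom_volume()].
#' @param seed integer seed; fixed seed gives bit-identical volumes.
#' @return list with `volume` (`ct_volume`), `truth` (`synthetic_truth`
#'   with `rho_apparent_field` and bone `bone_mask`), and `phantom`
#'   (the `phantom_spec` used, or `NULL`).
#' @export
generate_femur_volume <- function(dims = c(48L, 48L, 96L),
                                  spacing = c(1.5, 1.5, 1.5),
                                  preset = c("femur", "column"),
                                  density_range = c(0.1, 1.8),
                                  cortical_range = c(1.0, 1.8),
                                  trabecular_range = c(0.1, 0.6),
                                  shell_voxels = 2L,
                                  blend_voxels = 4L,
                                  column_density = 0.5,
                                  column_halfwidth = NULL,
                                  phantom = default_phantom(dims),
                                  hu_slope = 600, hu_intercept = 0,
                                  noise_sd = 0, seed = 1L) {
  preset <- match.arg(preset)
  dims <- as.integer(dims)
  if (shell_voxels < 1) stop("degenerate shape: zero-thickness cortical shell")
  stopifnot(cortical_range[1] < cortical_range[2],
            trabecular_range[1] < trabecular_range[2])
  withr_seed(seed)

  if (preset == "column") {
    hw <- if (is.null(column_halfwidth)) max(2L, dims[1] %/% 4L) else as.integer(column_halfwidth)
    cx <- dims[1] %/% 2L; cy <- dims[2] %/% 2L
    zr <- c(max(1L, dims[3] %/% 6L), dims[3] - max(1L, dims[3] %/% 6L))
    mask <- array(FALSE, dim = dims)
    mask[(cx - hw + 1L):(cx + hw), (cy - hw + 1L):(cy + hw), zr[1]:zr[2]] <- TRUE
    rho <- array(0, dim = dims)
    rho[mask] <- column_density
  } else {
    geo <- femur_geometry(dims)
    mask <- geo$mask
    depth <- mask_depth(mask)
    # depth-based density profile: cortical plateau for depth <= shell,
    # linear blend down to the trabecular band, then a smooth low-frequency
    # trabecular field covering its range
    d <- depth[mask]
    nvox <- length(d)
    co <- cortical_range; tr <- trabecular_range
    # smooth trabecular variation: low-frequency sinusoid of position plus
    # seeded smoothed noise, scaled into [0, 1]
    idx <- which(mask, arr.ind = TRUE)
    u <- 0.5 + 0.25 * sin(2 * pi * idx[, 1] / dims[1] * 1.7) *
               cos(2 * pi * idx[, 2] / dims[2] * 1.3) +
         0.25 * sin(2 * pi * idx[, 3] / dims[3] * 2.1)
    u <- u + stats::rnorm(nvox, sd = 0.08)
    u <- (u - min(u)) / (max(u) - min(u))
    rho_tr <- tr[1] + u * (tr[2] - tr[1])
    # cortical value varies with height so the shell also spans its range
    zfrac <- (idx[, 3] - 1) / max(1L, dims[3] - 1L)
    rho_co <- co[1] + (co[2] - co[1]) * (0.25 + 0.75 * zfrac^0.8)
    w <- pmin(pmax((d - shell_voxels) / max(1L, blend_voxels), 0), 1)
    vals <- (1 - w) * rho_co + w * rho_tr
    vals <- pmin(pmax(vals, density_range[1]), density_range[2])
    rho <- array(0, dim = dims)
    rho[mask] <- vals
  }

  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "phantom_spec"))
    for (roi in phantom$insert_rois) {
      if (!roi_inside(roi, dims)) stop("phantom ROI outside the volume")
      box <- mask[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]]
      if (any(box)) stop("phantom ROI intersects the bone object")
    }
    for (i in seq_along(phantom$insert_rois)) {
      roi <- phantom$insert_rois[[i]]
      rho[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]] <-
        phantom$insert_densities[i]
    }
  }

  hu <- hu_slope * rho + hu_intercept
  if (noise_sd > 0) hu <- hu + stats::rnorm(length(hu), sd = noise_sd)
  truth <- structure(list(
    rho_apparent_field = rho, bone_mask = mask,
    hu_slope = hu_slope, hu_intercept = hu_intercept,
    noise_sd = noise_sd), class = "synthetic_truth")
  list(volume = ct_volume(hu, spacing), truth = truth, phantom = phantom)
}

# Parametric proximal femur aligned with z: shaft cylinder at the bottom,
# neck frustum, head sphere at the top, all axisymmetric about the grid
# center line.
femur_geometry <- function(dims) {
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  z0 <- max(3L, round(dims[3] * 0.18))       # leave room for the phantom slab
  z1 <- dims[3] - 2L
  h <- z1 - z0
  shaft_top <- z0 + round(0.45 * h)
  neck_top <- z0 + round(0.70 * h)
  r_shaft <- 0.16 * min(dims[1], dims[2])
  r_neck <- 0.11 * min(dims[1], dims[2])
  r_head <- 0.24 * min(dims[1], dims[2])
  head_cz <- neck_top + r_head * 0.75
  ii <- array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims)
  jj <- array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dim = dims)
  kk <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims)
  r2 <- (ii - cx)^2 + (jj - cy)^2
  shaft <- r2 <= r_shaft^2 & kk >= z0 & kk <= shaft_top
  # frustum: radius tapers linearly from shaft to neck
  tfrac <- pmin(pmax((kk - shaft_top) / max(1, neck_top - shaft_top), 0), 1)
  r_taper <- r_shaft + (r_neck - r_shaft) * tfrac
  neck <- r2 <= r_taper^2 & kk > shaft_top & kk <= neck_top
  head <- (ii - cx)^2 + (jj - cy)^2 + (kk - head_cz)^2 <= r_head^2 & kk <= z1
  list(mask = shaft | neck | head)
}

# Distance-to-surface in voxel layers via iterative 6-neighbour erosion:
# depth 1 on the surface layer, increasing inward.
mask_depth <- function(mask) {
  depth <- array(0L, dim = dim(mask))
  cur <- mask
  layer <- 0L
  while (any(cur)) {
    layer <- layer + 1L
    er <- erode6(cur)
    depth[cur & !er] <- layer
    cur <- er
    if (layer > max(dim(mask))) break
  }
  depth
}

# 6-neighbour binary erosion with FALSE outside the grid
erode6 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    if (ax == 1) {
      if (by == 1) r[2:d[1], , ] <- m[1:(d[1] - 1), , ] else r[1:(d[1] - 1), , ] <- m[2:d[1], , ]
    } else if (ax == 2) {
      if (by == 1) r[, 2:d[2], ] <- m[, 1:(d[2] - 1), ] else r[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
    } else {
      if (by == 1) r[, , 2:d[3]] <- m[, , 1:(d[3] - 1)] else r[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
    }
    r
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out & shift(m, ax, by)
  out
}
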