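#' Density-to-modulus law for femoral bone
#'
#' Maps ash density to an isotropic elastic modulus through the piecewise
#' empirical law used for QCT-based femoral FE models:
#'
#' * `E = 0.001` MPa at `rho_ash = 0`
#' * `E = 33900 * rho^2.2` for `0 < rho_ash <= 0.27`
#' * `E = 5307 * rho + 469` for `0.27 < rho_ash <= 0.6`
#' * `E = 10200 * rho^2.01` for `rho_ash > 0.6`
#'
#' The 0.001 MPa value at zero density is applied as a floor over the whole
#' domain: the low-density power branch dips below it for
#' `rho_ash < ~4e-4`, and the floor keeps the law non-decreasing and every
#' element stiffness matrix non-singular.
#'
#' @param rho_ash numeric vector of ash densities (g/cm^3), all `>= 0`.
#' @return numeric vector of elastic moduli (MPa).
#' @seealso [yield_strength()], [bin_materials()]
#' @export
#' @examples
#' elastic_modulus(c(0, 0.2, 0.5, 1.0))
elastic_modulus <- function(rho_ash) {
  stopifnot(is.numeric(rho_ash))
  if (any(!is.finite(rho_ash))) stop("rho_ash must be finite")
  if (any(rho_ash < 0)) stop("rho_ash must be non-negative")
  e <- ifelse(rho_ash <= 0.27, 33900 * rho_ash^2.2,
       ifelse(rho_ash <= 0.6,  5307 * rho_ash + 469,
                               10200 * rho_ash^2.01))
  pmax(e, 0.001)
}

#' Density-to-yield-strength law for femoral bone
#'
#' Piecewise power law for the von Mises yield stress:
#' `sigma = 137 * rho_ash^1.88` for `rho_ash < 0.317` and
#' `sigma = 114 * rho_ash^1.72` for `rho_ash >= 0.317` (MPa).
#' The two branches agree to within about 0.01% at the 0.317 g/cm^3
#' breakpoint.
#'
#' @inheritParams elastic_modulus
#' @return numeric vector of yield stresses (MPa).
#' @export
#' @examples
#' yield_strength(c(0, 0.317, 1.0))
yield_strength <- function(rho_ash) {
  stopifnot(is.numeric(rho_ash))
  if (any(!is.finite(rho_ash))) stop("rho_ash must be finite")
  if (any(rho_ash < 0)) stop("rho_ash must be non-negative")
  ifelse(rho_ash < 0.317, 137 * rho_ash^1.88, 114 * rho_ash^1.72)
}

#' Poisson's ratio used for all femoral bone elements
#' @return scalar, 0.4
#' @export
bone_poisson <- function() 0.4

#' Discretize a density field into material bins
#'
#' Splits the ash-density range observed over the bone mask into `n_bins`
#' equal-width bins and evaluates the modulus and yield laws at each bin
#' midpoint, producing the fixed set of materials ("120 kinds" by default)
#' assigned to the FE model. `n_bins = Inf` requests exact per-voxel
#' materials (no binning); the table then carries only the range and the
#' laws are evaluated pointwise downstream.
#'
#' @param dv a `density_volume` (see [hu_to_apparent()]) with `rho_ash` filled,
#'   or a numeric array/vector of ash densities.
#' @param bone_mask logical array/vector, same shape, marking bone voxels.
#' @param n_bins number of material bins (default 120), or `Inf` for
#'   unbinned per-element materials.
#' @return an object of class `material_table`: a list with `n_bins`,
#'   `bin_edges`, a tibble `bins` (`bin`, `rho_mid`, `E_MPa`, `sigma_MPa`,
#'   `nu`), the Poisson ratio `nu`, and `voxel_bin` (bin index per masked
#'   voxel, in mask order).
#' @export
bin_materials <- function(dv, bone_mask, n_bins = 120) {
  rho <- if (inherits(dv, "density_volume")) dv$rho_ash else dv
  stopifnot(is.numeric(rho), is.logical(bone_mask))
  if (length(rho) != length(bone_mask)) stop("dv and bone_mask differ in length")
  if (!any(bone_mask)) stop("bone_mask is empty")
  if (!(is.numeric(n_bins) && length(n_bins) == 1 && n_bins >= 1)) {
    stop("n_bins must be a single number >= 1")
  }
  vals <- rho[bone_mask]
  rng <- range(vals)

  if (is.infinite(n_bins)) {
    out <- structure(list(
      n_bins = Inf, bin_edges = rng, bins = NULL, nu = bone_poisson(),
      rho_range = rng, voxel_bin = NULL), class = "material_table")
    return(out)
  }

  n_bins <- as.integer(n_bins)
  if (rng[1] == rng[2]) {
    # degenerate uniform field: a single occupied bin regardless of n_bins
    edges <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = n_bins + 1L)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  idx <- material_bin_index(vals, edges)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mids <- pmax(mids, 0)
  bins <- tibble::tibble(
    bin = seq_len(n_bins),
    rho_mid = mids,
    E_MPa = elastic_modulus(mids),
    sigma_MPa = yield_strength(mids),
    nu = bone_poisson())
  structure(list(
    n_bins = n_bins, bin_edges = edges, bins = bins, nu = bone_poisson(),
    rho_range = rng, voxel_bin = idx), class = "material_table")
}

# Bin index lookup shared by bin_materials() and the mesh material
# assignment; values outside the edge range are clamped to the end bins.
material_bin_index <- function(rho, edges) {
  idx <- findInterval(rho, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}

#' Per-element material properties for a mesh
#'
#' Maps element ash densities through a [bin_materials()] table (or, for an
#' unbinned table, through the laws pointwise) and fills in the PMMA pad
#' properties (E = 2500 MPa, nu = 0.3, no yield).
#'
#' @param model a `hex_model` from [build_mesh()] / [attach_pads()].
#' @param materials a `material_table`.
#' @return tibble with one row per element: `E_MPa`, `nu`, `sigma_MPa`
#'   (`Inf` for pads), `bin` (`NA` for pads or unbinned).
#' @export
element_materials <- function(model, materials) {
  stopifnot(inherits(model, "hex_model"), inherits(materials, "material_table"))
  is_bone <- model$element_kind == "bone"
  n <- length(model$element_kind)
  E <- numeric(n); nu <- numeric(n); sig <- numeric(n)
  bin <- rep(NA_integer_, n)
  rho <- model$element_rho[is_bone]
  if (is.infinite(materials$n_bins)) {
    E[is_bone] <- elastic_modulus(pmax(rho, 0))
    sig[is_bone] <- yield_strength(pmax(rho, 0))
  } else {
    b <- material_bin_index(rho, materials$bin_edges)
    bin[is_bone] <- b
    E[is_bone] <- materials$bins$E_MPa[b]
    sig[is_bone] <- materials$bins$sigma_MPa[b]
  }
  nu[is_bone] <- materials$nu
  E[!is_bone] <- pmma_properties()$E_MPa
  nu[!is_bone] <- pmma_properties()$nu
  sig[!is_bone] <- Inf
  tibble::tibble(E_MPa = E, nu = nu, sigma_MPa = sig, bin = bin)
}

#' PMMA pad material properties
#'
#' The polymethylmethacrylate pads that transmit load in the simulated
#' compression test: E = 2500 MPa, nu = 0.3, no yield.
#' @return list with `E_MPa` and `nu`.
#' @export
pmma_properties <- function() list(E_MPa = 2500, nu = 0.3)

#' @export
print.material_table <- function(x, ...) {
  if (is.infinite(x$n_bins)) {
    cat("<material_table> unbinned (exact per-element laws), rho_ash range [",
        format(x$rho_range[1], digits = 4), ", ",
        format(x$rho_range[2], digits = 4), "] g/cm^3\n", sep = "")
  } else {
    occ <- length(unique(x$voxel_bin))
    cat("<material_table> ", x$n_bins, " bins over rho_ash [",
        format(x$rho_range[1], digits = 4), ", ",
        format(x$rho_range[2], digits = 4), "] g/cm^3; ",
        occ, " occupied\n", sep = "")
  }
  invisible(x)
}
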