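#' Run the full QCT-to-strength pipeline
#'
#' Chains phantom calibration, density conversion, material binning, voxel
#' hexahedral meshing with PMMA pads, and the elastic--perfectly-plastic
#' compression solve into one call: CT volume in, femoral strength out.
#'
#' The bone mask is taken from `bone_mask` if supplied (e.g. the synthetic
#' ground truth), otherwise by thresholding apparent density at
#' `mask_threshold`.
#'
#' @param volume a `ct_volume`.
#' @param phantom a `phantom_spec` for the calibration inserts.
#' @param bone_mask optional logical array marking bone voxels.
#' @param mask_threshold apparent-density threshold (g/cm^3) used when no
#'   mask is given (default 0.05).
#' @param n_bins material bins (default 120; `Inf` for unbinned).
#' @param element_size hexahedron edge (mm, default 1.5).
#' @param pad_thickness,pad_span pad geometry, see [attach_pads()].
#' @param target_deformation,n_steps,tol,max_iter,top_clamped,linear_solver
#'   solver controls, see [solve_compression()].
#' @return object of class `fe_report`: list with `femoral_strength_N`,
#'   `solution` (the `fe_solution`), `calibration` (`calibration_line`),
#'   `materials` (`material_table`), `model` (`hex_model`), and a
#'   `summary` tibble (one row: strength, element/node/bin counts,
#'   calibration slope/intercept/r^2, clamped voxel count).
#' @export
run_pipeline <- function(volume, phantom, bone_mask = NULL,
                         mask_threshold = 0.05,
                         n_bins = 120, element_size = 1.5,
                         pad_thickness = 2L, pad_span = 3L,
                         target_deformation = 0.04, n_steps = 20L,
                         tol = 1e-6, max_iter = 100L, top_clamped = FALSE,
                         linear_solver = "sparse") {
  stopifnot(inherits(volume, "ct_volume"), inherits(phantom, "phantom_spec"))
  line <- fit_calibration(volume, phantom)
  dv <- hu_to_apparent(volume, line)
  dv <- apparent_to_ash(dv)
  if (is.null(bone_mask)) {
    bone_mask <- dv$rho_apparent > mask_threshold
    # exclude the phantom inserts from the bone mask
    for (roi in phantom$insert_rois) {
      bone_mask[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]] <- FALSE
    }
  }
  if (!any(bone_mask)) stop("empty bone mask: no voxels above threshold")
  materials <- bin_materials(dv, bone_mask, n_bins = n_bins)
  model <- build_mesh(dv, bone_mask, element_size = element_size)
  model <- attach_pads(model, pad_thickness = pad_thickness, pad_span = pad_span)
  sol <- solve_compression(model, materials,
                           target_deformation = target_deformation,
                           n_steps = n_steps, tol = tol, max_iter = max_iter,
                           top_clamped = top_clamped,
                           linear_solver = linear_solver)
  n_mat <- if (is.infinite(materials$n_bins)) sum(bone_mask)
           else length(unique(materials$voxel_bin))
  structure(list(
    femoral_strength_N = sol$femoral_strength,
    solution = sol,
    calibration = line,
    materials = materials,
    model = model,
    summary = tibble::tibble(
      femoral_strength_N = sol$femoral_strength,
      n_elements = sol$n_elements,
      n_bone_elements = sum(model$element_kind == "bone"),
      n_nodes = sol$n_nodes,
      n_materials = n_mat,
      femoral_height_mm = model$femoral_height,
      calibration_slope = line$slope,
      calibration_intercept = line$intercept,
      calibration_r_squared = line$r_squared,
      n_clamped_voxels = dv$n_clamped)),
    class = "fe_report")
}

#' @export
print.fe_report <- function(x, ...) {
  cat("<fe_report> femoral strength ", format(x$femoral_strength_N, digits = 6),
      " N\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Serializes the scalar summary, calibration line and reaction history of
#' an [run_pipeline()] report (not the mesh or fields) to a JSON file.
#'
#' @param report an `fe_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "fe_report"))
  out <- list(
    femoral_strength_N = report$femoral_strength_N,
    summary = as.list(report$summary),
    calibration = list(slope = report$calibration$slope,
                       intercept = report$calibration$intercept,
                       r_squared = report$calibration$r_squared,
                       n_points = report$calibration$n_points),
    reaction_history = report$solution$reaction_history)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
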