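#' Write a CT volume to disk
#'
#' NIfTI (`.nii` / `.nii.gz`, via RNifti) or MetaImage (`.mha`, local
#' binary with an embedded ASCII header) chosen by file extension. Voxel
#' spacing is stored in the header. An optional ground-truth annotation
#' list is written as a JSON sidecar (`<path>.json`).
#'
#' @param volume a `ct_volume`.
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @param truth optional `synthetic_truth`; scalar fields are written to
#'   the JSON sidecar (the dense density field and mask are summarized by
#'   range/count, not serialized).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, truth = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$intensities)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    write_metaimage(volume, path)
  } else {
    stop("unsupported extension (use .nii, .nii.gz or .mha): ", path)
  }
  if (!is.null(truth)) {
    side <- list(hu_slope = truth$hu_slope, hu_intercept = truth$hu_intercept,
                 noise_sd = truth$noise_sd,
                 n_bone_voxels = sum(truth$bone_mask),
                 rho_apparent_range = range(truth$rho_apparent_field))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a CT volume from disk
#'
#' Counterpart of [write_volume()] for `.nii`/`.nii.gz` and `.mha`.
#'
#' @param path input file path.
#' @return a `ct_volume`.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    ct_volume(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
  } else if (grepl("\\.mha$", path)) {
    read_metaimage(path)
  } else {
    stop("unsupported extension: ", path)
  }
}

# Minimal MetaImage writer: ASCII header + little-endian float64 raw data
# appended in the same file (ElementDataFile = LOCAL).
write_metaimage <- function(volume, path) {
  d <- dim(volume$intensities)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementSpacing =", paste(volume$spacing, collapse = " ")),
    paste("Offset =", paste(volume$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$intensities), con, size = 8, endian = "little")
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated MetaImage header")
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL")) {
    stop("only LOCAL MetaImage data supported")
  }
  if (!identical(hdr$ElementType, "MET_DOUBLE")) {
    stop("only MET_DOUBLE MetaImage data supported")
  }
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  org <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, " ")[[1]]) else c(0, 0, 0)
  vals <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
  ct_volume(array(vals, dim = d), spacing = sp, origin = org)
}

#' Write a calibration line to JSON
#'
#' @param line a `calibration_line`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(line, path) {
  stopifnot(inherits(line, "calibration_line"))
  jsonlite::write_json(list(slope = line$slope, intercept = line$intercept,
                            r_squared = line$r_squared,
                            n_points = line$n_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cohort table to CSV
#'
#' One header row, one subject per row, `group` column with values
#' `t2dm`/`control`.
#'
#' @param cohort cohort tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path input path.
#' @return tibble with a `group` column.
#' @export
read_cohort_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"group" %in% names(out)) stop("cohort CSV lacks a group column")
  out
}

#' Export a hexahedral model as legacy VTK
#'
#' Writes the mesh as an ASCII VTK unstructured grid (cell type 12,
#' hexahedron) with element kind and ash density as cell data, for visual
#' inspection in ParaView and friends.
#'
#' @param model a `hex_model`.
#' @param path output `.vtk` path.
#' @param cell_data optional named list of additional numeric per-element
#'   vectors to append as cell data.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(model, path, cell_data = list()) {
  stopifnot(inherits(model, "hex_model"))
  n <- nrow(model$nodes); m <- nrow(model$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "voxel hexahedral mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(model$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELLS", m, m * 9L), con)
  utils::write.table(cbind(8L, model$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(12L, m)), con)
  writeLines(paste("CELL_DATA", m), con)
  writeLines(c("SCALARS rho_ash double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(ifelse(is.na(model$element_rho), -1, model$element_rho)),
             con)
  writeLines(c("SCALARS is_pad int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(model$element_kind == "pad")), con)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    stopifnot(length(v) == m)
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
    writeLines(format(v), con)
  }
  invisible(path)
}
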