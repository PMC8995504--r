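#' Fit the phantom calibration line
#'
#' Ordinary least squares of known insert densities on the mean HU inside
#' each insert region of interest, giving the affine HU -> apparent-density
#' map used for the whole scan. The calibration phantom carries inserts of
#' known calcium-hydroxyapatite-equivalent density (0.05/0.1/0.2 g/cm^3 by
#' default) scanned together with the subject.
#'
#' @param volume a `ct_volume` (see [generate_phantom_volume()]).
#' @param phantom a `phantom_spec` describing insert densities and ROIs.
#' @return object of class `calibration_line`: list with `slope` (g/cm^3 per
#'   HU), `intercept` (g/cm^3), `r_squared`, `n_points`, and a tibble
#'   `points` of (`hu_mean`, `density`) pairs.
#' @export
fit_calibration <- function(volume, phantom) {
  stopifnot(inherits(volume, "ct_volume"), inherits(phantom, "phantom_spec"))
  n <- length(phantom$insert_densities)
  if (n < 2) stop("calibration needs at least 2 phantom inserts")
  hu_mean <- vapply(phantom$insert_rois, function(roi) {
    mean(volume$intensities[roi$x[1]:roi$x[2],
                            roi$y[1]:roi$y[2],
                            roi$z[1]:roi$z[2]])
  }, numeric(1))
  if (diff(range(hu_mean)) == 0) {
    stop("singular calibration fit: identical ROI mean HU for distinct densities")
  }
  rho <- phantom$insert_densities
  fit <- stats::lm(rho ~ hu_mean)
  # noiseless phantoms fit exactly; the perfect-fit warning is expected
  r2 <- if (n == 2) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_points = n,
    points = tibble::tibble(hu_mean = hu_mean, density = rho)),
    class = "calibration_line")
}

#' Convert a HU volume to apparent density
#'
#' Applies the calibration line voxelwise:
#' `rho_apparent = max(0, slope * HU + intercept)`. Negative calibrated
#' densities (air, soft tissue, noise) are clamped to zero and counted.
#'
#' @param volume a `ct_volume`.
#' @param line a `calibration_line` from [fit_calibration()].
#' @return object of class `density_volume`: list with `rho_apparent`
#'   (array, g/cm^3), `rho_ash` (`NULL` until [apparent_to_ash()]),
#'   `spacing` (mm), and `n_clamped` (count of voxels clamped at zero).
#' @export
hu_to_apparent <- function(volume, line) {
  stopifnot(inherits(volume, "ct_volume"), inherits(line, "calibration_line"))
  raw <- line$slope * volume$intensities + line$intercept
  n_clamped <- sum(raw < 0)
  structure(list(
    rho_apparent = pmax(raw, 0),
    rho_ash = NULL,
    spacing = volume$spacing,
    n_clamped = n_clamped),
    class = "density_volume")
}

#' Convert apparent density to ash density
#'
#' Elementwise affine conversion `rho_ash = 1.22 * rho_apparent + 0.0526`
#' (g/cm^3), the standard relation between apparent density (bone mass per
#' total volume) and ash (mineral) density used for QCT material mapping.
#'
#' @param dv a `density_volume` with `rho_apparent` filled.
#' @return the same `density_volume` with `rho_ash` filled.
#' @export
apparent_to_ash <- function(dv) {
  stopifnot(inherits(dv, "density_volume"))
  if (is.null(dv$rho_apparent)) stop("rho_apparent missing")
  dv$rho_ash <- 1.22 * dv$rho_apparent + 0.0526
  dv
}

#' @export
print.calibration_line <- function(x, ...) {
  cat("<calibration_line> rho = ", format(x$slope, digits = 6), " * HU + ",
      format(x$intercept, digits = 6), "  (r^2 = ",
      format(x$r_squared, digits = 4), ", ", x$n_points, " inserts)\n",
      sep = "")
  invisible(x)
}
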