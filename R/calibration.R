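# Intensity-to-density calibration: insert densities from mass/volume,
# per-scan linear regression of density on mean insert intensity, voxel-wise
# density mapping, and agreement statistics between two density maps.

#' Bundled reference measurements of the five polymer inserts
#'
#' Masses (analytical balance) and volumes (laser scan and CT scan) of the
#' nylon, PEEK, acetal, PPS and PTFE inserts of the in-house density
#' calibration phantom, together with the manufacturer-specified densities.
#' These are the package's default insert measurements; derived densities
#' come from [build_insert_table()].
#'
#' @return A data.frame with columns `material`, `manufacturer_density`
#'   (g/cc), `mass_g`, `volume_laser_mm3`, `volume_ct_mm3`.
#' @export
reference_insert_measurements <- function() {
  data.frame(
    material = c("Nylon", "PEEK", "Acetal", "PPS", "PTFE"),
    manufacturer_density = c(1.14, 1.32, 1.42, 1.64, 2.18),
    mass_g = c(10.25, 10.87, 11.98, 14.12, 18.21),
    volume_laser_mm3 = c(8925.62, 8265.49, 8444.13, 8593.82, 8414.74),
    volume_ct_mm3 = c(8863.84, 8286.66, 8391.10, 8808.03, 8546.67),
    stringsAsFactors = FALSE)
}

#' Density from mass and volume
#'
#' `density (g/cc) = mass (g) / volume (mm^3) * 1000`. No rounding is
#' applied; round only at report time.
#'
#' @param mass_g Mass in g (> 0).
#' @param volume_mm3 Volume in mm^3 (> 0).
#' @return Density in g/cc.
#' @export
insert_density_from_mass_volume <- function(mass_g, volume_mm3) {
  if (any(mass_g <= 0) || any(volume_mm3 <= 0))
    stop("mass and volume must be strictly positive")
  mass_g / volume_mm3 * 1000
}

#' Insert measurement table with derived densities
#'
#' Computes, per insert, the density from each volume determination and
#' their mean. The mean is taken on the unrounded per-method densities.
#'
#' @param measurements A data.frame like
#'   [reference_insert_measurements()] with columns `material`, `mass_g`,
#'   `volume_laser_mm3`, `volume_ct_mm3`.
#' @return The input with columns `density_laser`, `density_ct`,
#'   `density_mean` (g/cc) appended.
#' @export
build_insert_table <- function(measurements = reference_insert_measurements()) {
  need <- c("material", "mass_g", "volume_laser_mm3", "volume_ct_mm3")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurements table is missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- measurements
  out$density_laser <- insert_density_from_mass_volume(out$mass_g,
                                                       out$volume_laser_mm3)
  out$density_ct <- insert_density_from_mass_volume(out$mass_g,
                                                    out$volume_ct_mm3)
  out$density_mean <- (out$density_laser + out$density_ct) / 2
  out
}

#' Fit the per-scan intensity-to-density calibration line
#'
#' Ordinary least squares of density on mean insert intensity (this is the
#' direction the mapping uses), solved exactly via the normal equations as
#' implemented by [stats::lm()].
#'
#' @param intensity Mean insert intensities (>= 2 distinct values).
#' @param density Certified insert densities (g/cc).
#' @return An object of class `calibration_line` with `slope` (g/cc per
#'   intensity unit), `intercept` (g/cc), `r_squared`, `residuals` and `n`.
#' @export
fit_calibration <- function(intensity, density) {
  intensity <- as.numeric(intensity)
  density <- as.numeric(density)
  if (length(intensity) != length(density) || length(intensity) < 2L)
    stop("need >= 2 paired (intensity, density) points")
  if (anyDuplicated(intensity)) {
    k <- tapply(density, intensity, function(v) length(unique(v)))
    if (any(k > 1))
      stop("duplicate intensities with different densities: rank deficient")
  }
  if (diff(range(intensity)) == 0)
    stop("intensities are all equal: rank deficient")
  fit <- stats::lm(density ~ intensity)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((density - mean(density))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 residuals = unname(stats::residuals(fit)),
                 n = length(intensity)),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line> density = %.6g * I + %.6g (R^2 = %.6f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Map an intensity volume to density through a calibration line
#'
#' Voxel-wise `density = slope * intensity + intercept`, clamped below at 0
#' (physical floor). Voxels predicting outside the calibrated insert
#' density range are extrapolations; their count is reported when `range`
#' is supplied.
#'
#' @param vol An `"intensity"` [volume_image()].
#' @param line A [calibration_line()][fit_calibration].
#' @param range Optional length-2 calibrated density range (g/cc) used to
#'   count extrapolated voxels.
#' @return A `"g/cc"` [volume_image()]; attribute `n_extrapolated` holds the
#'   out-of-range voxel count when `range` is given.
#' @export
map_density <- function(vol, line, range = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  if (vol$unit != "intensity")
    stop("`vol` must carry unit \"intensity\", got \"", vol$unit, "\"")
  rho <- pmax(0, line$slope * vol$voxels + line$intercept)
  out <- volume_image(array(rho, dim(vol$voxels)), vol$spacing, vol$origin,
                      unit = "g/cc")
  if (!is.null(range)) {
    attr(out, "n_extrapolated") <- sum(rho < min(range) | rho > max(range))
  }
  out
}

#' Voxel-paired agreement statistics between two density maps
#'
#' Bland-Altman-style summary over a mask: bias (mean difference), the
#' precision half-width sigma (SD of differences), 1.96 sigma limits of
#' agreement, Pearson correlation, and the OLS slope of the second
#' measurement on the first. Identical inputs report bias = sigma = 0,
#' slope = 1 and (for non-constant data) R = 1.
#'
#' @param d1,d2 `"g/cc"` [volume_image()]s on the same grid.
#' @param mask Optional logical array or label [volume_image()] (non-zero =
#'   included); default: all voxels.
#' @return An object of class `agreement_stats`: `bias`, `sigma`,
#'   `loa` (1.96 sigma), `r`, `slope`, `n`.
#' @export
agreement_stats <- function(d1, d2, mask = NULL) {
  stopifnot(inherits(d1, "volume_image"), inherits(d2, "volume_image"))
  stopifnot_same_grid(d1, d2)
  m <- if (is.null(mask)) rep(TRUE, length(d1$voxels))
  else if (inherits(mask, "volume_image")) as.vector(mask$voxels != 0)
  else as.vector(mask)
  if (!any(m)) stop("mask is empty")
  x <- d1$voxels[m]
  y <- d2$voxels[m]
  n <- length(x)
  if (n < 2L) stop("need >= 2 paired voxels")
  diffs <- y - x
  bias <- mean(diffs)
  sigma <- stats::sd(diffs)
  identical_data <- sigma == 0 && bias == 0
  sx <- stats::sd(x); sy <- stats::sd(y)
  r <- if (identical_data) 1
  else if (sx == 0 || sy == 0) NA_real_
  else stats::cor(x, y)
  slope <- if (identical_data) 1
  else if (sx == 0) NA_real_
  else stats::cov(x, y) / stats::var(x)
  structure(list(bias = bias, sigma = sigma, loa = 1.96 * sigma, r = r,
                 slope = slope, n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(paste0("<agreement_stats> bias %.4g g/cc, sigma %.4g g/cc ",
                     "(LoA +/-%.4g), R %.4f, slope %.4f, n %d\n"),
              x$bias, x$sigma, x$loa, x$r, x$slope, x$n))
  invisible(x)
}
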