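# Forward scan model: CT intensity is affine in real density with
# protocol-dependent gain and offset plus additive Gaussian noise. The
# multiplicative protocol dependence below is a configurable stand-in for
# scanner physics; the calibration procedure never sees these constants and
# must recover the per-scan line from the phantom inserts alone.

#' Scan protocol descriptor
#'
#' @param voltage_kv Tube voltage (kV), > 0.
#' @param exposure_ms Exposure/integration time (ms), > 0.
#' @param filter One of `"no"`, `"0.25 mm Cu"`, `"0.25 mm Sn"`,
#'   `"0.75 mm Sn"`.
#' @param voxel_mm Voxel size (mm), scalar or per-axis.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units), >= 0. The default keeps the standard error of an insert mean
#'   intensity well below 0.1% of its value for typical insert sizes.
#' @param seed Integer seed; renders are bit-reproducible given the seed.
#' @param label Optional scan label.
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(voltage_kv = 100, exposure_ms = 100,
                          filter = c("no", "0.25 mm Cu", "0.25 mm Sn",
                                     "0.75 mm Sn"),
                          voxel_mm = 0.07, noise_sd = 10, seed = 1L,
                          label = NULL) {
  filter <- match.arg(filter)
  if (voltage_kv <= 0 || exposure_ms <= 0 || any(voxel_mm <= 0))
    stop("voltage, exposure and voxel size must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(voltage_kv = voltage_kv, exposure_ms = exposure_ms,
                 filter = filter, voxel_mm = voxel_mm, noise_sd = noise_sd,
                 seed = as.integer(seed), label = label),
            class = "scan_protocol")
}

#' Constants of the affine intensity model
#'
#' `gain = g0 * (voltage/100)^alpha * (exposure/100)^beta * f(filter)` in
#' intensity units per g/cc, and `offset = b0 * f(filter)` in intensity
#' units.
#'
#' @param g0 Reference gain (intensity per g/cc).
#' @param alpha Voltage exponent (negative: higher kV compresses contrast).
#' @param beta Exposure exponent.
#' @param b0 Reference offset (intensity units).
#' @param filter_factors Named multipliers per beam filter.
#' @return A list of model constants.
#' @export
scan_model <- function(g0 = 1000, alpha = -0.4, beta = 0.15, b0 = 50,
                       filter_factors = c("no" = 1.00, "0.25 mm Cu" = 0.95,
                                          "0.25 mm Sn" = 0.90,
                                          "0.75 mm Sn" = 0.82)) {
  list(g0 = g0, alpha = alpha, beta = beta, b0 = b0,
       filter_factors = filter_factors)
}

#' Gain and offset implied by a protocol
#' @param protocol A [scan_protocol()].
#' @param model A [scan_model()].
#' @return Named numeric `c(gain, offset)`.
#' @export
protocol_gain_offset <- function(protocol, model = scan_model()) {
  f <- model$filter_factors[[protocol$filter]]
  gain <- model$g0 * (protocol$voltage_kv / 100)^model$alpha *
    (protocol$exposure_ms / 100)^model$beta * f
  offset <- model$b0 * f
  c(gain = gain, offset = offset)
}

#' Render a CT-like intensity volume from ground truth
#'
#' `intensity = gain * density + offset + N(0, noise_sd)`; bit-identical
#' under a fixed protocol seed.
#'
#' @param gt A [ground_truth()].
#' @param protocol A [scan_protocol()].
#' @param model A [scan_model()].
#' @return An intensity [volume_image()] on the ground-truth grid.
#' @export
render_scan <- function(gt, protocol, model = scan_model()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(protocol, "scan_protocol"))
  go <- protocol_gain_offset(protocol, model)
  vox <- go[["gain"]] * gt$density$voxels + go[["offset"]]
  if (protocol$noise_sd > 0) {
    noise <- withr::with_seed(protocol$seed,
                              stats::rnorm(length(vox), 0, protocol$noise_sd))
    vox <- vox + array(noise, dim(vox))
  }
  volume_image(vox, gt$density$spacing, gt$density$origin, unit = "intensity")
}

#' Degrade a micro-CT volume to a medical-CT analogue
#'
#' Block-averages to approximately `target_mm` voxels (factor =
#' `round(target_mm / spacing)` per axis, the partial-volume effect) and
#' applies independent re-noising.
#'
#' @param vol A micro-CT-resolution [volume_image()] (all spacings must be
#'   below `target_mm`).
#' @param target_mm Target voxel size (mm); default 0.5.
#' @param noise_sd Noise SD added after downsampling (same units as `vol`).
#' @param seed Integer seed for the re-noising.
#' @return A coarse [volume_image()].
#' @export
simulate_medical_ct <- function(vol, target_mm = 0.5, noise_sd = 0,
                                seed = 1L) {
  stopifnot(inherits(vol, "volume_image"))
  if (any(vol$spacing >= target_mm))
    stop("input is already at medical-CT resolution (spacing >= ",
         target_mm, " mm)")
  factor <- pmax(1L, as.integer(round(target_mm / vol$spacing)))
  out <- block_average_resample(vol, factor)
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              stats::rnorm(length(out$voxels), 0, noise_sd))
    out$voxels <- out$voxels + array(noise, dim(out$voxels))
  }
  out
}
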