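#' 3D scalar volume with physical metadata
#'
#' A `volume_image` is a 3D numeric array together with per-axis voxel
#' spacing (mm), the world position of the centre of voxel (1,1,1) (mm),
#' and a unit tag. World coordinates follow the voxel-centre convention:
#' the centre of voxel with (0-based) index `k` along an axis lies at
#' `origin + k * spacing`.
#'
#' @param voxels 3D numeric array.
#' @param spacing Numeric length-3, per-axis voxel size in mm
#'   (strictly positive; anisotropic spacing is fully supported).
#' @param origin Numeric length-3, world position (mm) of the centre of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @param unit One of `"intensity"`, `"g/cc"`, `"label"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing, origin = c(0, 0, 0),
                         unit = c("intensity", "g/cc", "label")) {
  unit <- match.arg(unit)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("grid must be non-empty")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (unit == "label") {
    if (any(voxels < 0) || any(voxels != round(voxels)))
      stop("label volumes must contain non-negative integers")
    storage.mode(voxels) <- "integer"
  } else {
    storage.mode(voxels) <- "double"
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 unit = unit),
            class = "volume_image")
}

#' Labelled mask volume
#'
#' Convenience constructor for integer label volumes (0 = background) that
#' share grid semantics with a companion [volume_image()].
#'
#' @param labels 3D array of non-negative integers.
#' @inheritParams volume_image
#' @return A `volume_image` with `unit == "label"`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  volume_image(labels, spacing, origin, unit = "label")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels [%s]\n", d[1], d[2], d[3],
              x$unit))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin:  (%.4g, %.4g, %.4g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  rng <- range(x$voxels)
  cat(sprintf("  range:   [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' Voxel volume in mm^3
#' @param vol A `volume_image`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Per-axis world coordinates of voxel centres
#'
#' @param vol A `volume_image`.
#' @return A list of three numeric vectors (mm), one per axis.
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$voxels)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Check two volumes share a grid
#' @param a,b `volume_image` objects.
#' @param tol Numeric tolerance on spacing/origin (mm).
#' @return `TRUE` invisibly, or an error.
#' @keywords internal
stopifnot_same_grid <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("volumes are on different grids (dimensions differ)")
  if (max(abs(a$spacing - b$spacing)) > tol ||
      max(abs(a$origin - b$origin)) > tol)
    stop("volumes are on different grids (spacing/origin differ)")
  invisible(TRUE)
}

#' Grid description helper
#'
#' @param dims Integer length-3 grid dimensions.
#' @param spacing Numeric length-3 voxel size (mm).
#' @param origin Numeric length-3 world origin (mm).
#' @return A list with elements `dims`, `spacing`, `origin`.
#' @export
grid_spec <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  origin <- as.numeric(origin)
  list(dims = dims, spacing = spacing, origin = origin)
}
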