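# Density calibration phantom (DCP) specification and voxelisation.

#' Density calibration phantom specification
#'
#' Describes a block of base polymer carrying cylindrical inserts of
#' certified density. Cylinders are axis-aligned (long axis = z).
#'
#' @param materials Character vector of insert material names.
#' @param densities Certified insert densities (g/cc), strictly positive and
#'   pairwise distinct.
#' @param radius_mm Cylinder radius per insert (recycled).
#' @param height_mm Cylinder height per insert (recycled).
#' @param centers_mm n x 3 matrix of cylinder centre positions (mm, world).
#' @param base_density Density of the base material (g/cc); must sit below
#'   the smallest insert density so intensity thresholding can order the
#'   classes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(materials, densities, radius_mm, height_mm,
                         centers_mm, base_density = 1.0) {
  n <- length(materials)
  if (n < 2L) stop("a phantom needs at least 2 inserts (regression needs >= 2 points)")
  densities <- as.numeric(densities)
  if (length(densities) != n) stop("`densities` must match `materials`")
  if (any(densities <= 0)) stop("insert densities must be strictly positive")
  if (anyDuplicated(densities)) stop("insert densities must be pairwise distinct")
  radius_mm <- rep_len(as.numeric(radius_mm), n)
  height_mm <- rep_len(as.numeric(height_mm), n)
  centers_mm <- matrix(as.numeric(centers_mm), ncol = 3L)
  if (nrow(centers_mm) != n) stop("`centers_mm` must have one row per insert")
  # pairwise disjointness for parallel z-axis cylinders
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dz <- abs(centers_mm[i, 3] - centers_mm[j, 3])
    overlap_z <- dz < (height_mm[i] + height_mm[j]) / 2
    dxy <- sqrt(sum((centers_mm[i, 1:2] - centers_mm[j, 1:2])^2))
    if (overlap_z && dxy < radius_mm[i] + radius_mm[j])
      stop("insert cylinders overlap: ", materials[i], " and ", materials[j])
  }
  structure(list(materials = materials, densities = densities,
                 radius_mm = radius_mm, height_mm = height_mm,
                 centers_mm = centers_mm, base_density = base_density),
            class = "phantom_spec")
}

#' Default five-insert polymer phantom
#'
#' Five polymer inserts (nylon, PEEK, acetal, PPS, PTFE) whose certified
#' densities are the mean of the mass/laser-volume and mass/CT-volume
#' determinations in the bundled reference measurements
#' ([reference_insert_measurements()]): 1.15, 1.31, 1.42, 1.62 and
#' 2.15 g/cc. Inserts are arranged on a ring inside a 1.0 g/cc polymer base.
#'
#' @param radius_mm Insert cylinder radius (mm).
#' @param height_mm Insert cylinder height (mm).
#' @param ring_radius_mm Radius of the ring of insert centres (mm).
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(radius_mm = 4, height_mm = 12,
                                 ring_radius_mm = 12) {
  tab <- build_insert_table()
  n <- nrow(tab)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(ring_radius_mm * cos(ang), ring_radius_mm * sin(ang), 0)
  phantom_spec(tab$material, tab$density_mean, radius_mm, height_mm, centers,
               base_density = 1.0)
}

# Volume fraction of each grid voxel inside one z-aligned cylinder. The
# axial overlap is separable and computed exactly per slice; the in-plane
# disc fraction uses `ss` x `ss` midpoint supersampling at boundary voxels.
.cylinder_fraction <- function(xs, ys, zs, center, radius, height, spacing,
                               ss = 3L) {
  rx <- xs - center[1]
  ry <- ys - center[2]
  rz <- zs - center[3]
  # exact 1D overlap of each voxel slab with the cylinder's z extent
  zlo <- pmax(rz - spacing[3] / 2, -height / 2)
  zhi <- pmin(rz + spacing[3] / 2, height / 2)
  zov <- pmax(0, zhi - zlo) / spacing[3]
  rd2 <- outer(rx^2, ry^2, `+`)
  margin <- sqrt(spacing[1]^2 + spacing[2]^2) / 2
  inside <- rd2 <= max(radius - margin, 0)^2
  outside <- rd2 >= (radius + margin)^2
  xyfrac <- matrix(0, length(rx), length(ry))
  xyfrac[inside] <- 1
  bnd <- which(!inside & !outside, arr.ind = TRUE)
  if (nrow(bnd) > 0) {
    off <- ((seq_len(ss) - 0.5) / ss - 0.5)
    cx <- rx[bnd[, 1]]
    cy <- ry[bnd[, 2]]
    acc <- numeric(nrow(bnd))
    for (ox in off) for (oy in off)
      acc <- acc + as.numeric((cx + ox * spacing[1])^2 +
                              (cy + oy * spacing[2])^2 <= radius^2)
    xyfrac[bnd] <- acc / ss^2
  }
  array(outer(as.vector(xyfrac), zov), c(length(rx), length(ry), length(rz)))
}

#' Voxelise a phantom specification onto a grid
#'
#' Interior voxels carry the certified insert density, base material
#' elsewhere; voxels cut by a cylinder surface get a volume-weighted mixed
#' density computed by 3x3x3 supersampling (partial-volume rendering).
#' Labels mark voxels with more than half their volume inside an insert.
#'
#' @param spec A [phantom_spec()].
#' @param grid A [grid_spec()]; the grid is centred on the insert ring unless
#'   an origin is given explicitly via `grid$origin`.
#' @param supersample Supersampling factor per axis for boundary voxels.
#' @return A [ground_truth()] whose labels use
#'   `tissue_labels$insert_base + k` for insert `k`.
#' @export
generate_phantom <- function(spec, grid, supersample = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- grid$dims; sp <- grid$spacing; org <- grid$origin
  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  dens <- array(spec$base_density, d)
  labs <- array(0L, d)
  n <- length(spec$materials)
  for (i in seq_len(n)) {
    c_i <- spec$centers_mm[i, ]
    r_i <- spec$radius_mm[i]
    h_i <- spec$height_mm[i]
    if (c_i[1] - r_i < xs[1] - sp[1] / 2 || c_i[1] + r_i > xs[d[1]] + sp[1] / 2 ||
        c_i[2] - r_i < ys[1] - sp[2] / 2 || c_i[2] + r_i > ys[d[2]] + sp[2] / 2 ||
        c_i[3] - h_i / 2 < zs[1] - sp[3] / 2 ||
        c_i[3] + h_i / 2 > zs[d[3]] + sp[3] / 2)
      stop("insert ", spec$materials[i], " does not fit inside the grid")
    frac <- .cylinder_fraction(xs, ys, zs, c_i, r_i, h_i, sp,
                               ss = as.integer(supersample))
    dens <- dens + frac * (spec$densities[i] - spec$base_density)
    labs[frac > 0.5] <- tissue_labels$insert_base + i
  }
  density <- volume_image(dens, sp, org, unit = "g/cc")
  labels <- label_volume(labs, sp, org)
  ground_truth(density, labels,
               info = list(kind = "phantom", spec = spec,
                           supersample = supersample))
}

#' Grid large enough to hold a phantom
#'
#' @param spec A [phantom_spec()].
#' @param spacing Voxel size (mm), scalar or per-axis.
#' @param margin_mm Base-material margin around the inserts (mm).
#' @return A [grid_spec()] centred on the inserts.
#' @export
phantom_grid <- function(spec, spacing = 0.5, margin_mm = 2) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  lo <- c(min(spec$centers_mm[, 1] - spec$radius_mm),
          min(spec$centers_mm[, 2] - spec$radius_mm),
          min(spec$centers_mm[, 3] - spec$height_mm / 2)) - margin_mm
  hi <- c(max(spec$centers_mm[, 1] + spec$radius_mm),
          max(spec$centers_mm[, 2] + spec$radius_mm),
          max(spec$centers_mm[, 3] + spec$height_mm / 2)) + margin_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(dims, spacing, origin = lo)
}
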