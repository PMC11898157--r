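# Periprosthetic regions of interest: Gruen zones around the stem, the
# fixed-thickness bone-implant interface shell, and per-zone density and
# BV/TV summaries.

#' Define the seven Gruen zones around an implant
#'
#' A deterministic 3D operationalisation of the classic radiographic zones:
#' the implant axis is the principal axis of the implant mask (oriented
#' towards superior); periprosthetic bone within the implant's axial extent
#' is split into proximal/middle/distal thirds of the implant length;
#' voxels lateral of the axis plane (normal = medial-lateral axis through
#' the implant centroid) take zones 1-3 proximal-to-distal, medial voxels
#' take 5-7 distal-to-proximal; zone 4 is bone in the distal cap below the
#' implant tip.
#'
#' @param implant_labels A label [volume_image()] in which the implant
#'   voxels carry `implant_label`.
#' @param fcs A [define_fcs()] frame supplying the medial-lateral and
#'   superior-inferior directions.
#' @param bone_domain A label [volume_image()] (non-zero = bone domain to
#'   partition) on the same grid.
#' @param implant_label Label code of the implant.
#' @param cap_fraction Axial extent of zone 4 below the tip, as a fraction
#'   of implant length.
#' @return An object of class `roi_set`: `zones` (label volume, labels 1-7),
#'   `meta` (implant axis, centroid, extent, boundaries).
#' @export
define_gruen_zones <- function(implant_labels, fcs, bone_domain,
                               implant_label = tissue_labels$implant,
                               cap_fraction = 1 / 3) {
  stopifnot(inherits(implant_labels, "volume_image"),
            inherits(bone_domain, "volume_image"),
            inherits(fcs, "femur_coordinate_system"))
  stopifnot_same_grid(implant_labels, bone_domain)
  imp <- implant_labels$voxels == implant_label
  if (!any(imp)) stop("implant mask is empty")
  if (!any(bone_domain$voxels != 0)) stop("bone domain is empty")
  sp <- implant_labels$spacing
  org <- implant_labels$origin
  iw <- which(imp, arr.ind = TRUE)
  pw <- sweep(sweep(iw - 1, 2, sp, `*`), 2, org, `+`)
  centroid <- colMeans(pw)
  cv <- stats::cov(pw)
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  si <- fcs$axes[, "si"]
  if (sum(axis * si) < 0) axis <- -axis
  s_imp <- as.vector(sweep(pw, 2, centroid) %*% axis)
  s_min <- min(s_imp)
  s_max <- max(s_imp)
  len <- s_max - s_min
  b1 <- s_min + len / 3
  b2 <- s_min + 2 * len / 3
  d <- dim(bone_domain$voxels)
  bd <- which(bone_domain$voxels != 0, arr.ind = TRUE)
  bw <- sweep(sweep(bd - 1, 2, sp, `*`), 2, org, `+`)
  rel <- sweep(bw, 2, centroid)
  s <- as.vector(rel %*% axis)
  m <- as.vector(rel %*% fcs$axes[, "ml"])
  zone <- integer(nrow(bd))
  within <- s >= s_min & s <= s_max
  lateral <- m < 0
  # lateral: 1 proximal, 2 middle, 3 distal
  zone[within & lateral & s > b2] <- 1L
  zone[within & lateral & s > b1 & s <= b2] <- 2L
  zone[within & lateral & s <= b1] <- 3L
  # medial: 5 distal, 6 middle, 7 proximal
  zone[within & !lateral & s <= b1] <- 5L
  zone[within & !lateral & s > b1 & s <= b2] <- 6L
  zone[within & !lateral & s > b2] <- 7L
  cap <- s < s_min & s >= s_min - cap_fraction * len
  zone[cap] <- 4L
  zarr <- array(0L, d)
  zarr[bd[zone > 0L, , drop = FALSE]] <- zone[zone > 0L]
  zarr[imp] <- 0L
  zones <- label_volume(zarr, sp, org)
  structure(list(zones = zones,
                 meta = list(axis = axis, centroid = centroid,
                             s_range = c(s_min, s_max),
                             boundaries = c(b1, b2),
                             cap_fraction = cap_fraction)),
            class = "roi_set")
}

#' Interface shell around a cavity or implant
#'
#' Voxels whose Euclidean distance to the mask (mm, anisotropic-aware
#' distance transform) lies in `(0, thickness_mm]`, intersected with the
#' bone domain.
#'
#' @param mask A label [volume_image()] (non-zero = cavity/implant) or a
#'   logical array.
#' @param thickness_mm Shell thickness (mm), > 0.
#' @param bone_domain A label [volume_image()] (non-zero = admissible
#'   voxels) or logical array on the same grid.
#' @param spacing Required when `mask` is a plain array.
#' @return A binary label [volume_image()] (1 = shell).
#' @export
interface_shell <- function(mask, thickness_mm, bone_domain, spacing = NULL) {
  if (thickness_mm <= 0) stop("`thickness_mm` must be > 0")
  if (inherits(mask, "volume_image")) {
    m <- mask$voxels != 0
    sp <- mask$spacing
    org <- mask$origin
  } else {
    if (is.null(spacing)) stop("`spacing` required for plain array masks")
    m <- mask != 0
    sp <- rep_len(as.numeric(spacing), 3L)
    org <- c(0, 0, 0)
  }
  bd <- if (inherits(bone_domain, "volume_image")) bone_domain$voxels != 0
  else bone_domain != 0
  dist <- distance_transform(m, sp, cap_mm = thickness_mm * 1.5)
  shell <- dist > 0 & dist <= thickness_mm & bd
  label_volume(array(as.integer(shell), dim(m)), sp, org)
}

#' Bone volume fraction within a region of interest
#'
#' `BV/TV = |bone voxels in ROI| / |ROI voxels|`.
#'
#' @param bone_mask A label [volume_image()] or logical array (non-zero =
#'   bone).
#' @param roi A label [volume_image()] or logical array (non-zero = ROI).
#' @return Fraction in `[0, 1]`.
#' @export
bv_tv <- function(bone_mask, roi) {
  b <- if (inherits(bone_mask, "volume_image")) bone_mask$voxels != 0
  else bone_mask != 0
  r <- if (inherits(roi, "volume_image")) roi$voxels != 0 else roi != 0
  if (!identical(dim(b), dim(r))) stop("grids do not match")
  n <- sum(r)
  if (n == 0L) stop("ROI is empty")
  sum(b & r) / n
}

#' Per-zone density and BV/TV summary
#'
#' For every Gruen zone: voxel count, bone-masked mean density, whole-ROI
#' mean density (both are reported because either convention is defensible
#' for mixed-tissue zones) and BV/TV. Post-implantation, a one-voxel rind
#' around the implant should be excluded from `bone_mask` by the caller to
#' guard against bright-implant bleed-in.
#'
#' @param density A `"g/cc"` [volume_image()].
#' @param rois A `roi_set` from [define_gruen_zones()] (or a label volume of
#'   zone codes).
#' @param bone_mask A label [volume_image()] or logical array (non-zero =
#'   bone).
#' @return A data.frame with columns `zone`, `n_voxels`, `n_bone`,
#'   `mean_density_bone`, `mean_density_roi`, `bvtv`, `empty`.
#' @export
zone_density_summary <- function(density, rois, bone_mask) {
  stopifnot(inherits(density, "volume_image"))
  zones <- if (inherits(rois, "roi_set")) rois$zones else rois
  stopifnot_same_grid(density, zones)
  b <- if (inherits(bone_mask, "volume_image")) bone_mask$voxels != 0
  else bone_mask != 0
  zv <- zones$voxels
  out <- do.call(rbind, lapply(1:7, function(z) {
    m <- zv == z
    n <- sum(m)
    if (n == 0L)
      return(data.frame(zone = z, n_voxels = 0L, n_bone = 0L,
                        mean_density_bone = NA_real_,
                        mean_density_roi = NA_real_,
                        bvtv = NA_real_, empty = TRUE))
    mb <- m & b
    nb <- sum(mb)
    data.frame(zone = z, n_voxels = n, n_bone = nb,
               mean_density_bone = if (nb > 0) mean(density$voxels[mb])
               else NA_real_,
               mean_density_roi = mean(density$voxels[m]),
               bvtv = nb / n, empty = FALSE)
  }))
  out
}
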