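# Surgical stages on the synthetic femur: broaching (cavity creation with
# mass-conserving debris compaction into a thin interface shell) and
# uncemented implantation (cavity filled by the stem).

#' Parameters of the broached cavity / implant
#'
#' The implant is modelled as a tapered square prism along the shaft (z)
#' axis, entering from the proximal end: cross-section half-width shrinks
#' linearly from `width_mm[1]` (proximal) to `width_mm[2]` (distal tip) over
#' `length_mm`.
#'
#' @param width_mm Length-2 proximal/distal cross-section widths (mm).
#' @param length_mm Implant/cavity length along the shaft axis (mm).
#' @param shell_thickness_mm Thickness of the bone-implant interface shell
#'   (mm); default 1, the depth to which compacted trabecular debris is
#'   deposited.
#' @param debris_retention Fraction in `[0, 1]` of the removed trabecular
#'   mass that is re-deposited into the shell (the rest is flushed).
#' @param implant_density Implant material density (g/cc); default 4.43
#'   (Ti-6Al-4V).
#' @return An object of class `surgical_stage_params`.
#' @export
surgical_stage_params <- function(width_mm = c(8, 4), length_mm = 20,
                                  shell_thickness_mm = 1,
                                  debris_retention = 1,
                                  implant_density = 4.43) {
  width_mm <- rep_len(as.numeric(width_mm), 2L)
  if (any(width_mm <= 0) || length_mm <= 0)
    stop("implant dimensions must be positive")
  if (shell_thickness_mm <= 0) stop("`shell_thickness_mm` must be positive")
  if (debris_retention < 0 || debris_retention > 1)
    stop("`debris_retention` must lie in [0, 1]")
  structure(list(width_mm = width_mm, length_mm = length_mm,
                 shell_thickness_mm = shell_thickness_mm,
                 debris_retention = debris_retention,
                 implant_density = implant_density),
            class = "surgical_stage_params")
}

#' Cavity mask of the tapered broach/implant
#'
#' @param gt A femur [ground_truth()].
#' @param stage A [surgical_stage_params()].
#' @return Logical 3D array marking cavity voxels.
#' @export
cavity_mask <- function(gt, stage) {
  grid <- list(dims = dim(gt$density$voxels), spacing = gt$density$spacing,
               origin = gt$density$origin)
  d <- grid$dims; sp <- grid$spacing; org <- grid$origin
  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  axis_xy <- gt$info$axis_xy
  if (is.null(axis_xy)) axis_xy <- c(mean(range(xs)), mean(range(ys)))
  z_top <- zs[d[3]]
  z0 <- z_top - stage$length_mm
  mask <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    if (zs[k] < z0) next
    t <- (zs[k] - z0) / stage$length_mm      # 0 at tip, 1 proximal
    w <- stage$width_mm[2] + (stage$width_mm[1] - stage$width_mm[2]) * t
    inx <- abs(xs - axis_xy[1]) <= w / 2
    iny <- abs(ys - axis_xy[2]) <= w / 2
    mask[, , k] <- outer(inx, iny, `&`)
  }
  mask
}

#' Broach the femur: remove cavity bone, compact debris into the shell
#'
#' Trabecular bone inside the cavity is removed. A fraction
#' `debris_retention` of the removed mass is re-deposited into the interface
#' shell (the distance-transform band of `shell_thickness_mm` outside the
#' cavity, restricted to the medullary canal), converting marrow voxels to
#' trabecular bone closest-to-the-cavity-first until the mass budget is
#' spent. Post-state bone mass equals pre-state mass minus
#' `(1 - debris_retention)` times the removed mass, up to at most one
#' partially filled voxel. If the shell saturates (occupancy 1 everywhere)
#' the unplaced mass is reported in `info$unplaced_mass_g` with a warning.
#'
#' @param gt A femur [ground_truth()].
#' @param stage A [surgical_stage_params()].
#' @return A new [ground_truth()]; `info` records `removed_mass_g`,
#'   `deposited_mass_g`, `unplaced_mass_g`, `shell_bvtv_pre`,
#'   `shell_bvtv_post` and the logical arrays `cavity` and `shell`.
#' @export
apply_broaching <- function(gt, stage) {
  stopifnot(inherits(gt, "ground_truth"),
            inherits(stage, "surgical_stage_params"))
  labs <- gt$labels$voxels
  dens <- gt$density$voxels
  sp <- gt$density$spacing
  cav <- cavity_mask(gt, stage)
  if (any(labs[cav] == tissue_labels$cortical))
    stop("implant cavity breaches the cortical shell; shrink the implant")
  vv <- voxel_volume(gt$density)            # mm^3
  removed_idx <- cav & labs == tissue_labels$trabecular
  removed_mass <- sum(dens[removed_idx]) * vv / 1000
  labs[cav] <- tissue_labels$cavity
  dens[cav] <- 0
  # interface shell: distance band outside the cavity, inside the canal
  dist <- distance_transform(cav, sp, cap_mm = stage$shell_thickness_mm * 1.5)
  in_canal <- labs %in% c(tissue_labels$marrow, tissue_labels$trabecular)
  shell <- dist > 0 & dist <= stage$shell_thickness_mm & in_canal
  shell_n <- sum(shell)
  shell_bvtv_pre <- sum(labs[shell] == tissue_labels$trabecular) / shell_n
  budget <- stage$debris_retention * removed_mass            # g
  voxel_mass <- gt$info$params$trabecular_density * vv / 1000
  marrow_density <- gt$info$params$marrow_density
  deposited <- 0
  unplaced <- 0
  if (budget > 0) {
    cand <- which(shell & labs == tissue_labels$marrow)
    cand <- cand[order(dist[cand])]          # closest to the cavity first
    n_full <- floor(budget / voxel_mass)
    if (n_full >= length(cand)) {
      conv <- cand
      frac <- 0
      unplaced <- budget - length(cand) * voxel_mass
      if (unplaced > 1e-12)
        warning(sprintf(paste0("shell saturated: %.4g g of debris could not",
                               " be placed"), unplaced))
    } else {
      conv <- if (n_full > 0) cand[seq_len(n_full)] else integer(0)
      frac <- (budget - n_full * voxel_mass) / voxel_mass
    }
    labs[conv] <- tissue_labels$trabecular
    dens[conv] <- gt$info$params$trabecular_density
    deposited <- length(conv) * voxel_mass
    if (frac > 0 && n_full < length(cand)) {
      # one partially occupied voxel absorbs the remainder of the budget
      v <- cand[n_full + 1L]
      dens[v] <- marrow_density +
        frac * (gt$info$params$trabecular_density - marrow_density)
      if (frac >= 0.5) {
        labs[v] <- tissue_labels$trabecular
        deposited <- deposited + dens[v] * vv / 1000
      }
    }
  }
  shell_bvtv_post <- sum(labs[shell] == tissue_labels$trabecular) / shell_n
  density <- volume_image(dens, sp, gt$density$origin, unit = "g/cc")
  labels <- label_volume(labs, sp, gt$density$origin)
  info <- gt$info
  info$stage <- "post-broaching"
  info$stage_params <- stage
  info$removed_mass_g <- removed_mass
  info$deposited_mass_g <- deposited
  info$unplaced_mass_g <- unplaced
  info$shell_bvtv_pre <- shell_bvtv_pre
  info$shell_bvtv_post <- shell_bvtv_post
  info$cavity <- cav
  info$shell <- shell
  ground_truth(density, labels, info = info)
}

#' Debris retention needed for a target shell BV/TV increase
#'
#' Closed-form inversion of the deposition model: raising shell BV/TV by
#' `delta_pp` percentage points converts `delta * n_shell` marrow voxels, a
#' mass of `n * trabecular_density * voxel_volume`, which must equal
#' `retention * removed_mass`.
#'
#' @param gt Pre-surgery femur [ground_truth()].
#' @param stage A [surgical_stage_params()] (its `debris_retention` is
#'   ignored).
#' @param delta_pp Target shell BV/TV increase in percentage points.
#' @return Retention fraction in `[0, 1]`; errors if the target needs more
#'   than the removed mass.
#' @export
retention_for_shell_bvtv_delta <- function(gt, stage, delta_pp) {
  labs <- gt$labels$voxels
  dens <- gt$density$voxels
  sp <- gt$density$spacing
  cav <- cavity_mask(gt, stage)
  vv <- voxel_volume(gt$density)
  removed_mass <- sum(dens[cav & labs == tissue_labels$trabecular]) * vv / 1000
  dist <- distance_transform(cav, sp, cap_mm = stage$shell_thickness_mm * 1.5)
  in_canal <- labs %in% c(tissue_labels$marrow, tissue_labels$trabecular)
  shell <- dist > 0 & dist <= stage$shell_thickness_mm & in_canal
  n_convert <- delta_pp / 100 * sum(shell)
  need <- n_convert * gt$info$params$trabecular_density * vv / 1000
  if (need > removed_mass)
    stop(sprintf("target +%.2f pp needs %.4g g but only %.4g g is removed",
                 delta_pp, need, removed_mass))
  n_marrow <- sum(shell & labs == tissue_labels$marrow)
  if (n_convert > n_marrow)
    stop("shell cannot absorb the requested BV/TV increase (saturation)")
  need / removed_mass
}

#' Insert the implant into the broached cavity
#'
#' Cavity voxels become implant voxels at the implant material density; all
#' bone labels (and hence bone mass) are untouched.
#'
#' @param gt A post-broaching [ground_truth()].
#' @param stage A [surgical_stage_params()]; its geometry must not exceed
#'   the broached cavity.
#' @return A new [ground_truth()] with `info$stage == "post-implantation"`.
#' @export
insert_implant <- function(gt, stage) {
  stopifnot(inherits(gt, "ground_truth"))
  labs <- gt$labels$voxels
  dens <- gt$density$voxels
  if (!any(labs == tissue_labels$cavity))
    stop("no broached cavity present; call apply_broaching() first")
  imp <- cavity_mask(gt, stage)
  if (any(labs[imp] %in% c(tissue_labels$trabecular, tissue_labels$cortical)))
    stop("implant exceeds the broached cavity")
  labs[imp] <- tissue_labels$implant
  dens[imp] <- stage$implant_density
  density <- volume_image(dens, gt$density$spacing, gt$density$origin,
                          unit = "g/cc")
  labels <- label_volume(labs, gt$density$spacing, gt$density$origin)
  info <- gt$info
  info$stage <- "post-implantation"
  info$implant <- imp
  ground_truth(density, labels, info = info)
}
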