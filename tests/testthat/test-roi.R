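# Gruen zones, interface shell, BV/TV and zone summaries.

implanted_femur <- function() fixture("implanted", {
  fem <- surgery_femur()
  stage <- surgery_stage(retention = 0.3)
  imp <- insert_implant(apply_broaching(fem, stage), stage)
  list(pre = fem, imp = imp, stage = stage)
})

test_that("Gruen zones split the implant length into exact thirds", {
  s <- implanted_femur()
  fcs <- canonical_fcs()
  rois <- define_gruen_zones(s$imp$labels, fcs, bone_domain_volume(s$imp))
  zv <- rois$zones$voxels
  zs <- voxel_centers(s$imp$labels)[[3]]
  # implant axial extent and third boundaries from the implant mask itself
  imp_z <- range(zs[apply(s$imp$labels$voxels == tissue_labels$implant,
                          3, any)])
  len <- diff(imp_z)
  b1 <- imp_z[1] + len / 3
  b2 <- imp_z[1] + 2 * len / 3
  sp <- s$imp$labels$spacing[3]
  # zone 3 (distal lateral) spans [tip, b1]; zone 1 proximal of b2
  z3 <- range(zs[apply(zv == 3L, 3, any)])
  expect_lt(abs(z3[1] - imp_z[1]), 1.5 * sp)
  expect_lt(abs(z3[2] - b1), 1.5 * sp)
  z1 <- range(zs[apply(zv == 1L, 3, any)])
  expect_lt(abs(z1[1] - b2), 1.5 * sp)
  # zone 4 sits strictly below the implant tip
  z4 <- range(zs[apply(zv == 4L, 3, any)])
  expect_lt(z4[2], imp_z[1] + 1.5 * sp)
  # zones partition the periprosthetic bone domain within the axial extent
  # (shrunk by half a voxel: the fitted implant axis is numerically not
  # exactly the grid axis, so the extreme slices are boundary cases)
  dom <- bone_domain_volume(s$imp)$voxels != 0 &
    s$imp$labels$voxels != tissue_labels$implant
  in_extent <- array(rep(zs >= imp_z[1] + sp / 2 & zs <= imp_z[2] - sp / 2,
                         each = prod(dim(zv)[1:2])), dim(zv))
  expect_true(all(zv[dom & in_extent] > 0L))
  expect_true(all(zv %in% 0:7))
})

test_that("mirroring the femur swaps lateral and medial zone labels", {
  s <- implanted_femur()
  right <- define_gruen_zones(s$imp$labels, canonical_fcs(),
                              bone_domain_volume(s$imp))
  left_fcs <- define_fcs(c(0, 0, 40), c(0, 0, -300), c(0, 30, -300),
                         side = "left")
  left <- define_gruen_zones(s$imp$labels, left_fcs,
                             bone_domain_volume(s$imp))
  swap <- c(`1` = 7L, `2` = 6L, `3` = 5L, `4` = 4L, `5` = 3L, `6` = 2L,
            `7` = 1L)
  for (z in 1:7) {
    n_r <- sum(right$zones$voxels == z)
    n_l <- sum(left$zones$voxels == swap[[as.character(z)]])
    # equal up to voxels sitting exactly on the sagittal split plane
    expect_lt(abs(n_l - n_r) / n_r, 2e-3,
              label = paste("zone", z, "mirror deviation"))
  }
})

test_that("zones are equivariant under rigid motion of all inputs", {
  s <- implanted_femur()
  rois <- define_gruen_zones(s$imp$labels, canonical_fcs(),
                             bone_domain_volume(s$imp))
  # rotate the whole scene 90 degrees about z: (x,y) -> (-y,x) via array ops
  rot_arr <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  rot_vol <- function(v) {
    a <- rot_arr(v$voxels)
    label_volume(a, v$spacing[c(2, 1, 3)], v$origin)
  }
  R <- rotation_z(90)
  fcs_rot <- define_fcs(R %*% c(0, 0, 40), R %*% c(0, 0, -300),
                        R %*% c(0, 30, -300), side = "right")
  rois_rot <- define_gruen_zones(rot_vol(s$imp$labels), fcs_rot,
                                 rot_vol(bone_domain_volume(s$imp)))
  for (z in 1:7) {
    n_ref <- sum(rois$zones$voxels == z)
    n_rot <- sum(rois_rot$zones$voxels == z)
    # identical up to boundary-voxel discrepancies from the fitted axis
    expect_lt(abs(n_rot - n_ref) / n_ref, 2e-3,
              label = paste("zone", z, "count deviation"))
  }
})

test_that("interface shell matches the analytic annulus volume", {
  # cylindrical cavity r = 3 mm in a wide bone domain, shell t = 1 mm;
  # the voxel-centre distance transform converges first-order in spacing,
  # so the comparison runs at 62.5 um voxels
  d <- c(164, 164, 8)
  sp <- rep(0.0625, 3)
  xs <- (seq_len(d[1]) - 1) * sp[1] - (d[1] - 1) / 2 * sp[1]
  ys <- xs
  rd <- sqrt(outer(xs^2, ys^2, `+`))
  cav <- array(rep(rd <= 3, d[3]), d)
  dom <- array(TRUE, d)
  shell <- interface_shell(cav, thickness_mm = 1, dom, spacing = sp)
  h <- d[3] * sp[3]
  analytic <- pi * (4^2 - 3^2) * h
  got <- sum(shell$voxels) * prod(sp)
  expect_lt(abs(got / analytic - 1), 0.03)
  expect_error(interface_shell(cav, 0, dom, spacing = sp), "thickness")
})

test_that("a one-pitch shell on an isotropic grid is a one-voxel rind", {
  d <- c(12, 12, 12)
  cav <- array(FALSE, d)
  cav[5:8, 5:8, 5:8] <- TRUE
  shell <- interface_shell(cav, thickness_mm = 1, array(TRUE, d),
                           spacing = rep(1, 3))
  expect_identical(shell$voxels == 1L,
                   phantomcal:::dilate_mask(cav, 1L) & !cav)
})

test_that("BV/TV counts bone voxels over ROI voxels", {
  d <- c(10, 10, 10)
  roi <- array(TRUE, d)
  expect_equal(bv_tv(array(TRUE, d), roi), 1.0)
  half <- array(FALSE, d)
  half[1:5, , ] <- TRUE
  expect_equal(bv_tv(half, roi), 0.5)
  expect_error(bv_tv(half, array(FALSE, d)), "empty")
})

test_that("broaching raises shell BV/TV by the configured amount", {
  fem <- surgery_femur()
  stage <- surgery_stage()
  r <- retention_for_shell_bvtv_delta(fem, stage, delta_pp = 10)
  br <- apply_broaching(fem, surgery_stage(retention = r))
  shell <- br$info$shell
  pre_bvtv <- bv_tv(fem$labels$voxels == tissue_labels$trabecular, shell)
  post_bvtv <- bv_tv(br$labels$voxels == tissue_labels$trabecular, shell)
  expect_lt(abs(100 * (post_bvtv - pre_bvtv) - 10), 1)
  # shell BV/TV unchanged without debris
  br0 <- apply_broaching(fem, surgery_stage(retention = 0))
  expect_equal(bv_tv(br0$labels$voxels == tissue_labels$trabecular, shell),
               pre_bvtv)
})

test_that("zone summaries match a brute-force voxel-list oracle", {
  s <- implanted_femur()
  rois <- define_gruen_zones(s$imp$labels, canonical_fcs(),
                             bone_domain_volume(s$imp))
  bm <- bone_mask_volume(s$imp)
  zsum <- zone_density_summary(s$imp$density, rois, bm)
  zv <- rois$zones$voxels
  for (z in c(1L, 4L, 7L)) {
    m <- zv == z
    mb <- m & bm$voxels != 0
    row <- zsum[zsum$zone == z, ]
    expect_equal(row$mean_density_roi, mean(s$imp$density$voxels[m]),
                 tolerance = 1e-9)
    expect_equal(row$mean_density_bone, mean(s$imp$density$voxels[mb]),
                 tolerance = 1e-9)
    expect_equal(row$bvtv, sum(mb) / sum(m), tolerance = 1e-12)
  }
  # uniform density: every zone mean equals that density
  u <- volume_image(array(1.5, dim(zv)), s$imp$density$spacing,
                    s$imp$density$origin, unit = "g/cc")
  us <- zone_density_summary(u, rois, bm)
  expect_true(all(abs(us$mean_density_roi - 1.5) < 1e-12))
  # an empty zone is flagged and carries NA summaries
  empty_zones <- label_volume(array(0L, dim(zv)) + (zv == 1L) * 1L,
                              rois$zones$spacing, rois$zones$origin)
  es <- zone_density_summary(u, empty_zones, bm)
  expect_true(es$empty[es$zone == 2])
  expect_true(is.na(es$mean_density_roi[es$zone == 2]))
})
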