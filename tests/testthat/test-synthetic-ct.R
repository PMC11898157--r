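# Generators: phantom, femur, surgical stages, forward scan model.

test_that("phantom interior voxels carry the certified densities", {
  ph <- small_phantom()
  spec <- small_phantom_spec()
  got <- sort(vapply(seq_along(spec$densities), function(i) {
    m <- ph$labels$voxels == tissue_labels$insert_base + i
    # interior = eroded label mask, clear of any partial-volume voxel
    m <- phantomcal:::erode_mask(m, 2L)
    unique_d <- unique(ph$density$voxels[m])
    expect_length(unique_d, 1)
    unique_d
  }, numeric(1)))
  expect_equal(got, sort(spec$densities), tolerance = 1e-12)
  expect_equal(round(got, 2), c(1.15, 1.31, 1.42, 1.62, 2.15))
})

test_that("an insert at base density renders a locally constant volume", {
  spec <- phantom_spec(c("ghost", "real"), c(1.0, 1.5), radius_mm = 2,
                       height_mm = 6,
                       centers_mm = rbind(c(-5, 0, 0), c(5, 0, 0)),
                       base_density = 1.0)
  ph <- generate_phantom(spec, phantom_grid(spec, spacing = 0.5))
  xs <- voxel_centers(ph$density)[[1]]
  left <- ph$density$voxels[xs < 0, , ]
  expect_true(all(left == 1.0))
})

test_that("voxelised insert mass matches the closed-form cylinder volume", {
  spec <- phantom_spec(c("a", "b"), c(1.5, 2.0), radius_mm = 4, height_mm = 12,
                       centers_mm = rbind(c(-7.1, 0.2, 0.1), c(7.2, -0.1, 0)),
                       base_density = 1.0)
  ph <- generate_phantom(spec, phantom_grid(spec, spacing = 0.4))
  vv <- voxel_volume(ph$density)
  xs <- voxel_centers(ph$density)[[1]]
  true_vol <- pi * 4^2 * 12
  for (i in 1:2) {
    side <- if (i == 1) xs < 0 else xs >= 0
    frac <- (ph$density$voxels - 1.0) / (spec$densities[i] - 1.0)
    v_est <- sum(frac[side, , ]) * vv
    expect_lt(abs(v_est / true_vol - 1), 0.005)
    mass_est <- v_est / 1000 * spec$densities[i]
    expect_equal(mass_est, true_vol / 1000 * spec$densities[i],
                 tolerance = 0.005)
  }
})

test_that("phantom specification invariants are enforced", {
  expect_error(phantom_spec("one", 1.5, 3, 8, rbind(c(0, 0, 0))),
               "at least 2")
  expect_error(phantom_spec(c("a", "b"), c(1.5, 1.5), 3, 8,
                            rbind(c(-9, 0, 0), c(9, 0, 0))), "distinct")
  expect_error(phantom_spec(c("a", "b"), c(1.5, 2.0), 3, 8,
                            rbind(c(0, 0, 0), c(2, 0, 0))), "overlap")
})

test_that("femur realises its BV/TV target and a pure cortical shell", {
  fem <- small_femur()
  expect_gte(fem$info$bvtv_realised, 0.28)
  expect_lte(fem$info$bvtv_realised, 0.32)
  cort <- fem$labels$voxels == tissue_labels$cortical
  expect_equal(unique(fem$density$voxels[cort]),
               small_femur_params()$cortical_density)
  # recorded mass agrees with direct voxel bookkeeping
  expect_equal(fem$mass_g, bone_mass(fem$density, fem$labels),
               tolerance = 1e-12)
  expect_error(bone_phantom_params(bvtv_target = 1.0), "strictly inside")
})

test_that("femur generation is deterministic under a fixed seed", {
  a <- generate_femur(small_femur_params(seed = 3L), spacing = 0.5)
  b <- generate_femur(small_femur_params(seed = 3L), spacing = 0.5)
  expect_identical(a$density$voxels, b$density$voxels)
})

test_that("broaching at retention 0 empties the cavity, leaves the shell", {
  fem <- surgery_femur()
  br <- apply_broaching(fem, surgery_stage(retention = 0))
  cav <- br$info$cavity
  expect_true(all(br$labels$voxels[cav] == tissue_labels$cavity))
  expect_true(all(br$density$voxels[cav] == 0))
  expect_equal(br$info$shell_bvtv_post, br$info$shell_bvtv_pre)
  expect_equal(br$mass_g, fem$mass_g - br$info$removed_mass_g,
               tolerance = 1e-9)
})

test_that("broaching at retention 1 conserves bone mass within 0.1%", {
  fem <- surgery_femur()
  br <- apply_broaching(fem, surgery_stage(retention = 1))
  expect_lt(abs(br$mass_g - fem$mass_g) / fem$mass_g, 0.001)
  expect_gt(br$info$shell_bvtv_post, br$info$shell_bvtv_pre)
})

test_that("retention inversion hits a requested shell BV/TV increase", {
  fem <- surgery_femur()
  stage <- surgery_stage()
  r <- retention_for_shell_bvtv_delta(fem, stage, delta_pp = 10)
  br <- apply_broaching(fem, surgery_stage(retention = r))
  delta <- 100 * (br$info$shell_bvtv_post - br$info$shell_bvtv_pre)
  expect_lt(abs(delta - 10), 1)
})

test_that("implantation fills exactly the cavity and keeps bone mass", {
  fem <- surgery_femur()
  stage <- surgery_stage()
  br <- apply_broaching(fem, stage)
  imp <- insert_implant(br, stage)
  m <- imp$info$implant
  expect_true(all(imp$labels$voxels[m] == tissue_labels$implant))
  expect_equal(unique(imp$density$voxels[m]), stage$implant_density)
  expect_equal(imp$mass_g, br$mass_g, tolerance = 1e-12)
  # an implant wider than the broached cavity must be rejected
  big <- surgical_stage_params(width_mm = c(9, 5), length_mm = 16)
  expect_error(insert_implant(br, big), "exceeds")
  expect_error(insert_implant(fem, stage), "apply_broaching")
})

test_that("noise-free renders are exactly affine in density", {
  ph <- small_phantom()
  p <- scan_protocol(110, 80, "0.25 mm Sn", noise_sd = 0, seed = 1)
  scan <- render_scan(ph, p)
  go <- protocol_gain_offset(p)
  expect_equal(scan$voxels,
               go[["gain"]] * ph$density$voxels + go[["offset"]],
               tolerance = 1e-12)
})

test_that("renders are bit-identical under the same seed", {
  ph <- small_phantom()
  p <- scan_protocol(100, 100, "no", noise_sd = 25, seed = 99)
  expect_identical(render_scan(ph, p)$voxels, render_scan(ph, p)$voxels)
})

test_that("insert mean intensity sits within 3 standard errors of the model", {
  ph <- small_phantom()
  spec <- small_phantom_spec()
  p <- scan_protocol(100, 100, "0.25 mm Cu", noise_sd = 15, seed = 21)
  scan <- render_scan(ph, p)
  go <- protocol_gain_offset(p)
  for (i in seq_along(spec$densities)) {
    m <- phantomcal:::erode_mask(
      ph$labels$voxels == tissue_labels$insert_base + i, 2L)
    expected <- go[["gain"]] * spec$densities[i] + go[["offset"]]
    se <- p$noise_sd / sqrt(sum(m))
    expect_lt(abs(mean(scan$voxels[m]) - expected), 3 * se)
  }
})

test_that("medical-CT simulation downsamples by round(target/spacing)", {
  fem <- small_femur()                        # 0.25 mm voxels
  scan <- render_scan(fem, scan_protocol(noise_sd = 0))
  med <- simulate_medical_ct(scan, target_mm = 0.5)
  expect_equal(med$spacing, rep(0.5, 3))      # factor 2
  coarse <- volume_image(array(0, c(4, 4, 4)), spacing = rep(0.6, 3))
  expect_error(simulate_medical_ct(coarse), "resolution")
  # constant input stays constant up to the injected noise
  const <- volume_image(array(7, c(8, 8, 8)), spacing = rep(0.1, 3))
  out <- simulate_medical_ct(const, noise_sd = 0.1, seed = 4)
  expect_lt(max(abs(out$voxels - 7)), 0.5)
  expect_equal(mean(out$voxels), 7, tolerance = 0.05)
})

test_that("mass bookkeeping is consistent across every stage transition", {
  fem <- surgery_femur()
  stage <- surgery_stage(retention = 0.5)
  br <- apply_broaching(fem, stage)
  expected <- fem$mass_g - (1 - 0.5) * br$info$removed_mass_g
  expect_lt(abs(br$mass_g - expected) / fem$mass_g, 0.001)
  imp <- insert_implant(br, stage)
  expect_equal(imp$mass_g, br$mass_g, tolerance = 1e-12)
})
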