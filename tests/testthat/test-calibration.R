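test_that("density from mass and volume reproduces the reference table", {
  expect_equal(round(insert_density_from_mass_volume(10.25, 8925.62), 2),
               1.15)   # nylon, laser volume
  expect_equal(round(insert_density_from_mass_volume(18.21, 8546.67), 2),
               2.13)   # PTFE, CT volume
  expect_equal(insert_density_from_mass_volume(1, 1000), 1.00)
  expect_error(insert_density_from_mass_volume(-1, 10), "positive")
  expect_error(insert_density_from_mass_volume(1, 0), "positive")
})

test_that("the insert table reproduces every reference density at 2 dp", {
  tab <- build_insert_table()
  expect_equal(round(tab$density_laser, 2), c(1.15, 1.32, 1.42, 1.64, 2.16))
  expect_equal(round(tab$density_ct, 2), c(1.16, 1.31, 1.43, 1.60, 2.13))
  expect_equal(round(tab$density_mean, 2), c(1.15, 1.31, 1.42, 1.62, 2.15))
  # the mean column comes from unrounded per-method densities
  expect_equal(tab$density_mean,
               (tab$mass_g / tab$volume_laser_mm3 +
                tab$mass_g / tab$volume_ct_mm3) * 1000 / 2,
               tolerance = 1e-12)
  # equal volumes for both methods: the mean equals either method
  eq <- build_insert_table(data.frame(
    material = c("x", "y"), mass_g = c(10, 12),
    volume_laser_mm3 = c(8000, 8000), volume_ct_mm3 = c(8000, 8000)))
  expect_equal(eq$density_mean, eq$density_laser)
})

test_that("calibration fitting is exact on collinear points", {
  pts_i <- c(1000, 1400, 1800, 2200)
  fit <- fit_calibration(pts_i, 0.001 * pts_i)
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # two points: exact interpolation, zero residuals
  two <- fit_calibration(c(1000, 2000), c(1.0, 2.1))
  expect_equal(two$residuals, c(0, 0), tolerance = 1e-12)
  expect_equal(two$slope * 1500 + two$intercept, 1.55, tolerance = 1e-12)
})

test_that("OLS matches the closed-form normal-equation oracle", {
  withr::with_seed(10, {
    x <- c(1150, 1310, 1420, 1620, 2150) + rnorm(5, 0, 5)
    y <- c(1.15, 1.31, 1.42, 1.62, 2.15)
  })
  fit <- fit_calibration(x, y)
  # independent oracle: solve the normal equations explicitly
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  ss_res <- sum((y - X %*% beta)^2)
  expect_equal(fit$r_squared, 1 - ss_res / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  expect_error(fit_calibration(c(1, 1, 2), c(0.5, 0.9, 1.2)), "rank")
})

test_that("density mapping is affine, clamped, and unit-checked", {
  v <- volume_image(array(c(-500, 0, 1500, 3000), c(4, 1, 1)),
                    spacing = rep(1, 3))
  line <- fit_calibration(c(0, 1000), c(0, 1))   # slope 0.001, intercept 0
  d <- map_density(v, line, range = c(1.15, 2.15))
  expect_equal(as.vector(d$voxels), c(0, 0, 1.5, 3))   # negative clamps to 0
  expect_identical(d$unit, "g/cc")
  expect_equal(attr(d, "n_extrapolated"), 3L)
  expect_error(map_density(d, line), "intensity")
})

test_that("zero-noise render maps back to truth on pure-label voxels", {
  ph <- small_phantom()
  spec <- small_phantom_spec()
  p <- scan_protocol(110, 100, "0.25 mm Cu", noise_sd = 0, seed = 1)
  scan <- render_scan(ph, p)
  go <- protocol_gain_offset(p)
  line <- fit_calibration(go[["gain"]] * spec$densities + go[["offset"]],
                          spec$densities)
  d <- map_density(scan, line)
  # pure-label voxels: eroded insert interiors, clear of partial volume
  pure <- phantomcal:::erode_mask(ph$labels$voxels > 0, 2L)
  err <- abs(d$voxels - ph$density$voxels)
  expect_lt(max(err[pure]), 1e-9)
})

test_that("mapping is equivariant under intensity rescaling", {
  ph <- small_phantom()
  spec <- small_phantom_spec()
  scan <- render_scan(ph, scan_protocol(noise_sd = 5, seed = 31))
  labs <- segment_inserts(scan, spec)
  ins <- mean_intensity_per_label(scan, labs)
  cert <- spec$densities[ins$label - tissue_labels$insert_base]
  d1 <- map_density(scan, fit_calibration(ins$mean, cert))
  scaled <- volume_image(scan$voxels * 3.7, scan$spacing, scan$origin,
                         unit = "intensity")
  d2 <- map_density(scaled, fit_calibration(ins$mean * 3.7, cert))
  expect_equal(d1$voxels, d2$voxels, tolerance = 1e-9)
})

test_that("agreement statistics satisfy their identities", {
  withr::with_seed(12, a <- array(runif(20^3, 1, 2), c(20, 20, 20)))
  d1 <- volume_image(a, rep(0.2, 3), unit = "g/cc")
  # identical inputs: zero bias and sigma, unit slope and correlation
  s0 <- agreement_stats(d1, d1)
  expect_equal(s0$bias, 0)
  expect_equal(s0$sigma, 0)
  expect_equal(s0$slope, 1)
  expect_equal(s0$r, 1)
  # pure scaling: the regression slope reads the scale factor
  d2 <- volume_image(1.006 * a, rep(0.2, 3), unit = "g/cc")
  expect_equal(agreement_stats(d1, d2)$slope, 1.006, tolerance = 1e-9)
  expect_error(agreement_stats(d1, d2, mask = array(FALSE, dim(a))), "empty")
})

test_that("agreement sigma estimates the injected difference noise", {
  n <- c(50, 50, 50)                          # 1.25e5 voxels
  withr::with_seed(13, {
    base <- array(runif(prod(n), 1, 2), n)
    noise <- array(rnorm(prod(n), 0, 0.05), n)
  })
  d1 <- volume_image(base, rep(0.2, 3), unit = "g/cc")
  d2 <- volume_image(base + noise, rep(0.2, 3), unit = "g/cc")
  s <- agreement_stats(d1, d2)
  expect_gte(s$sigma, 0.045)
  expect_lte(s$sigma, 0.055)
  expect_equal(s$loa, 1.96 * s$sigma)
})
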