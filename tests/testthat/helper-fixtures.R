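# Shared fixtures, built once per test run and cached. Sizes are desk-scale
# versions of the study geometry: every quantitative property tested is
# resolution-checked, not size-dependent.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

small_phantom_spec <- function()
  default_phantom_spec(radius_mm = 3, height_mm = 8, ring_radius_mm = 9)

small_phantom <- function() fixture("phantom", {
  spec <- small_phantom_spec()
  generate_phantom(spec, phantom_grid(spec, spacing = 0.5))
})

small_femur_params <- function(seed = 7L)
  bone_phantom_params(outer_radius_mm = 6, length_mm = 15,
                      cortical_thickness_mm = 1.2,
                      correlation_length_mm = 0.5, seed = seed)

small_femur <- function() fixture("femur",
  generate_femur(small_femur_params(), spacing = 0.25))

surgery_femur <- function() fixture("surgery_femur",
  generate_femur(bone_phantom_params(outer_radius_mm = 8, length_mm = 24,
                                     cortical_thickness_mm = 1.5,
                                     correlation_length_mm = 0.5, seed = 7),
                 spacing = 0.2))

surgery_stage <- function(retention = 1)
  surgical_stage_params(width_mm = c(7, 3.5), length_mm = 16,
                        debris_retention = retention)

# tapered-tube surface point cloud (shaft segment) for registration tests
femur_surface_points <- function(n = 1200, seed = 42L) {
  withr::with_seed(seed, {
    th <- stats::runif(n, 0, 2 * pi)
    z <- stats::runif(n, 0, 30)
    r <- 8 + 2 * z / 30
    cbind(r * cos(th), r * sin(th), z)
  })
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

canonical_fcs <- function()
  define_fcs(head_center = c(0, 0, 40), condyle_midpoint = c(0, 0, -300),
             medial_point = c(30, 0, -300), side = "right")

as_mask_volume <- function(mask, like) {
  label_volume(array(as.integer(mask), dim(like$voxels)), like$spacing,
               like$origin)
}

bone_domain_volume <- function(gt) {
  keep <- c(tissue_labels$marrow, tissue_labels$trabecular,
            tissue_labels$cortical)
  as_mask_volume(gt$labels$voxels %in% keep, gt$labels)
}

bone_mask_volume <- function(gt)
  as_mask_volume(gt$labels$voxels %in% bone_labels(), gt$labels)
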