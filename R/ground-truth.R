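#' Ground-truth container for synthetic volumes
#'
#' Pairs a voxel-wise real-density map (g/cc) with a tissue label volume and
#' bookkeeping of total bone mass, so downstream stages can be validated
#' against known truth.
#'
#' @param density A [volume_image()] with unit `"g/cc"`.
#' @param labels A label [volume_image()] on the same grid.
#' @param info Optional list of generator metadata.
#' @return An object of class `ground_truth` with elements `density`,
#'   `labels`, `mass_g` (bone mass in g) and `info`.
#' @export
ground_truth <- function(density, labels, info = list()) {
  stopifnot(inherits(density, "volume_image"), density$unit == "g/cc",
            inherits(labels, "volume_image"), labels$unit == "label")
  stopifnot_same_grid(density, labels)
  structure(list(density = density, labels = labels,
                 mass_g = bone_mass(density, labels), info = info),
            class = "ground_truth")
}

#' Bone mass from a density map and label volume
#'
#' Mass (g) is the sum of density (g/cc) times voxel volume (mm^3, converted
#' to cc) over voxels whose label is bone (trabecular or cortical).
#'
#' @param density A `"g/cc"` [volume_image()].
#' @param labels A label [volume_image()] on the same grid.
#' @param which Integer label codes counted as bone.
#' @return Mass in g.
#' @export
bone_mass <- function(density, labels, which = bone_labels()) {
  stopifnot_same_grid(density, labels)
  m <- labels$voxels %in% which
  sum(density$voxels[m]) * voxel_volume(density) / 1000
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$density$voxels)
  cat(sprintf("<ground_truth> %d x %d x %d voxels, bone mass %.4g g\n",
              d[1], d[2], d[3], x$mass_g))
  tab <- table(x$labels$voxels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  invisible(x)
}
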