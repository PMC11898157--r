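# Segmentation: per-insert thresholding for the phantom, masked intensity
# histograms, and marker-seeded gradient watershed for bone.

#' Segment phantom inserts from an intensity volume
#'
#' The `n_inserts + 1` dominant intensity modes (base material plus one per
#' insert) are located on a smoothed histogram, and the threshold between
#' neighbouring modes is set by Otsu's method on the voxels lying between
#' them. Each insert mask is then cleaned by keeping the
#' largest 6-connected component and eroding it (default 2 voxels) to shed
#' partial-volume boundary voxels, which makes the masked mean intensity
#' unbiased on the synthetic oracle.
#'
#' The mapping from intensity band to insert assumes the scanner gain is
#' positive (denser inserts are brighter) and that the base material is the
#' least dense component in view.
#'
#' @param vol An `"intensity"` [volume_image()] containing the phantom.
#' @param spec The [phantom_spec()] (supplies the number of inserts and the
#'   density ordering).
#' @param erode_voxels Erosion depth applied to each insert mask.
#' @param max_sample Maximum number of voxels used for clustering.
#' @return A label [volume_image()]; insert `k` (in `spec` order) has label
#'   `tissue_labels$insert_base + k`.
#' @export
segment_inserts <- function(vol, spec, erode_voxels = 2L, max_sample = 2e5) {
  stopifnot(inherits(vol, "volume_image"), inherits(spec, "phantom_spec"))
  x <- as.vector(vol$voxels)
  n_ins <- length(spec$densities)
  k <- n_ins + 1L
  samp <- if (length(x) > max_sample) {
    x[round(seq(1L, length(x), length.out = max_sample))]
  } else x
  # histogram-peak estimates of the base/insert intensity modes
  centers <- find_intensity_modes(samp, k)
  # refine thresholds between neighbouring modes with Otsu
  thresholds <- vapply(seq_len(k - 1L), function(i) {
    between <- samp[samp >= centers[i] & samp <= centers[i + 1L]]
    if (length(between) < 10L) (centers[i] + centers[i + 1L]) / 2
    else otsu_threshold(between)
  }, numeric(1))
  ord <- order(spec$densities)               # ascending density = ascending band
  labs <- array(0L, dim(vol$voxels))
  for (b in seq_len(n_ins)) {
    lo <- thresholds[b]
    hi <- if (b < n_ins) thresholds[b + 1L] else Inf
    mask <- vol$voxels > lo & vol$voxels <= hi
    if (!any(mask))
      stop("segmentation error: found 0 components for insert band ", b,
           " (expected 1)")
    cc <- connected_components(mask)
    mask <- cc == 1L                          # largest component
    mask <- erode_mask(mask, as.integer(erode_voxels))
    if (!any(mask))
      stop("segmentation error: insert band ", b,
           " vanished after erosion (found 0, expected 1 component)")
    labs[mask] <- tissue_labels$insert_base + ord[b]
  }
  label_volume(labs, vol$spacing, vol$origin)
}

#' Intensity histogram of a masked sample
#'
#' Bin width follows the Freedman-Diaconis rule on the masked sample; the
#' reported moments are computed from the raw voxels, not from the bins.
#'
#' @param x Numeric vector of masked voxel values.
#' @return An object of class `intensity_histogram`: `breaks`, `counts`,
#'   `n`, `mean`, `variance`.
#' @export
intensity_histogram <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty sample")
  if (diff(range(x)) == 0) {
    breaks <- c(x[1] - 0.5, x[1] + 0.5)
    counts <- length(x)
  } else {
    iqr <- stats::IQR(x)
    bw <- if (iqr > 0) 2 * iqr / length(x)^(1 / 3) else diff(range(x)) / 30
    nb <- max(1L, min(512L, ceiling(diff(range(x)) / bw)))
    breaks <- seq(min(x), max(x), length.out = nb + 1L)
    counts <- hist(x, breaks = breaks, plot = FALSE)$counts
  }
  structure(list(breaks = breaks, counts = counts, n = length(x),
                 mean = mean(x), variance = if (length(x) > 1L) stats::var(x) else 0),
            class = "intensity_histogram")
}

#' Per-label intensity summaries
#'
#' For every non-zero label, the masked intensity histogram and its moments.
#'
#' @param vol An intensity [volume_image()].
#' @param labels A label [volume_image()] on the same grid.
#' @return A data.frame with columns `label`, `n`, `mean`, `variance` and a
#'   list column `histogram` of [intensity_histogram()] objects.
#' @export
mean_intensity_per_label <- function(vol, labels) {
  stopifnot(inherits(vol, "volume_image"), inherits(labels, "volume_image"))
  stopifnot_same_grid(vol, labels)
  lv <- as.vector(labels$voxels)
  present <- sort(unique(lv[lv > 0L]))
  if (length(present) == 0L) stop("label volume contains no non-zero labels")
  hs <- lapply(present, function(l) intensity_histogram(vol$voxels[lv == l]))
  out <- data.frame(label = present,
                    n = vapply(hs, `[[`, 0, "n"),
                    mean = vapply(hs, `[[`, 0, "mean"),
                    variance = vapply(hs, `[[`, 0, "variance"))
  out$histogram <- hs
  out
}

#' Marker-seeded gradient watershed bone segmentation
#'
#' The volume is smoothed (Gaussian, `sigma_mm`), conservative bone and
#' background markers are taken at upper/lower intensity quantiles, and
#' marker labels are flooded over the gradient-magnitude landscape in
#' ascending gradient bands (discrete immersion). Voxels never reached by
#' the flood are assigned to the marker whose mean smoothed intensity is
#' closer.
#'
#' @param vol An intensity [volume_image()].
#' @param sigma_mm Smoothing sigma in mm (0 disables smoothing).
#' @param bone_quantile Intensity quantile seeding the bone marker.
#' @param background_quantile Intensity quantile bounding the background
#'   marker.
#' @param n_levels Number of gradient flooding bands.
#' @return A binary label [volume_image()] (1 = bone).
#' @export
watershed_bone_segmentation <- function(vol, sigma_mm = 0.2,
                                        bone_quantile = 0.99,
                                        background_quantile = 0.50,
                                        n_levels = 24L) {
  stopifnot(inherits(vol, "volume_image"))
  sm <- gaussian_smooth(vol$voxels, sigma_mm, vol$spacing)
  q <- stats::quantile(sm, c(background_quantile, bone_quantile),
                       names = FALSE)
  bg_marker <- sm <= q[1]
  bone_marker <- sm >= q[2]
  if (!any(bone_marker) || !any(bg_marker))
    stop("empty marker at the chosen quantiles; adjust the thresholds")
  if (q[1] >= q[2])
    stop("marker quantiles do not separate bone from background")
  grad <- gradient_magnitude(sm, vol$spacing)
  labs <- array(0L, dim(sm))
  labs[bg_marker] <- 1L
  labs[bone_marker] <- 2L
  free <- grad[labs == 0L]
  levels <- if (length(free)) {
    unique(stats::quantile(free, seq_len(n_levels) / n_levels, names = FALSE))
  } else numeric(0)
  for (lev in c(levels, Inf)) {
    repeat {
      nb <- neighbor_reduce(labs, pmax, fill = 0L, include_self = FALSE)
      grow <- labs == 0L & nb > 0L & grad <= lev
      if (!any(grow)) break
      labs[grow] <- nb[grow]
    }
  }
  if (any(labs == 0L)) {
    mu_bg <- mean(sm[bg_marker])
    mu_bone <- mean(sm[bone_marker])
    rest <- labs == 0L
    labs[rest] <- ifelse(abs(sm[rest] - mu_bone) <= abs(sm[rest] - mu_bg),
                         2L, 1L)
  }
  label_volume(array(as.integer(labs == 2L), dim(sm)), vol$spacing,
               vol$origin)
}
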