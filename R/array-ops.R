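# Vectorised 3D array primitives shared by the generators, segmentation and
# ROI code. All operate on plain arrays; physical units enter only through
# the spacing arguments.

#' Shift a 3D array along one axis
#'
#' Content moves towards higher indices for `by > 0`; vacated positions are
#' filled with `fill`.
#' @param a 3D array.
#' @param axis Axis (1..3).
#' @param by Integer shift.
#' @param fill Fill value for vacated positions.
#' @return Shifted array of identical dimensions.
#' @keywords internal
shift_array <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  n <- d[axis]
  if (by == 0L) return(a)
  if (abs(by) >= n) return(array(fill, d))
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  src <- idx
  dst <- idx
  if (by > 0L) {
    src[[axis]] <- seq_len(n - by)
    dst[[axis]] <- (by + 1L):n
  } else {
    src[[axis]] <- (1L - by):n
    dst[[axis]] <- seq_len(n + by)
  }
  out <- array(fill, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Apply f cumulatively over the six face neighbours (and optionally self).
neighbor_reduce <- function(a, f, fill, include_self = TRUE) {
  acc <- if (include_self) a else NULL
  for (axis in 1:3) {
    for (by in c(-1L, 1L)) {
      s <- shift_array(a, axis, by, fill)
      acc <- if (is.null(acc)) s else f(acc, s)
    }
  }
  acc
}

#' Binary erosion with the 6-connected structuring element
#' @param mask Logical 3D array.
#' @param iterations Erosion depth in voxels.
#' @return Logical array.
#' @keywords internal
erode_mask <- function(mask, iterations = 1L) {
  m <- mask
  for (i in seq_len(iterations))
    m <- neighbor_reduce(m, `&`, fill = FALSE)
  m
}

#' Binary dilation with the 6-connected structuring element
#' @keywords internal
dilate_mask <- function(mask, iterations = 1L) {
  m <- mask
  for (i in seq_len(iterations))
    m <- neighbor_reduce(m, `|`, fill = FALSE)
  m
}

#' 6-connected components of a binary mask
#'
#' Iterative minimum-label propagation; component ids are relabelled 1..k in
#' decreasing size order so component 1 is always the largest.
#' @param mask Logical 3D array.
#' @return Integer array, 0 = background.
#' @keywords internal
connected_components <- function(mask) {
  d <- dim(mask)
  ids <- array(0L, d)
  ids[mask] <- seq_len(sum(mask))
  ids[!mask] <- NA_integer_
  repeat {
    nxt <- neighbor_reduce(ids, function(x, y) pmin(x, y, na.rm = TRUE),
                           fill = NA_integer_)
    nxt[!mask] <- NA_integer_
    if (identical(nxt, ids)) break
    ids <- nxt
  }
  ids[!mask] <- 0L
  lab <- ids[mask]
  sizes <- sort(table(lab), decreasing = TRUE)
  remap <- integer(max(lab))
  remap[as.integer(names(sizes))] <- seq_along(sizes)
  ids[mask] <- remap[lab]
  ids
}

# Group-sum along one axis with block length `f` (trailing partial blocks
# allowed). Returns an array whose `axis` dimension is ceiling(n / f).
axis_group_sum <- function(a, axis, f) {
  if (f == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  grp <- (seq_len(n) - 1L) %/% f
  m <- matrix(ap, nrow = n)
  s <- rowsum(m, group = grp, reorder = TRUE)
  dn <- d[perm]
  dn[1] <- nrow(s)
  out <- array(s, dn)
  aperm(out, order(perm))
}

#' Separable Gaussian smoothing with physical sigma
#'
#' Boundary handling renormalises the kernel over the available support so
#' edge voxels are unbiased for constant inputs.
#' @param a 3D numeric array.
#' @param sigma_mm Gaussian standard deviation in mm (scalar).
#' @param spacing Numeric length-3 voxel size (mm).
#' @return Smoothed array.
#' @keywords internal
gaussian_smooth <- function(a, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(a)
  num <- a
  den <- array(1, dim(a))
  for (axis in 1:3) {
    sv <- sigma_mm / spacing[axis]
    r <- max(1L, ceiling(3 * sv))
    k <- exp(-0.5 * ((-r:r) / sv)^2)
    k <- k / sum(k)
    nn <- array(0, dim(a))
    dd <- array(0, dim(a))
    for (j in seq_along(k)) {
      by <- j - r - 1L
      nn <- nn + k[j] * shift_array(num, axis, by, 0)
      dd <- dd + k[j] * shift_array(den, axis, by, 0)
    }
    num <- nn
    den <- dd
  }
  num / den
}

#' Gradient magnitude with central differences (per-mm units)
#' @keywords internal
gradient_magnitude <- function(a, spacing) {
  g2 <- array(0, dim(a))
  for (axis in 1:3) {
    # replicate edges so boundary gradients stay one-sided
    fw <- shift_array(a, axis, -1L, NA)
    bw <- shift_array(a, axis, 1L, NA)
    fw[is.na(fw)] <- a[is.na(fw)]
    bw[is.na(bw)] <- a[is.na(bw)]
    g2 <- g2 + ((fw - bw) / (2 * spacing[axis]))^2
  }
  sqrt(g2)
}

#' Euclidean distance transform, exact up to a distance cap
#'
#' Separable squared-distance transform with anisotropic spacing. Distances
#' beyond `cap_mm` are returned as `Inf`; the per-axis scan range is capped
#' accordingly, which keeps the cost proportional to the cap.
#' @param mask Logical 3D array; distance is measured to the nearest `TRUE`
#'   voxel centre.
#' @param spacing Numeric length-3 voxel size (mm).
#' @param cap_mm Largest distance (mm) that must be exact.
#' @return Numeric array of distances in mm (`0` inside the mask, `Inf`
#'   beyond the cap).
#' @keywords internal
distance_transform <- function(mask, spacing, cap_mm) {
  d2 <- array(Inf, dim(mask))
  d2[mask] <- 0
  for (axis in 1:3) {
    s <- spacing[axis]
    smax <- ceiling(cap_mm / s)
    cur <- d2
    for (sh in seq_len(smax)) {
      off <- (sh * s)^2
      if (off > cap_mm^2 + 2 * s * cap_mm) break
      cur <- pmin(cur,
                  shift_array(d2, axis, sh, Inf) + off,
                  shift_array(d2, axis, -sh, Inf) + off)
    }
    d2 <- cur
  }
  out <- sqrt(d2)
  out[out > cap_mm] <- Inf
  out
}

#' Locate the k dominant intensity modes of a sample
#'
#' Peaks of a lightly smoothed fixed-width histogram, ranked by height with
#' greedy minimum-separation suppression. Robust to one mode dominating the
#' sample (a phantom's base material) because peak height within a mode
#' does not compete across modes.
#'
#' @param x Numeric vector.
#' @param k Number of modes expected.
#' @param nbins Histogram resolution.
#' @param smooth Moving-average half-window (bins) applied to the counts.
#' @return Ascending numeric vector of k mode locations.
#' @keywords internal
find_intensity_modes <- function(x, k, nbins = 512L, smooth = 2L) {
  rng <- range(x)
  if (diff(rng) == 0) {
    if (k == 1L) return(rng[1])
    stop("segmentation error: found 1 intensity mode, expected ", k)
  }
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- hist(x, breaks = br, plot = FALSE)
  cnt <- h$counts
  if (smooth > 0L) {
    w <- 2L * smooth + 1L
    cnt <- as.numeric(stats::filter(c(rep(0, smooth), cnt, rep(0, smooth)),
                                    rep(1 / w, w), sides = 2))
    cnt <- cnt[(smooth + 1L):(smooth + nbins)]
  }
  left <- c(-Inf, cnt[-nbins])
  right <- c(cnt[-1], -Inf)
  peaks <- which(cnt >= left & cnt > right & cnt > 0)
  if (length(peaks) == 0L)
    stop("segmentation error: found 0 intensity modes, expected ", k)
  peaks <- peaks[order(cnt[peaks], decreasing = TRUE)]
  min_sep <- max(3L, nbins %/% (8L * k))
  keep <- integer(0)
  for (p in peaks) {
    if (all(abs(keep - p) > min_sep)) keep <- c(keep, p)
    if (length(keep) == k) break
  }
  if (length(keep) < k)
    stop("segmentation error: found ", length(keep),
         " intensity modes, expected ", k)
  sort(h$mids[keep])
}

#' Otsu threshold of a numeric sample
#'
#' Maximises between-class variance on a fixed-width histogram.
#' @param x Numeric vector.
#' @param nbins Number of histogram bins.
#' @return Threshold value.
#' @keywords internal
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  k <- which.max(bcv[-length(bcv)])
  (mids[k] + mids[k + 1L]) / 2
}
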