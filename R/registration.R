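# Rigid alignment across surgical stages: anatomical coordinate frame,
# SVD-based iterative closest point, and label transfer between grids.

#' Rigid transform (rotation + translation, world coordinates)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 translation (mm).
#' @param rms Optional final RMS residual (mm).
#' @param iterations Optional iteration count.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rms = NA_real_, iterations = NA_integer_) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal (R'R = I within 1e-9)")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rms = rms, iterations = iterations),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param t A [rigid_transform()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts %*% t(t$rotation), 2, t$translation, `+`)
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Anatomical femur coordinate system
#'
#' Builds a right-handed orthonormal frame from landmark proxies by
#' Gram-Schmidt: the superior-inferior axis runs from the condylar midpoint
#' to the head centre; the medial-lateral axis is the medial landmark
#' direction orthogonalised against it; anterior-posterior completes the
#' right-handed set. For a left femur the medial-lateral axis is flipped so
#' "medial" keeps its anatomical meaning.
#'
#' @param head_center Length-3 femoral head centre (mm).
#' @param condyle_midpoint Length-3 condylar midpoint proxy (mm).
#' @param medial_point Length-3 point on the medial side of the shaft (mm).
#' @param side `"right"` or `"left"`.
#' @return An object of class `femur_coordinate_system`: `origin` and a 3x3
#'   matrix `axes` whose columns are medial-lateral, anterior-posterior and
#'   superior-inferior unit vectors.
#' @export
define_fcs <- function(head_center, condyle_midpoint, medial_point,
                       side = c("right", "left")) {
  side <- match.arg(side)
  si <- as.numeric(head_center) - as.numeric(condyle_midpoint)
  nsi <- sqrt(sum(si^2))
  if (nsi < 1e-9) stop("head centre and condylar midpoint coincide")
  si <- si / nsi
  mlr <- as.numeric(medial_point) - as.numeric(condyle_midpoint)
  ml <- mlr - sum(mlr * si) * si
  nml <- sqrt(sum(ml^2))
  if (nml < 1e-9) stop("landmarks are collinear; cannot define a frame")
  ml <- ml / nml
  if (side == "left") ml <- -ml
  ap <- c(si[2] * ml[3] - si[3] * ml[2],
          si[3] * ml[1] - si[1] * ml[3],
          si[1] * ml[2] - si[2] * ml[1])   # si x ml
  axes <- cbind(ml = ml, ap = ap, si = si)
  structure(list(origin = as.numeric(condyle_midpoint), axes = axes,
                 side = side),
            class = "femur_coordinate_system")
}

# nearest-neighbour indices of each row of `query` in `ref`, brute force in
# chunks (point sets at stage-registration scale are a few thousand points)
.nn_index <- function(query, ref, chunk = 512L) {
  n <- nrow(query)
  out <- integer(n)
  ref2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    d <- outer(rowSums(q^2), ref2, `+`) - 2 * q %*% t(ref)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

# closed-form rigid Procrustes (Kabsch) for paired point sets
.procrustes_rigid <- function(src, tgt) {
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  H <- crossprod(sweep(src, 2, cs), sweep(tgt, 2, ct))
  sv <- svd(H)
  dfix <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% dfix %*% t(sv$u)
  t <- ct - as.vector(R %*% cs)
  list(rotation = R, translation = t)
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbour correspondence with the SVD-based
#' Procrustes update; terminates when the RMS residual changes by less than
#' `tolerance_mm` or after `max_iterations`.
#'
#' @param source,target n x 3 matrices of surface points (mm); at least 3
#'   non-collinear points each, with initial overlap (same specimen).
#' @param max_iterations Iteration cap.
#' @param tolerance_mm Convergence threshold on the RMS change (mm).
#' @return A [rigid_transform()] mapping source onto target, with final
#'   `rms` (mm) and `iterations`.
#' @export
icp_rigid_register <- function(source, target, max_iterations = 50L,
                               tolerance_mm = 1e-6) {
  source <- matrix(as.numeric(source), ncol = 3L)
  target <- matrix(as.numeric(target), ncol = 3L)
  if (nrow(source) < 3L || nrow(target) < 3L)
    stop("need at least 3 points per set")
  for (pts in list(source, target)) {
    s <- svd(sweep(pts, 2, colMeans(pts)))$d
    if (s[2] < 1e-9 * max(s[1], 1))
      stop("degenerate (collinear) point set: rank deficient")
  }
  R <- diag(3)
  tr <- c(0, 0, 0)
  cur <- source
  prev_rms <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    nn <- .nn_index(cur, target)
    pr <- .procrustes_rigid(source, target[nn, , drop = FALSE])
    R <- pr$rotation
    tr <- pr$translation
    cur <- sweep(source %*% t(R), 2, tr, `+`)
    rms <- sqrt(mean(rowSums((cur - target[nn, , drop = FALSE])^2)))
    if (abs(prev_rms - rms) < tolerance_mm || it >= max_iterations) break
    prev_rms <- rms
  }
  rigid_transform(R, tr, rms = rms, iterations = it)
}

#' Transfer a label volume through a rigid transform
#'
#' Nearest-neighbour resampling through world coordinates (labels must not
#' be interpolated): each target voxel centre is pulled back through the
#' inverse transform and sampled from the source grid; voxels mapping
#' outside the source grid become 0.
#'
#' @param roi A label [volume_image()] in the source frame.
#' @param t A [rigid_transform()] mapping source world coordinates to
#'   target world coordinates.
#' @param target_grid A [grid_spec()] for the output.
#' @return A label [volume_image()] on `target_grid`.
#' @export
transfer_roi <- function(roi, t, target_grid) {
  stopifnot(inherits(roi, "volume_image"), roi$unit == "label",
            inherits(t, "rigid_transform"))
  d <- target_grid$dims
  sp <- target_grid$spacing
  org <- target_grid$origin
  xs <- org[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  w <- cbind(rep(xs, times = d[2] * d[3]),
             rep(rep(ys, each = d[1]), times = d[3]),
             rep(zs, each = d[1] * d[2]))
  ws <- apply_transform(invert_transform(t), w)
  sd_ <- dim(roi$voxels)
  idx <- sweep(sweep(ws, 2, roi$origin), 2, roi$spacing, `/`)
  idx <- round(idx) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= sd_[1] &
    idx[, 2] >= 1 & idx[, 2] <= sd_[2] &
    idx[, 3] >= 1 & idx[, 3] <= sd_[3]
  out <- integer(nrow(idx))
  out[ok] <- roi$voxels[idx[ok, , drop = FALSE]]
  label_volume(array(out, d), sp, org)
}
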