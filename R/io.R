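# Volume input/output. NIfTI goes through RNifti, TIFF stacks through the
# tiff package plus a required key=value sidecar (TIFF has no standard 3D
# spacing field), and MetaImage (.mhd/.mha) is read/written directly: the
# format is a plain-text key=value header plus raw little-endian voxel data.

.format_from_path <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.(mhd|mha)$", lp)) return("metaimage")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(tif|tiff)$", lp)) return("tiff")
  stop("cannot infer volume format from path: ", path)
}

#' Read a 3D volume with physical metadata
#'
#' Supported formats: MetaImage (`.mhd`/`.mha`), NIfTI (`.nii`/`.nii.gz`) and
#' multi-page TIFF stacks with a required `<file>.spacing.txt` sidecar
#' carrying `spacing_mm`, and optionally `origin_mm` and `unit`.
#'
#' @param path File path.
#' @param format One of `"metaimage"`, `"nifti"`, `"tiff"`; inferred from the
#'   extension when omitted.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- if (is.null(format)) .format_from_path(path) else
    match.arg(format, c("metaimage", "nifti", "tiff"))
  switch(format,
         metaimage = .read_metaimage(path),
         nifti = .read_nifti(path),
         tiff = .read_tiff_stack(path))
}

#' Write a 3D volume with physical metadata
#'
#' The unit tag is stored in the header (MetaImage `Comment`, NIfTI
#' `descrip`) or the TIFF sidecar and recovered by [read_volume()].
#'
#' @param vol A [volume_image()].
#' @param path Output path (parent directory must exist).
#' @param format See [read_volume()]; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  format <- if (is.null(format)) .format_from_path(path) else
    match.arg(format, c("metaimage", "nifti", "tiff"))
  switch(format,
         metaimage = .write_metaimage(vol, path),
         nifti = .write_nifti(vol, path),
         tiff = .write_tiff_stack(vol, path))
  invisible(path)
}

# ---- MetaImage ----

.write_metaimage <- function(vol, path) {
  local <- grepl("\\.mha$", tolower(path))
  et <- if (vol$unit == "label") "MET_INT" else "MET_DOUBLE"
  datafile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(vol$voxels), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                    collapse = " ")),
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    paste0("Comment = unit:", vol$unit),
    paste("ElementType =", et),
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  write_data <- function(con) {
    if (vol$unit == "label")
      writeBin(as.integer(vol$voxels), con, size = 4L, endian = "little")
    else
      writeBin(as.double(vol$voxels), con, size = 8L, endian = "little")
  }
  if (local) {
    write_data(con)
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    write_data(rawcon)
  }
  invisible(path)
}

.parse_mhd_header <- function(lines) {
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1) x[2] else "", ""))
  stats::setNames(as.list(vals), keys)
}

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) stop("corrupt MetaImage header: ", path)
    lines <- c(lines, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  h <- .parse_mhd_header(lines)
  need <- c("DimSize", "ElementSpacing", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("MetaImage header missing field(s): ",
                         paste(miss, collapse = ", "))
  dims <- as.integer(strsplit(h$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(h$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(h$Offset))
    as.numeric(strsplit(h$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  unit <- "intensity"
  if (!is.null(h$Comment) && grepl("^unit:", h$Comment))
    unit <- sub("^unit:", "", h$Comment)
  n <- prod(dims)
  read_data <- function(con) {
    switch(h$ElementType,
           MET_DOUBLE = readBin(con, "double", n, size = 8L, endian = "little"),
           MET_FLOAT = readBin(con, "double", n, size = 4L, endian = "little"),
           MET_INT = readBin(con, "integer", n, size = 4L, endian = "little"),
           MET_SHORT = readBin(con, "integer", n, size = 2L, endian = "little"),
           MET_UCHAR = as.integer(readBin(con, "raw", n)),
           stop("unsupported MetaImage ElementType: ", h$ElementType))
  }
  if (identical(h$ElementDataFile, "LOCAL")) {
    vox <- read_data(con)
  } else {
    raw_path <- file.path(dirname(path), h$ElementDataFile)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    rc <- file(raw_path, "rb")
    on.exit(close(rc), add = TRUE)
    vox <- read_data(rc)
  }
  if (length(vox) != n) stop("corrupt MetaImage data: expected ", n,
                             " voxels, got ", length(vox))
  volume_image(array(vox, dims), spacing, origin, unit = unit)
}

# ---- NIfTI ----

.write_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  m[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img$descrip <- paste0("unit:", vol$unit)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  spacing <- RNifti::pixdim(img)[1:3]
  x <- RNifti::xform(img)
  origin <- x[1:3, 4]
  unit <- "intensity"
  if (grepl("^unit:", h$descrip)) unit <- sub("^unit:", "", h$descrip)
  vox <- array(as.numeric(img), dim(img)[1:3])
  volume_image(vox, spacing, origin, unit = unit)
}

# ---- TIFF stack + sidecar ----

.sidecar_path <- function(path) paste0(path, ".spacing.txt")

.write_tiff_stack <- function(vol, path) {
  d <- dim(vol$voxels)
  # one 32-bit float page per z slice; values scaled into [0,1] by an
  # affine recorded in the sidecar (writeTIFF clamps outside [0,1])
  rng <- range(vol$voxels)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(d[3]), function(k)
    (vol$voxels[, , k] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(c(
    paste("spacing_mm =", paste(format(vol$spacing, digits = 17),
                                collapse = " ")),
    paste("origin_mm =", paste(format(vol$origin, digits = 17),
                               collapse = " ")),
    paste("unit =", vol$unit),
    paste("value_offset =", format(rng[1], digits = 17)),
    paste("value_scale =", format(scale, digits = 17))),
    .sidecar_path(path))
  invisible(path)
}

.read_tiff_stack <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc))
    stop("TIFF stack is missing its spacing sidecar (expected ", sc,
         " with a `spacing_mm` entry)")
  h <- .parse_mhd_header(readLines(sc))
  if (is.null(h$spacing_mm))
    stop("sidecar ", sc, " is missing the required field `spacing_mm`")
  spacing <- as.numeric(strsplit(h$spacing_mm, "\\s+")[[1]])
  origin <- if (!is.null(h$origin_mm))
    as.numeric(strsplit(h$origin_mm, "\\s+")[[1]]) else c(0, 0, 0)
  unit <- if (!is.null(h$unit)) h$unit else "intensity"
  off <- if (!is.null(h$value_offset)) as.numeric(h$value_offset) else 0
  scl <- if (!is.null(h$value_scale)) as.numeric(h$value_scale) else 1
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  vox <- array(0, d)
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]] * scl + off
  if (unit == "label") vox <- round(vox)
  volume_image(vox, spacing, origin, unit = unit)
}

# ---- Resampling ----

#' Block-average downsampling (partial-volume analogue)
#'
#' Each output voxel is the arithmetic mean of its source block; trailing
#' partial blocks are averaged over the voxels available, so grid dimensions
#' need not divide evenly. Output spacing is input spacing times the factor.
#' On evenly dividing grids the grand mean (and hence total
#' intensity x volume) is conserved.
#'
#' @param vol A [volume_image()].
#' @param factor Integer downsampling factor, scalar or per-axis (>= 1).
#' @return A coarser [volume_image()] with the same unit tag.
#' @export
block_average_resample <- function(vol, factor) {
  stopifnot(inherits(vol, "volume_image"))
  factor <- as.integer(round(factor))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (length(factor) != 3L || any(factor < 1L))
    stop("`factor` must be >= 1 on each axis")
  num <- vol$voxels
  storage.mode(num) <- "double"
  den <- array(1, dim(num))
  for (axis in 1:3) {
    num <- axis_group_sum(num, axis, factor[axis])
    den <- axis_group_sum(den, axis, factor[axis])
  }
  out <- num / den
  new_spacing <- vol$spacing * factor
  # first coarse voxel centre sits at the mean of its source block centres
  new_origin <- vol$origin + (factor - 1) / 2 * vol$spacing
  unit <- if (vol$unit == "label") "intensity" else vol$unit
  volume_image(out, new_spacing, new_origin, unit = unit)
}
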