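mha_types <- list(MET_UCHAR = list(what = "integer", size = 1L,
                                   signed = FALSE),
                  MET_USHORT = list(what = "integer", size = 2L,
                                    signed = FALSE),
                  MET_SHORT = list(what = "integer", size = 2L,
                                   signed = TRUE),
                  MET_FLOAT = list(what = "numeric", size = 4L,
                                   signed = TRUE),
                  MET_DOUBLE = list(what = "numeric", size = 8L,
                                    signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("corrupt MetaImage header (no ElementDataFile): ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("corrupt MetaImage header line in ", path,
                               ": ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  type <- mha_types[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported MetaImage ElementType ",
                          hdr$ElementType, " in ", path)
  if (identical(hdr$ByteOrderMSB, "True") ||
      identical(hdr$BinaryDataByteOrderMSB, "True"))
    stop("big-endian MetaImage not supported: ", path)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = type$signed, endian = "little")
  } else {
    dpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(dpath)) stop("MetaImage data file missing: ", dpath)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    raw <- readBin(dcon, type$what, n = n, size = type$size,
                   signed = type$signed, endian = "little")
  }
  if (length(raw) < n) stop("truncated MetaImage data in ", path)
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, length(dims))
  # MetaImage stores x (col) fastest; R matrices store rows fastest, so the
  # first MetaImage dim maps to R columns
  if (length(dims) == 2L) {
    img <- t(matrix(raw, dims[1], dims[2]))
    list(image = img, spacing = c(sp[2], sp[1]))
  } else {
    arr <- aperm(array(raw, dims), c(2, 1, 3))
    list(image = arr, spacing = c(sp[2], sp[1], sp[3]))
  }
}

write_metaimage <- function(image, path, spacing = c(1, 1),
                            type = "MET_FLOAT") {
  tp <- mha_types[[type]]
  if (is.null(tp)) stop("unsupported MetaImage ElementType ", type)
  stopifnot(is.matrix(image))
  hdr <- c("ObjectType = Image",
           "NDims = 2",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d", ncol(image), nrow(image)),
           sprintf("ElementSpacing = %.17g %.17g", spacing[2], spacing[1]),
           sprintf("ElementType = %s", type),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  dat <- as.vector(t(image))  # x fastest
  if (tp$what == "integer") dat <- as.integer(round(dat))
  writeBin(dat, con, size = tp$size, endian = "little")
  invisible(path)
}

image_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return("nii")
  tolower(tools::file_ext(p))
}

#' Read a grayscale image with physical spacing
#'
#' Supported formats: PNG (spacing defaults to 1 mm/pixel, overridable),
#' NIfTI (`.nii`, `.nii.gz`; spacing from the header) and MetaImage
#' (`.mha`/`.mhd`, little-endian).  3D volumes are exposed slice-wise along
#' the transverse (third) axis via `slice`.
#'
#' @param path File path.
#' @param spacing Optional `(row mm, col mm)` override.
#' @param slice Transverse slice index for 3D volumes.
#' @return List with `image` (numeric matrix) and `spacing`.
#' @export
read_image <- function(path, spacing = NULL, slice = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- image_ext(path)
  out <- switch(ext,
    png = {
      px <- png::readPNG(path)
      if (length(dim(px)) == 3L) px <- apply(px[, , 1:min(3, dim(px)[3]),
                                                drop = FALSE], c(1, 2), mean)
      list(image = px, spacing = c(1, 1))
    },
    nii = {
      v <- RNifti::readNifti(path)
      pd <- RNifti::pixdim(v)
      arr <- array(as.vector(v), dim(v))
      if (length(dim(arr)) == 2L) list(image = arr, spacing = pd[1:2])
      else list(image = arr, spacing = pd[seq_along(dim(arr))])
    },
    mha = read_metaimage(path),
    mhd = read_metaimage(path),
    stop("unknown image extension '", ext, "' for ", path))
  if (length(dim(out$image)) == 3L) {
    if (is.null(slice))
      stop(path, " is a 3D volume; pass `slice` to pick a transverse slice")
    if (slice < 1L || slice > dim(out$image)[3])
      stop("slice ", slice, " outside volume ", path)
    out <- list(image = out$image[, , slice], spacing = out$spacing[1:2])
  }
  if (!is.null(spacing)) out$spacing <- as.numeric(spacing)
  storage.mode(out$image) <- "double"
  out
}

#' Write a grayscale image or mask
#'
#' PNG is written 8-bit grayscale with values clipped to `[0, 1]` (use the
#' float formats when full precision matters); NIfTI and MetaImage carry
#' the spacing in their headers (masks as 8-bit, images as 32-bit float
#' for MetaImage, double for NIfTI).
#'
#' @param image Numeric or binary matrix.
#' @param path Destination; format from the extension.
#' @param spacing `(row mm, col mm)`.
#' @param mask Write as 8-bit label data.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, spacing = c(1, 1), mask = FALSE) {
  stopifnot(is.matrix(image))
  ext <- image_ext(path)
  switch(ext,
    png = png::writePNG(pmin(pmax(image, 0), 1), path),
    nii = {
      v <- RNifti::asNifti(image)
      RNifti::pixdim(v) <- spacing
      RNifti::writeNifti(v, path)
    },
    mha = write_metaimage(if (mask) image else image, path, spacing,
                          type = if (mask) "MET_UCHAR" else "MET_FLOAT"),
    mhd = stop(".mhd writing not supported; use .mha (LOCAL data)"),
    stop("unknown image extension '", ext, "' for ", path))
  invisible(path)
}

#' Read a binary mask
#'
#' @param path File path.
#' @param spacing,slice As in [read_image()].
#' @return List with `mask` (integer 0/1 matrix) and `spacing`.
#' @export
read_mask <- function(path, spacing = NULL, slice = NULL) {
  x <- read_image(path, spacing, slice)
  list(mask = matrix(as.integer(x$image > 0.5 * max(x$image, 1e-12)),
                     nrow(x$image), ncol(x$image)),
       spacing = x$spacing)
}
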