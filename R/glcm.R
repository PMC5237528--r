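#' GLCM appearance-feature configuration
#'
#' Settings for the gray-level co-occurrence matrices (GLCMs) computed on a
#' square patch around each pixel, and for the 12 texture statistics derived
#' from each GLCM.  With `J` offsets the appearance vector has length `12 * J`
#' (all 12 features for the first offset, then the second, and so on).
#'
#' Angles are measured counterclockwise from the +column direction in degrees,
#' restricted to \{0, 45, 90, 135\}; image coordinates are (row, col) with row
#' increasing downward, so a 45-degree offset points up-and-right.
#'
#' @param quant_levels Number of quantization bins Q (>= 2).  Gray levels are
#'   indexed 0..Q-1 in all feature formulas.
#' @param distances,angles Offset set: every combination of `distances` (pixel
#'   distances >= 1) and `angles` is used, so `J = length(distances) *
#'   length(angles)`.
#' @param patch_radius Patch half-width r; the patch is the (2r+1) x (2r+1)
#'   window centered on the pixel.  Images are reflect-padded by r so border
#'   pixels have full patches.
#' @param symmetric If `TRUE`, each pair is counted in both orders and the
#'   GLCM equals its transpose.
#' @param intensity_range Length-2 numeric `(min, max)` used for quantization,
#'   or `NULL` to use the 0.5th--99.5th intensity percentiles of each image
#'   (CT slices carry extreme air/bone values that would otherwise swallow
#'   the dynamic range).
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(quant_levels = 16L,
                        distances = c(1L, 2L),
                        angles = c(0, 45, 90, 135),
                        patch_radius = 7L,
                        symmetric = TRUE,
                        intensity_range = NULL) {
  quant_levels <- as.integer(quant_levels)
  distances <- as.integer(distances)
  stopifnot(quant_levels >= 2L, length(distances) >= 1L, all(distances >= 1L),
            length(angles) >= 1L, all(angles %in% c(0, 45, 90, 135)),
            patch_radius >= 1L)
  if (2L * patch_radius + 1L <= max(distances))
    stop("patch window side must exceed the largest offset distance")
  if (!is.null(intensity_range)) {
    stopifnot(length(intensity_range) == 2L,
              intensity_range[1] < intensity_range[2])
  }
  # distance-major enumeration: (d1, each angle), (d2, each angle), ...
  offsets <- expand.grid(angle = angles, distance = distances,
                         KEEP.OUT.ATTRS = FALSE)[, c("distance", "angle")]
  rownames(offsets) <- NULL
  structure(list(quant_levels = quant_levels,
                 offsets = offsets,
                 patch_radius = as.integer(patch_radius),
                 symmetric = isTRUE(symmetric),
                 intensity_range = intensity_range),
            class = "glcm_config")
}

#' @method print glcm_config
#' @export
print.glcm_config <- function(x, ...) {
  cat("GLCM configuration\n")
  cat("  Q =", x$quant_levels, "levels;", nrow(x$offsets),
      "offsets; patch", 2 * x$patch_radius + 1, "x",
      2 * x$patch_radius + 1, if (x$symmetric) "(symmetric)\n" else "\n")
  cat("  appearance vector length:", 12 * nrow(x$offsets), "\n")
  invisible(x)
}

# (row, col) step for a distance/angle offset; angle CCW from +col
offset_step <- function(distance, angle) {
  d <- as.integer(distance)
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135"))
}

resolve_range <- function(image, cfg) {
  if (!is.null(cfg$intensity_range)) return(as.numeric(cfg$intensity_range))
  rng <- stats::quantile(image, c(0.005, 0.995), names = FALSE)
  if (rng[1] >= rng[2]) rng <- range(image)
  if (rng[1] >= rng[2]) rng <- c(rng[1], rng[1] + 1)
  rng
}

#' Quantize a grayscale image into Q gray levels
#'
#' Clips intensities to the configured range and bins them into
#' `quant_levels` equal-width bins, returning integer levels `0..Q-1`.
#'
#' @param image Numeric matrix.
#' @param cfg A [glcm_config()].
#' @return Integer matrix of the same shape with values in `0..Q-1`.
#' @export
quantize_image <- function(image, cfg = glcm_config()) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) {
    bad <- which(!is.finite(image), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite pixel at (row %d, col %d)", bad[1], bad[2]))
  }
  rng <- resolve_range(image, cfg)
  q <- floor((pmin(pmax(image, rng[1]), rng[2]) - rng[1]) /
               (rng[2] - rng[1]) * cfg$quant_levels)
  q <- pmin(q, cfg$quant_levels - 1L)
  matrix(as.integer(q), nrow(image), ncol(image))
}

#' Co-occurrence matrix of a quantized patch
#'
#' Counts ordered gray-level pairs `(x, x + d * direction(theta))` inside the
#' patch and normalizes by the pair count.  With `symmetric = TRUE` the
#' transposed pairs are added first.
#'
#' @param patch Integer matrix of gray levels in `0..Q-1` (already quantized).
#' @param distance,angle The offset (pixels, degrees).
#' @param cfg A [glcm_config()]; supplies Q and the symmetry flag.
#' @return An object of class `glcm`: list with `probs` (Q x Q, sums to 1),
#'   `offset`, and `pair_count`.
#' @export
compute_glcm <- function(patch, distance, angle, cfg = glcm_config()) {
  stopifnot(is.matrix(patch))
  Q <- cfg$quant_levels
  if (any(patch < 0 | patch >= Q)) stop("patch is not quantized to 0..Q-1")
  st <- offset_step(distance, angle)
  nr <- nrow(patch); nc <- ncol(patch)
  r0 <- max(1L, 1L - st[1]); r1 <- min(nr, nr - st[1])
  c0 <- max(1L, 1L - st[2]); c1 <- min(nc, nc - st[2])
  if (r0 > r1 || c0 > c1)
    stop("offset does not fit inside the patch")
  r <- r0:r1
  c <- c0:c1
  a <- patch[r, c, drop = FALSE]
  b <- patch[r + st[1], c + st[2], drop = FALSE]
  counts <- matrix(0, Q, Q)
  tab <- table(factor(a, levels = 0:(Q - 1)), factor(b, levels = 0:(Q - 1)))
  counts <- counts + as.matrix(tab)
  if (cfg$symmetric) counts <- counts + t(counts)
  pair_count <- sum(counts)
  if (pair_count == 0) stop("no co-occurring pairs for this offset")
  structure(list(probs = counts / pair_count,
                 offset = c(distance = as.integer(distance),
                            angle = as.numeric(angle)),
                 pair_count = as.integer(pair_count)),
            class = "glcm")
}

#' The 12 GLCM texture statistics
#'
#' Evaluates, in this fixed order: energy, contrast, correlation, homogeneity,
#' entropy (natural log), autocorrelation, dissimilarity, cluster shade,
#' cluster tendency, maximum probability, variance (around the grand mean
#' `(mu_a + mu_b) / 2`), and sum mean `(1/2) * sum((a + b) p)`.  Gray levels
#' are indexed `0..Q-1`; `0 log 0` is treated as 0.  A degenerate GLCM with
#' zero marginal variance yields correlation 0 with a warning.
#'
#' @param g A `glcm` object or a normalized Q x Q probability matrix.
#' @return Named numeric vector of length 12.
#' @export
haralick12 <- function(g) {
  p <- if (inherits(g, "glcm")) g$probs else g
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (abs(sum(p) - 1) > 1e-9) stop("GLCM is not normalized")
  v <- cpp_haralick(p)
  names(v) <- haralick_names
  a <- (seq_len(nrow(p)) - 1)
  mu_a <- sum(a * rowSums(p)); mu_b <- sum(a * colSums(p))
  va <- sum((a - mu_a)^2 * rowSums(p)); vb <- sum((a - mu_b)^2 * colSums(p))
  if (sqrt(va) * sqrt(vb) <= 1e-12)
    warning("degenerate GLCM (zero marginal variance); correlation set to 0")
  v
}

haralick_names <- c("energy", "contrast", "correlation", "homogeneity",
                    "entropy", "autocorrelation", "dissimilarity",
                    "cluster_shade", "cluster_tendency", "max_probability",
                    "variance", "sum_mean")

#' Feature schema of an appearance vector
#'
#' @param cfg A [glcm_config()].
#' @return Data frame with columns `feature`, `distance`, `angle`, one row per
#'   appearance-vector entry, in vector order.
#' @export
appearance_schema <- function(cfg = glcm_config()) {
  J <- nrow(cfg$offsets)
  data.frame(feature = rep(haralick_names, J),
             distance = rep(cfg$offsets$distance, each = 12L),
             angle = rep(cfg$offsets$angle, each = 12L))
}

reflect_pad <- function(image, r) {
  nr <- nrow(image); nc <- ncol(image)
  if (r >= nr || r >= nc) stop("patch radius exceeds image size")
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  image[ri, ci, drop = FALSE]
}

#' Appearance vectors at every pixel (or a subset)
#'
#' Quantizes the image, reflect-pads it by the patch radius, and computes the
#' `12 * J` GLCM feature vector at each requested pixel.
#'
#' @param image Numeric matrix.
#' @param cfg A [glcm_config()].
#' @param pixels Optional integer matrix/data frame with columns (row, col),
#'   1-based; default all pixels in column-major order.
#' @return Numeric matrix, one row per pixel, `12 * J` columns named by the
#'   schema (`feature.dD.aA`).
#' @export
appearance_features <- function(image, cfg = glcm_config(), pixels = NULL) {
  stopifnot(is.matrix(image))
  q <- quantize_image(image, cfg)
  qp <- reflect_pad(q, cfg$patch_radius)
  if (is.null(pixels)) {
    pixels <- cbind(rep(seq_len(nrow(image)), ncol(image)),
                    rep(seq_len(ncol(image)), each = nrow(image)))
  } else {
    pixels <- as.matrix(pixels)
    if (any(pixels[, 1] < 1 | pixels[, 1] > nrow(image) |
            pixels[, 2] < 1 | pixels[, 2] > ncol(image)))
      stop("pixel index outside the image")
  }
  steps <- t(vapply(seq_len(nrow(cfg$offsets)), function(j)
    offset_step(cfg$offsets$distance[j], cfg$offsets$angle[j]), integer(2)))
  feats <- cpp_appearance(qp, cfg$quant_levels,
                          as.integer(steps[, 1]), as.integer(steps[, 2]),
                          cfg$patch_radius, cfg$symmetric,
                          as.integer(pixels[, 1] + cfg$patch_radius),
                          as.integer(pixels[, 2] + cfg$patch_radius))
  sch <- appearance_schema(cfg)
  colnames(feats) <- sprintf("%s.d%d.a%d", sch$feature, sch$distance,
                             sch$angle)
  feats
}

#' Appearance vector at one pixel
#'
#' @param image Numeric matrix.
#' @param x Length-2 integer (row, col), 1-based.
#' @param cfg A [glcm_config()].
#' @return Named numeric vector of length `12 * J`.
#' @export
appearance_vector <- function(image, x, cfg = glcm_config()) {
  drop(appearance_features(image, cfg, pixels = rbind(as.integer(x))))
}
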