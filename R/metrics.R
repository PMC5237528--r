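#' Surface voxels of a binary mask
#'
#' Foreground pixels with at least one face-adjacent (4-neighbor) background
#' pixel.  The area outside the image counts as background, so foreground on
#' the image border is surface.
#'
#' @param mask Binary matrix.
#' @return Integer matrix of (row, col) coordinates, one surface voxel per
#'   row, in column-major order.
#' @export
surface_voxels <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  if (sum(mask) == 0L) stop("mask is empty; it has no surface")
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  core <- pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
  nb_bg <- !pad[1:nrow(m), 2:(ncol(m) + 1L)] |
    !pad[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)] |
    !pad[2:(nrow(m) + 1L), 1:ncol(m)] |
    !pad[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)]
  which(core & nb_bg, arr.ind = TRUE, useNames = FALSE)
}

check_pair <- function(A, B, spacing) {
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)),
            all(A %in% c(0, 1)), all(B %in% c(0, 1)),
            length(spacing) == 2L, all(spacing > 0))
}

#' Volumetric overlap error
#'
#' `VOE = 1 - vol(A intersect B) / vol(A union B)`; 0 for identical masks,
#' 1 for disjoint ones.  Symmetric in its arguments.
#'
#' @param A,B Binary matrices (ground truth, result).
#' @return Fraction in `[0, 1]`.
#' @export
voe <- function(A, B) {
  check_pair(A, B, c(1, 1))
  u <- sum(A | B)
  if (u == 0L) return(0)
  1 - sum(A & B) / u
}

#' Relative volume difference
#'
#' The set-difference form `RVD = vol(A \\ B) / vol(B)` by default; the
#' signed volume-ratio variant `(vol(B) - vol(A)) / vol(A)` used by the
#' grand-challenge evaluation is available with `signed = TRUE`.
#'
#' @param A,B Binary matrices (ground truth, result).
#' @param signed Use the signed variant.
#' @return Fraction (nonnegative unless `signed`).
#' @export
rvd <- function(A, B, signed = FALSE) {
  check_pair(A, B, c(1, 1))
  if (signed) {
    if (sum(A) == 0L) stop("ground-truth mask is empty")
    return((sum(B) - sum(A)) / sum(A))
  }
  if (sum(B) == 0L) stop("result mask is empty")
  sum(A & !B) / sum(B)
}

#' Symmetric surface-to-surface distances
#'
#' For every surface voxel of A, the minimum Euclidean distance (in mm,
#' respecting anisotropic spacing) to the surface of B, and vice versa.
#' Computed with an exact two-pass squared distance transform.
#'
#' @param A,B Binary matrices.
#' @param spacing Physical pixel size `(row mm, col mm)`.
#' @return List with numeric vectors `a_to_b` and `b_to_a`.
#' @export
surface_distances <- function(A, B, spacing = c(1, 1)) {
  check_pair(A, B, spacing)
  sa <- surface_voxels(A)
  sb <- surface_voxels(B)
  site_a <- matrix(FALSE, nrow(A), ncol(A)); site_a[sa] <- TRUE
  site_b <- matrix(FALSE, nrow(B), ncol(B)); site_b[sb] <- TRUE
  d_to_b <- sqrt(cpp_edt_sq(site_b, spacing[1], spacing[2]))
  d_to_a <- sqrt(cpp_edt_sq(site_a, spacing[1], spacing[2]))
  list(a_to_b = d_to_b[sa], b_to_a = d_to_a[sb])
}

#' Surface-distance summaries: ASD, RMSD, MSD
#'
#' Average, root-mean-square, and maximum of the pooled symmetric
#' surface-to-surface distances, in mm.
#'
#' @param A,B Binary matrices.
#' @param spacing Physical pixel size `(row mm, col mm)`.
#' @return Distance in mm.
#' @export
asd <- function(A, B, spacing = c(1, 1)) {
  d <- surface_distances(A, B, spacing)
  (sum(d$a_to_b) + sum(d$b_to_a)) / (length(d$a_to_b) + length(d$b_to_a))
}

#' @rdname asd
#' @export
rmsd <- function(A, B, spacing = c(1, 1)) {
  d <- surface_distances(A, B, spacing)
  sqrt((sum(d$a_to_b^2) + sum(d$b_to_a^2)) /
         (length(d$a_to_b) + length(d$b_to_a)))
}

#' @rdname asd
#' @export
msd <- function(A, B, spacing = c(1, 1)) {
  d <- surface_distances(A, B, spacing)
  max(max(d$a_to_b), max(d$b_to_a))
}

#' All five segmentation metrics at once
#'
#' @param A Ground-truth binary matrix.
#' @param B Result binary matrix.
#' @param spacing Physical pixel size `(row mm, col mm)`.
#' @return Object of class `surface_metrics`: `voe` and `rvd` as fractions,
#'   `asd`, `rmsd`, `msd` in mm.
#' @export
seg_metrics <- function(A, B, spacing = c(1, 1)) {
  check_pair(A, B, spacing)
  d <- surface_distances(A, B, spacing)
  nd <- length(d$a_to_b) + length(d$b_to_a)
  structure(list(
    voe = voe(A, B),
    rvd = rvd(A, B),
    asd = (sum(d$a_to_b) + sum(d$b_to_a)) / nd,
    rmsd = sqrt((sum(d$a_to_b^2) + sum(d$b_to_a^2)) / nd),
    msd = max(max(d$a_to_b), max(d$b_to_a))),
    class = "surface_metrics")
}

#' @method print surface_metrics
#' @export
print.surface_metrics <- function(x, ...) {
  cat(sprintf("VOE %.2f%%  RVD %.2f%%  ASD %.2f mm  RMSD %.2f mm  MSD %.2f mm\n",
              100 * x$voe, 100 * x$rvd, x$asd, x$rmsd, x$msd))
  invisible(x)
}

# reference errors defining score 75: VOE %, RVD %, ASD mm, RMSD mm, MSD mm
score_reference <- c(voe = 6.4, rvd = 4.7, asd = 1.0, rmsd = 1.8, msd = 19)

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Grand-challenge scores from the five metrics
#'
#' Each metric maps linearly to `100 - 25 * metric / reference`, floored at
#' 0, where the reference errors (VOE 6.4%, RVD 4.7%, ASD 1.0 mm, RMSD
#' 1.8 mm, MSD 19 mm) represent typical human rater performance (score 75).
#' Per-metric scores are rounded half away from zero; the total is the
#' rounded mean of the five unrounded scores.
#'
#' @param m A `surface_metrics` object, or a numeric vector
#'   `c(voe, rvd, asd, rmsd, msd)` with VOE/RVD as fractions (or in percent
#'   if `percent = TRUE`).
#' @param percent Set when `m` is numeric and VOE/RVD are already percent.
#' @return Object of class `score_card`: integer per-metric scores and
#'   `total`.
#' @export
challenge_scores <- function(m, percent = FALSE) {
  if (inherits(m, "surface_metrics"))
    v <- c(100 * m$voe, 100 * m$rvd, m$asd, m$rmsd, m$msd)
  else {
    v <- as.numeric(m)
    stopifnot(length(v) == 5L)
    if (!percent) v[1:2] <- 100 * v[1:2]
  }
  if (any(v < 0)) v <- abs(v)  # signed RVD scores by magnitude
  raw <- pmax(0, 100 - 25 * v / score_reference)
  structure(list(scores = setNames(as.integer(round_half_away(raw)),
                                   names(score_reference)),
                 total = as.integer(round_half_away(mean(raw))),
                 unrounded = setNames(raw, names(score_reference))),
            class = "score_card")
}

#' @method print score_card
#' @export
print.score_card <- function(x, ...) {
  cat("Challenge scores:",
      paste(sprintf("%s %d", toupper(names(x$scores)), x$scores),
            collapse = "  "),
      sprintf(" | total %d\n", x$total))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' Not part of the challenge metric set; used internally to judge phantom
#' segmentations.
#'
#' @param A,B Binary matrices.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(A, B) {
  check_pair(A, B, c(1, 1))
  s <- sum(A) + sum(B)
  if (s == 0L) return(1)
  2 * sum(A & B) / s
}
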