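#' Specification of a synthetic abdominal phantom slice
#'
#' The phantom emulates the statistical structure the segmentation method is
#' built for: one large irregular bright organ (the "liver") placed
#' right-of-center, nearby confuser structures whose mean intensity matches
#' the liver's within `confuser_delta` but whose texture correlation length
#' differs, darker internal lesions that still count as liver tissue, and
#' additive Gaussian noise.  Textures are band-limited noise fields with an
#' organ-specific correlation length (Gaussian-smoothed white noise rescaled
#' to `texture_amp`), so organs of equal mean intensity can only be told
#' apart by second-order statistics — exactly what GLCM features measure.
#'
#' @param image_size `(rows, cols)`, each at least 64.
#' @param liver_intensity,background_intensity Mean intensities in `[0, 1]`.
#' @param confuser_intensity Mean confuser intensity, or `NULL` to draw it
#'   per confuser as liver mean plus Uniform(-delta, delta).
#' @param confuser_delta Largest liver/confuser mean difference.
#' @param liver_texture_scale,confuser_texture_scale,background_texture_scale
#'   Gaussian smoothing sigma (pixels) of each organ's texture field.
#' @param texture_amp Standard deviation of each texture field.
#' @param n_confusers Number of confuser organs.
#' @param confuser_size Range of confuser semi-axes as a fraction of the
#'   liver's.
#' @param lesion_count,lesion_intensity Internal lesions (darker discs,
#'   included in the truth mask: lesions are liver tissue).
#' @param noise_sigma Additive Gaussian pixel noise.
#' @param spacing Physical pixel size `(row mm, col mm)`.
#' @param area_range Admissible liver area fraction of the image.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(128L, 128L),
                         liver_intensity = 0.62,
                         background_intensity = 0.35,
                         confuser_intensity = NULL,
                         confuser_delta = 0.02,
                         liver_texture_scale = 0.8,
                         confuser_texture_scale = 1.1,
                         background_texture_scale = 1.2,
                         texture_amp = 0.06,
                         n_confusers = 2L,
                         confuser_size = c(0.35, 0.5),
                         lesion_count = 2L,
                         lesion_intensity = 0.45,
                         noise_sigma = 0.03,
                         spacing = c(1, 1),
                         area_range = c(0.12, 0.30)) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 64L),
            liver_intensity >= 0, liver_intensity <= 1,
            background_intensity >= 0, background_intensity <= 1,
            lesion_intensity >= 0, lesion_intensity <= 1,
            noise_sigma >= 0, n_confusers >= 0L, lesion_count >= 0L,
            all(spacing > 0), confuser_delta >= 0,
            area_range[1] >= 0.10, area_range[2] <= 0.40)
  structure(list(image_size = image_size,
                 liver_intensity = liver_intensity,
                 background_intensity = background_intensity,
                 confuser_intensity = confuser_intensity,
                 confuser_delta = confuser_delta,
                 liver_texture_scale = liver_texture_scale,
                 confuser_texture_scale = confuser_texture_scale,
                 background_texture_scale = background_texture_scale,
                 texture_amp = texture_amp,
                 n_confusers = as.integer(n_confusers),
                 confuser_size = as.numeric(confuser_size),
                 lesion_count = as.integer(lesion_count),
                 lesion_intensity = lesion_intensity,
                 noise_sigma = noise_sigma,
                 spacing = as.numeric(spacing),
                 area_range = area_range),
            class = "phantom_spec")
}

smooth_noise <- function(nr, nc, sigma, amp) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma > 0) z <- as.matrix(EBImage::gblur(z, sigma = sigma))
  s <- stats::sd(z)
  if (s > 0) z <- z / s * amp
  z
}

# smooth star-shaped blob: ellipse with low-order harmonic radial wobble
blob_mask <- function(nr, nc, center, semi_row, semi_col, wobble_amp,
                      wobble_phase) {
  dy <- (matrix(seq_len(nr), nr, nc) - center[1]) / semi_row
  dx <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]) / semi_col
  rad <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  g <- 1
  for (k in seq_along(wobble_amp))
    g <- g + wobble_amp[k] * cos((k + 1) * phi + wobble_phase[k])
  rad <= g
}

#' Generate one phantom case
#'
#' Fully deterministic given `(spec, seed)`.  The liver contour is a
#' harmonic perturbation of an ellipse; confusers are ellipses sharing the
#' liver's mean intensity but not its texture scale, placed disjoint from
#' yet within 3 pixels of the liver boundary; lesions sit strictly inside
#' the liver and are part of the truth mask; noise is added last.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return Object of class `phantom_case`: `image`, `truth_mask`,
#'   `confuser_masks`, `base` (the piecewise-constant mean image before any
#'   texture or noise), `spec`, `seed`.
#' @export
generate_case <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  npx <- nr * nc
  margin <- 5L

  liver <- NULL
  for (try in 1:25) {
    center <- c(nr * (0.5 + runif(1, -0.06, 0.06)),
                nc * (0.60 + runif(1, -0.04, 0.06)))
    frac <- runif(1, spec$area_range[1] + 0.02, spec$area_range[2] - 0.02)
    q <- runif(1, 0.75, 1.3)
    semi_col <- sqrt(frac * npx / pi * q)
    semi_row <- sqrt(frac * npx / pi / q)
    amp <- runif(3, 0, 0.08)
    phase <- runif(3, 0, 2 * pi)
    m <- blob_mask(nr, nc, center, semi_row, semi_col, amp, phase)
    f <- mean(m)
    touches <- any(m[c(seq_len(margin), nr - seq_len(margin) + 1L), ]) ||
      any(m[, c(seq_len(margin), nc - seq_len(margin) + 1L)])
    if (f >= 0.10 && f <= 0.40 && !touches && center[2] > nc / 2) {
      liver <- m
      liver_geom <- list(center = center, semi_row = semi_row,
                         semi_col = semi_col, amp = amp, phase = phase)
      break
    }
  }
  if (is.null(liver))
    stop("phantom constraint violated: liver area fraction in [0.10, 0.40] ",
         "away from the border could not be achieved")

  # distance (pixels) from anywhere to the liver, for adjacency checks
  d_liver <- sqrt(cpp_edt_sq(liver, 1, 1))

  confusers <- list()
  occupied <- liver
  for (i in seq_len(spec$n_confusers)) {
    placed <- FALSE
    for (try in 1:60) {
      psi <- runif(1, 0, 2 * pi)
      g <- 1
      for (k in seq_along(liver_geom$amp))
        g <- g + liver_geom$amp[k] * cos((k + 1) * psi + liver_geom$phase[k])
      bpt <- c(liver_geom$center[1] + liver_geom$semi_row * g * sin(psi),
               liver_geom$center[2] + liver_geom$semi_col * g * cos(psi))
      cs_row <- liver_geom$semi_row * runif(1, spec$confuser_size[1],
                                            spec$confuser_size[2])
      cs_col <- liver_geom$semi_col * runif(1, spec$confuser_size[1],
                                            spec$confuser_size[2])
      gap <- runif(1, 1.2, 2.8)
      reach <- mean(c(cs_row, cs_col)) + gap
      ctr <- bpt + reach * c(sin(psi), cos(psi))
      m <- blob_mask(nr, nc, ctr, cs_row, cs_col, runif(1, 0, 0.05),
                     runif(1, 0, 2 * pi))
      if (!any(m)) next
      if (any(m & occupied)) next
      dmin <- min(d_liver[m])
      if (dmin < 1 || dmin > 3) next
      confusers[[length(confusers) + 1L]] <- m
      occupied <- occupied | m
      placed <- TRUE
      break
    }
    if (!placed)
      stop("phantom constraint violated: could not place confuser ", i,
           " disjoint from yet within 3 pixels of the liver")
  }

  # lesions: darker discs strictly inside the liver (still liver tissue)
  d_inside <- sqrt(cpp_edt_sq(!liver, 1, 1))  # depth inside the liver
  lesions <- matrix(FALSE, nr, nc)
  for (i in seq_len(spec$lesion_count)) {
    rad <- runif(1, 2, min(5, max(3, max(d_inside) / 3)))
    elig <- which(d_inside > rad + 1)
    if (length(elig) == 0L) next
    ctr_idx <- sample(elig, 1)
    ctr <- c((ctr_idx - 1L) %% nr + 1L, (ctr_idx - 1L) %/% nr + 1L)
    lesions <- lesions | blob_mask(nr, nc, ctr, rad, rad, numeric(0),
                                   numeric(0))
  }
  lesions <- lesions & liver

  base <- matrix(spec$background_intensity, nr, nc)
  base[liver] <- spec$liver_intensity
  for (m in confusers) {
    ci <- if (is.null(spec$confuser_intensity))
      spec$liver_intensity + runif(1, -spec$confuser_delta,
                                   spec$confuser_delta)
    else spec$confuser_intensity
    base[m] <- ci
  }
  base[lesions] <- spec$lesion_intensity

  img <- base
  img <- img + smooth_noise(nr, nc, spec$background_texture_scale,
                            spec$texture_amp) * !occupied
  img <- img + smooth_noise(nr, nc, spec$liver_texture_scale,
                            spec$texture_amp) * liver
  if (length(confusers) > 0) {
    ctex <- smooth_noise(nr, nc, spec$confuser_texture_scale,
                         spec$texture_amp)
    conf_any <- Reduce(`|`, confusers)
    img <- img + ctex * conf_any
  }
  if (spec$noise_sigma > 0) img <- img + rnorm(npx, 0, spec$noise_sigma)

  structure(list(image = img,
                 truth_mask = matrix(as.integer(liver), nr, nc),
                 confuser_masks = lapply(confusers, function(m)
                   matrix(as.integer(m), nr, nc)),
                 lesion_mask = matrix(as.integer(lesions), nr, nc),
                 base = base, spec = spec, seed = as.integer(seed)),
            class = "phantom_case")
}

#' @method print phantom_case
#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "Phantom case (seed %d): %d x %d, liver %.1f%% of image, %d confuser(s), %d lesion px\n",
    x$seed, nrow(x$image), ncol(x$image), 100 * mean(x$truth_mask),
    length(x$confuser_masks), sum(x$lesion_mask)))
  invisible(x)
}

#' Generate a reproducible train/test phantom dataset
#'
#' Cases get disjoint seeds derived from the master seed, and each case's
#' spec is jittered by up to 10 percent in organ intensities and liver
#' shape so cases differ in more than noise (mirroring a cohort of scans
#' rather than replicates of one).
#'
#' @param n_train,n_test Number of training and test cases.
#' @param spec A [phantom_spec()].
#' @param seed Master seed.
#' @return List with elements `train` and `test`, each a list of
#'   `phantom_case` objects.
#' @export
generate_dataset <- function(n_train = 18L, n_test = 2L,
                             spec = phantom_spec(), seed = 1L) {
  n_train <- as.integer(n_train); n_test <- as.integer(n_test)
  stopifnot(n_train >= 0L, n_test >= 0L)
  n <- n_train + n_test
  if (n == 0L) return(list(train = list(), test = list()))
  set.seed(as.integer(seed))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  clamp01 <- function(x) min(1, max(0, x))
  cases <- lapply(seq_len(n), function(i) {
    sp <- spec
    # intensity variation mimics CT acquisition: a common gain factor per
    # scan (contrast timing / calibration) plus small organ-level drift;
    # organ CONTRASTS are preserved, unlike independent per-organ jitter,
    # because CT intensities are calibrated across scans
    gain <- runif(1, 0.9, 1.1)
    sp$liver_intensity <- clamp01(spec$liver_intensity * gain *
                                    runif(1, 0.98, 1.02))
    sp$background_intensity <- clamp01(spec$background_intensity * gain *
                                         runif(1, 0.98, 1.02))
    sp$lesion_intensity <- clamp01(spec$lesion_intensity * gain *
                                     runif(1, 0.98, 1.02))
    w <- sort(runif(2, spec$area_range[1], spec$area_range[2]))
    if (diff(w) > 0.04) sp$area_range <- w
    generate_case(sp, case_seeds[i])
  })
  list(train = cases[seq_len(n_train)],
       test = if (n_test > 0) cases[n_train + seq_len(n_test)] else list())
}
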