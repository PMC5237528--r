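test_that("quantization bins intensities as specified", {
  cfg <- glcm_config(quant_levels = 8, intensity_range = c(0, 255))
  # constant image maps to a single bin
  q <- quantize_image(matrix(100, 5, 5), cfg)
  expect_length(unique(as.vector(q)), 1L)
  # two-bin split of the full range
  cfg2 <- glcm_config(quant_levels = 2, intensity_range = c(0, 1))
  q2 <- quantize_image(matrix(c(0.1, 0.4, 0.6, 0.9), 2, 2), cfg2)
  expect_equal(as.vector(q2), c(0L, 0L, 1L, 1L))
  # a ramp spanning the range lands evenly: counts equal within 1
  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  counts <- tabulate(quantize_image(ramp, cfg) + 1L, nbins = 8)
  expect_lte(diff(range(counts)), 1L)
  # non-finite pixels are refused with a located error
  bad <- matrix(1, 3, 3); bad[2, 3] <- NA
  expect_error(quantize_image(bad, cfg), "row 2, col 3")
})

test_that("co-occurrence counting matches hand enumeration", {
  cfg <- glcm_config(quant_levels = 2, distances = 1, angles = 0,
                     patch_radius = 1, symmetric = FALSE,
                     intensity_range = c(0, 1))
  # patch [[0,0],[1,1]] (rows) has two horizontal pairs: (0,0) and (1,1)
  g <- compute_glcm(rbind(c(0L, 0L), c(1L, 1L)), 1, 0, cfg)
  expect_equal(g$pair_count, 2L)
  expect_equal(g$probs[1, 1], 0.5)
  expect_equal(g$probs[2, 2], 0.5)
  expect_equal(sum(g$probs), 1)
  # constant patch: all mass on the diagonal cell
  cfg16 <- glcm_config(quant_levels = 16)
  gc <- compute_glcm(matrix(3L, 6, 6), 1, 0, cfg16)
  expect_equal(gc$probs[4, 4], 1)
  # symmetric GLCMs equal their transpose
  set.seed(7)
  for (ang in c(0, 45, 90, 135)) {
    p <- matrix(sample(0:15, 64, replace = TRUE), 8, 8)
    gs <- compute_glcm(p, 2, ang, cfg16)
    expect_identical(gs$probs, t(gs$probs))
  }
  # offset larger than the patch is an error
  expect_error(compute_glcm(matrix(0L, 2, 2), 5, 0, cfg16), "offset")
})

test_that("the 12 texture statistics have their closed forms on simple GLCMs", {
  d <- matrix(0, 4, 4); d[2, 2] <- 1  # all mass on one diagonal cell
  h <- suppressWarnings(haralick12(d))
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["dissimilarity"]], 0)
  expect_equal(h[["homogeneity"]], 1)
  expect_equal(h[["max_probability"]], 1)
  expect_warning(haralick12(d), "degenerate")

  u <- matrix(0.25, 2, 2)  # uniform over Q = 2
  hu <- haralick12(u)
  expect_equal(hu[["energy"]], 0.25)
  expect_equal(hu[["entropy"]], log(4))
  expect_equal(hu[["max_probability"]], 0.25)
})

test_that("the 12 statistics agree with the brute-force oracle", {
  set.seed(42)
  for (i in 1:100) {
    Q <- sample(c(2, 4, 8, 16), 1)
    p <- random_glcm(Q)
    expect_equal(haralick12(p), oracle_haralick(p), tolerance = 1e-10)
  }
})

test_that("appearance vectors have the documented length and schema order", {
  cfg <- glcm_config(distances = 1, angles = c(0, 45, 90, 135))  # J = 4
  img <- matrix(runif(900), 30, 30)
  v <- appearance_vector(img, c(15, 15), cfg)
  expect_length(v, 48L)
  sch <- appearance_schema(cfg)
  expect_equal(nrow(sch), 48L)
  expect_equal(sch$feature[1:12], sch$feature[13:24])  # 12 per offset
  expect_error(appearance_vector(img, c(0, 5), cfg), "outside")

  # constant image: identical vector at every pixel
  cimg <- matrix(1, 20, 20)
  f <- appearance_features(cimg, cfg)
  expect_lt(max(abs(sweep(f, 2, f[1, ]))), 1e-12)
})

test_that("per-pixel C++ sweep equals compute_glcm + haralick12 composition", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  cfg <- glcm_config(quant_levels = 8, distances = c(1, 2),
                     angles = c(0, 90), patch_radius = 3,
                     intensity_range = c(0, 1))
  x <- c(17L, 14L)
  v <- appearance_vector(img, x, cfg)
  q <- quantize_image(img, cfg)
  ref <- unlist(lapply(seq_len(nrow(cfg$offsets)), function(j) {
    patch <- q[(x[1] - 3):(x[1] + 3), (x[2] - 3):(x[2] + 3)]
    g <- compute_glcm(patch, cfg$offsets$distance[j], cfg$offsets$angle[j],
                      cfg)
    suppressWarnings(haralick12(g))
  }))
  expect_equal(unname(v), unname(ref), tolerance = 1e-12)
})

test_that("appearance features respect the mirror symmetry of the lattice", {
  # left-right mirroring with 0/90-degree symmetric GLCMs maps the feature
  # vector at x to the vector at the mirrored pixel
  set.seed(11)
  img <- matrix(runif(625), 25, 25)
  cfg <- glcm_config(quant_levels = 8, distances = 1, angles = c(0, 90),
                     patch_radius = 2, intensity_range = c(0, 1))
  mimg <- img[, ncol(img):1]
  x <- c(13L, 8L)
  mx <- c(13L, ncol(img) - 8L + 1L)
  expect_equal(appearance_vector(img, x, cfg),
               appearance_vector(mimg, mx, cfg), tolerance = 1e-12)
})

test_that("appearance vectors are invariant to a shifted intensity scale", {
  set.seed(5)
  img <- matrix(runif(400), 20, 20)
  cfg <- glcm_config(quant_levels = 8, patch_radius = 2,
                     intensity_range = c(0, 1))
  cfg_shift <- glcm_config(quant_levels = 8, patch_radius = 2,
                           intensity_range = c(10, 11))
  expect_equal(appearance_features(img, cfg),
               appearance_features(img + 10, cfg_shift), tolerance = 1e-12)
})

test_that("every GLCM is a probability distribution", {
  set.seed(9)
  cfg <- glcm_config(quant_levels = 8)
  for (i in 1:20) {
    p <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    d <- sample(1:2, 1); ang <- sample(c(0, 45, 90, 135), 1)
    g <- compute_glcm(p, d, ang, cfg)
    expect_true(all(g$probs >= 0))
    expect_equal(sum(g$probs), 1, tolerance = 1e-9)
  }
})
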