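# small, quick fixture shared by the cascade tests: two-texture phantoms at
# 64 x 64 with one confuser, built once per test run
tiny_spec <- function() {
  phantom_spec(image_size = c(64, 64), n_confusers = 1L, lesion_count = 1L,
               area_range = c(0.12, 0.25))
}

tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(3, 1, tiny_spec(), seed = 19)
      cache <<- list(
        data = ds,
        model = liver_prior_model(ds$train, U = 2, n_rounds = 40,
                                  n_per_class = 300, rng_seed = 19))
    }
    cache
  }
})

test_that("context sampling reads the map along eight rays", {
  cfg <- context_config(radii = c(3, 6, 9, 12, 15), include_center = TRUE)
  expect_equal(liverseg:::context_length(cfg), 41L)
  # constant field: every sample equals the field value
  pm <- matrix(0.7, 40, 40)
  v <- context_features(pm, c(20, 20), cfg)
  expect_length(v, 41L)
  expect_true(all(v == 0.7))
  # at the image corner, rays leaving the image read 0
  vc <- context_features(pm, c(1, 1), cfg)
  expect_true(any(vc == 0))
  # enumerate: only rays into the lower-right quadrant (k = 0 right,
  # k = 6 down, k = 7 down-right) stay inside from pixel (1, 1)
  off <- liverseg:::context_offsets(cfg)
  inside <- 1 + off[, 1] >= 1 & 1 + off[, 1] <= 40 &
    1 + off[, 2] >= 1 & 1 + off[, 2] <= 40
  expect_equal(unname(vc[inside]), rep(0.7, sum(inside)))
  expect_equal(unname(vc[!inside]), rep(0, sum(!inside)))
  expect_error(context_features(pm, c(0, 5), cfg), "outside")
})

test_that("vectorized context features match the per-pixel sampler", {
  set.seed(23)
  pm <- matrix(runif(30 * 20), 30, 20)
  cfg <- context_config(radii = c(2, 5, 11))
  all_f <- liverseg:::context_features_all(pm, cfg)
  for (x in list(c(1, 1), c(15, 10), c(30, 20), c(3, 19))) {
    expect_equal(unname(all_f[(x[2] - 1) * 30 + x[1], ]),
                 unname(context_features(pm, x, cfg)))
  }
})

test_that("a U = 0 cascade is an appearance-only classifier", {
  tm <- tiny_model()
  ds <- tm$data
  m0 <- liver_prior_model(ds$train[1:2], U = 0, n_rounds = 20,
                          n_per_class = 200, rng_seed = 5)
  expect_length(m0$stages, 1L)
  img <- ds$test[[1]]$image
  pm <- predict(m0, img)
  A <- appearance_features(img, m0$glcm)
  expect_equal(pm$probs,
               matrix(margin_to_prob(boost_margin(m0$stages[[1]], A)),
                      nrow(img)))
  expect_equal(pm$iteration, 0L)
})

test_that("cascade training is deterministic and improves the training fit", {
  tm <- tiny_model()
  mod <- tm$model
  expect_length(mod$stages, 3L)
  # training cross-entropy is non-increasing over stages
  expect_true(all(diff(mod$history$cross_entropy) <= 1e-12))
  # stage 0 consumes appearance only; later stages appearance + context
  expect_equal(mod$stages[[1]]$n_features, 96L)
  expect_equal(mod$stages[[2]]$n_features,
               96L + liverseg:::context_length(mod$context))
  # refitting with the same seed is bit-identical
  mod2 <- liver_prior_model(tm$data$train, U = 2, n_rounds = 40,
                            n_per_class = 300, rng_seed = 19)
  expect_identical(mod$stages, mod2$stages)
})

test_that("probability maps stay in [0, 1] at every stage and converge", {
  tm <- tiny_model()
  img <- tm$data$test[[1]]$image
  A <- appearance_features(img, tm$model$glcm)
  for (s in 0:2) {
    pm <- predict(tm$model, img, appearance = A, stage = s,
                  max_extra_iters = 0)
    expect_true(all(pm$probs >= 0 & pm$probs <= 1))
  }
  # infinite tolerance: exactly U + 1 stage applications, no extras
  pmi <- predict(tm$model, img, appearance = A, tol = Inf)
  expect_equal(pmi$extra_iterations, 0L)
  expect_equal(pmi$iteration, 2L)
  # convergence loop never exceeds its budget
  pme <- predict(tm$model, img, appearance = A, tol = 1e-9,
                 max_extra_iters = 3)
  expect_lte(pme$extra_iterations, 3L)
})

test_that("auto-context sharpens the liver/background probability contrast", {
  # the map should strengthen inside the liver relative to everything else
  # (non-liver areas are weakened), so the mean probability contrast grows
  tm <- tiny_model()
  te <- tm$data$test[[1]]
  A <- appearance_features(te$image, tm$model$glcm)
  pm0 <- predict(tm$model, te$image, appearance = A, stage = 0)
  pmU <- predict(tm$model, te$image, appearance = A)
  liver <- te$truth_mask == 1
  expect_gt(mean(pmU$probs[liver]) - mean(pmU$probs[!liver]),
            mean(pm0$probs[liver]) - mean(pm0$probs[!liver]))
  # non-liver areas are weakened outright
  expect_lt(mean(pmU$probs[!liver]), mean(pm0$probs[!liver]))
})

test_that("cascades survive a plain-text round trip", {
  tm <- tiny_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cascade(tm$model, path)
  back <- read_cascade(path)
  expect_equal(back$stages, lapply(tm$model$stages, function(s) {
    s$feature_names <- NULL; s
  }))
  expect_equal(back$glcm$offsets, tm$model$glcm$offsets)
  expect_equal(back$context$radii, tm$model$context$radii)
  # prediction equivalence
  img <- tm$data$test[[1]]$image
  expect_equal(predict(back, img)$probs, predict(tm$model, img)$probs)
  # version / format guards
  other <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(format = "something-else"), other)
  expect_error(read_cascade(other), "not a liverseg cascade")
})
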