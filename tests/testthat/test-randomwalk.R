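test_that("seed selection thresholds and falls back as documented", {
  p <- matrix(0.5, 4, 5)
  p[1, 1] <- 1; p[4, 5] <- 0
  cfg <- rw_config(seed_hi = 0.99, seed_lo = 0.01)
  s <- select_seeds(p, cfg)
  expect_equal(s$liver, 1L)           # column-major index of (1,1)
  expect_equal(s$background, 20L)
  expect_false(any(s$fallback))
  # constant map: no contrast at all
  expect_error(select_seeds(matrix(0.5, 4, 4), cfg), "no seed contrast")
  # max below seed_hi: fallback takes exactly ceil(1% of N) liver seeds
  p2 <- matrix(runif(400, 0.2, 0.9), 20, 20)
  p2[3, 3] <- 0.005                   # background threshold still met
  expect_warning(s2 <- select_seeds(p2, cfg), "top")
  expect_equal(length(s2$liver), ceiling(0.01 * 400))
  expect_true(s2$fallback["liver"])
})

test_that("the fused edge weight follows its exponential form", {
  cfg <- rw_config(alpha = 0.5, beta = 90, weight_floor = 0)
  # zero differences give weight 1
  expect_equal(edge_weight(0.3, 0.3, 0.7, 0.7, cfg), 1)
  # alpha = 0: classic intensity-only weight
  cfg0 <- rw_config(alpha = 0, beta = 50, weight_floor = 0)
  expect_equal(edge_weight(0.2, 0.5, 0.1, 0.9, cfg0), exp(-50 * 0.09))
  # worked value: alpha .5, beta 90, dG .1, dP .2
  expect_equal(edge_weight(0, 0.1, 0, 0.2, cfg), exp(-2.25))
  expect_equal(exp(-2.25), 0.10540, tolerance = 1e-4)
  # symmetry in (i, j)
  expect_equal(edge_weight(0.1, 0.6, 0.2, 0.9, cfg),
               edge_weight(0.6, 0.1, 0.9, 0.2, cfg))
})

test_that("lattice graphs have the right edge counts and weight range", {
  img <- matrix(runif(9), 3, 3)
  pm <- matrix(runif(9), 3, 3)
  seeds <- list(liver = 1L, background = 9L)
  g4 <- build_graph(img, pm, seeds, rw_config(connectivity = 4))
  expect_equal(nrow(g4$edges), 12L)
  g8 <- build_graph(img, pm, seeds, rw_config(connectivity = 8))
  expect_equal(nrow(g8$edges), 20L)
  set.seed(4)
  img2 <- matrix(runif(100), 10, 10)
  pm2 <- matrix(runif(100), 10, 10)
  gg <- build_graph(img2, pm2, list(liver = 1L, background = 100L),
                    rw_config())
  expect_true(all(gg$weights > 0))
  expect_true(all(gg$weights <= 1 + rw_config()$weight_floor))
  expect_error(build_graph(img, matrix(0.5, 2, 2), seeds, rw_config()),
               "shapes differ")
})

test_that("chain potentials solve the reduced system exactly", {
  # unit weights: middle of a 3-chain sits at 1/2 by symmetry
  g <- pixel_graph(3, rbind(c(1, 2), c(2, 3)), c(1, 1),
                   list(liver = 1L, background = 3L))
  expect_equal(solve_potentials(g)$values[2], 0.5, tolerance = 1e-10)
  # weights (2, 1): v2 = (2*1 + 1*0) / 3
  g2 <- pixel_graph(3, rbind(c(1, 2), c(2, 3)), c(2, 1),
                    list(liver = 1L, background = 3L))
  expect_equal(solve_potentials(g2)$values[2], 2 / 3, tolerance = 1e-10)
  # fully seeded graphs return the seed labels
  g3 <- pixel_graph(2, rbind(c(1, 2)), 1, list(liver = 1L, background = 2L))
  expect_equal(solve_potentials(g3)$values, c(1, 0))
  # unseeded component is refused
  g4 <- pixel_graph(5, rbind(c(1, 2), c(3, 4), c(4, 5)), rep(1, 3),
                    list(liver = 1L, background = 2L))
  expect_error(solve_potentials(g4), "component")
})

test_that("potentials obey the discrete maximum principle and complementarity", {
  set.seed(31)
  for (i in 1:8) {
    img <- matrix(runif(64), 8, 8)
    pm <- matrix(runif(64), 8, 8)
    seeds <- list(liver = sample(64, 3), background = sample(setdiff(1:64,
                  1:64 * 0), 3))
    seeds$background <- setdiff(seeds$background, seeds$liver)
    if (length(seeds$background) == 0) next
    g <- build_graph(img, pm, seeds, rw_config())
    f <- solve_potentials(g)
    expect_gte(min(f$values), 0)
    expect_lte(max(f$values), 1)
    # solving the complementary (background) problem sums to 1 pixelwise
    gswap <- pixel_graph(g$n_nodes, g$edges, g$weights,
                         list(liver = seeds$background,
                              background = seeds$liver), dim = g$dim)
    fb <- solve_potentials(gswap)
    expect_equal(as.vector(f$values + fb$values), rep(1, 64),
                 tolerance = 1e-8)
    # harmonicity: each unseeded value is the weighted mean of neighbors
    un <- setdiff(1:64, c(seeds$liver, seeds$background))
    W <- matrix(0, 64, 64)
    W[g$edges] <- g$weights; W <- W + t(W)
    est <- (W %*% as.vector(f$values))[un] / rowSums(W)[un]
    expect_equal(as.vector(f$values)[un], est, tolerance = 1e-7)
  }
})

test_that("sparse solve matches a dense direct solve on small grids", {
  set.seed(41)
  for (n in c(8, 14, 20)) {
    img <- matrix(runif(n * n), n, n)
    pm <- matrix(runif(n * n), n, n)
    seeds <- list(liver = sample(n * n, 4), background = NULL)
    seeds$background <- sample(setdiff(seq_len(n * n), seeds$liver), 4)
    g <- build_graph(img, pm, seeds, rw_config())
    f <- solve_potentials(g)
    # dense route, built independently from the edge list
    L <- matrix(0, n * n, n * n)
    for (e in seq_len(nrow(g$edges))) {
      i <- g$edges[e, 1]; j <- g$edges[e, 2]; w <- g$weights[e]
      L[i, j] <- L[i, j] - w; L[j, i] <- L[j, i] - w
      L[i, i] <- L[i, i] + w; L[j, j] <- L[j, j] + w
    }
    x <- numeric(n * n); x[seeds$liver] <- 1
    seeded <- c(seeds$liver, seeds$background)
    un <- setdiff(seq_len(n * n), seeded)
    x[un] <- solve(L[un, un], -L[un, seeded] %*% x[seeded])
    expect_equal(as.vector(f$values), x, tolerance = 1e-8)
  }
})

test_that("with alpha = 0 the walker reproduces the classic intensity-only formulation", {
  set.seed(51)
  for (i in 1:3) {
    img <- matrix(runif(256), 16, 16)
    fg <- sample(256, 3)
    bg <- sample(setdiff(1:256, fg), 3)
    cfg <- rw_config(alpha = 0, beta = 90, weight_floor = 1e-6)
    g <- build_graph(img, matrix(runif(256), 16, 16), # prior must be ignored
                     list(liver = fg, background = bg), cfg)
    mask <- label_mask(solve_potentials(g),
                       list(liver = fg, background = bg))$mask
    ref <- oracle_random_walker(img, fg, bg, beta = 90)
    expect_equal(mask, ref)
  }
})

test_that("labeling thresholds at one-half with ties going to liver", {
  f <- structure(list(values = matrix(c(0.5, 0.4999, 0.75, 0.1), 2, 2),
                      residual = 0), class = "potential_field")
  m <- label_mask(f)
  expect_equal(as.vector(m$mask), c(1L, 0L, 1L, 0L))
})

test_that("a perfect prior makes the full segmentation reproduce the truth", {
  set.seed(61)
  truth <- matrix(0L, 24, 24); truth[7:16, 9:20] <- 1L
  img <- 0.35 + 0.25 * truth + matrix(rnorm(576, 0, 0.02), 24, 24)
  seg <- rw_segment(img, prior = truth + 0)   # prior = indicator
  expect_equal(seg$mask, truth)
})
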