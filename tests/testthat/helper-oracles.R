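# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately share no code with the package.

# double-loop evaluation of the 12 co-occurrence statistics over (a, b)
oracle_haralick <- function(p) {
  Q <- nrow(p)
  lev <- 0:(Q - 1)
  energy <- contrast <- homogeneity <- entropy <- autoc <- dissim <- 0
  mu_a <- mu_b <- 0
  for (a in lev) for (b in lev) {
    v <- p[a + 1, b + 1]
    mu_a <- mu_a + a * v
    mu_b <- mu_b + b * v
  }
  var_a <- var_b <- corr <- shade <- tend <- variance <- summean <- 0
  maxp <- 0
  mu <- (mu_a + mu_b) / 2
  for (a in lev) for (b in lev) {
    v <- p[a + 1, b + 1]
    energy <- energy + v^2
    contrast <- contrast + (a - b)^2 * v
    homogeneity <- homogeneity + v / (1 + abs(a - b))
    if (v > 0) entropy <- entropy - v * log(v)
    autoc <- autoc + a * b * v
    dissim <- dissim + abs(a - b) * v
    var_a <- var_a + (a - mu_a)^2 * v
    var_b <- var_b + (b - mu_b)^2 * v
    corr <- corr + (a - mu_a) * (b - mu_b) * v
    shade <- shade + (a + b - mu_a - mu_b)^3 * v
    tend <- tend + (a + b - mu_a - mu_b)^2 * v
    variance <- variance + (a - mu)^2 * v
    summean <- summean + (a + b) * v / 2
    maxp <- max(maxp, v)
  }
  sd_ab <- sqrt(var_a) * sqrt(var_b)
  c(energy = energy, contrast = contrast,
    correlation = if (sd_ab > 1e-12) corr / sd_ab else 0,
    homogeneity = homogeneity, entropy = entropy,
    autocorrelation = autoc, dissimilarity = dissim,
    cluster_shade = shade, cluster_tendency = tend,
    max_probability = maxp, variance = variance, sum_mean = summean)
}

random_glcm <- function(Q) {
  p <- matrix(stats::rexp(Q * Q), Q, Q)
  p / sum(p)
}

# brute-force pairwise-minimum surface distances
oracle_surface_distances <- function(A, B, spacing = c(1, 1)) {
  surf <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    keep <- apply(idx, 1, function(x) {
      r <- x[1]; c <- x[2]
      r == 1 || c == 1 || r == nrow(m) || c == ncol(m) ||
        m[r - 1, c] == 0 || m[r + 1, c] == 0 ||
        m[r, c - 1] == 0 || m[r, c + 1] == 0
    })
    idx[keep, , drop = FALSE]
  }
  sa <- surf(A); sb <- surf(B)
  mind <- function(from, to) {
    apply(from, 1, function(x)
      min(sqrt(((x[1] - to[, 1]) * spacing[1])^2 +
                 ((x[2] - to[, 2]) * spacing[2])^2)))
  }
  list(a_to_b = mind(sa, sb), b_to_a = mind(sb, sa))
}

# dense two-class random walker in the classic intensity-only formulation:
# full Laplacian, both label systems solved, argmax labeling
oracle_random_walker <- function(image, seeds_fg, seeds_bg, beta) {
  g <- image - min(image)
  if (max(g) > 0) g <- g / max(g)
  nr <- nrow(image); nc <- ncol(image); n <- nr * nc
  W <- matrix(0, n, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- (c - 1) * nr + r
    if (r < nr) {
      j <- i + 1
      W[i, j] <- W[j, i] <- exp(-beta * (g[r, c] - g[r + 1, c])^2) + 1e-6
    }
    if (c < nc) {
      j <- i + nr
      W[i, j] <- W[j, i] <- exp(-beta * (g[r, c] - g[r, c + 1])^2) + 1e-6
    }
  }
  L <- diag(rowSums(W)) - W
  seeded <- c(seeds_fg, seeds_bg)
  un <- setdiff(seq_len(n), seeded)
  probs <- matrix(0, n, 2)
  for (k in 1:2) {
    xs <- numeric(length(seeded))
    xs[seq_along(seeds_fg)] <- if (k == 1) 1 else 0
    xs[length(seeds_fg) + seq_along(seeds_bg)] <- if (k == 1) 0 else 1
    probs[un, k] <- solve(L[un, un], -L[un, seeded] %*% xs)
    probs[seeded, k] <- xs
  }
  matrix(as.integer(probs[, 1] >= probs[, 2]), nr, nc)
}
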