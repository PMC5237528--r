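#' Random-walker configuration
#'
#' @param alpha Mixing weight in `[0, 1]` between the probability-map term
#'   (`alpha`) and the intensity term (`1 - alpha`) in the edge weight
#'   `w_ij = exp(-beta * ((1 - alpha) dG^2 + alpha dP^2))`.
#' @param beta Contrast scale (> 0) applied to squared differences of
#'   `[0, 1]`-normalized signals; 90 is the conventional scale at this
#'   normalization.
#' @param connectivity Lattice neighborhood, 4 or 8.
#' @param seed_hi Pixels with prior probability `>= seed_hi` become liver
#'   seeds (the logistic link never reaches 1 exactly, so "probability 1"
#'   means saturation).
#' @param seed_lo Pixels with prior probability `<= seed_lo` become
#'   background seeds.
#' @param weight_floor Small constant added to every edge weight so the
#'   graph Laplacian stays well conditioned (exp of large negative arguments
#'   underflows to exact 0 and would disconnect the lattice).
#' @param solver_tol Residual tolerance for the sparse linear solve.
#' @return Object of class `rw_config`.
#' @export
rw_config <- function(alpha = 0.5, beta = 90, connectivity = 4L,
                      seed_hi = 0.99, seed_lo = 0.01,
                      weight_floor = 1e-6, solver_tol = 1e-8) {
  stopifnot(alpha >= 0, alpha <= 1, beta > 0, connectivity %in% c(4L, 8L),
            seed_lo < seed_hi, weight_floor >= 0, solver_tol > 0)
  structure(list(alpha = alpha, beta = beta,
                 connectivity = as.integer(connectivity),
                 seed_hi = seed_hi, seed_lo = seed_lo,
                 weight_floor = weight_floor, solver_tol = solver_tol),
            class = "rw_config")
}

#' Automatic seed selection from a prior probability map
#'
#' Saturated map pixels become hard constraints for the walker.  If a class
#' has no saturated pixel, the top (or bottom) 1 percent of pixels by
#' probability are used instead, ties broken by raster order, with a
#' warning.  A constant map admits no seeds at all.
#'
#' @param pm A `probability_map` or numeric matrix in `[0, 1]`.
#' @param cfg An [rw_config()].
#' @return List with integer vectors `liver` and `background` (column-major
#'   pixel indices) and a `fallback` flag per class.
#' @export
select_seeds <- function(pm, cfg = rw_config()) {
  p <- if (inherits(pm, "probability_map")) pm$probs else pm
  stopifnot(is.matrix(p), all(p >= 0), all(p <= 1))
  if (max(p) - min(p) <= .Machine$double.eps)
    stop("no seed contrast: probability map is constant")
  liver <- which(p >= cfg$seed_hi)
  bg <- which(p <= cfg$seed_lo)
  k <- ceiling(0.01 * length(p))
  fb <- c(liver = FALSE, background = FALSE)
  if (length(liver) == 0L) {
    ord <- order(p, seq_along(p), decreasing = c(TRUE, FALSE),
                 method = "radix")
    liver <- ord[seq_len(k)]
    fb["liver"] <- TRUE
    warning(sprintf("no pixel reached seed_hi = %g; using top %d pixels",
                    cfg$seed_hi, k))
  }
  if (length(bg) == 0L) {
    ord <- order(p, seq_along(p), method = "radix")
    bg <- setdiff(ord[seq_len(k)], liver)
    fb["background"] <- TRUE
    warning(sprintf("no pixel fell below seed_lo = %g; using bottom %d pixels",
                    cfg$seed_lo, k))
  }
  if (length(liver) == 0L || length(bg) == 0L)
    stop("no seed contrast: could not form both seed classes")
  list(liver = sort(liver), background = sort(bg), fallback = fb)
}

#' Fused intensity + probability edge weight
#'
#' `w = exp(-beta * ((1 - alpha) * (g_i - g_j)^2 + alpha * (p_i - p_j)^2))`
#' plus the configured floor.  At `alpha = 0` this is the classic
#' intensity-only random-walker weight; at `alpha = 1` the prior map alone
#' decides where the walk is cheap.
#'
#' @param g_i,g_j Intensities normalized to `[0, 1]`.
#' @param p_i,p_j Prior probabilities.
#' @param cfg An [rw_config()].
#' @return Weights in `(0, 1 + weight_floor]`, symmetric in (i, j).
#' @export
edge_weight <- function(g_i, g_j, p_i, p_j, cfg = rw_config()) {
  exp(-cfg$beta * ((1 - cfg$alpha) * (g_i - g_j)^2 +
                     cfg$alpha * (p_i - p_j)^2)) + cfg$weight_floor
}

#' Weighted pixel-lattice graph
#'
#' One lattice carries both signals: nodes are pixels, edges join 4- or
#' 8-neighbors, and each edge weight fuses the intensity and probability
#' differences via [edge_weight()].  Intensities are min-max normalized to
#' `[0, 1]` first so `beta` has a data-independent meaning.
#'
#' @param image Numeric matrix.
#' @param pm Probability map (same shape).
#' @param seeds Seed list from [select_seeds()].
#' @param cfg An [rw_config()].
#' @return Object of class `pixel_graph`: `dim`, `edges` (m x 2 node
#'   indices), `weights`, `seeds`.
#' @export
build_graph <- function(image, pm, seeds, cfg = rw_config()) {
  p <- if (inherits(pm, "probability_map")) pm$probs else pm
  stopifnot(is.matrix(image), is.matrix(p))
  if (!all(dim(image) == dim(p)))
    stop("image and probability map shapes differ")
  g <- image - min(image)
  if (max(g) > 0) g <- g / max(g)
  nr <- nrow(image); nc <- ncol(image)
  steps <- list(c(1L, 0L), c(0L, 1L))
  if (cfg$connectivity == 8L)
    steps <- c(steps, list(c(1L, 1L), c(-1L, 1L)))
  edges <- NULL; weights <- NULL
  for (st in steps) {
    r <- seq(max(1L, 1L - st[1]), min(nr, nr - st[1]))
    c <- seq(max(1L, 1L - st[2]), min(nc, nc - st[2]))
    from <- as.vector(outer(r, (c - 1L) * nr, `+`))
    to <- as.vector(outer(r + st[1], (c + st[2] - 1L) * nr, `+`))
    w <- edge_weight(g[from], g[to], p[from], p[to], cfg)
    edges <- rbind(edges, cbind(from, to))
    weights <- c(weights, w)
  }
  pixel_graph(nr * nc, edges, weights, seeds, dim = c(nr, nc))
}

#' Construct a pixel graph directly
#'
#' Mostly used internally by [build_graph()]; exposed so small graphs with
#' hand-picked weights can be solved directly.
#'
#' @param n_nodes Number of nodes.
#' @param edges m x 2 integer matrix of node pairs.
#' @param weights Positive edge weights (symmetric by construction: each
#'   undirected edge is listed once).
#' @param seeds List with `liver` and `background` node-index vectors.
#' @param dim Optional lattice dimensions for reshaping results.
#' @return Object of class `pixel_graph`.
#' @export
pixel_graph <- function(n_nodes, edges, weights, seeds, dim = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(nrow(edges) == length(weights), all(weights > 0),
            all(edges >= 1L), all(edges <= n_nodes),
            length(intersect(seeds$liver, seeds$background)) == 0L)
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 weights = as.numeric(weights),
                 seeds = list(liver = as.integer(seeds$liver),
                              background = as.integer(seeds$background)),
                 dim = dim),
            class = "pixel_graph")
}

#' Solve the seed-constrained combinatorial Dirichlet problem
#'
#' Minimizes `x' L x` over unseeded nodes with liver seeds fixed at 1 and
#' background seeds at 0, i.e. solves the reduced sparse SPD system
#' `L_uu x_u = -L_us x_s`.  The solution at each unseeded node is the
#' weighted mean of its neighbors (harmonic), hence the probability that a
#' random walk from that node reaches a liver seed first.
#'
#' @param graph A `pixel_graph` with at least one seed of each class.
#' @param tol Residual tolerance; exceeding it signals an ill-conditioned
#'   system.
#' @return Object of class `potential_field`: `values` (per node, in
#'   `[0, 1]`, matrix-shaped when the graph has lattice dims), `residual`.
#' @export
solve_potentials <- function(graph, tol = 1e-8) {
  stopifnot(inherits(graph, "pixel_graph"))
  s1 <- graph$seeds$liver; s0 <- graph$seeds$background
  if (length(s1) == 0L || length(s0) == 0L)
    stop("need at least one seed of each class")
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, graph$n_nodes -
                                       igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  seeded_comp <- unique(comp[c(s1, s0)])
  orphan <- setdiff(unique(comp), seeded_comp)
  if (length(orphan) > 0L)
    stop("connected component(s) without any seed: ",
         paste(orphan, collapse = ", "))
  n <- graph$n_nodes
  W <- Matrix::sparseMatrix(i = c(graph$edges[, 1], graph$edges[, 2]),
                            j = c(graph$edges[, 2], graph$edges[, 1]),
                            x = c(graph$weights, graph$weights),
                            dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  x <- numeric(n)
  x[s1] <- 1
  seeded <- c(s1, s0)
  un <- setdiff(seq_len(n), seeded)
  if (length(un) > 0L) {
    b <- -L[un, seeded, drop = FALSE] %*% x[seeded]
    Luu <- L[un, un, drop = FALSE]
    xu <- tryCatch(as.numeric(Matrix::solve(Luu, b)),
                   error = function(e)
                     stop("singular reduced system: ", conditionMessage(e)))
    res <- max(abs(Luu %*% xu - b))
    if (!is.finite(res) || res > max(tol, tol * max(abs(b))) * 1e4)
      stop(sprintf("ill-conditioned system: residual %.3g", res))
    x[un] <- pmin(pmax(xu, 0), 1)
  } else res <- 0
  if (length(un) == 0L) res <- 0
  values <- if (!is.null(graph$dim)) matrix(x, graph$dim[1], graph$dim[2])
            else x
  structure(list(values = values, residual = as.numeric(res)),
            class = "potential_field")
}

#' Threshold potentials into a binary mask
#'
#' Labels a pixel liver when its potential is at least 1/2 (ties go to
#' liver).
#'
#' @param field A `potential_field`.
#' @param seeds Optional seed list for bookkeeping.
#' @return Object of class `segmentation`: `mask`, `seeds_used`,
#'   `solver_residual`.
#' @export
label_mask <- function(field, seeds = NULL) {
  stopifnot(inherits(field, "potential_field"))
  v <- field$values
  mask <- ifelse(v >= 0.5, 1L, 0L)
  if (is.matrix(v)) mask <- matrix(mask, nrow(v), ncol(v))
  structure(list(mask = mask,
                 seeds_used = c(liver = length(seeds$liver),
                                background = length(seeds$background)),
                 solver_residual = field$residual),
            class = "segmentation")
}

#' @method print segmentation
#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d liver pixels (%.1f%% of image)\n",
              sum(x$mask), 100 * mean(x$mask)))
  if (!any(is.na(x$seeds_used)))
    cat(sprintf("  seeds: %d liver / %d background; solver residual %.2g\n",
                x$seeds_used["liver"], x$seeds_used["background"],
                x$solver_residual))
  invisible(x)
}

#' @export
plot.segmentation <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    graphics::image(t(image)[, nrow(image):1], col = gray.colors(256),
                    axes = FALSE, asp = nrow(image) / ncol(image), ...)
    graphics::contour(t(x$mask)[, nrow(x$mask):1], levels = 0.5,
                      add = TRUE, col = "red", drawlabels = FALSE)
  } else {
    graphics::image(t(x$mask)[, nrow(x$mask):1], col = c("black", "white"),
                    axes = FALSE, asp = nrow(x$mask) / ncol(x$mask), ...)
  }
  invisible(x)
}

#' Full prior-guided segmentation of one image
#'
#' Runs the whole pipeline: cascade probability map, automatic seeds, fused
#' edge weights, harmonic solve, threshold.  `prior` may be a fitted
#' [liver_prior_model()] (the map is computed), or a precomputed
#' `probability_map`/matrix.
#'
#' @param image Numeric matrix.
#' @param prior Model or probability map.
#' @param cfg An [rw_config()].
#' @param ... Passed to `predict.liver_prior_model` when `prior` is a model.
#' @return A `segmentation` with provenance: iterations used, seed counts,
#'   solver residual, and the prior map itself.
#' @export
rw_segment <- function(image, prior, cfg = rw_config(), ...) {
  pm <- if (inherits(prior, "liver_prior_model"))
    predict(prior, image, ...) else prior
  p <- if (inherits(pm, "probability_map")) pm$probs else pm
  seeds <- tryCatch(select_seeds(p, cfg),
                    error = function(e) stop("seed selection: ",
                                             conditionMessage(e)))
  graph <- build_graph(image, p, seeds, cfg)
  field <- tryCatch(solve_potentials(graph, tol = cfg$solver_tol),
                    error = function(e) stop("potential solve: ",
                                             conditionMessage(e)))
  # seeds are hard constraints
  field$values[seeds$liver] <- 1
  field$values[seeds$background] <- 0
  out <- label_mask(field, seeds)
  out$prior <- pm
  out$iterations <- if (inherits(pm, "probability_map")) pm$iteration else NA
  out
}
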