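#' Context-feature configuration
#'
#' Context features are probabilities sampled from the previous stage's map
#' along 8 rays at 45-degree intervals around the pixel, at a fixed radius
#' sequence, optionally preceded by the pixel's own probability.  Samples
#' falling outside the image read as probability 0 (background; the liver is
#' assumed not to touch the image border).
#'
#' @param radii Ordered positive integer pixel distances along each ray.
#' @param include_center Prepend the center probability itself.
#' @return Object of class `context_config`.  The feature count is
#'   `8 * length(radii) + include_center`.
#' @export
context_config <- function(radii = c(3L, 6L, 9L, 12L, 15L),
                           include_center = TRUE) {
  radii <- as.integer(radii)
  stopifnot(length(radii) >= 1L, all(radii >= 1L))
  structure(list(n_rays = 8L, angle_step = 45, radii = radii,
                 include_center = isTRUE(include_center)),
            class = "context_config")
}

#' @method print context_config
#' @export
print.context_config <- function(x, ...) {
  cat("Context sampling: 8 rays at 45 deg, radii {",
      paste(x$radii, collapse = ", "), "}",
      if (x$include_center) "+ center", "->",
      context_length(x), "features\n")
  invisible(x)
}

context_length <- function(cfg) {
  cfg$n_rays * length(cfg$radii) + as.integer(cfg$include_center)
}

# (row, col) sampling offsets in feature order: center first (if any), then
# ray-major / radius-minor; ray k points at angle k*45 deg CCW from +col.
context_offsets <- function(cfg) {
  ang <- (0:7) * pi / 4
  off <- cbind(0L, 0L)[0, , drop = FALSE]
  if (cfg$include_center) off <- rbind(off, c(0L, 0L))
  for (k in seq_along(ang)) {
    dr <- as.integer(round(-cfg$radii * sin(ang[k])))
    dc <- as.integer(round(cfg$radii * cos(ang[k])))
    off <- rbind(off, cbind(dr, dc))
  }
  dimnames(off) <- NULL
  off
}

# context features for every pixel of a probability map: one shifted copy of
# the map per offset, zero-filled outside the image
context_features_all <- function(pm, cfg = context_config()) {
  probs <- if (inherits(pm, "probability_map")) pm$probs else pm
  stopifnot(is.matrix(probs))
  off <- context_offsets(cfg)
  nr <- nrow(probs); nc <- ncol(probs)
  out <- matrix(0, nr * nc, nrow(off))
  for (j in seq_len(nrow(off))) {
    dr <- off[j, 1]; dc <- off[j, 2]
    sr <- seq(max(1L, 1L - dr), min(nr, nr - dr))
    sc <- seq(max(1L, 1L - dc), min(nc, nc - dc))
    if (length(sr) && length(sc)) {
      sh <- matrix(0, nr, nc)
      sh[sr, sc] <- probs[sr + dr, sc + dc, drop = FALSE]
      out[, j] <- as.vector(sh)
    }
  }
  colnames(out) <- context_feature_names(cfg)
  out
}

context_feature_names <- function(cfg) {
  nm <- character(0)
  if (cfg$include_center) nm <- "ctx.center"
  for (k in 0:7) nm <- c(nm, sprintf("ctx.ray%d.r%d", k, cfg$radii))
  nm
}

#' Context features at one pixel
#'
#' @param pm A `probability_map` or a numeric matrix of probabilities.
#' @param x Length-2 integer (row, col), 1-based.
#' @param cfg A [context_config()].
#' @return Named numeric vector; out-of-image samples are 0.
#' @export
context_features <- function(pm, x, cfg = context_config()) {
  probs <- if (inherits(pm, "probability_map")) pm$probs else pm
  stopifnot(is.matrix(probs))
  x <- as.integer(x)
  if (x[1] < 1L || x[1] > nrow(probs) || x[2] < 1L || x[2] > ncol(probs))
    stop("pixel index outside the probability map")
  off <- context_offsets(cfg)
  r <- x[1] + off[, 1]; c <- x[2] + off[, 2]
  inside <- r >= 1L & r <= nrow(probs) & c >= 1L & c <= ncol(probs)
  v <- numeric(nrow(off))
  v[inside] <- probs[cbind(r[inside], c[inside])]
  names(v) <- context_feature_names(cfg)
  v
}

#' Bundle an image with its ground-truth label map
#'
#' @param image Numeric matrix.
#' @param label_map Binary matrix of the same shape (1 = liver).
#' @param id Case identifier.
#' @return Object of class `training_case`.
#' @export
training_case <- function(image, label_map, id = "case") {
  stopifnot(is.matrix(image), is.matrix(label_map),
            all(dim(image) == dim(label_map)))
  label_map <- matrix(as.integer(label_map > 0.5),
                      nrow(label_map), ncol(label_map))
  structure(list(image = image, label_map = label_map, id = as.character(id)),
            class = "training_case")
}

as_training_case <- function(x, i) {
  if (inherits(x, "training_case")) return(x)
  if (inherits(x, "phantom_case"))
    return(training_case(x$image, x$truth_mask, paste0("phantom", x$seed)))
  if (is.list(x) && !is.null(x$image) && !is.null(x$label_map))
    return(training_case(x$image, x$label_map,
                         if (is.null(x$id)) paste0("case", i) else x$id))
  stop("cases must be training_case or phantom_case objects")
}

#' Fit an auto-context cascade of boosted texture classifiers
#'
#' This is the model-construction step of the segmentation pipeline.  Stage 0
#' is an AdaBoost classifier on GLCM appearance features alone.  Each later
#' stage `u = 1..U` is trained on the appearance features concatenated with
#' context features sampled from the probability maps the previous stage
#' produced on the full training images, so that every stage can exploit the
#' evolving spatial layout of the liver as well as its texture.
#'
#' @param cases List of [training_case()] (or phantom cases) — typically one
#'   slice per scan, the slice with the largest liver cross-section.
#' @param U Number of context iterations; `U = 0` gives a plain
#'   appearance-only classifier.
#' @param glcm A [glcm_config()].
#' @param context A [context_config()].
#' @param n_rounds AdaBoost rounds per stage.
#' @param n_per_class Training pixels sampled per class per case.
#' @param rng_seed Integer master seed; the per-case pixel samples derive
#'   from it, so refits are bit-identical.
#' @return Object of class `liver_prior_model` with elements `stages` (list
#'   of `adaboost` classifiers, length `U + 1`), the two configs, and a
#'   per-stage training history.
#' @export
liver_prior_model <- function(cases, U = 4L,
                              glcm = glcm_config(),
                              context = context_config(),
                              n_rounds = 100L,
                              n_per_class = 2000L,
                              rng_seed = 1L) {
  stopifnot(length(cases) >= 1L, U >= 0L)
  cases <- lapply(seq_along(cases), function(i) as_training_case(cases[[i]], i))
  set.seed(rng_seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, length(cases))

  appear <- vector("list", length(cases))
  sel <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    appear[[i]] <- appearance_features(cases[[i]]$image, glcm)
    s <- sample_training_pixels(cases[[i]]$label_map, n_per_class,
                                rng_seed = case_seeds[i], id = cases[[i]]$id)
    # linear index into the column-major feature matrix
    s$lin <- (s$pixels[, "col"] - 1L) * nrow(cases[[i]]$image) +
      s$pixels[, "row"]
    sel[[i]] <- s
  }
  y <- unlist(lapply(sel, `[[`, "labels"))

  stages <- vector("list", U + 1L)
  history <- data.frame(stage = integer(0), train_error = numeric(0),
                        cross_entropy = numeric(0))
  gather <- function(ctx) {
    do.call(rbind, lapply(seq_along(cases), function(i) {
      Xi <- appear[[i]][sel[[i]]$lin, , drop = FALSE]
      if (!is.null(ctx)) Xi <- cbind(Xi, ctx[[i]][sel[[i]]$lin, , drop = FALSE])
      Xi
    }))
  }

  X <- gather(NULL)
  stages[[1]] <- tryCatch(train_boost(X, y, n_rounds),
                          error = function(e)
                            stop("stage 0: ", conditionMessage(e)))
  p_tr <- predict(stages[[1]], X)
  history <- rbind(history, data.frame(
    stage = 0L, train_error = mean((p_tr >= 0.5) != (y == 1L)),
    cross_entropy = cross_entropy(y, p_tr)))

  maps <- lapply(seq_along(cases), function(i) {
    matrix(predict(stages[[1]], appear[[i]]), nrow(cases[[i]]$image))
  })
  if (U >= 1L) {
    for (u in seq_len(U)) {
      ctx <- lapply(maps, context_features_all, cfg = context)
      X <- gather(ctx)
      stages[[u + 1L]] <- tryCatch(train_boost(X, y, n_rounds),
                                   error = function(e)
                                     stop("stage ", u, ": ",
                                          conditionMessage(e)))
      p_tr <- predict(stages[[u + 1L]], X)
      history <- rbind(history, data.frame(
        stage = u, train_error = mean((p_tr >= 0.5) != (y == 1L)),
        cross_entropy = cross_entropy(y, p_tr)))
      maps <- lapply(seq_along(cases), function(i) {
        Xi <- cbind(appear[[i]], ctx[[i]])
        matrix(predict(stages[[u + 1L]], Xi), nrow(cases[[i]]$image))
      })
    }
  }
  structure(list(stages = stages, U = as.integer(U), glcm = glcm,
                 context = context, n_rounds = as.integer(n_rounds),
                 n_per_class = as.integer(n_per_class),
                 rng_seed = as.integer(rng_seed),
                 n_cases = length(cases), history = history),
            class = "liver_prior_model")
}

cross_entropy <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @method print liver_prior_model
#' @export
print.liver_prior_model <- function(x, ...) {
  cat("Auto-context liver prior model\n")
  cat("  stages:", length(x$stages), "(U =", x$U, "context iterations)\n")
  cat("  appearance features:", 12 * nrow(x$glcm$offsets),
      "| context features:", context_length(x$context), "\n")
  cat("  trained on", x$n_cases, "case(s),", x$n_per_class,
      "pixels/class/case\n")
  invisible(x)
}

#' @method summary liver_prior_model
#' @export
summary.liver_prior_model <- function(object, ...) {
  print(object)
  cat("\nTraining history (sampled pixels):\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' Apply the cascade to an image: the prior probability map
#'
#' Runs stage 0 on every pixel, then each context stage reading context from
#' the previous map.  After the last trained stage the final stage is
#' re-applied up to `max_extra_iters` more times, stopping as soon as the
#' mean absolute change between successive maps falls below `tol`
#' (test-time iteration to convergence).
#'
#' @param object A `liver_prior_model`.
#' @param image Numeric matrix to classify.
#' @param max_extra_iters Maximum re-applications of the final stage.
#' @param tol Mean-absolute-change convergence tolerance.
#' @param appearance Optional precomputed [appearance_features()] matrix for
#'   `image` (saves the dominant cost when classifying repeatedly).
#' @param stage Stop after this stage (0 = appearance-only map, no context);
#'   default runs all `U + 1` stages plus the convergence loop.
#' @param ... Unused.
#' @return Object of class `probability_map`: `probs` (matrix in `[0,1]`),
#'   `iteration` (index of the last stage applied, counting extras), and
#'   `converged`.
#' @export
predict.liver_prior_model <- function(object, image, max_extra_iters = 5L,
                                      tol = 1e-3, appearance = NULL,
                                      stage = NULL, ...) {
  stopifnot(is.matrix(image))
  last <- if (is.null(stage)) object$U else as.integer(stage)
  stopifnot(last >= 0L, last <= object$U)
  A <- if (is.null(appearance)) appearance_features(image, object$glcm)
       else appearance
  prev <- NULL
  map <- matrix(predict(object$stages[[1]], A), nrow(image))
  if (last >= 1L) {
    for (u in seq_len(last)) {
      prev <- map
      Xi <- cbind(A, context_features_all(map, object$context))
      map <- matrix(predict(object$stages[[u + 1L]], Xi), nrow(image))
    }
  }
  delta <- if (is.null(prev)) 0 else mean(abs(map - prev))
  extra <- 0L
  final <- object$stages[[last + 1L]]
  while (last >= 1L && last == object$U && extra < max_extra_iters &&
         delta >= tol) {
    prev <- map
    Xi <- cbind(A, context_features_all(map, object$context))
    map <- matrix(predict(final, Xi), nrow(image))
    delta <- mean(abs(map - prev))
    extra <- extra + 1L
  }
  structure(list(probs = map, iteration = last + extra,
                 converged = delta < tol, extra_iterations = extra),
            class = "probability_map")
}

#' @method print probability_map
#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf(
    "Probability map %d x %d, iteration %d%s, mean p = %.3f\n",
    nrow(x$probs), ncol(x$probs), x$iteration,
    if (isTRUE(x$converged)) " (converged)" else "", mean(x$probs)))
  invisible(x)
}

#' Serialize / restore a trained cascade as plain text
#'
#' The archive is a version-tagged YAML document holding every stump, stage
#' weight and both configurations, so models survive round trips through
#' text-only storage.
#'
#' @param model A `liver_prior_model`.
#' @param path File path.
#' @return `write_cascade` returns `path` invisibly; `read_cascade` the model.
#' @export
write_cascade <- function(model, path) {
  stopifnot(inherits(model, "liver_prior_model"))
  doc <- list(
    format = "liverseg-cascade", version = 1L,
    U = model$U, n_rounds = model$n_rounds, n_per_class = model$n_per_class,
    rng_seed = model$rng_seed, n_cases = model$n_cases,
    glcm = list(quant_levels = model$glcm$quant_levels,
                distances = unique(model$glcm$offsets$distance),
                angles = unique(model$glcm$offsets$angle),
                patch_radius = model$glcm$patch_radius,
                symmetric = model$glcm$symmetric,
                intensity_range = model$glcm$intensity_range),
    context = list(radii = model$context$radii,
                   include_center = model$context$include_center),
    stages = lapply(model$stages, function(s)
      list(feature = s$feature, threshold = s$threshold,
           polarity = s$polarity, alpha = s$alpha,
           n_features = s$n_features)),
    history = as.list(model$history))
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "liverseg-cascade"))
    stop("not a liverseg cascade archive: ", path)
  if (!identical(as.integer(doc$version), 1L))
    stop("unsupported cascade archive version: ", doc$version)
  glcm <- glcm_config(doc$glcm$quant_levels, doc$glcm$distances,
                      doc$glcm$angles, doc$glcm$patch_radius,
                      doc$glcm$symmetric, unlist(doc$glcm$intensity_range))
  context <- context_config(doc$context$radii, doc$context$include_center)
  stages <- lapply(doc$stages, function(s)
    structure(list(feature = as.integer(unlist(s$feature)),
                   threshold = as.numeric(unlist(s$threshold)),
                   polarity = as.integer(unlist(s$polarity)),
                   alpha = as.numeric(unlist(s$alpha)),
                   n_features = as.integer(s$n_features)),
              class = "adaboost"))
  structure(list(stages = stages, U = as.integer(doc$U), glcm = glcm,
                 context = context, n_rounds = as.integer(doc$n_rounds),
                 n_per_class = as.integer(doc$n_per_class),
                 rng_seed = as.integer(doc$rng_seed),
                 n_cases = as.integer(doc$n_cases),
                 history = as.data.frame(doc$history)),
            class = "liver_prior_model")
}
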