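#' Train a discrete AdaBoost classifier with decision stumps
#'
#' Binary boosting with depth-1 stumps `h(x) = polarity * sign(x[f] - thr)`.
#' Labels are 0/1 and mapped internally to -1/+1.  Stump search scans every
#' midpoint threshold of every feature for the minimum weighted error; ties
#' break deterministically (lowest feature index, then lowest threshold), so
#' training is reproducible — `rng_seed` is accepted for interface symmetry
#' but the procedure involves no randomness.  Boosting stops early when a
#' round separates the data perfectly or no weak learner beats chance.
#'
#' @param X Numeric matrix, one row per sample.
#' @param y Binary labels (0 = background, 1 = liver).
#' @param n_rounds Maximum number of boosting rounds.
#' @param rng_seed Unused; kept so all training entry points share a seed
#'   argument.
#' @return Object of class `adaboost`: stump parameters, their weights, and
#'   the training feature count.
#' @export
train_boost <- function(X, y, n_rounds = 100L, rng_seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), n_rounds >= 1L)
  if (any(!is.finite(X))) stop("non-finite feature value in training data")
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; both labels are required")
  fit <- cpp_adaboost(X, 2L * y - 1L, as.integer(n_rounds))
  structure(list(feature = as.integer(fit$feature),
                 threshold = as.numeric(fit$threshold),
                 polarity = as.integer(fit$polarity),
                 alpha = as.numeric(fit$alpha),
                 n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "adaboost")
}

#' @method print adaboost
#' @export
print.adaboost <- function(x, ...) {
  cat("AdaBoost classifier:", length(x$alpha), "decision stumps over",
      x$n_features, "features\n")
  invisible(x)
}

#' Boosted margin H(f) for feature rows
#'
#' @param object An `adaboost` classifier.
#' @param X Numeric matrix with `n_features` columns.
#' @return Numeric vector of margins (weighted stump votes).
#' @export
boost_margin <- function(object, X) {
  stopifnot(inherits(object, "adaboost"))
  X <- as.matrix(X)
  if (ncol(X) != object$n_features)
    stop(sprintf("feature length mismatch: classifier expects %d, got %d",
                 object$n_features, ncol(X)))
  H <- numeric(nrow(X))
  for (m in seq_along(object$alpha)) {
    h <- ifelse(X[, object$feature[m]] > object$threshold[m], 1L, -1L) *
      object$polarity[m]
    H <- H + object$alpha[m] * h
  }
  H
}

#' @export
predict.adaboost <- function(object, newdata, type = c("prob", "margin"),
                             ...) {
  type <- match.arg(type)
  H <- boost_margin(object, newdata)
  if (type == "margin") H else margin_to_prob(H)
}

#' Map a boosted margin to a class probability
#'
#' The logistic link `p = e^H / (e^H + e^{-H})`, evaluated in overflow-safe
#' form; strictly increasing in `H`, with `margin_to_prob(0) = 0.5` and
#' `margin_to_prob(-H) = 1 - margin_to_prob(H)`.
#'
#' @param H Numeric vector of margins.
#' @return Probabilities in `[0, 1]`.
#' @export
margin_to_prob <- function(H) {
  stopifnot(all(is.finite(H)))
  stats::plogis(2 * H)
}

#' Balanced training-pixel sample from a labeled slice
#'
#' Draws up to `n_per_class` pixels per class without replacement, uniformly
#' at random, deterministically for a given seed.  If a class has fewer
#' pixels than requested, the whole class is used with a warning.
#'
#' @param label_map Binary matrix (1 = liver).
#' @param n_per_class Pixels per class.
#' @param rng_seed Integer seed.
#' @param id Case identifier used in error messages.
#' @return List with `pixels` (n x 2 matrix of row, col) and `labels`.
#' @export
sample_training_pixels <- function(label_map, n_per_class = 2000L,
                                   rng_seed = 1L, id = "case") {
  stopifnot(is.matrix(label_map), all(label_map %in% c(0, 1)))
  pos <- which(label_map == 1)
  neg <- which(label_map == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop(sprintf("case '%s': one class is absent from the label map", id))
  take <- function(idx, cls) {
    if (length(idx) < n_per_class) {
      warning(sprintf("case '%s': class %d has only %d pixels (%d requested)",
                      id, cls, length(idx), n_per_class))
      idx
    } else sample(idx, n_per_class)
  }
  set.seed(rng_seed)
  s_pos <- take(pos, 1L)
  s_neg <- take(neg, 0L)
  idx <- c(s_pos, s_neg)
  list(pixels = cbind(row = (idx - 1L) %% nrow(label_map) + 1L,
                      col = (idx - 1L) %/% nrow(label_map) + 1L),
       labels = rep(c(1L, 0L), c(length(s_pos), length(s_neg))))
}
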