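config_schema <- list(
  glcm = c("quant_levels", "distances", "angles", "patch_radius",
           "symmetric", "intensity_range"),
  context = c("radii", "include_center"),
  boost = c("n_rounds", "n_per_class", "U"),
  random_walk = c("alpha", "beta", "connectivity", "seed_hi", "seed_lo",
                  "weight_floor", "solver_tol"),
  phantom = c("image_size", "liver_intensity", "background_intensity",
              "confuser_intensity", "confuser_delta", "liver_texture_scale",
              "confuser_texture_scale", "background_texture_scale",
              "texture_amp", "n_confusers", "lesion_count",
              "lesion_intensity", "noise_sigma", "spacing", "area_range"),
  paths = c("output_dir", "model"),
  seed = NULL, log_level = NULL)

#' Load and validate a run configuration
#'
#' Reads a YAML file with optional sections `glcm`, `context`, `boost`,
#' `random_walk`, `phantom`, `paths` plus top-level `seed` and `log_level`.
#' Every value is validated through the corresponding config constructor
#' before any computation; unknown sections or keys are rejected by name.
#'
#' @param path YAML file, or a list with the same structure.
#' @return Object of class `run_config` with fully-constructed module
#'   configs and defaults filled in.
#' @export
run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else if (is.list(path)) path
         else {
           if (!file.exists(path)) stop("no such config file: ", path)
           yaml::read_yaml(path)
         }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(raw), names(config_schema))) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(raw[[sec]]), allowed)
    if (length(bad) > 0L)
      stop("unknown config key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  build <- function(fn, args) do.call(fn, args[!vapply(args, is.null,
                                                       logical(1))])
  glcm_args <- raw$glcm
  if (!is.null(glcm_args$distances))
    glcm_args$distances <- as.integer(unlist(glcm_args$distances))
  if (!is.null(glcm_args$angles))
    glcm_args$angles <- as.numeric(unlist(glcm_args$angles))
  ctx_args <- raw$context
  if (!is.null(ctx_args$radii)) ctx_args$radii <- as.integer(unlist(ctx_args$radii))
  boost <- utils::modifyList(list(n_rounds = 100L, n_per_class = 2000L,
                                  U = 4L), as.list(raw$boost))
  ph_args <- raw$phantom
  for (k in c("image_size", "spacing", "area_range"))
    if (!is.null(ph_args[[k]])) ph_args[[k]] <- as.numeric(unlist(ph_args[[k]]))
  structure(list(
    glcm = build(glcm_config, as.list(glcm_args)),
    context = build(context_config, as.list(ctx_args)),
    boost = boost,
    random_walk = build(rw_config, as.list(raw$random_walk)),
    phantom = build(phantom_spec, as.list(ph_args)),
    paths = as.list(raw$paths),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    log_level = if (is.null(raw$log_level)) "info" else raw$log_level),
    class = "run_config")
}

#' @method print run_config
#' @export
print.run_config <- function(x, ...) {
  cat("liverseg run configuration (seed", x$seed, ")\n")
  print(x$glcm); print(x$context)
  cat("  boosting:", x$boost$n_rounds, "rounds, U =", x$boost$U,
      ",", x$boost$n_per_class, "px/class\n")
  cat("  random walk: alpha", x$random_walk$alpha, "beta",
      x$random_walk$beta, "\n")
  invisible(x)
}
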