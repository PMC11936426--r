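#' End-to-end run configuration
#'
#' Bundles the synthetic-data, architecture, training and saliency options
#' of a full run. One master seed is fanned out to named substreams per
#' stage, so e.g. changing the saliency options cannot perturb the
#' training randomness.
#'
#' @param synth a [synth_config()].
#' @param spec a [cnn_spec()].
#' @param train a [train_config()].
#' @param xai list of saliency options: `variant` (`"gradcam"` or
#'   `"gradcampp"`), `n_maps` (overlays rendered for the first validation
#'   images), `alpha` blend, `colormap`, optional `layer_id`.
#' @param seed master seed, propagated to all stages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(synth = synth_preset("balanced"),
                       spec = cnn_spec(),
                       train = train_config(),
                       xai = list(variant = "gradcam", n_maps = 4L,
                                  alpha = 0.5, colormap = "jet"),
                       seed = 1L) {
  synth$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  structure(list(synth = synth, spec = spec, train = train, xai = xai,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Lossless inverse of [write_run_config()]: the round trip reproduces the
#' configuration exactly.
#'
#' @param path YAML file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- synth_config(n_per_class = y$synth$n_per_class,
                      image_shape = y$synth$image_shape,
                      noise_sigma = y$synth$noise_sigma, seed = y$synth$seed)
  spec <- cnn_spec(input_shape = y$spec$input_shape,
                   n_classes = y$spec$n_classes,
                   fc_sizes = y$spec$fc_sizes,
                   dropout_rate = y$spec$dropout_rate,
                   beta = y$spec$beta, activation = y$spec$activation,
                   filters = y$spec$filters)
  tr <- train_config(batch_size = y$train$batch_size,
                     learning_rate = y$train$learning_rate,
                     lr_decay_factor = y$train$lr_decay_factor,
                     patience = y$train$patience,
                     max_epochs = y$train$max_epochs,
                     optimizer = y$train$optimizer,
                     class_weights = y$train$class_weights,
                     validation_fraction = y$train$validation_fraction,
                     seed = y$train$seed, verbose = y$train$verbose)
  run_config(synth = syn, spec = spec, train = tr, xai = y$xai,
             seed = y$seed)
}

#' Run the full synthesize-train-evaluate-explain pipeline
#'
#' Produces an idempotent run directory: `config.yaml`, `model.rds` (the
#' fitted object with the spec embedded), `history.csv`, `metrics.json`
#' (validation metrics), and `maps/` with one saliency overlay PNG per
#' requested validation image. Every artifact is regenerable from the
#' config and seed; an existing run directory is refused unless
#' `force = TRUE`.
#'
#' @param config a [run_config()].
#' @param out_dir run directory to create.
#' @param force overwrite an existing run directory.
#' @return invisibly, a list with the fitted object, the validation
#'   metrics report, and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L) {
    if (!force)
      stop("run directory ", out_dir,
           " already contains artifacts; use force = TRUE to overwrite")
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(file.path(out_dir, "maps"), recursive = TRUE,
             showWarnings = FALSE)

  dataset <- generate_lesions(config$synth)
  fit <- ngndg_cnn(dataset$images, dataset$labels, spec = config$spec,
                   config = config$train, class_names = dataset$classes)
  xv <- dataset$images[fit$split$valid, , , , drop = FALSE]
  yv <- dataset$labels[fit$split$valid]
  report <- suppressMessages(evaluate_cnn(fit, xv, yv))

  write_run_config(config, file.path(out_dir, "config.yaml"))
  saveRDS(fit, file.path(out_dir, "model.rds"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics_to_list(report),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  n_maps <- min(config$xai$n_maps %||% 4L, length(yv))
  variant <- config$xai$variant %||% "gradcam"
  for (i in seq_len(n_maps)) {
    img <- xv[i, , , ]
    sm <- explain(fit, img, target_class = yv[i], variant = variant,
                  layer_id = config$xai$layer_id)
    ov <- render_overlay(sm, img, colormap = config$xai$colormap %||% "jet",
                         alpha = config$xai$alpha %||% 0.5)
    png::writePNG(pmin(pmax(ov, 0), 1),
                  file.path(out_dir, "maps",
                            sprintf("valid_%03d_class%d_%s.png",
                                    i, yv[i], variant)))
  }

  invisible(list(fit = fit, metrics = report,
                 paths = list(
                   config = file.path(out_dir, "config.yaml"),
                   model = file.path(out_dir, "model.rds"),
                   history = file.path(out_dir, "history.csv"),
                   metrics = file.path(out_dir, "metrics.json"),
                   maps = file.path(out_dir, "maps"))))
}
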