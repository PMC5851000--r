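# End-to-end experiment orchestration: simulate -> sample -> train ->
# evaluate, reproducibly from one seed.

#' Configuration of a full estimation experiment
#'
#' Bundles the simulator, index, network and optimizer settings with the
#' experiment type: `"dnn-rgb"` (the full model), `"dnn-gray"` (spectral
#' ablation), `"lr-rgb"` (spatial ablation) — all under leave-one-bay-out
#' cross-validation — or `"dnn-t"` (temporal ablation, leave-one-stage-out).
#' One global seed fans out to deterministic sub-streams for scene
#' generation, weight initialization, batch shuffling, augmentation and
#' dropout, so identical configurations reproduce identical reports.
#'
#' @param synthetic A [synth_config()].
#' @param index Vegetation index name for the targets.
#' @param vi A [vi_params()].
#' @param net A [net_config()] (its `in_channels` is adjusted automatically
#'   for `"dnn-gray"`).
#' @param train A [train_config()].
#' @param experiment One of `"dnn-rgb"`, `"dnn-gray"`, `"lr-rgb"`, `"dnn-t"`.
#' @param folds Optional integer subset of bay folds to run (default: all).
#' @param temporal_stages Optional subset of held-out stages for `"dnn-t"`.
#' @param out_hw Standardized plot-image size.
#' @param output_dir Optional directory for report, models and manifest.
#' @param seed Global experiment seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = synth_config(), index = "NDVI",
                       vi = vi_params(), net = net_config(),
                       train = train_config(),
                       experiment = c("dnn-rgb", "dnn-gray", "lr-rgb", "dnn-t"),
                       folds = NULL, temporal_stages = NULL,
                       out_hw = c(15, 208), output_dir = NULL, seed = 1L) {
  experiment <- match.arg(experiment)
  index <- toupper(index)
  if (!index %in% VI_INDICES) stop("unknown index: ", index, call. = FALSE)
  structure(list(synthetic = synthetic, index = index, vi = vi, net = net,
                 train = train, experiment = experiment, folds = folds,
                 temporal_stages = temporal_stages,
                 out_hw = as.integer(out_hw), output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate and sample the full plot dataset of a trial
#'
#' Generates every (bay, stage) scene of the synthetic configuration and
#' crops all plot samples with their VI targets.
#'
#' @param synthetic A [synth_config()].
#' @param index,vi Vegetation index and its parameters.
#' @param out_hw Standardized plot-image size.
#' @return A `plot_samples` object covering the whole trial.
#' @export
build_dataset <- function(synthetic, index = "NDVI", vi = vi_params(),
                          out_hw = c(15, 208)) {
  parts <- list()
  for (bi in seq_len(synthetic$n_bays)) {
    for (st in seq_len(synthetic$n_stages)) {
      scene <- generate_field(synthetic, bi, st)
      parts[[length(parts) + 1L]] <-
        sample_plots(scene, index = index, params = vi, out_hw = out_hw)
    }
  }
  bind_samples(parts)
}

fit_one <- function(samples, train_idx, cfg, seed_label) {
  tr <- cfg$train
  tr$seed <- substream_seed(cfg$seed, "fit", cfg$experiment, seed_label)
  train_set <- samples[train_idx]
  switch(cfg$experiment,
    "lr-rgb" = vi_lm(train_set),
    "dnn-gray" = {
      net <- cfg$net
      net$c <- 1L
      vi_dnn(to_grayscale(train_set), net = net, train = tr)
    },
    vi_dnn(train_set, net = cfg$net, train = tr)  # dnn-rgb / dnn-t
  )
}

predict_one <- function(model, samples, test_idx, cfg) {
  test_set <- samples[test_idx]
  if (cfg$experiment == "dnn-gray") test_set <- to_grayscale(test_set)
  predict(model, test_set)
}

#' Run a full estimation experiment
#'
#' Simulates the trial, samples all plots, trains the selected model under
#' the appropriate validation scheme (bay folds for `dnn-rgb` / `dnn-gray` /
#' `lr-rgb`; temporal hold-out for `dnn-t`), pools the held-out predictions
#' and evaluates them. With `output_dir` set, writes `report.csv`,
#' `report.json`, a `manifest.yaml` carrying the seed and configuration hash,
#' and the trained models.
#'
#' @param cfg A [run_config()].
#' @return The `eval_report`, invisibly, with the pooled per-sample
#'   predictions attached as attribute `"predictions"` and the trained
#'   models as attribute `"models"`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  syn <- cfg$synthetic
  syn$seed <- substream_seed(cfg$seed, "synthetic")
  message(sprintf("[%s] simulating %d bays x %d plots x %d stages",
                  cfg$experiment, syn$n_bays, syn$plots_per_bay, syn$n_stages))
  samples <- build_dataset(syn, cfg$index, cfg$vi, cfg$out_hw)
  message(sprintf("[%s] %d samples (%d excluded)", cfg$experiment,
                  length(samples), nrow(samples$excluded)))

  if (cfg$experiment == "dnn-t") {
    splits <- temporal_holdout_splits(samples, stages = cfg$temporal_stages)
    labels <- vapply(splits, function(s) paste0("stage", s$stage), "")
  } else {
    splits <- make_bay_folds(samples)
    if (!is.null(cfg$folds)) splits <- splits[cfg$folds]
    labels <- vapply(splits, function(s) paste0("fold", s$fold_id), "")
  }

  preds <- list()
  models <- list()
  n_train <- n_test <- 0L
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    message(sprintf("[%s] %s: training on %d, testing on %d",
                    cfg$experiment, labels[i], length(sp$train),
                    length(sp$test)))
    model <- fit_one(samples, sp$train, cfg, labels[i])
    est <- predict_one(model, samples, sp$test, cfg)
    preds[[i]] <- data.frame(split = labels[i],
                             plot_id = samples$meta$plot_id[sp$test],
                             bay = samples$meta$bay[sp$test],
                             stage = samples$meta$stage[sp$test],
                             observed = samples$meta$target_vi[sp$test],
                             estimated = est, stringsAsFactors = FALSE)
    models[[labels[i]]] <- model
    n_train <- n_train + length(sp$train)
    n_test <- n_test + length(sp$test)
  }
  pd <- do.call(rbind, preds)
  report <- summarize_errors(pd$observed, pd$estimated, pd$stage,
                             model_name = cfg$experiment,
                             n_train = n_train, n_test = n_test)
  attr(report, "predictions") <- pd
  attr(report, "models") <- models

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_eval_report(report,
                      csv_path = file.path(cfg$output_dir, "report.csv"),
                      json_path = file.path(cfg$output_dir, "report.json"))
    write.csv(pd, file.path(cfg$output_dir, "predictions.csv"),
              row.names = FALSE)
    hashable <- cfg[c("index", "experiment", "folds", "temporal_stages",
                      "out_hw", "seed")]
    hashable$synthetic <- unclass(syn)
    hashable$net <- unclass(cfg$net)
    hashable$train <- unclass(cfg$train)
    hashable$vi <- unclass(cfg$vi)
    manifest <- list(seed = cfg$seed, config_hash = config_hash(hashable),
                     experiment = cfg$experiment,
                     n_samples = length(samples),
                     n_excluded = nrow(samples$excluded),
                     n_train = n_train, n_test = n_test,
                     splits = labels)
    writeLines(yaml::as.yaml(manifest),
               file.path(cfg$output_dir, "manifest.yaml"))
    for (lb in names(models))
      if (inherits(models[[lb]], "vi_dnn"))
        save_vi_dnn(models[[lb]], file.path(cfg$output_dir, paste0("model_", lb)))
  }
  invisible(report)
}
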