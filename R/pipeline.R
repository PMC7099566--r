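# End-to-end orchestration: generate -> preprocess -> train (original and
# flip-augmented variants) -> evaluate, with every artifact written to a
# self-describing run directory. Configuration round-trips through JSON.

#' Full-run configuration
#'
#' Bundles the per-stage configurations plus the cohort composition and a
#' global seed from which the cohort, split, and training seeds are derived
#' deterministically.
#'
#' @param phantom A [phantom_config()].
#' @param n_benign,n_malignant Cohort composition (defaults 43/20, the
#'   published class proportions).
#' @param z_range Inclusive axial slicing range.
#' @param fraction_train Training fraction for the stratified split.
#' @param augment Also train on the flip-augmented variant (the published
#'   comparison trains both).
#' @param train A [train_config()] (its seed is overridden by a derived one).
#' @param eval_k Folds for [kfold_cv()] runs driven from this config.
#' @param sweep_rates Learning-rate grid for [learning_rate_sweep()] runs.
#' @param global_seed Master seed.
#' @param write_volumes Write per-patient NIfTI files during
#'   [run_pipeline()] (the manifest is always written).
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = phantom_config(),
                       n_benign = 43L, n_malignant = 20L,
                       z_range = c(6L, 25L), fraction_train = 0.75,
                       augment = TRUE, train = train_config(),
                       eval_k = 10L, sweep_rates = c(0.03, 0.1, 0.3, 1.0, 3.0),
                       global_seed = 1L, write_volumes = FALSE) {
  structure(list(phantom = phantom, n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 z_range = as.integer(z_range),
                 fraction_train = fraction_train, augment = isTRUE(augment),
                 train = train, eval_k = as.integer(eval_k),
                 sweep_rates = sweep_rates,
                 global_seed = as.integer(global_seed),
                 write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' Serialize a run configuration to JSON
#' @param config A [run_config()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Inverse of [write_run_config()]: reconstructs the typed configuration
#' objects, so write -> read is lossless.
#'
#' @param path `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- x$phantom
  ph$tumor_semiaxes_cm <- as.list(ph$tumor_semiaxes_cm)
  run_config(phantom = do.call(phantom_config, ph),
             n_benign = x$n_benign, n_malignant = x$n_malignant,
             z_range = x$z_range, fraction_train = x$fraction_train,
             augment = x$augment, train = do.call(train_config, x$train),
             eval_k = x$eval_k, sweep_rates = x$sweep_rates,
             global_seed = x$global_seed, write_volumes = x$write_volumes)
}

#' Save a model checkpoint
#'
#' Writes the parameter arrays (`params.rds`) plus a JSON sidecar describing
#' the architecture and, optionally, the training configuration.
#'
#' @param params `network_params`.
#' @param dir Checkpoint directory (created if needed).
#' @param train_cfg Optional [train_config()] recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(params, dir, train_cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(params, file.path(dir, "params.rds"))
  meta <- list(architecture = "conv6@5x5-bn-sigmoid-avgpool / conv12@5x5-bn-sigmoid-avgpool / fc300x2-softmax",
               shape_chain = NET_SHAPE_CHAIN, features = NET_FEATURES,
               train_config = if (!is.null(train_cfg)) unclass(train_cfg))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       pretty = TRUE, auto_unbox = TRUE)
  invisible(dir)
}

#' Load a model checkpoint
#' @param dir Directory written by [save_checkpoint()].
#' @return `network_params`.
#' @export
load_checkpoint <- function(dir) readRDS(file.path(dir, "params.rds"))

write_report_json <- function(report, path) {
  out <- report
  out$roc_points <- NULL
  jsonlite::write_json(list(metrics = unclass(out)), path, digits = NA,
                       pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full pipeline into a run directory
#'
#' Generates the synthetic cohort, builds the slice dataset, performs the
#' stratified split, trains and evaluates the network on the original
#' training set and (if configured) on the flip-augmented one, and writes a
#' self-describing run directory: `config.json`, `manifest.csv`,
#' `dataset_index.csv`, per-variant model checkpoints, training histories,
#' evaluation reports (JSON) and ROC curves (CSV). Re-running from the
#' stored config reproduces the reports bit for bit.
#'
#' @param config A [run_config()].
#' @param output_dir Writable output directory.
#' @param verbose Log per-stage counts.
#' @return Invisibly, a list with the split, per-variant fits and reports,
#'   and `output_dir`.
#' @export
run_pipeline <- function(config = run_config(), output_dir,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  write_run_config(config, file.path(output_dir, "config.json"))
  seeds <- derive_seeds(config$global_seed, 3L)

  cohort <- generate_cohort(config$n_benign, config$n_malignant,
                            config$phantom, seed = seeds[1])
  save_cohort(cohort, file.path(output_dir, "volumes"),
              write_volumes = config$write_volumes)
  say("stage generate: %d volumes (%d benign / %d malignant)",
      length(cohort), config$n_benign, config$n_malignant)

  dataset <- build_dataset(cohort, config$z_range[1], config$z_range[2])
  split <- stratified_split(dataset, config$fraction_train, seed = seeds[2])
  index <- dataset$meta
  key <- paste(index$patient_id, index$z_index)
  train_key <- paste(split$train$meta$patient_id, split$train$meta$z_index)
  index$partition <- ifelse(key %in% train_key, "train", "test")
  utils::write.csv(index, file.path(output_dir, "dataset_index.csv"),
                   row.names = FALSE)
  say("stage preprocess: %d slices; split %d train / %d test",
      n_images(dataset), n_images(split$train), n_images(split$test))

  variants <- list(original = split)
  if (config$augment) variants$augmented <- augment_flip_minority(split)

  fits <- list(); reports <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    cfg <- config$train
    cfg$seed <- seeds[3]
    say("stage train (%s): %d training images", nm, n_images(v$train))
    fit <- train_network(init_params(cfg$seed), v$train, v$test, cfg)
    rep <- evaluate_classifier(fit$params, v$test)
    save_checkpoint(fit$params, file.path(output_dir, paste0("model_", nm)), cfg)
    utils::write.csv(fit$history,
                     file.path(output_dir, paste0("history_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(rep$roc_points,
                     file.path(output_dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
    write_report_json(rep, file.path(output_dir, paste0("report_", nm, ".json")))
    say("stage evaluate (%s): acc %.3f sens %.3f spec %.3f auc %.3f (best epoch %d)",
        nm, rep$accuracy, rep$sensitivity, rep$specificity, rep$auc,
        fit$best_epoch)
    fits[[nm]] <- fit; reports[[nm]] <- rep
  }
  invisible(list(split = split, fits = fits, reports = reports,
                 output_dir = output_dir))
}
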