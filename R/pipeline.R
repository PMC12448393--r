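# YAML-backed run configuration and the command implementations behind the
# `exec/ecfusion` entry point (synth / train / predict / evaluate). All logic
# lives here so it is unit-testable; the executable is a thin dispatcher.

MODEL_KEYS <- c("n_feat", "n_heads", "n_blocks", "kernel_sizes", "use_gfe",
                "use_lfe", "autoregressive", "zero_seq", "zero_tdi",
                "paper_subscripts", "threshold")
TRAIN_KEYS <- c("lambda1", "lambda2", "margin", "phase1_epochs", "phase1_batch",
                "phase1_lr", "phase2_epochs", "phase2_batch", "phase2_lr",
                "beta1", "beta2", "triplets_per_epoch", "seed")
SYNTH_KEYS <- c("branching", "proteins_per_leaf", "length_range", "n_feat",
                "separation", "noise", "rho", "motif_length", "motif_strength",
                "multi_label_prob", "parent_dep", "seed")

#' Read and validate a YAML run configuration
#'
#' The file may hold three sections — `model`, `train`, `synth` — whose keys
#' must match the arguments of [model_config()], [train_config()] and
#' [synth_config()]; unknown keys (and unknown sections) are rejected by
#' name. Two profiles ship with the package: `paper.yaml` (the published
#' hyperparameters) and `test.yaml` (a toy profile that runs in seconds);
#' retrieve them with `system.file("config", ..., package = "ecfusion")`.
#'
#' @param path Path to the YAML file.
#' @param seed Optional seed overriding the `train`/`synth` seeds.
#' @return List with `model` ([model_config()]), `train` ([train_config()]),
#'   `synth` ([synth_config()]).
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  bad_sections <- setdiff(names(raw), c("model", "train", "synth"))
  if (length(bad_sections) > 0L) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in '%s' section: %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    x
  }
  model <- check_keys(raw$model, MODEL_KEYS, "model")
  train <- check_keys(raw$train, TRAIN_KEYS, "train")
  synth <- check_keys(raw$synth, SYNTH_KEYS, "synth")
  if (!is.null(seed)) {
    train$seed <- as.integer(seed)
    synth$seed <- as.integer(seed)
  }
  list(model = do.call(model_config, as.list(model)),
       train = do.call(train_config, as.list(train)),
       synth = do.call(synth_config, as.list(synth)))
}

#' Generate a synthetic fixture directory
#'
#' @param config Run configuration from [read_run_config()], or a
#'   [synth_config()].
#' @param out_dir Output directory.
#' @return Paths of the emitted files, invisibly.
#' @export
cmd_synth <- function(config, out_dir) {
  sc <- if (inherits(config, "synth_config")) config else config$synth
  synth <- generate_dataset(sc)
  write_synth_dataset(synth, out_dir)
}

load_data_dir <- function(data_dir) {
  assemble_dataset(file.path(data_dir, "sequences.fasta"),
                   file.path(data_dir, "tdi.fasta"),
                   file.path(data_dir, "embeddings.rds"),
                   file.path(data_dir, "labels.tsv"),
                   quiet = TRUE)
}

#' Train a model from a fixture directory
#'
#' Runs the requested phase(s) and writes a checkpoint plus a JSON-lines
#' training log (`epoch`, `phase`, `loss`, `lr` per line). Phase 2 alone
#' requires a phase-1 checkpoint via `resume`, unless `no_pretrain = TRUE`
#' (the "no-tripletloss" ablation: the head is trained on a frozen random
#' extractor).
#'
#' @param config Run configuration from [read_run_config()].
#' @param data_dir Directory produced by [cmd_synth()] (or laid out the same
#'   way).
#' @param out_checkpoint Checkpoint output path.
#' @param phase `"both"`, `"1"`, or `"2"`.
#' @param resume Optional phase-1 checkpoint to start phase 2 from.
#' @param no_pretrain Allow phase 2 from random initialization.
#' @param log_file Optional JSON-lines log path (default: alongside the
#'   checkpoint).
#' @return The fitted/partial model, invisibly.
#' @export
cmd_train <- function(config, data_dir, out_checkpoint, phase = c("both", "1", "2"),
                      resume = NULL, no_pretrain = FALSE, log_file = NULL) {
  phase <- match.arg(phase)
  dataset <- load_data_dir(data_dir)
  mc <- config$model
  tc <- config$train
  if (is.null(log_file)) log_file <- paste0(out_checkpoint, ".log.jsonl")
  if (phase == "both") {
    fit <- train_model(dataset, mc, tc, skip_phase1 = FALSE)
  } else if (phase == "1") {
    params <- init_model_params(mc, dataset$spaces, seed = tc$seed)
    p1 <- train_phase1(dataset, params, mc, tc)
    fit <- structure(list(params = p1$params, config = mc, spaces = dataset$spaces,
                          trace = p1$trace, train_ec_freq = dataset$ec_freq,
                          train_cfg = tc),
                     class = "ecfusion_fit")
  } else {
    if (is.null(resume) && !no_pretrain) {
      stop("phase 2 requires a phase-1 checkpoint (resume=) or no_pretrain=TRUE",
           call. = FALSE)
    }
    if (!is.null(resume)) {
      ck <- load_checkpoint(resume)
      params <- ck$params
      mc <- ck$config
    } else {
      params <- init_model_params(mc, dataset$spaces, seed = tc$seed)
    }
    p2 <- train_phase2(dataset, params, mc, tc)
    fit <- structure(list(params = p2$params, config = mc, spaces = dataset$spaces,
                          trace = p2$trace, train_ec_freq = dataset$ec_freq,
                          train_cfg = tc),
                     class = "ecfusion_fit")
  }
  save_checkpoint(fit$params, fit$config, fit$spaces, out_checkpoint,
                  extra = list(train_ec_freq = fit$train_ec_freq))
  jsonlite::stream_out(fit$trace, file(log_file), verbose = FALSE)
  invisible(fit)
}

#' Predict EC numbers for a fixture directory
#'
#' One output row per input protein (the decoder's greedy fallback guarantees
#' at least one EC each); optionally exports per-residue attention-importance
#' scores.
#'
#' @param checkpoint Path written by [cmd_train()].
#' @param data_dir Input directory (labels optional at prediction time only
#'   in the sense that they are not used).
#' @param out_tsv Predictions TSV path.
#' @param threshold Decoding threshold; default from the checkpoint config.
#' @param importance Optional path for the importance TSV.
#' @return The predictions tibble, invisibly.
#' @export
cmd_predict <- function(checkpoint, data_dir, out_tsv, threshold = NULL,
                        importance = NULL) {
  ck <- load_checkpoint(checkpoint)
  dataset <- load_data_dir(data_dir)
  fit <- list(params = ck$params, config = ck$config, spaces = ck$spaces)
  preds <- predict_dataset(dataset, fit, threshold)
  write_predictions(preds, out_tsv)
  if (!is.null(importance)) {
    readr::write_tsv(importance_table(dataset, ck$params, ck$config), importance,
                     progress = FALSE)
  }
  invisible(preds)
}

#' Evaluate predictions against ground truth
#'
#' Emits protein-level macro and micro metrics, the per-digit table and the
#' frequency-binned table as one JSON report.
#'
#' @param pred_tsv Predictions TSV from [cmd_predict()].
#' @param truth_tsv Ground-truth label TSV.
#' @param train_labels_tsv Training label TSV used for per-EC frequencies.
#' @param out_json Output JSON path.
#' @param edges Frequency bin edges.
#' @return The report list, invisibly.
#' @export
cmd_evaluate <- function(pred_tsv, truth_tsv, train_labels_tsv, out_json,
                         edges = c(0, 5, 10, 15, 20)) {
  preds <- read_predictions(pred_tsv)
  truth <- read_ec_labels(truth_tsv)
  train_labels <- read_ec_labels(train_labels_tsv)
  freqs <- table(train_labels$ec)
  freqs <- stats::setNames(as.integer(freqs), names(freqs))
  report <- list(
    protein_level = protein_level_metrics(preds, truth, mode = "both"),
    per_digit = per_digit_metrics(preds, truth, mode = "macro"),
    binned = bin_by_frequency(preds, truth, freqs, edges = edges,
                              missing_freq = "zero")
  )
  jsonlite::write_json(report, out_json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}
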