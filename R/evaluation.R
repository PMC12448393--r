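# Evaluation harness: protein-level and per-digit precision/recall/F1,
# EC-frequency binning, 3Di recovery rates, and the ablation runner.

# normalize a predictions/truth input to a protein_id/ec tibble
as_label_table <- function(x, what = "labels") {
  if (is.data.frame(x)) {
    stopifnot(all(c("protein_id", "ec") %in% names(x)))
    return(tibble::tibble(protein_id = x$protein_id, ec = x$ec))
  }
  if (is.list(x)) {
    return(tibble::tibble(protein_id = rep(names(x), lengths(x)),
                          ec = unlist(x, use.names = FALSE)))
  }
  stop(what, " must be a tibble (protein_id, ec) or a named list of EC sets",
       call. = FALSE)
}

set_prf <- function(pred_sets, truth_sets) {
  tp <- mapply(function(p, t) length(intersect(p, t)), pred_sets, truth_sets)
  np <- lengths(pred_sets)
  nt <- lengths(truth_sets)
  prec <- ifelse(np > 0, tp / np, 0)
  rec <- ifelse(nt > 0, tp / nt, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(tp = tp, np = np, nt = nt, precision = prec, recall = rec, f1 = f1)
}

#' Protein-level precision, recall and F1 of EC predictions
#'
#' Per protein, precision is the fraction of predicted ECs that are true and
#' recall the fraction of true ECs predicted; the F1 is their harmonic mean
#' (zero when the intersection is empty). `"macro"` averages the per-protein
#' values; `"micro"` pools true/false positive counts over all proteins
#' before forming the ratios. Both are computed on exact four-level EC
#' matches.
#'
#' @param pred Predictions: tibble with columns `protein_id`, `ec` (e.g. from
#'   [predict_dataset()]) or a named list of EC sets.
#' @param truth Ground truth in the same forms.
#' @param mode `"macro"`, `"micro"`, or `"both"`.
#' @return Tibble with columns `mode`, `precision`, `recall`, `f1`,
#'   `n_proteins`.
#' @export
protein_level_metrics <- function(pred, truth, mode = c("both", "macro", "micro")) {
  mode <- match.arg(mode)
  pred <- as_label_table(pred, "pred")
  truth <- as_label_table(truth, "truth")
  ids <- sort(unique(truth$protein_id))
  if (!setequal(ids, unique(pred$protein_id))) {
    stop("prediction and truth cover different protein ids", call. = FALSE)
  }
  pred_sets <- lapply(ids, function(i) unique(pred$ec[pred$protein_id == i]))
  truth_sets <- lapply(ids, function(i) unique(truth$ec[truth$protein_id == i]))
  m <- set_prf(pred_sets, truth_sets)
  rows <- list()
  if (mode %in% c("both", "macro")) {
    rows$macro <- tibble::tibble(mode = "macro", precision = mean(m$precision),
                                 recall = mean(m$recall), f1 = mean(m$f1),
                                 n_proteins = length(ids))
  }
  if (mode %in% c("both", "micro")) {
    tp <- sum(m$tp)
    prec <- if (sum(m$np) > 0) tp / sum(m$np) else 0
    rec <- if (sum(m$nt) > 0) tp / sum(m$nt) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    rows$micro <- tibble::tibble(mode = "micro", precision = prec, recall = rec,
                                 f1 = f1, n_proteins = length(ids))
  }
  dplyr::bind_rows(rows)
}

#' Per-digit (per-level) metrics
#'
#' Level-k metrics are [protein_level_metrics()] computed on the deduplicated
#' k-level prefix sets of predictions and truths, so level 1 scores the EC
#' class alone and level 4 the exact EC number. Because a level-k match
#' implies a match of every coarser prefix, F1 is non-increasing in k.
#'
#' @inheritParams protein_level_metrics
#' @param mode `"macro"` or `"micro"`.
#' @return Tibble with columns `level`, `mode`, `precision`, `recall`, `f1`,
#'   `n_proteins` (four rows per mode).
#' @export
per_digit_metrics <- function(pred, truth, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  pred <- as_label_table(pred, "pred")
  truth <- as_label_table(truth, "truth")
  purrr::map_dfr(1:4, function(k) {
    pk <- dplyr::distinct(dplyr::mutate(pred,
                                        ec = vapply(.data$ec, ec_prefix, character(1), k = k)))
    tk <- dplyr::distinct(dplyr::mutate(truth,
                                        ec = vapply(.data$ec, ec_prefix, character(1), k = k)))
    dplyr::mutate(protein_level_metrics(pk, tk, mode = mode), level = k,
                  .before = 1L)
  })
}

#' Bin per-EC F1 by training-set frequency
#'
#' Computes one F1 per EC label over the evaluated proteins (micro counts:
#' a true positive for every protein where the EC is both predicted and true,
#' a false positive/negative where only one holds), assigns each EC to a
#' half-open-left frequency bin `(e_i, e_{i+1}]` by how often it occurred in
#' training, and aggregates mean F1 per bin. Default edges give widths of 5:
#' `(0, 5], (5, 10], ...` with a final unbounded bin.
#'
#' @inheritParams protein_level_metrics
#' @param train_freqs Named integer vector: training occurrences per EC (e.g.
#'   the `ec_freq` field of an `ec_dataset` or `train_ec_freq` of a fit).
#' @param edges Strictly increasing finite bin edges starting at 0; a final
#'   `Inf` edge is appended automatically.
#' @param missing_freq `"error"` to reject evaluated ECs absent from
#'   `train_freqs`, or `"zero"` to count them as frequency 0 (first bin's
#'   left edge; reported as bin `(0, e1]`).
#' @return Tibble with columns `bin`, `lower`, `upper`, `n_ecs`, `f1`.
#' @export
bin_by_frequency <- function(pred, truth, train_freqs,
                             edges = c(0, 5, 10, 15, 20),
                             missing_freq = c("error", "zero")) {
  missing_freq <- match.arg(missing_freq)
  stopifnot(!is.unsorted(edges, strictly = TRUE), edges[1] == 0)
  pred <- as_label_table(pred, "pred")
  truth <- as_label_table(truth, "truth")
  ecs <- sort(unique(c(pred$ec, truth$ec)))
  freq <- train_freqs[ecs]
  if (anyNA(freq)) {
    if (missing_freq == "error") {
      stop("no training frequency for EC(s): ",
           paste(ecs[is.na(freq)], collapse = ", "), call. = FALSE)
    }
    freq[is.na(freq)] <- 0L
  }
  per_ec <- vapply(ecs, function(e) {
    p_ids <- pred$protein_id[pred$ec == e]
    t_ids <- truth$protein_id[truth$ec == e]
    tp <- length(intersect(p_ids, t_ids))
    fp <- length(setdiff(p_ids, t_ids))
    fn <- length(setdiff(t_ids, p_ids))
    if (tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  all_edges <- c(edges, Inf)
  # half-open-left bins (e_i, e_{i+1}]
  bin_idx <- vapply(freq, function(f) {
    which(f <= all_edges[-1] & f > c(all_edges[-length(all_edges)]))[1]
  }, integer(1))
  bin_idx[freq == 0] <- 1L
  keep <- !is.na(per_ec)
  tibble::tibble(ec = ecs, freq = as.integer(freq), bin_idx = bin_idx,
                 f1 = per_ec)[keep, ] |>
    dplyr::group_by(.data$bin_idx) |>
    dplyr::summarise(n_ecs = dplyr::n(), f1 = mean(.data$f1), .groups = "drop") |>
    dplyr::mutate(lower = all_edges[.data$bin_idx],
                  upper = all_edges[.data$bin_idx + 1L],
                  bin = sprintf("(%g, %g]", .data$lower, .data$upper)) |>
    dplyr::select("bin", "lower", "upper", "n_ecs", "f1")
}

#' 3Di recovery rate of a predicted string
#'
#' Fraction of positions at which a predicted 3Di string matches the
#' structure-derived reference string.
#'
#' @param predicted_3di,reference_3di Equal-length non-empty strings over the
#'   3Di alphabet.
#' @return Fraction in `[0, 1]`.
#' @export
recovery_rate <- function(predicted_3di, reference_3di) {
  stopifnot(is.character(predicted_3di), is.character(reference_3di),
            length(predicted_3di) == 1L, length(reference_3di) == 1L)
  if (nchar(predicted_3di) == 0L) stop("empty 3Di string", call. = FALSE)
  if (nchar(predicted_3di) != nchar(reference_3di)) {
    stop(sprintf("3Di length mismatch: %d vs %d",
                 nchar(predicted_3di), nchar(reference_3di)), call. = FALSE)
  }
  a <- strsplit(predicted_3di, "")[[1]]
  b <- strsplit(reference_3di, "")[[1]]
  mean(a == b)
}

#' Summary statistics of a set of recovery rates
#'
#' @param rates Non-empty numeric vector of per-protein recovery rates.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return One-row tibble: `mean`, `sd`, `min`, `max`, `median`, `n`.
#' @export
recovery_summary <- function(rates, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(rates) == 0L) stop("no recovery rates supplied", call. = FALSE)
  s <- if (length(rates) == 1L) 0 else stats::sd(rates)
  if (sd_type == "population") s <- s * sqrt((length(rates) - 1) / length(rates))
  tibble::tibble(mean = mean(rates), sd = s, min = min(rates), max = max(rates),
                 median = stats::median(rates), n = length(rates))
}

#' Retrain and score ablation variants
#'
#' Each requested variant disables one architectural component and retrains
#' from scratch with the shared seed list: `"-G"` passes the raw streams
#' through in place of the cross-attention pathway, `"-L"` drops the local
#' convolution pathway, `"-H"` replaces the autoregressive head with four
#' independent MLPs, `"seq_only"`/`"tdi_only"` zero out one input modality,
#' and `"no_triplet"` skips the contrastive phase. `"full"` is the unmodified
#' pipeline.
#'
#' @param train,test Training and held-out `ec_dataset`s.
#' @param model_cfg,train_cfg Base configurations (the variants modify copies).
#' @param variants Character vector of variant names.
#' @param seeds Integer vector; every variant is retrained once per seed.
#' @param level EC level at which to score (default 4, exact EC).
#' @param mode Averaging mode passed to the metrics.
#' @return Tibble with columns `variant`, `seed`, `precision`, `recall`, `f1`.
#' @export
run_ablation <- function(train, test, model_cfg = model_config(),
                         train_cfg = train_config(),
                         variants = c("full", "-G", "-L", "-H",
                                      "seq_only", "tdi_only", "no_triplet"),
                         seeds = 1L, level = 4L, mode = "macro") {
  known <- c("full", "-G", "-L", "-H", "seq_only", "tdi_only", "no_triplet")
  bad <- setdiff(variants, known)
  if (length(bad) > 0L) stop("unknown ablation variant(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  truth <- test$labels
  purrr::map_dfr(variants, function(v) {
    cfg <- model_cfg
    skip1 <- FALSE
    switch(v,
           "-G" = { cfg$use_gfe <- FALSE },
           "-L" = { cfg$use_lfe <- FALSE },
           "-H" = { cfg$autoregressive <- FALSE },
           seq_only = { cfg$zero_tdi <- TRUE },
           tdi_only = { cfg$zero_seq <- TRUE },
           no_triplet = { skip1 <- TRUE },
           full = NULL)
    purrr::map_dfr(seeds, function(s) {
      tc <- train_cfg
      tc$seed <- as.integer(s)
      fit <- train_model(train, cfg, tc, skip_phase1 = skip1)
      preds <- predict_dataset(test, fit)
      m <- per_digit_metrics(preds, truth, mode = mode)
      m <- m[m$level == level, ]
      tibble::tibble(variant = v, seed = as.integer(s),
                     precision = m$precision, recall = m$recall, f1 = m$f1)
    })
  })
}
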