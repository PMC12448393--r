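#' Read a FASTA file into a named character vector
#'
#' Used for both amino-acid sequences and 3Di structural-alphabet strings
#' (Foldseek's 20-letter discretization of local backbone geometry), which are
#' distributed in the same FASTA format. Sequences are uppercased; wrapped
#' lines and CRLF endings are normalized.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence record(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Write per-residue embedding pairs to a single-file container
#'
#' The container is a single file holding, per protein id, two dense float
#' matrices: `seq` (the sequence-model embedding) and `tdi` (the 3Di
#' structure-model embedding), each L x N with one row per residue. Both
#' matrices of a pair must agree in shape and contain only finite values.
#' The on-disk format (version 1) is an R serialization of a named list and is
#' read back losslessly by [read_embeddings()].
#'
#' @param pairs Named list; each element a list with matrices `seq` and `tdi`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(pairs, path) {
  stopifnot(is.list(pairs), length(pairs) > 0L, !is.null(names(pairs)))
  for (id in names(pairs)) validate_embedding_pair(pairs[[id]], id)
  obj <- list(format = "ecfusion-embeddings", version = 1L, proteins = pairs)
  saveRDS(obj, path, version = 2L)
  invisible(path)
}

validate_embedding_pair <- function(pair, id) {
  if (!is.list(pair) || !all(c("seq", "tdi") %in% names(pair))) {
    stop(sprintf("embedding entry '%s' must hold 'seq' and 'tdi' matrices", id),
         call. = FALSE)
  }
  s <- pair$seq; t <- pair$tdi
  if (!is.matrix(s) || !is.matrix(t)) {
    stop(sprintf("embeddings for '%s' must be matrices", id), call. = FALSE)
  }
  if (!all(dim(s) == dim(t))) {
    stop(sprintf("shape mismatch for '%s': seq is %dx%d but tdi is %dx%d",
                 id, nrow(s), ncol(s), nrow(t), ncol(t)), call. = FALSE)
  }
  if (nrow(s) < 1L) stop(sprintf("embeddings for '%s' have no residues", id), call. = FALSE)
  if (!all(is.finite(s)) || !all(is.finite(t))) {
    stop(sprintf("non-finite values in embeddings for '%s'", id), call. = FALSE)
  }
  invisible(pair)
}

#' Read embedding pairs for a set of protein ids
#'
#' @param path Container written by [write_embeddings()].
#' @param ids Protein ids to load; default all ids in the container. Missing
#'   ids are reported collectively in one error.
#' @return Named list of validated `seq`/`tdi` matrix pairs.
#' @export
read_embeddings <- function(path, ids = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "ecfusion-embeddings")) {
    stop("not an ecfusion embedding container: ", path, call. = FALSE)
  }
  pairs <- obj$proteins
  if (is.null(ids)) ids <- names(pairs)
  missing <- setdiff(ids, names(pairs))
  if (length(missing) > 0L) {
    stop("ids absent from embedding container: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- pairs[ids]
  for (id in ids) validate_embedding_pair(out[[id]], id)
  out
}

#' Assemble a modelling dataset from its four source files
#'
#' Inner-joins amino-acid FASTA, 3Di FASTA, the embedding container and the EC
#' label table on protein id. Proteins missing from any source are dropped
#' with a message; embedding row counts must equal sequence lengths (a length
#' mismatch is an error, never a truncation, since an off-by-one residue
#' misalignment would silently corrupt attention maps). Per-EC training
#' frequencies (number of proteins annotated with each EC) are recorded for
#' frequency-binned evaluation.
#'
#' @param fasta,tdi_fasta Paths to the amino-acid and 3Di FASTA files.
#' @param embeddings Path to the embedding container.
#' @param labels_tsv Path to the EC label TSV.
#' @param quiet Suppress the drop-summary message.
#' @return An `ec_dataset`: `proteins` (named list with `id`, `sequence`,
#'   `tdi_sequence`, `seq` and `tdi` matrices, `ec` character vector),
#'   `labels` tibble, `spaces` ([build_label_spaces()] over the kept proteins),
#'   and `ec_freq` (named per-EC protein counts).
#' @export
assemble_dataset <- function(fasta, tdi_fasta, embeddings, labels_tsv, quiet = FALSE) {
  seqs <- read_fasta(fasta)
  tdis <- read_fasta(tdi_fasta)
  labels <- read_ec_labels(labels_tsv)
  ids_lab <- unique(labels$protein_id)
  keep <- Reduce(intersect, list(names(seqs), names(tdis), ids_lab))
  if (length(keep) == 0L) stop("no protein id is present in all sources", call. = FALSE)
  dropped <- setdiff(unique(c(names(seqs), names(tdis), ids_lab)), keep)
  if (length(dropped) > 0L && !quiet) {
    message(sprintf("assemble_dataset: dropped %d id(s) missing from some source: %s",
                    length(dropped), paste(utils::head(dropped, 10L), collapse = ", ")))
  }
  keep <- sort(keep)
  emb <- read_embeddings(embeddings, keep)
  proteins <- lapply(keep, function(id) {
    L <- nrow(emb[[id]]$seq)
    if (nchar(seqs[[id]]) != L) {
      stop(sprintf("protein '%s': sequence has %d residues but embeddings have %d rows",
                   id, nchar(seqs[[id]]), L), call. = FALSE)
    }
    if (nchar(tdis[[id]]) != L) {
      stop(sprintf("protein '%s': 3Di string has %d letters but embeddings have %d rows",
                   id, nchar(tdis[[id]]), L), call. = FALSE)
    }
    list(id = id, sequence = seqs[[id]], tdi_sequence = tdis[[id]],
         seq = emb[[id]]$seq, tdi = emb[[id]]$tdi,
         ec = sort(labels$ec[labels$protein_id == id]))
  })
  names(proteins) <- keep
  labels <- labels[labels$protein_id %in% keep, ]
  new_ec_dataset(proteins, labels)
}

new_ec_dataset <- function(proteins, labels) {
  spaces <- build_label_spaces(labels)
  freq <- table(labels$ec)
  structure(list(proteins = proteins,
                 labels = tibble::as_tibble(labels),
                 spaces = spaces,
                 ec_freq = stats::setNames(as.integer(freq), names(freq))),
            class = "ec_dataset")
}

#' @export
print.ec_dataset <- function(x, ...) {
  cat(sprintf("<ec_dataset> %d proteins, %d distinct ECs, level sizes %s\n",
              length(x$proteins), length(x$ec_freq),
              paste(label_space_sizes(x$spaces), collapse = "/")))
  invisible(x)
}

#' Split a dataset into training and held-out parts
#'
#' Stratified by each protein's first EC so every class can appear on both
#' sides when it has at least two members.
#'
#' @param dataset An `ec_dataset`.
#' @param test_fraction Fraction of proteins held out.
#' @param seed Integer seed controlling the split.
#' @return List with `train` and `test` datasets; the training-set label
#'   spaces and EC frequencies are used for both.
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "ec_dataset"), test_fraction > 0, test_fraction < 1)
  ids <- names(dataset$proteins)
  cls <- vapply(dataset$proteins, function(p) p$ec[[1]], character(1))
  test_ids <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(ids, cls), function(members) {
      n_test <- max(1L, floor(length(members) * test_fraction))
      if (length(members) == 1L) return(character(0))
      sample(members, n_test)
    }), use.names = FALSE)
  })
  subset_ds <- function(keep) {
    new_ec_dataset(dataset$proteins[keep],
                   dataset$labels[dataset$labels$protein_id %in% keep, ])
  }
  train <- subset_ds(setdiff(ids, test_ids))
  test <- subset_ds(sort(test_ids))
  # evaluate the held-out set against training-time spaces and frequencies
  test$spaces <- train$spaces
  test$ec_freq <- train$ec_freq
  list(train = train, test = test)
}

#' Write decoded predictions to TSV
#'
#' One row per protein: `protein_id<TAB>EC/confidence;EC/confidence;...`,
#' mirroring the multi-EC annotation style of Swiss-Prot entries.
#'
#' @param predictions Tibble with columns `protein_id`, `ec`, `confidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  joined <- predictions |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      cell = paste(sprintf("%s/%.4f", .data$ec, .data$confidence), collapse = ";"),
      .groups = "drop")
  readr::write_tsv(joined, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `protein_id`, `ec`, `confidence`.
#' @export
read_predictions <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("protein_id", "cell"),
                         col_types = "cc", progress = FALSE)
  out <- tidyr::separate_rows(raw, "cell", sep = ";")
  parts <- strsplit(out$cell, "/", fixed = TRUE)
  tibble::tibble(protein_id = out$protein_id,
                 ec = vapply(parts, `[[`, character(1), 1L),
                 confidence = as.numeric(vapply(parts, `[[`, character(1), 2L)))
}
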