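#' Parse an EC number
#'
#' An Enzyme Commission (EC) number is a four-level hierarchical code,
#' `class.subclass.sub-subclass.serial`, written as four dot-separated positive
#' integers (e.g. `"2.7.7.7"`). Individual levels may exceed 9 (e.g.
#' `"2.1.1.359"`). Placeholder levels used by some databases for partial
#' annotations (`"-"`, `"n1"`, ...) are rejected: the model works with fully
#' resolved four-digit labels only.
#'
#' @param text A single EC string, four dot-separated integer tokens.
#'   Surrounding whitespace is ignored.
#' @return An `ec_number`: an integer vector of length 4 (levels 1-4).
#' @examples
#' parse_ec("2.7.7.7")
#' parse_ec("2.1.1.359")
#' @seealso [format_ec()], [ec_prefix()]
#' @export
parse_ec <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("EC number must be a single character string", call. = FALSE)
  }
  s <- trimws(text)
  if (s == "") stop("EC number is empty", call. = FALSE)
  tokens <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(tokens) != 4L || any(tokens == "")) {
    stop(sprintf("malformed EC number '%s': expected four dot-separated digits", s),
         call. = FALSE)
  }
  if (any(grepl("[-nN]", tokens))) {
    stop(sprintf("EC number '%s' contains placeholder levels; only fully resolved labels are accepted", s),
         call. = FALSE)
  }
  if (!all(grepl("^[0-9]+$", tokens))) {
    stop(sprintf("EC number '%s' has non-numeric levels", s), call. = FALSE)
  }
  digits <- as.integer(tokens)
  if (any(is.na(digits)) || any(digits < 1L)) {
    stop(sprintf("EC number '%s' has levels outside the positive integers", s),
         call. = FALSE)
  }
  structure(digits, class = "ec_number")
}

#' Canonical dotted form of an EC number
#'
#' @param ec An `ec_number` from [parse_ec()], or a bare integer vector of
#'   length 4.
#' @return The canonical dotted string.
#' @examples
#' format_ec(parse_ec(" 2.7.7.7 "))
#' @export
format_ec <- function(ec) {
  ec <- unclass(ec)
  stopifnot(length(ec) == 4L)
  paste(as.integer(ec), collapse = ".")
}

#' @export
format.ec_number <- function(x, ...) format_ec(x)

#' @export
print.ec_number <- function(x, ...) {
  cat("<EC ", format_ec(x), ">\n", sep = "")
  invisible(x)
}

#' Level-k prefix of an EC number
#'
#' The first `k` levels as a dotted prefix key; used throughout for per-digit
#' evaluation and for the per-level label vocabularies.
#'
#' @param ec An `ec_number` or EC string.
#' @param k Level, in 1..4.
#' @return Prefix string, e.g. `ec_prefix("2.7.7.7", 2)` is `"2.7"`.
#' @export
ec_prefix <- function(ec, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > 4 || k != as.integer(k)) {
    stop("prefix level k must be an integer in 1..4", call. = FALSE)
  }
  if (is.character(ec)) ec <- parse_ec(ec)
  paste(unclass(ec)[seq_len(k)], collapse = ".")
}

# prefixes of a character vector of ECs at level k, deduplicated, sorted
# numerically on the digit tuple (deterministic vocabulary order)
ec_prefixes <- function(ecs, k) {
  mat <- vapply(ecs, function(e) unclass(parse_ec(e)), integer(4))
  keys <- unname(apply(mat[seq_len(k), , drop = FALSE], 2L, paste, collapse = "."))
  uniq <- !duplicated(keys)
  keys <- keys[uniq]
  ord <- do.call(order, lapply(seq_len(k), function(i) mat[i, uniq]))
  keys[ord]
}

#' Build per-level label spaces from training EC annotations
#'
#' The level-k vocabulary is the set of distinct k-level prefixes observed in
#' the training labels (so level 4 holds full EC numbers, level 1 the top-level
#' classes). Each vocabulary is sorted numerically on its digit tuple, which
#' fixes index assignment across runs; a parent map links every level-k entry
#' to its (k-1)-prefix.
#'
#' @param ec_lists A list of character vectors (one per protein, each the
#'   protein's EC set), or a tibble with columns `protein_id` and `ec`
#'   (one row per protein/EC pair) as returned by [read_ec_labels()].
#' @return An `ec_label_spaces` object: `levels` (four character vectors),
#'   `index` (named lookup per level), and `parent` (for k >= 2, integer vector
#'   mapping each level-k entry to its parent's index at level k-1).
#' @examples
#' sp <- build_label_spaces(list(c("1.1.1.1", "1.1.1.2"), "2.7.7.7"))
#' label_space_sizes(sp)
#' @export
build_label_spaces <- function(ec_lists) {
  if (is.data.frame(ec_lists)) {
    stopifnot(all(c("protein_id", "ec") %in% names(ec_lists)))
    ec_lists <- split(ec_lists$ec, ec_lists$protein_id)
  }
  all_ecs <- unique(unlist(ec_lists, use.names = FALSE))
  if (length(all_ecs) == 0L) stop("no EC labels supplied", call. = FALSE)
  levels <- lapply(1:4, function(k) ec_prefixes(all_ecs, k))
  index <- lapply(levels, function(v) stats::setNames(seq_along(v), v))
  parent <- vector("list", 4L)
  for (k in 2:4) {
    par_key <- vapply(levels[[k]],
                      function(p) ec_prefix(paste0(p, strrep(".1", 4L - k)), k - 1L),
                      character(1))
    parent[[k]] <- unname(index[[k - 1L]][par_key])
    if (anyNA(parent[[k]])) stop("internal error: orphan prefix in label space")
  }
  structure(list(levels = levels, index = index, parent = parent),
            class = "ec_label_spaces")
}

#' Vocabulary sizes of a label space
#'
#' @param spaces An `ec_label_spaces` object.
#' @return Integer vector of length 4.
#' @export
label_space_sizes <- function(spaces) {
  vapply(spaces$levels, length, integer(1))
}

#' @export
print.ec_label_spaces <- function(x, ...) {
  cat("<ec_label_spaces> level sizes:",
      paste(label_space_sizes(x), collapse = " / "), "\n")
  invisible(x)
}

#' Multi-hot target encoding of a protein's EC set
#'
#' For each level k the active entries are exactly the distinct k-prefixes of
#' the protein's EC numbers, so a single-EC enzyme has one active entry per
#' level while a multi-EC enzyme may activate several (typically at level 4).
#' Actives are ancestor-closed by construction.
#'
#' @param ec_set Character vector of EC strings (at least one).
#' @param spaces An `ec_label_spaces` object; every prefix of `ec_set` must be
#'   present, otherwise an unknown-label error is raised (labels are never
#'   silently dropped).
#' @return An `ec_target_encoding`: list of four 0/1 numeric vectors.
#' @export
encode_targets <- function(ec_set, spaces) {
  stopifnot(inherits(spaces, "ec_label_spaces"))
  if (length(ec_set) == 0L) stop("empty EC set cannot be encoded", call. = FALSE)
  enc <- vector("list", 4L)
  for (k in 1:4) {
    pref <- unique(vapply(ec_set, function(e) ec_prefix(e, k), character(1)))
    idx <- spaces$index[[k]][pref]
    if (anyNA(idx)) {
      stop(sprintf("unknown label(s) at level %d: %s", k,
                   paste(pref[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    v <- numeric(length(spaces$levels[[k]]))
    v[idx] <- 1
    enc[[k]] <- v
  }
  structure(enc, class = "ec_target_encoding")
}

#' Read a Swiss-Prot style EC label table
#'
#' Tab-separated, two columns without a header: a protein id and its EC set as
#' a `;`-separated cell (optional spaces after the semicolons), e.g.
#' `P1<TAB>2.1.1.359; 2.1.1.354`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `ec` (one row per protein/EC
#'   pair, each `ec` validated and canonicalized).
#' @export
read_ec_labels <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("protein_id", "ec"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) stop("empty label table: ", path, call. = FALSE)
  if (anyDuplicated(raw$protein_id)) {
    stop("duplicate protein ids in label table: ",
         paste(unique(raw$protein_id[duplicated(raw$protein_id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- tidyr::separate_rows(raw, "ec", sep = ";")
  out$ec <- vapply(trimws(out$ec), function(e) format_ec(parse_ec(e)), character(1))
  tibble::as_tibble(out[out$ec != "", ])
}

#' Write an EC label table
#'
#' Inverse of [read_ec_labels()]: one row per protein, ECs joined with `"; "`.
#'
#' @param labels Tibble with columns `protein_id`, `ec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ec_labels <- function(labels, path) {
  joined <- labels |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(ec = paste(.data$ec, collapse = "; "), .groups = "drop")
  readr::write_tsv(joined, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
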