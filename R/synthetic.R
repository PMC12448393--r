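# Synthetic-embedding generator: class-structured per-residue embedding pairs
# with correlated sequence/3Di channels, a 4-level hierarchical label tree,
# planted local "functional-site" motif windows, optional multi-label
# proteins, and Gaussian noise. Emits exactly the io-module formats so the
# whole pipeline runs on fixtures with no external data.

TDI_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALPHABET <- TDI_ALPHABET  # both are 20-letter alphabets over the same glyphs

#' Synthetic dataset configuration
#'
#' The generator plants a 4-level label hierarchy: every tree node at levels
#' 1-3 contributes a class direction at strength `separation`, while level-4
#' (leaf) identity is injected only as an increment relative to the level-3
#' prototype, scaled by `parent_dep` and shared across branches per digit
#' value — so level 4 is genuinely harder than level 3 and conditioning on
#' coarser predictions is informative. The 3Di channel is a `rho`-mixture of
#' a fixed linear transform of the sequence prototype and an independent
#' class-informative signal, so the two modalities are correlated yet
#' complementary. Each protein carries one planted motif window whose
#' residues receive an extra class-specific local signal (the learnable
#' target of the local pathway and the ground truth for attention
#' importance).
#'
#' @param branching Integer vector of length 4: children per node at each
#'   level (leaf count is the product).
#' @param proteins_per_leaf Proteins generated per leaf class.
#' @param length_range Min/max residue count L (uniform).
#' @param n_feat Feature width N of both embedding channels.
#' @param separation Class-separation strength s (embedding units) of the
#'   level 1-3 hierarchy directions.
#' @param noise Within-class residue noise sigma (i.i.d. Gaussian).
#' @param rho Sequence/3Di correlation in `[0, 1]`: 1 makes the 3Di channel a
#'   pure transform of the sequence signal, smaller values mix in independent
#'   class signal.
#' @param motif_length,motif_strength Planted functional-site window length
#'   and the strength of its extra class-specific signal (units of
#'   `separation`).
#' @param multi_label_prob Probability that a protein receives a second leaf
#'   label sharing its level-3 prefix (multi-EC enzymes).
#' @param parent_dep Relative strength of the level-4 increment.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(branching = c(4L, 3L, 3L, 3L), proteins_per_leaf = 10L,
                         length_range = c(20L, 30L), n_feat = 16L,
                         separation = 3, noise = 1, rho = 0.7,
                         motif_length = 7L, motif_strength = 2,
                         multi_label_prob = 0.1, parent_dep = 1, seed = 1L) {
  stopifnot(length(branching) == 4L, all(branching >= 1L),
            proteins_per_leaf >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[2] >= length_range[1],
            n_feat >= 1L, separation >= 0, noise >= 0,
            rho >= 0, rho <= 1, motif_length >= 1L,
            multi_label_prob >= 0, multi_label_prob < 1, parent_dep >= 0)
  if (length_range[1] < motif_length) {
    stop("length range lower bound is below the motif length", call. = FALSE)
  }
  structure(list(branching = as.integer(branching),
                 proteins_per_leaf = as.integer(proteins_per_leaf),
                 length_range = as.integer(length_range),
                 n_feat = as.integer(n_feat),
                 separation = separation, noise = noise, rho = rho,
                 motif_length = as.integer(motif_length),
                 motif_strength = motif_strength,
                 multi_label_prob = multi_label_prob,
                 parent_dep = parent_dep, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate the synthetic 4-level label tree
#'
#' Digit values at each level are assigned deterministically (1..branching),
#' so e.g. branching `c(2, 2, 2, 2)` yields the 16 leaves `1.1.1.1` ..
#' `2.2.2.2`.
#'
#' @param config A [synth_config()] (only `branching` is used).
#' @return Character vector of leaf EC strings (length = product of
#'   branchings).
#' @export
generate_label_tree <- function(config) {
  b <- config$branching
  if (any(b < 1L)) stop("branching must be at least 1 at every level", call. = FALSE)
  grid <- expand.grid(d4 = seq_len(b[4]), d3 = seq_len(b[3]),
                      d2 = seq_len(b[2]), d1 = seq_len(b[1]))
  sort_keys <- order(grid$d1, grid$d2, grid$d3, grid$d4)
  grid <- grid[sort_keys, ]
  sprintf("%d.%d.%d.%d", grid$d1, grid$d2, grid$d3, grid$d4)
}

# unit-scale random direction vector
rand_dir <- function(n) stats::rnorm(n) / sqrt(n)

#' Generate a synthetic embedding dataset
#'
#' Draws per-leaf prototype pairs from the hierarchical signal model of
#' [synth_config()], then per protein: a uniform length, residue embeddings =
#' prototype + Gaussian noise, one planted motif window with extra
#' class-specific signal in both channels, an optional second leaf label
#' sharing the level-3 prefix (the prototype is then the average of the two
#' leaves'), a 3Di string derived deterministically from the 3Di embeddings,
#' and a random amino-acid sequence of matching length.
#'
#' @param config A [synth_config()].
#' @return An `ec_synth_dataset`: the `dataset` (`ec_dataset`), `motifs`
#'   tibble (`protein_id`, `start`, `end`, 1-based inclusive), and the
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  N <- config$n_feat
  s <- config$separation
  leaves <- generate_label_tree(config)
  withr::with_seed(config$seed, {
    # hierarchy directions: one per node at levels 1..3; level-4 directions
    # are shared across branches per digit value, scaled by parent_dep
    node_dirs <- new.env(parent = emptyenv())
    dir_of <- function(key) {
      if (!exists(key, envir = node_dirs, inherits = FALSE)) {
        assign(key, rand_dir(N), envir = node_dirs)
      }
      get(key, envir = node_dirs, inherits = FALSE)
    }
    digit4_dirs <- lapply(seq_len(config$branching[4]), function(d) rand_dir(N))
    mix <- qr.Q(qr(matrix(stats::rnorm(N * N), N)))  # fixed transform seq -> 3Di
    # the serial (4th) digit of an EC number has no branch-independent
    # meaning: its signal direction is shared per digit value but its sign is
    # branch-contextual (flips per level-3 node), so decoding it benefits
    # from knowing the coarser levels — the property that makes the
    # autoregressive head informative
    branch_sign <- function(leaf) {
      key <- paste0("sgn", ec_prefix(leaf, 3))
      if (!exists(key, envir = node_dirs, inherits = FALSE)) {
        assign(key, sample(c(-1, 1), 1L), envir = node_dirs)
      }
      get(key, envir = node_dirs, inherits = FALSE)
    }
    proto <- function(leaf) {
      dg <- unclass(parse_ec(leaf))
      # residue-wide background carries the level 1-3 hierarchy only
      base <- s * (dir_of(ec_prefix(leaf, 1)) + dir_of(ec_prefix(leaf, 2)) +
                     dir_of(ec_prefix(leaf, 3)))
      fresh_bg <- s * dir_of(paste0("t", ec_prefix(leaf, 3)))
      tdi_bg <- config$rho * drop(base %*% mix) + sqrt(1 - config$rho^2) * fresh_bg
      # the level-4 (serial-digit) increment is realized at the functional
      # site only, mostly in the structural channel (a tenth of the weight in
      # the sequence channel), with a branch-contextual sign
      sgn <- branch_sign(leaf)
      seq_inc <- 0.1 * s * sgn * config$parent_dep * digit4_dirs[[dg[4]]]
      tdi_inc <- config$rho * drop(seq_inc %*% mix) +
        sqrt(1 - config$rho^2) * s * sgn * config$parent_dep *
          dir_of(paste0("t4_", dg[4]))
      list(seq = base, tdi = tdi_bg, seq_inc = seq_inc, tdi_inc = tdi_inc)
    }
    protos <- lapply(leaves, proto)
    names(protos) <- leaves
    # functional-site motifs are conserved at the family (sub-subclass)
    # level: one motif direction pair per level-3 node, shared by its leaves
    fam_keys <- unique(vapply(leaves, ec_prefix, character(1), k = 3))
    fam_motifs <- lapply(fam_keys, function(k) {
      list(seq = rand_dir(N) * sqrt(N), tdi = rand_dir(N) * sqrt(N))
    })
    names(fam_motifs) <- fam_keys
    motif_dirs <- lapply(leaves, function(l) fam_motifs[[ec_prefix(l, 3)]])
    names(motif_dirs) <- leaves

    n_prot <- length(leaves) * config$proteins_per_leaf
    ids <- sprintf("synthP%04d", seq_len(n_prot))
    proteins <- vector("list", n_prot)
    motif_rows <- vector("list", n_prot)
    label_rows <- vector("list", n_prot)
    i <- 0L
    for (leaf in leaves) {
      siblings <- setdiff(leaves[vapply(leaves, ec_prefix, character(1), k = 3) ==
                                   ec_prefix(leaf, 3)], leaf)
      for (r in seq_len(config$proteins_per_leaf)) {
        i <- i + 1L
        id <- ids[i]
        labels <- leaf
        if (length(siblings) > 0L && stats::runif(1) < config$multi_label_prob) {
          sib <- if (length(siblings) == 1L) siblings else sample(siblings, 1L)
          labels <- c(leaf, sib)
        }
        avg <- function(field) {
          Reduce(`+`, lapply(labels, function(l) protos[[l]][[field]])) / length(labels)
        }
        p_seq <- avg("seq"); p_tdi <- avg("tdi")
        inc_seq <- avg("seq_inc"); inc_tdi <- avg("tdi_inc")
        L <- config$length_range[1] +
          sample.int(config$length_range[2] - config$length_range[1] + 1L, 1L) - 1L
        emb_seq <- matrix(rep(p_seq, each = L), L, N) +
          matrix(stats::rnorm(L * N, 0, config$noise), L, N)
        emb_tdi <- matrix(rep(p_tdi, each = L), L, N) +
          matrix(stats::rnorm(L * N, 0, config$noise), L, N)
        m_start <- sample.int(L - config$motif_length + 1L, 1L)
        m_rows <- m_start:(m_start + config$motif_length - 1L)
        boost <- config$motif_strength * s
        add_seq <- boost * motif_dirs[[leaf]]$seq + inc_seq
        add_tdi <- boost * motif_dirs[[leaf]]$tdi + inc_tdi
        emb_seq[m_rows, ] <- emb_seq[m_rows, ] +
          matrix(rep(add_seq, each = length(m_rows)), length(m_rows), N)
        emb_tdi[m_rows, ] <- emb_tdi[m_rows, ] +
          matrix(rep(add_tdi, each = length(m_rows)), length(m_rows), N)
        tdi_str <- paste(TDI_ALPHABET[(max.col(emb_tdi[, seq_len(min(20L, N)),
                                                       drop = FALSE],
                                               ties.method = "first") - 1L) %% 20L + 1L],
                         collapse = "")
        aa_str <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
        proteins[[i]] <- list(id = id, sequence = aa_str, tdi_sequence = tdi_str,
                              seq = emb_seq, tdi = emb_tdi, ec = sort(labels))
        motif_rows[[i]] <- tibble::tibble(protein_id = id, start = m_start,
                                          end = m_start + config$motif_length - 1L)
        label_rows[[i]] <- tibble::tibble(protein_id = id, ec = sort(labels))
      }
    }
    names(proteins) <- ids
    dataset <- new_ec_dataset(proteins, dplyr::bind_rows(label_rows))
    structure(list(dataset = dataset, motifs = dplyr::bind_rows(motif_rows),
                   config = config),
              class = "ec_synth_dataset")
  })
}

#' @export
print.ec_synth_dataset <- function(x, ...) {
  cat(sprintf("<ec_synth_dataset> %d proteins over %d leaves (branching %s)\n",
              length(x$dataset$proteins), prod(x$config$branching),
              paste(x$config$branching, collapse = "x")))
  invisible(x)
}

#' Generate a reference/corrupted 3Di string pair
#'
#' The reference is uniform over the 20-letter 3Di alphabet; the corrupted
#' copy substitutes each position independently with probability
#' `error_rate`, drawing uniformly from the 19 other letters (a substitution
#' never preserves the letter, so rate 1 gives recovery 0).
#'
#' @param length String length (at least 1).
#' @param error_rate Per-position substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `reference` and `corrupted` strings.
#' @export
generate_3di_pair <- function(length, error_rate, seed = 1L) {
  stopifnot(length >= 1L)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    ref <- sample(TDI_ALPHABET, length, replace = TRUE)
    flip <- stats::runif(length) < error_rate
    corr <- ref
    if (any(flip)) {
      corr[flip] <- vapply(ref[flip], function(ch) {
        sample(setdiff(TDI_ALPHABET, ch), 1L)
      }, character(1))
    }
    list(reference = paste(ref, collapse = ""),
         corrupted = paste(corr, collapse = ""))
  })
}

#' Write a synthetic dataset to the pipeline's file formats
#'
#' Emits the amino-acid FASTA, 3Di FASTA, embedding container, label TSV and
#' ground-truth motif TSV into a directory, plus a manifest of file checksums.
#'
#' @param synth An `ec_synth_dataset` from [generate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_synth_dataset <- function(synth, out_dir) {
  stopifnot(inherits(synth, "ec_synth_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- synth$dataset
  paths <- c(fasta = file.path(out_dir, "sequences.fasta"),
             tdi_fasta = file.path(out_dir, "tdi.fasta"),
             embeddings = file.path(out_dir, "embeddings.rds"),
             labels = file.path(out_dir, "labels.tsv"),
             motifs = file.path(out_dir, "motifs.tsv"))
  write_fasta(vapply(ds$proteins, `[[`, character(1), "sequence"), paths["fasta"])
  write_fasta(vapply(ds$proteins, `[[`, character(1), "tdi_sequence"), paths["tdi_fasta"])
  write_embeddings(lapply(ds$proteins, function(p) list(seq = p$seq, tdi = p$tdi)),
                   paths["embeddings"])
  write_ec_labels(ds$labels, paths["labels"])
  readr::write_tsv(synth$motifs, paths["motifs"], progress = FALSE)
  manifest <- tibble::tibble(file = basename(paths),
                             md5 = vapply(paths, function(p) {
                               unname(tools::md5sum(p))
                             }, character(1)))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  invisible(paths)
}
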