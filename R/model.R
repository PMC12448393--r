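#' Model configuration
#'
#' Architecture hyperparameters of the dual-pathway feature extractor and the
#' prediction head, plus the ablation switches.
#'
#' @param n_feat Feature width N of the per-residue embeddings (both
#'   modalities must be delivered at this width).
#' @param n_heads Attention heads h; per-head projection width is `N/h`.
#' @param n_blocks Number of stacked GFE blocks and of LFE blocks (default 3).
#' @param kernel_sizes Odd kernel sizes of the three parallel convolution
#'   branches in each LFE block (default 7, 9, 11).
#' @param use_gfe Enable the global cross-attention pathway; when `FALSE` the
#'   raw streams pass through unchanged (the "-G" ablation).
#' @param use_lfe Enable the local convolution pathway; when `FALSE` the fused
#'   features are the global sequence stream alone (the "-L" ablation).
#' @param autoregressive Feed each level's previous-level prediction into the
#'   next prediction MLP; when `FALSE` the four MLPs are independent (the
#'   "-H" ablation).
#' @param zero_seq,zero_tdi Zero out one input modality (the "3Di-only" and
#'   "seq-only" ablations respectively).
#' @param paper_subscripts Use the literal query/key subscript order of the
#'   multi-head attention definition instead of the prose reading (see
#'   [gfe_block()]).
#' @param threshold Decoding threshold tau for [decode_predictions()].
#' @return A `model_config` list.
#' @export
model_config <- function(n_feat = 16L, n_heads = 2L, n_blocks = 3L,
                         kernel_sizes = c(7L, 9L, 11L),
                         use_gfe = TRUE, use_lfe = TRUE, autoregressive = TRUE,
                         zero_seq = FALSE, zero_tdi = FALSE,
                         paper_subscripts = FALSE, threshold = 0.5) {
  if (n_feat %% n_heads != 0L) {
    stop("feature width n_feat must be divisible by n_heads", call. = FALSE)
  }
  if (any(kernel_sizes %% 2L != 1L)) stop("kernel sizes must be odd", call. = FALSE)
  if (zero_seq && zero_tdi) stop("cannot zero out both modalities", call. = FALSE)
  structure(list(n_feat = as.integer(n_feat), n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks),
                 kernel_sizes = as.integer(kernel_sizes),
                 use_gfe = isTRUE(use_gfe), use_lfe = isTRUE(use_lfe),
                 autoregressive = isTRUE(autoregressive),
                 zero_seq = isTRUE(zero_seq), zero_tdi = isTRUE(zero_tdi),
                 paper_subscripts = isTRUE(paper_subscripts),
                 threshold = threshold),
            class = "model_config")
}

#' Pooled feature width of a configuration
#'
#' 2N when the local pathway is on (global sequence stream side-by-side with
#' the local output), N otherwise.
#'
#' @param config A `model_config`.
#' @return Integer width of the pooled protein vector.
#' @export
fused_width <- function(config) {
  if (config$use_lfe) 2L * config$n_feat else config$n_feat
}

# variance-scaled uniform init (zero-mean, Glorot-style bounds)
init_mat <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_attention_layer <- function(N) {
  list(Wq = init_mat(N, N), Wk = init_mat(N, N), Wv = init_mat(N, N),
       Wo = init_mat(N, N), ln_g = rep(1, N), ln_b = rep(0, N))
}

init_conv_branch <- function(k, c_in, c_out) {
  lim <- sqrt(6 / (k * c_in + c_out))
  list(W = array(stats::runif(k * c_in * c_out, -lim, lim), c(k, c_in, c_out)),
       b = rep(0, c_out))
}

init_lfe_block <- function(config) {
  N <- config$n_feat
  list(conv = lapply(config$kernel_sizes, init_conv_branch, c_in = 2L * N, c_out = N),
       mlp = list(W1 = init_mat(3L * N, 3L * N), b1 = rep(0, 3L * N),
                  W2 = init_mat(3L * N, N), b2 = rep(0, N)))
}

init_mlp <- function(n_in, n_out) {
  list(W1 = init_mat(n_in, n_in), b1 = rep(0, n_in),
       W2 = init_mat(n_in, n_out), b2 = rep(0, n_out))
}

#' Initialize model parameters
#'
#' Projection and convolution weights use variance-scaled uniform
#' initialization; biases start at zero, layer-norm gains at one. Seeded and
#' reproducible.
#'
#' @param config A [model_config()].
#' @param spaces An `ec_label_spaces`; fixes the output widths of the four
#'   prediction MLPs.
#' @param seed Integer seed.
#' @return A parameter tree with components `extractor` (`gfe` blocks with
#'   `layer1`/`layer2`, `lfe` blocks with `conv`/`mlp`) and `head`
#'   (`mlp1`..`mlp4`).
#' @export
init_model_params <- function(config, spaces, seed = 1L) {
  stopifnot(inherits(config, "model_config"), inherits(spaces, "ec_label_spaces"))
  withr::with_seed(as.integer(seed), {
    N <- config$n_feat
    extractor <- list(
      gfe = lapply(seq_len(config$n_blocks), function(i) {
        list(layer1 = init_attention_layer(N), layer2 = init_attention_layer(N))
      }),
      lfe = lapply(seq_len(config$n_blocks), function(i) init_lfe_block(config))
    )
    sizes <- label_space_sizes(spaces)
    D <- fused_width(config)
    head <- lapply(1:4, function(j) {
      n_in <- if (j == 1L || !config$autoregressive) D else D + sizes[j - 1L]
      init_mlp(n_in, sizes[j])
    })
    names(head) <- paste0("mlp", 1:4)
    list(extractor = extractor, head = head)
  })
}

# prepare the two input streams under the ablation switches
input_streams <- function(pair, config) {
  s <- pair$seq; t <- pair$tdi
  if (config$zero_seq) s <- matrix(0, nrow(s), ncol(s))
  if (config$zero_tdi) t <- matrix(0, nrow(t), ncol(t))
  list(seq = s, tdi = t)
}

# Full extractor forward with caches for backprop.
#
# Global pathway: n_blocks GFE blocks chained on the (seq, tdi) stream pair.
# Local pathway: block 1 consumes the raw stacked pair; block i > 1 stacks
# the global sequence output of block i-1 with the local output of block i-1.
# Fusion concatenates the final global sequence stream with the final local
# output (per residue), then mean-pools over residues.
extractor_forward <- function(pair, params, config) {
  st <- input_streams(pair, config)
  nb <- config$n_blocks
  s <- st$seq; t <- st$tdi
  gfe_caches <- vector("list", nb)
  seq_hats <- vector("list", nb)
  if (config$use_gfe) {
    for (i in seq_len(nb)) {
      f <- gfe_forward(s, t, params$extractor$gfe[[i]], config$n_heads,
                       config$paper_subscripts)
      s <- f$seq; t <- f$tdi
      gfe_caches[[i]] <- f$cache
      seq_hats[[i]] <- s
    }
  } else {
    for (i in seq_len(nb)) seq_hats[[i]] <- s
  }
  lfe_caches <- vector("list", nb)
  locals <- vector("list", nb)
  if (config$use_lfe) {
    X <- cbind(st$seq, st$tdi)
    for (i in seq_len(nb)) {
      f <- lfe_forward(X, params$extractor$lfe[[i]])
      lfe_caches[[i]] <- f$cache
      locals[[i]] <- f$out
      if (i < nb) X <- cbind(seq_hats[[i]], f$out)
    }
    fused <- cbind(seq_hats[[nb]], locals[[nb]])
  } else {
    fused <- seq_hats[[nb]]
  }
  pooled <- colMeans(fused)
  list(fused = fused, pooled = pooled,
       cache = list(streams = st, gfe = gfe_caches, lfe = lfe_caches,
                    seq_hats = seq_hats, locals = locals, L = nrow(st$seq)))
}

# Backward from d_pooled (gradient wrt the pooled vector) to extractor
# parameter gradients. Returns a gradient tree mirroring params$extractor.
extractor_backward <- function(d_pooled, params, config, cache) {
  nb <- config$n_blocks
  N <- config$n_feat
  L <- cache$L
  d_fused <- matrix(rep(d_pooled / L, each = L), L, length(d_pooled))
  if (config$use_lfe) {
    d_seq_hat_final <- d_fused[, seq_len(N), drop = FALSE]
    d_local <- d_fused[, N + seq_len(N), drop = FALSE]
  } else {
    d_seq_hat_final <- d_fused
    d_local <- NULL
  }
  # gradient wrt each block's global sequence output, accumulated from the
  # fusion (block nb) and from the LFE chaining inputs (blocks 1..nb-1)
  d_seq_hat <- lapply(seq_len(nb), function(i) matrix(0, L, N))
  d_seq_hat[[nb]] <- d_seq_hat_final
  lfe_grads <- vector("list", nb)
  d_raw_seq <- matrix(0, L, N)
  d_raw_tdi <- matrix(0, L, N)
  if (config$use_lfe) {
    for (i in rev(seq_len(nb))) {
      b <- lfe_backward(d_local, params$extractor$lfe[[i]], cache$lfe[[i]])
      lfe_grads[[i]] <- b$grads
      left <- b$dX[, seq_len(N), drop = FALSE]
      right <- b$dX[, N + seq_len(N), drop = FALSE]
      if (i == 1L) {
        d_raw_seq <- d_raw_seq + left
        d_raw_tdi <- d_raw_tdi + right
        d_local <- NULL
      } else {
        d_seq_hat[[i - 1L]] <- d_seq_hat[[i - 1L]] + left
        d_local <- right
      }
    }
  }
  gfe_grads <- vector("list", nb)
  if (config$use_gfe) {
    ds <- d_seq_hat[[nb]]
    dt <- matrix(0, L, N)
    for (i in rev(seq_len(nb))) {
      b <- gfe_backward(ds, dt, params$extractor$gfe[[i]], cache$gfe[[i]],
                        config$paper_subscripts)
      gfe_grads[[i]] <- b$grads
      ds <- b$d_seq
      dt <- b$d_tdi
      if (i > 1L) ds <- ds + d_seq_hat[[i - 1L]]
    }
    d_raw_seq <- d_raw_seq + ds
    d_raw_tdi <- d_raw_tdi + dt
  } else {
    for (i in seq_len(nb)) d_raw_seq <- d_raw_seq + d_seq_hat[[i]]
    # without attention nothing else reaches the raw tdi stream
    gfe_grads <- zero_like(params$extractor$gfe)
  }
  list(grads = list(gfe = gfe_grads, lfe = if (config$use_lfe) lfe_grads
                    else zero_like(params$extractor$lfe)),
       d_seq = d_raw_seq, d_tdi = d_raw_tdi)
}

#' Run the feature extractor on one protein
#'
#' Executes the global cross-attention pathway (3 stacked GFE blocks) and the
#' local multi-kernel convolution pathway (3 LFE blocks, chained so that each
#' later block sees the previous global sequence output stacked with the
#' previous local output), and fuses the final global sequence stream with the
#' final local output per residue.
#'
#' @param pair A list with `seq` and `tdi` matrices (`L x N`), e.g. one
#'   element of [read_embeddings()] or of an `ec_dataset`.
#' @param params Parameter tree from [init_model_params()].
#' @param config The matching [model_config()].
#' @return List with `fused` (`L x 2N`, or `L x N` without the local pathway)
#'   and `pooled` (unweighted mean over residues, the fixed-size protein
#'   vector used by the prediction head and the triplet loss).
#' @export
extract_features <- function(pair, params, config) {
  validate_embedding_pair(pair, if (!is.null(pair$id)) pair$id else "?")
  if (ncol(pair$seq) != config$n_feat) {
    stop(sprintf("embedding width %d does not match configured n_feat %d",
                 ncol(pair$seq), config$n_feat), call. = FALSE)
  }
  f <- extractor_forward(pair, params, config)
  list(fused = f$fused, pooled = f$pooled)
}

#' Per-residue attention importance scores
#'
#' Extracts the attention weights of the final GFE block's second layer (the
#' layer that refreshes the sequence stream by attending over the updated 3Di
#' stream), averages them over heads and query positions, and min-max
#' normalizes over residues to `[0, 1]`. Residues the model attends to most
#' score 1. When all residues receive identical attention (including the
#' degenerate L = 1 case) the normalization is undefined and all scores are 0.
#'
#' @param pair A `seq`/`tdi` embedding pair.
#' @param params,config Model parameters and configuration (requires
#'   `use_gfe = TRUE`).
#' @return Numeric vector of length L with values in `[0, 1]`.
#' @export
attention_importance <- function(pair, params, config) {
  if (!config$use_gfe) {
    stop("attention importance requires the global pathway (use_gfe = TRUE)",
         call. = FALSE)
  }
  f <- extractor_forward(pair, params, config)
  cache2 <- f$cache$gfe[[config$n_blocks]]$l2
  A <- Reduce(`+`, cache2$A) / length(cache2$A)   # mean over heads
  col_score <- colMeans(A)                        # mean over query positions
  rng <- range(col_score)
  if (rng[2] - rng[1] < 1e-12) return(rep(0, length(col_score)))
  (col_score - rng[1]) / (rng[2] - rng[1])
}

#' Export attention importance for a dataset as a tibble
#'
#' @param dataset An `ec_dataset`.
#' @param params,config Model parameters and configuration.
#' @return Tibble with columns `protein_id`, `residue_index` (1-based),
#'   `amino_acid`, `score`.
#' @export
importance_table <- function(dataset, params, config) {
  purrr::map_dfr(dataset$proteins, function(p) {
    sc <- attention_importance(p, params, config)
    tibble::tibble(protein_id = p$id,
                   residue_index = seq_along(sc),
                   amino_acid = strsplit(p$sequence, "")[[1]],
                   score = sc)
  })
}

# --- parameter-tree utilities ----------------------------------------------

# recursive map over two parameter trees with identical shape
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else {
    f(a)
  }
}

zero_like <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map2(`+`, a, b)

# flatten all leaves into one numeric vector (for freeze-contract checks)
tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE) else as.numeric(a)
}

#' Save a model checkpoint
#'
#' Single-file checkpoint bundling the parameter tree, its configuration, the
#' label spaces and a format version, so prediction needs no side files.
#'
#' @param params Parameter tree.
#' @param config A `model_config`.
#' @param spaces An `ec_label_spaces`.
#' @param path Output path.
#' @param extra Optional named list stored alongside (e.g. loss traces).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, config, spaces, path, extra = list()) {
  obj <- list(format = "ecfusion-checkpoint", version = 1L,
              params = params, config = config, spaces = spaces, extra = extra)
  saveRDS(obj, path, version = 2L)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return List with `params`, `config`, `spaces`, `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "ecfusion-checkpoint")) {
    stop("not an ecfusion checkpoint: ", path, call. = FALSE)
  }
  obj
}
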