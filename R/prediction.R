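# Autoregressive four-level EC prediction head.
#
# Four two-layer MLPs with sigmoid outputs, one per EC level. MLP 1 sees the
# pooled fused features; MLP j > 1 additionally sees the previous level's
# prediction vector (ground-truth multi-hot under teacher forcing during
# training, the predicted probabilities at inference). The previous level is
# fed as a full vector, not a single decoded digit, so multi-EC enzymes can
# carry several active parents forward.

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward through one head MLP for a batch X (n x d_in); returns probabilities
# and cache
mlp_forward <- function(X, p) {
  H_pre <- sweep(X %*% p$W1, 2L, p$b1, `+`)
  H <- relu(H_pre)
  Z <- sweep(H %*% p$W2, 2L, p$b2, `+`)
  Y <- sigmoid(Z)
  list(out = Y, cache = list(X = X, H_pre = H_pre, H = H, Y = Y))
}

# backward given dZ (gradient wrt the pre-sigmoid logits)
mlp_backward_logits <- function(dZ, p, cache) {
  dW2 <- t(cache$H) %*% dZ
  db2 <- colSums(dZ)
  dH <- dZ %*% t(p$W2)
  dH_pre <- dH * (cache$H_pre > 0)
  dW1 <- t(cache$X) %*% dH_pre
  db1 <- colSums(dH_pre)
  dX <- dH_pre %*% t(p$W1)
  list(dX = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Batched head forward. pooled: n x D matrix. prev_override: optional list of
# four n x |V_k| matrices (teacher forcing uses the target encodings for
# levels 1..3; entry j is what MLP j+1 consumes). Returns per-level
# probability matrices.
head_forward <- function(pooled, head, config, prev_override = NULL) {
  probs <- vector("list", 4L)
  caches <- vector("list", 4L)
  for (j in 1:4) {
    X <- if (j == 1L || !config$autoregressive) {
      pooled
    } else {
      prev <- if (!is.null(prev_override)) prev_override[[j - 1L]] else NULL
      if (is.null(prev)) prev <- probs[[j - 1L]]
      cbind(prev, pooled)
    }
    f <- mlp_forward(X, head[[j]])
    probs[[j]] <- f$out
    caches[[j]] <- f$cache
  }
  list(probs = probs, caches = caches)
}

#' Autoregressive EC-level prediction from pooled features
#'
#' Computes the four per-level probability vectors: level 1 from the pooled
#' fused features alone, each later level from the features plus the previous
#' level's prediction vector (or `prev_override`, e.g. ground-truth multi-hot
#' encodings under teacher forcing). All outputs are sigmoid probabilities
#' over the corresponding level vocabulary.
#'
#' @param pooled Pooled feature vector (length [fused_width()]) or an
#'   `n x D` matrix for a batch.
#' @param params Full parameter tree (uses `params$head`) or the head list
#'   itself.
#' @param spaces An `ec_label_spaces` (checked against the MLP widths).
#' @param config A [model_config()].
#' @param prev_override Optional list of three vectors/matrices replacing the
#'   autoregressive inputs of levels 2-4.
#' @return An `ec_prediction`: list of four probability vectors (or matrices
#'   for batched input) named `level1`..`level4`.
#' @export
autoregressive_forward <- function(pooled, params, spaces, config,
                                   prev_override = NULL) {
  head <- if (!is.null(params$head)) params$head else params
  if (is.null(dim(pooled))) pooled <- matrix(pooled, 1L)
  single <- nrow(pooled) == 1L
  if (ncol(pooled) != nrow(head[[1]]$W1)) {
    stop(sprintf("pooled width %d does not match head input width %d",
                 ncol(pooled), nrow(head[[1]]$W1)), call. = FALSE)
  }
  sizes <- label_space_sizes(spaces)
  for (j in 1:4) {
    if (ncol(head[[j]]$W2) != sizes[j]) {
      stop(sprintf("head MLP %d emits %d labels but level %d vocabulary has %d",
                   j, ncol(head[[j]]$W2), j, sizes[j]), call. = FALSE)
    }
  }
  if (!is.null(prev_override)) {
    prev_override <- lapply(prev_override, function(v) {
      if (is.null(v) || !is.null(dim(v))) v else matrix(v, 1L)
    })
  }
  f <- head_forward(pooled, head, config, prev_override)
  probs <- f$probs
  if (single) probs <- lapply(probs, function(m) m[1L, ])
  names(probs) <- paste0("level", 1:4)
  structure(probs, class = "ec_prediction")
}

#' Decode an EC set from per-level probabilities
#'
#' Candidate set: every level-4 label whose probability and whose whole
#' ancestor chain's probabilities are at least `threshold`; the confidence of
#' a decoded EC is the minimum over its chain. When no candidate survives, a
#' single greedy EC is emitted by walking the label tree root to leaf,
#' choosing the highest-probability child at each level, so every protein
#' receives at least one prediction. Raising the threshold never adds
#' predictions (before the fallback).
#'
#' @param prediction An `ec_prediction` (four per-level probability vectors).
#' @param spaces The `ec_label_spaces` the head was trained against.
#' @param threshold Decoding threshold tau in (0, 1), default 0.5.
#' @return Tibble with columns `ec`, `confidence`, `fallback`.
#' @export
decode_predictions <- function(prediction, spaces, threshold = 0.5) {
  stopifnot(inherits(spaces, "ec_label_spaces"))
  probs <- lapply(1:4, function(k) prediction[[k]])
  sizes <- label_space_sizes(spaces)
  stopifnot(all(vapply(probs, length, integer(1)) == sizes))
  # confidence of each level-4 label's full ancestor chain
  chain_min <- probs[[4]]
  ok <- probs[[4]] >= threshold
  idx <- seq_len(sizes[4])
  up <- idx
  for (k in 4:2) {
    up <- if (k == 4L) spaces$parent[[4]] else spaces$parent[[k]][up]
    chain_min <- pmin(chain_min, probs[[k - 1L]][up])
    ok <- ok & probs[[k - 1L]][up] >= threshold
  }
  if (any(ok)) {
    return(tibble::tibble(ec = spaces$levels[[4]][ok],
                          confidence = chain_min[ok],
                          fallback = FALSE))
  }
  # greedy root-to-leaf walk restricted to the child-of map
  best <- which.max(probs[[1]])
  conf <- probs[[1]][best]
  for (k in 2:4) {
    children <- which(spaces$parent[[k]] == best)
    best <- children[which.max(probs[[k]][children])]
    conf <- min(conf, probs[[k]][best])
  }
  tibble::tibble(ec = spaces$levels[[4]][best], confidence = conf, fallback = TRUE)
}

#' Predict EC numbers for every protein of a dataset
#'
#' Runs the feature extractor, the autoregressive head and the decoder for
#' each protein.
#'
#' @param dataset An `ec_dataset`.
#' @param fit A fitted model ([train_model()] result or a loaded checkpoint
#'   with `params`, `config`, `spaces`).
#' @param threshold Decoding threshold; defaults to the configuration's.
#' @return Tibble with columns `protein_id`, `ec`, `confidence`, `fallback`.
#' @export
predict_dataset <- function(dataset, fit, threshold = NULL) {
  stopifnot(inherits(dataset, "ec_dataset"))
  if (is.null(threshold)) threshold <- fit$config$threshold
  purrr::map_dfr(dataset$proteins, function(p) {
    feats <- extract_features(p, fit$params, fit$config)
    pred <- autoregressive_forward(feats$pooled, fit$params, fit$spaces, fit$config)
    dec <- decode_predictions(pred, fit$spaces, threshold)
    dplyr::mutate(dec, protein_id = p$id, .before = 1L)
  })
}
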