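# Two-phase training: a contrastive (triplet-loss) phase for the feature
# extractor, then a binary-cross-entropy phase for the prediction head on
# frozen, cached features.

#' Training configuration
#'
#' The default profile mirrors the published training recipe: phase 1 trains
#' the feature extractor with batches of 40 triplets for 1000 epochs at a
#' constant learning rate of 5e-4; phase 2 freezes the extractor and trains
#' the head with batch size 50 000 for 150 epochs at 1e-3 under cosine
#' annealing; Adam moments are 0.9/0.999. Tests and examples use much smaller
#' profiles (see `inst/config/test.yaml`).
#'
#' @param lambda1,lambda2 Loss weights of the triplet and BCE terms in the
#'   combined loss. Phase 1 runs with `lambda2 = 0`; phase 2 with
#'   `lambda1 = 0, lambda2 = 1`.
#' @param margin Triplet margin (Euclidean distance units on pooled
#'   features).
#' @param phase1_epochs,phase1_batch,phase1_lr Phase-1 schedule (constant
#'   learning rate).
#' @param phase2_epochs,phase2_batch,phase2_lr Phase-2 schedule
#'   (cosine-annealed learning rate).
#' @param beta1,beta2 Adam moment decay parameters.
#' @param triplets_per_epoch Number of triplets mined per phase-1 epoch;
#'   default one per training protein.
#' @param seed Integer seed controlling initialization, mining and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lambda1 = 1, lambda2 = 1, margin = 1,
                         phase1_epochs = 1000L, phase1_batch = 40L, phase1_lr = 5e-4,
                         phase2_epochs = 150L, phase2_batch = 50000L, phase2_lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999,
                         triplets_per_epoch = NULL, seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, margin > 0,
            phase1_epochs > 0, phase2_epochs > 0, phase1_lr > 0, phase2_lr > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, margin = margin,
                 phase1_epochs = as.integer(phase1_epochs),
                 phase1_batch = as.integer(phase1_batch),
                 phase1_lr = phase1_lr,
                 phase2_epochs = as.integer(phase2_epochs),
                 phase2_batch = as.integer(phase2_batch),
                 phase2_lr = phase2_lr,
                 beta1 = beta1, beta2 = beta2,
                 triplets_per_epoch = triplets_per_epoch,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Triplet loss
#'
#' `sum_i max(0, d(a_i, p_i) - d(a_i, n_i) + margin)` with Euclidean distance
#' on pooled feature vectors: anchors are pulled toward their positives (same
#' EC) and pushed at least `margin` away from their negatives (no shared EC).
#'
#' @param anchors,positives,negatives Matrices with one pooled feature vector
#'   per row (equal row counts and widths).
#' @param margin Positive margin.
#' @return Nonnegative scalar (sum over triplets).
#' @export
triplet_loss <- function(anchors, positives, negatives, margin = 1) {
  if (is.null(dim(anchors))) anchors <- matrix(anchors, 1L)
  if (is.null(dim(positives))) positives <- matrix(positives, 1L)
  if (is.null(dim(negatives))) negatives <- matrix(negatives, 1L)
  stopifnot(all(dim(anchors) == dim(positives)), all(dim(anchors) == dim(negatives)),
            margin > 0)
  d_ap <- sqrt(rowSums((anchors - positives)^2))
  d_an <- sqrt(rowSums((anchors - negatives)^2))
  sum(pmax(0, d_ap - d_an + margin))
}

# loss + gradients wrt the three row sets
triplet_loss_grad <- function(anchors, positives, negatives, margin) {
  eps <- 1e-12
  diff_ap <- anchors - positives
  diff_an <- anchors - negatives
  d_ap <- sqrt(rowSums(diff_ap^2))
  d_an <- sqrt(rowSums(diff_an^2))
  hinge <- d_ap - d_an + margin
  active <- hinge > 0
  loss <- sum(pmax(0, hinge))
  u_ap <- diff_ap / pmax(d_ap, eps)
  u_an <- diff_an / pmax(d_an, eps)
  act <- as.numeric(active)
  list(loss = loss,
       d_anchor = act * (u_ap - u_an),
       d_positive = act * (-u_ap),
       d_negative = act * u_an)
}

#' Mine triplet index triples from a dataset
#'
#' An anchor and its positive must share at least one full EC number (any
#' shared EC qualifies for multi-EC proteins); the negative must share none
#' with the anchor. Anchors whose every EC class has a single member are
#' skipped with a message. With probability `hard_frac` the negative is drawn
#' from the anchor's own sub-subclass (same level-3 prefix, disjoint EC set)
#' when such proteins exist — the hard negatives that teach the serial-digit
#' distinction — and otherwise uniformly over all valid negatives. Seeded and
#' reproducible.
#'
#' @param dataset An `ec_dataset` with at least two distinct EC classes.
#' @param count Number of triplets to mine.
#' @param seed Integer seed.
#' @param hard_frac Probability of attempting a same-family hard negative.
#' @param quiet Suppress the skip message.
#' @return Tibble with columns `anchor`, `positive`, `negative` (protein ids).
#' @export
sample_triplets <- function(dataset, count, seed = 1L, hard_frac = 0.5,
                            quiet = FALSE) {
  stopifnot(inherits(dataset, "ec_dataset"), count >= 1L)
  ids <- names(dataset$proteins)
  ec_sets <- lapply(dataset$proteins, `[[`, "ec")
  if (length(unique(unlist(ec_sets))) < 2L) {
    stop("triplet mining needs at least two distinct EC classes", call. = FALSE)
  }
  by_ec <- split(rep(ids, lengths(ec_sets)), unlist(ec_sets))
  # protein x EC and protein x family (level-3 prefix) incidence
  n <- length(ids)
  all_ecs <- names(by_ec)
  M <- matrix(0L, n, length(all_ecs), dimnames = list(ids, all_ecs))
  for (id in ids) M[id, ec_sets[[id]]] <- 1L
  fams <- vapply(all_ecs, ec_prefix, character(1), k = 3L)
  Fm <- t(rowsum(t(M), fams)) > 0L
  shares_ec <- tcrossprod(M) > 0L          # any shared full EC
  shares_fam <- tcrossprod(Fm * 1L) > 0L   # any shared sub-subclass
  has_positive <- vapply(ids, function(id) {
    any(vapply(ec_sets[[id]], function(e) length(by_ec[[e]]) > 1L, logical(1)))
  }, logical(1))
  if (!any(has_positive)) stop("no protein has a same-EC positive partner", call. = FALSE)
  if (any(!has_positive) && !quiet) {
    message(sprintf("sample_triplets: %d protein(s) in singleton classes skipped as anchors",
                    sum(!has_positive)))
  }
  anchors_pool <- ids[has_positive]
  withr::with_seed(as.integer(seed), {
    anchor <- sample(anchors_pool, count, replace = TRUE)
    positive <- character(count)
    negative <- character(count)
    want_hard <- stats::runif(count) < hard_frac
    for (i in seq_len(count)) {
      a <- anchor[i]
      shared_ecs <- ec_sets[[a]][vapply(ec_sets[[a]],
                                        function(e) length(by_ec[[e]]) > 1L, logical(1))]
      ec <- if (length(shared_ecs) == 1L) shared_ecs else sample(shared_ecs, 1L)
      pool <- setdiff(by_ec[[ec]], a)
      positive[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      neg_ok <- !shares_ec[a, ]
      if (!any(neg_ok)) {
        stop(sprintf("no valid negative exists for anchor '%s'", a), call. = FALSE)
      }
      if (want_hard[i] && any(neg_ok & shares_fam[a, ])) {
        neg_ok <- neg_ok & shares_fam[a, ]
      }
      neg_pool <- ids[neg_ok]
      negative[i] <- if (length(neg_pool) == 1L) neg_pool else sample(neg_pool, 1L)
    }
    tibble::tibble(anchor = anchor, positive = positive, negative = negative)
  })
}

#' Multi-level binary cross-entropy loss
#'
#' `sum_{j=1..4} sum_i -[y log p + (1-y) log(1-p)]` over every vocabulary
#' entry of every level (multi-label classification at each EC level), with
#' probabilities clamped to `[eps, 1-eps]`, `eps = 1e-7`.
#'
#' @param pred An `ec_prediction` (or plain list of four probability
#'   vectors/matrices).
#' @param target An `ec_target_encoding` (or list of four 0/1
#'   vectors/matrices of matching shape).
#' @return Nonnegative scalar, summed over levels, samples and entries.
#' @export
bce_multilevel_loss <- function(pred, target) {
  eps <- 1e-7
  total <- 0
  for (j in 1:4) {
    p <- pred[[j]]; y <- target[[j]]
    if (length(p) != length(y)) {
      stop(sprintf("level %d: prediction and target lengths differ", j), call. = FALSE)
    }
    p <- pmin(pmax(p, eps), 1 - eps)
    total <- total - sum(y * log(p) + (1 - y) * log(1 - p))
  }
  total
}

#' Combined two-phase loss
#'
#' `lambda1 * L_triplet + lambda2 * L_BCE`; phase 1 sets `lambda2 = 0`,
#' phase 2 sets `lambda1 = 0, lambda2 = 1`.
#'
#' @param l_triplet,l_bce The two loss terms.
#' @param lambda1,lambda2 Nonnegative weights.
#' @return Scalar.
#' @export
total_loss <- function(l_triplet, l_bce, lambda1, lambda2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  lambda1 * l_triplet + lambda2 * l_bce
}

# derive a bounded child seed from a base seed and stream/step labels
derive_seed <- function(seed, stream, step = 0L) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729 + step) %% 2147483647)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

cosine_lr <- function(base_lr, epoch, n_epochs) {
  base_lr * 0.5 * (1 + cos(pi * (epoch - 1L) / max(1L, n_epochs)))
}

# --- phase 1: contrastive training of the extractor ------------------------

#' Phase-1 training: contrastive learning of the feature extractor
#'
#' Mines seeded triplets each epoch, runs the extractor forward on every
#' protein of each batch, and updates only the extractor parameters by Adam
#' on the triplet loss over pooled features. Prediction-head parameters are
#' untouched (bit-identical before and after). Aborts with diagnostics if the
#' loss becomes non-finite.
#'
#' @param dataset Training `ec_dataset` (at least two EC classes).
#' @param params Parameter tree from [init_model_params()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Emit a per-epoch message.
#' @return List with updated `params` and `trace` (tibble: `epoch`, `phase`,
#'   `loss` — per-epoch mean triplet loss per triplet — and `lr`).
#' @export
train_phase1 <- function(dataset, params, model_cfg, train_cfg, verbose = FALSE) {
  stopifnot(inherits(dataset, "ec_dataset"), inherits(train_cfg, "train_config"))
  n_trip <- train_cfg$triplets_per_epoch
  if (is.null(n_trip)) n_trip <- length(dataset$proteins)
  state <- adam_init(params$extractor)
  trace <- vector("list", train_cfg$phase1_epochs)
  for (epoch in seq_len(train_cfg$phase1_epochs)) {
    triplets <- sample_triplets(dataset, n_trip,
                                seed = derive_seed(train_cfg$seed, 1L, epoch),
                                quiet = TRUE)
    n_batches <- ceiling(nrow(triplets) / train_cfg$phase1_batch)
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      rows <- ((b - 1L) * train_cfg$phase1_batch + 1L):min(b * train_cfg$phase1_batch,
                                                           nrow(triplets))
      batch <- triplets[rows, ]
      uids <- unique(c(batch$anchor, batch$positive, batch$negative))
      fw <- lapply(dataset$proteins[uids], extractor_forward,
                   params = params, config = model_cfg)
      pooled <- do.call(rbind, lapply(fw, `[[`, "pooled"))
      rownames(pooled) <- uids
      tg <- triplet_loss_grad(pooled[batch$anchor, , drop = FALSE],
                              pooled[batch$positive, , drop = FALSE],
                              pooled[batch$negative, , drop = FALSE],
                              train_cfg$margin)
      if (!is.finite(tg$loss)) {
        stop(sprintf("phase 1 diverged at epoch %d batch %d (non-finite loss)",
                     epoch, b), call. = FALSE)
      }
      epoch_loss <- epoch_loss + tg$loss
      # accumulate pooled-feature gradients per unique protein
      d_pooled <- matrix(0, length(uids), ncol(pooled),
                         dimnames = list(uids, NULL))
      for (i in seq_len(nrow(batch))) {
        d_pooled[batch$anchor[i], ] <- d_pooled[batch$anchor[i], ] + tg$d_anchor[i, ]
        d_pooled[batch$positive[i], ] <- d_pooled[batch$positive[i], ] + tg$d_positive[i, ]
        d_pooled[batch$negative[i], ] <- d_pooled[batch$negative[i], ] + tg$d_negative[i, ]
      }
      grads <- NULL
      for (id in uids) {
        if (all(d_pooled[id, ] == 0)) next
        bk <- extractor_backward(d_pooled[id, ], params, model_cfg, fw[[id]]$cache)
        grads <- if (is.null(grads)) bk$grads else tree_add(grads, bk$grads)
      }
      if (is.null(grads)) next   # every hinge inactive: no update
      st <- adam_step(params$extractor, grads, state,
                      train_cfg$phase1_lr, train_cfg$beta1, train_cfg$beta2)
      params$extractor <- st$params
      state <- st$state
    }
    trace[[epoch]] <- tibble::tibble(epoch = epoch, phase = 1L,
                                     loss = epoch_loss / nrow(triplets),
                                     lr = train_cfg$phase1_lr)
    if (verbose) message(sprintf("phase 1 epoch %d: mean triplet loss %.4f",
                                 epoch, epoch_loss / nrow(triplets)))
  }
  list(params = params, trace = dplyr::bind_rows(trace))
}

# --- phase 2: head training on frozen, cached features ---------------------

# cache pooled features for every protein (extractor frozen)
pool_dataset <- function(dataset, params, model_cfg) {
  pooled <- t(vapply(dataset$proteins,
                     function(p) extractor_forward(p, params, model_cfg)$pooled,
                     numeric(fused_width(model_cfg))))
  rownames(pooled) <- names(dataset$proteins)
  pooled
}

# stack per-level multi-hot targets into n x |V_k| matrices
target_matrices <- function(dataset) {
  encs <- lapply(dataset$proteins, function(p) encode_targets(p$ec, dataset$spaces))
  lapply(1:4, function(k) do.call(rbind, lapply(encs, `[[`, k)))
}

#' Phase-2 training: the autoregressive prediction head on frozen features
#'
#' Pools fused features once over the whole training set (the frozen-extractor
#' cache that makes very large batch sizes feasible), then trains the four
#' prediction MLPs by Adam on the summed multi-level BCE under teacher
#' forcing, with a cosine-annealed learning rate. Extractor parameters are
#' untouched.
#'
#' @inheritParams train_phase1
#' @param pooled Optional precomputed pooled-feature matrix (rows named by
#'   protein id); computed from `params`/`model_cfg` when omitted.
#' @return List with updated `params`, `trace` (per-epoch mean BCE per
#'   protein), and the `pooled` cache.
#' @export
train_phase2 <- function(dataset, params, model_cfg, train_cfg,
                         pooled = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "ec_dataset"), inherits(train_cfg, "train_config"))
  if (is.null(pooled)) pooled <- pool_dataset(dataset, params, model_cfg)
  targets <- target_matrices(dataset)
  n <- nrow(pooled)
  state <- adam_init(params$head)
  trace <- vector("list", train_cfg$phase2_epochs)
  for (epoch in seq_len(train_cfg$phase2_epochs)) {
    lr <- cosine_lr(train_cfg$phase2_lr, epoch, train_cfg$phase2_epochs)
    order_idx <- withr::with_seed(derive_seed(train_cfg$seed, 2L, epoch), sample.int(n))
    n_batches <- ceiling(n / train_cfg$phase2_batch)
    epoch_loss <- 0
    for (b in seq_len(n_batches)) {
      rows <- order_idx[((b - 1L) * train_cfg$phase2_batch + 1L):
                          min(b * train_cfg$phase2_batch, n)]
      X <- pooled[rows, , drop = FALSE]
      Y <- lapply(targets, function(m) m[rows, , drop = FALSE])
      fw <- head_forward(X, params$head, model_cfg, prev_override = Y[1:3])
      eps <- 1e-7
      loss <- 0
      grads <- vector("list", 4L)
      for (j in 1:4) {
        P <- pmin(pmax(fw$probs[[j]], eps), 1 - eps)
        loss <- loss - sum(Y[[j]] * log(P) + (1 - Y[[j]]) * log(1 - P))
        dZ <- fw$probs[[j]] - Y[[j]]   # sigmoid + BCE: d(loss)/d(logits)
        bk <- mlp_backward_logits(dZ, params$head[[j]], fw$caches[[j]])
        grads[[j]] <- bk$grads
      }
      names(grads) <- names(params$head)
      if (!is.finite(loss)) {
        stop(sprintf("phase 2 diverged at epoch %d (non-finite loss)", epoch),
             call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss
      st <- adam_step(params$head, grads, state, lr,
                      train_cfg$beta1, train_cfg$beta2)
      params$head <- st$params
      state <- st$state
    }
    trace[[epoch]] <- tibble::tibble(epoch = epoch, phase = 2L,
                                     loss = epoch_loss / n, lr = lr)
    if (verbose) message(sprintf("phase 2 epoch %d: mean BCE %.4f", epoch,
                                 epoch_loss / n))
  }
  list(params = params, trace = dplyr::bind_rows(trace), pooled = pooled)
}

#' Train the full model (both phases)
#'
#' Initializes parameters, runs the contrastive phase-1 on the extractor and
#' the BCE phase-2 on the head, and returns a fitted-model object usable with
#' [predict_dataset()], [tidy()] and [glance()].
#'
#' @param dataset Training `ec_dataset`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param skip_phase1 Train the head on a randomly initialized, frozen
#'   extractor (the "no-tripletloss" ablation).
#' @param verbose Per-epoch progress messages.
#' @return An `ecfusion_fit`: `params`, `config`, `spaces`, `trace`,
#'   `train_ec_freq`.
#' @export
train_model <- function(dataset, model_cfg = model_config(),
                        train_cfg = train_config(), skip_phase1 = FALSE,
                        verbose = FALSE) {
  params <- init_model_params(model_cfg, dataset$spaces, seed = train_cfg$seed)
  trace1 <- NULL
  if (!skip_phase1) {
    p1 <- train_phase1(dataset, params, model_cfg, train_cfg, verbose = verbose)
    params <- p1$params
    trace1 <- p1$trace
  }
  p2 <- train_phase2(dataset, params, model_cfg, train_cfg, verbose = verbose)
  structure(list(params = p2$params, config = model_cfg, spaces = dataset$spaces,
                 trace = dplyr::bind_rows(trace1, p2$trace),
                 train_ec_freq = dataset$ec_freq,
                 train_cfg = train_cfg),
            class = "ecfusion_fit")
}

#' @export
print.ecfusion_fit <- function(x, ...) {
  cat(sprintf("<ecfusion_fit> N=%d h=%d blocks=%d | label levels %s | %d training epochs\n",
              x$config$n_feat, x$config$n_heads, x$config$n_blocks,
              paste(label_space_sizes(x$spaces), collapse = "/"),
              nrow(x$trace)))
  invisible(x)
}
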