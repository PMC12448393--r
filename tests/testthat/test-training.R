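test_that("triplet loss reproduces closed-form hinge values and additivity", {
  # d(a,p)=0, d(a,n)=2, margin 1 -> hinge inactive
  a <- matrix(c(0, 0), 1); n <- matrix(c(2, 0), 1)
  expect_equal(triplet_loss(a, a, n, margin = 1), 0)
  # d(a,p)=1, d(a,n)=0.5, margin 0.2 -> max(0, 1 - 0.5 + 0.2) = 0.7
  p <- matrix(c(1, 0), 1); n2 <- matrix(c(0.5, 0), 1)
  expect_equal(triplet_loss(a, p, n2, margin = 0.2), 0.7, tolerance = 1e-9)
  # a batch of two such triplets sums
  expect_equal(triplet_loss(rbind(a, a), rbind(p, p), rbind(n2, n2), margin = 0.2),
               1.4, tolerance = 1e-9)
  expect_error(triplet_loss(a, p, matrix(0, 1, 3)), "dim")
})

test_that("triplet loss is nonnegative and zero exactly when margins are satisfied", {
  withr::local_seed(41)
  for (rep in 1:20) {
    A <- matrix(rnorm(12), 3); P <- matrix(rnorm(12), 3); Nn <- matrix(rnorm(12), 3)
    l <- triplet_loss(A, P, Nn, margin = 0.5)
    expect_gte(l, 0)
    d_ap <- sqrt(rowSums((A - P)^2)); d_an <- sqrt(rowSums((A - Nn)^2))
    expect_identical(l == 0, all(d_ap + 0.5 <= d_an))
  }
})

test_that("multi-level BCE matches closed forms and the scalar-loop oracle", {
  one <- function(p, y) {
    pr <- lapply(1:4, function(k) if (k == 1) p else numeric(0))
    tg <- lapply(1:4, function(k) if (k == 1) y else numeric(0))
    bce_multilevel_loss(pr, tg)
  }
  # perfect 0/1 predictions: loss at clamping order only
  expect_lt(one(c(1, 0), c(1, 0)), 1e-5)
  # single entry y=1, p=0.5 -> ln 2
  expect_equal(one(0.5, 1), log(2), tolerance = 1e-9)
  # two entries y=(1,0), p=(0.5,0.5) -> 2 ln 2
  expect_equal(one(c(0.5, 0.5), c(1, 0)), 2 * log(2), tolerance = 1e-9)
  withr::local_seed(43)
  for (rep in 1:20) {
    sizes <- sample(1:6, 4, replace = TRUE)
    pred <- lapply(sizes, function(m) runif(m))
    targ <- lapply(sizes, function(m) rbinom(m, 1, 0.4))
    expect_equal(bce_multilevel_loss(pred, targ), oracle_bce(pred, targ),
                 tolerance = 1e-8)
  }
  expect_error(bce_multilevel_loss(list(1:2, 1, 1, 1), list(1, 1, 1, 1)),
               "lengths differ")
})

test_that("the combined loss applies the phase weighting", {
  expect_equal(total_loss(3, 7, lambda1 = 1, lambda2 = 0), 3)   # phase 1
  expect_equal(total_loss(3, 7, lambda1 = 0, lambda2 = 1), 7)   # phase 2
  expect_equal(total_loss(3, 7, lambda1 = 0, lambda2 = 0), 0)
})

test_that("triplet mining respects the share/no-share contract and is reproducible", {
  ds <- tiny_dataset(n_per_class = 3L)
  tr <- sample_triplets(ds, 60L, seed = 9L, quiet = TRUE)
  ec_of <- function(id) ds$proteins[[id]]$ec
  for (i in seq_len(nrow(tr))) {
    expect_gt(length(intersect(ec_of(tr$anchor[i]), ec_of(tr$positive[i]))), 0L)
    expect_identical(length(intersect(ec_of(tr$anchor[i]), ec_of(tr$negative[i]))), 0L)
    expect_false(tr$anchor[i] == tr$positive[i])
  }
  expect_identical(sample_triplets(ds, 60L, seed = 9L, quiet = TRUE), tr)
  # singleton classes are skipped as anchors, with a log
  solo <- tiny_dataset(n_per_class = 1L)
  solo$proteins[["extra"]] <- solo$proteins[[1]]
  solo$proteins[["extra"]]$id <- "extra"
  solo$labels <- dplyr::bind_rows(solo$labels,
                                  tibble::tibble(protein_id = "extra", ec = "1.1.1.1"))
  expect_message(sample_triplets(solo, 5L, seed = 1L), "singleton classes skipped")
  # a one-class dataset has no valid triplets at all
  one_class <- tiny_dataset(n_per_class = 2L)
  keep <- names(one_class$proteins)[vapply(one_class$proteins,
                                           function(p) p$ec == "1.1.1.1", logical(1))]
  one_class <- ecfusion:::new_ec_dataset(
    one_class$proteins[keep],
    one_class$labels[one_class$labels$protein_id %in% keep, ])
  expect_error(sample_triplets(one_class, 3L, seed = 1L), "two distinct EC classes")
})

test_that("phase 1 trains only the extractor and phase 2 only the head (freeze contracts)", {
  ds <- tiny_dataset(n_per_class = 3L, L = 5L, N = 8L)
  cfg <- model_config(n_feat = 8L, n_heads = 2L)
  tc <- train_config(phase1_epochs = 2L, phase1_batch = 10L, phase2_epochs = 5L,
                     phase2_batch = 64L, triplets_per_epoch = 10L, seed = 3L)
  par <- init_model_params(cfg, ds$spaces, seed = 3L)
  p1 <- train_phase1(ds, par, cfg, tc)
  expect_identical(ecfusion:::tree_flatten(p1$params$head),
                   ecfusion:::tree_flatten(par$head))
  expect_false(identical(ecfusion:::tree_flatten(p1$params$extractor),
                         ecfusion:::tree_flatten(par$extractor)))
  p2 <- train_phase2(ds, p1$params, cfg, tc)
  expect_identical(ecfusion:::tree_flatten(p2$params$extractor),
                   ecfusion:::tree_flatten(p1$params$extractor))
  expect_false(identical(ecfusion:::tree_flatten(p2$params$head),
                         ecfusion:::tree_flatten(p1$params$head)))
  # determinism: the same seed reproduces the loss trace exactly
  p1b <- train_phase1(ds, par, cfg, tc)
  expect_identical(p1$trace, p1b$trace)
})

test_that("the cached-feature path gives predictions identical to the uncached path", {
  ds <- tiny_dataset(n_per_class = 3L, L = 5L, N = 8L)
  cfg <- model_config(n_feat = 8L, n_heads = 2L)
  tc <- train_config(phase1_epochs = 1L, phase1_batch = 10L, phase2_epochs = 5L,
                     phase2_batch = 64L, triplets_per_epoch = 10L, seed = 5L)
  par <- init_model_params(cfg, ds$spaces, seed = 5L)
  pooled <- ecfusion:::pool_dataset(ds, par, cfg)
  with_cache <- train_phase2(ds, par, cfg, tc, pooled = pooled)
  without <- train_phase2(ds, par, cfg, tc)
  expect_identical(with_cache$params, without$params)
})

test_that("training reduces both losses on a separable fixture", {
  synth <- generate_dataset(synth_config(branching = c(2L, 1L, 1L, 2L),
                                         proteins_per_leaf = 8L,
                                         length_range = c(8L, 10L), n_feat = 8L,
                                         separation = 4, noise = 1,
                                         multi_label_prob = 0, seed = 21L))
  ds <- synth$dataset
  cfg <- model_config(n_feat = 8L, n_heads = 2L)
  tc <- train_config(phase1_epochs = 4L, phase1_batch = 20L, phase2_epochs = 40L,
                     phase2_batch = 64L, triplets_per_epoch = 24L, seed = 1L)
  fit <- train_model(ds, cfg, tc)
  tr1 <- fit$trace[fit$trace$phase == 1L, ]
  tr2 <- fit$trace[fit$trace$phase == 2L, ]
  expect_lt(tr1$loss[nrow(tr1)], tr1$loss[1])
  expect_lt(tr2$loss[nrow(tr2)], tr2$loss[1])
})

test_that("analytic gradients match finite differences on random parameters", {
  ds <- tiny_dataset(n_per_class = 2L, L = 4L, N = 8L)
  cfg <- model_config(n_feat = 8L, n_heads = 2L)
  par <- init_model_params(cfg, ds$spaces, seed = 7L)
  trip <- sample_triplets(ds, 4L, seed = 7L, quiet = TRUE)
  margin <- 1
  uids <- unique(c(trip$anchor, trip$positive, trip$negative))

  pooled_of <- function(pp) {
    m <- t(vapply(ds$proteins[uids],
                  function(q) ecfusion:::extractor_forward(q, pp, cfg)$pooled,
                  numeric(fused_width(cfg))))
    rownames(m) <- uids
    m
  }
  targets <- ecfusion:::target_matrices(ds)
  # the two phase losses, as the training loop weights them: phase 1 is
  # lambda = (1, 0) and updates the extractor, phase 2 is lambda = (0, 1)
  # and updates the head on frozen features
  loss_phase1 <- function(pp) {
    pooled <- pooled_of(pp)
    lt <- triplet_loss(pooled[trip$anchor, , drop = FALSE],
                       pooled[trip$positive, , drop = FALSE],
                       pooled[trip$negative, , drop = FALSE], margin)
    total_loss(lt, 0, lambda1 = 1, lambda2 = 0)
  }
  X_frozen <- t(vapply(ds$proteins,
                       function(q) ecfusion:::extractor_forward(q, par, cfg)$pooled,
                       numeric(fused_width(cfg))))
  loss_phase2 <- function(pp) {
    fw <- ecfusion:::head_forward(X_frozen, pp$head, cfg, prev_override = targets[1:3])
    total_loss(0, bce_multilevel_loss(fw$probs, targets), lambda1 = 0, lambda2 = 1)
  }

  # analytic gradient of the combined loss
  fw <- lapply(ds$proteins[uids], ecfusion:::extractor_forward, params = par, config = cfg)
  pooled <- t(vapply(fw, `[[`, numeric(fused_width(cfg)), "pooled"))
  rownames(pooled) <- uids
  tg <- ecfusion:::triplet_loss_grad(pooled[trip$anchor, , drop = FALSE],
                                     pooled[trip$positive, , drop = FALSE],
                                     pooled[trip$negative, , drop = FALSE], margin)
  dp <- matrix(0, length(uids), ncol(pooled), dimnames = list(uids, NULL))
  for (i in seq_len(nrow(trip))) {
    dp[trip$anchor[i], ] <- dp[trip$anchor[i], ] + tg$d_anchor[i, ]
    dp[trip$positive[i], ] <- dp[trip$positive[i], ] + tg$d_positive[i, ]
    dp[trip$negative[i], ] <- dp[trip$negative[i], ] + tg$d_negative[i, ]
  }
  ext_grads <- NULL
  for (id in uids) {
    bk <- ecfusion:::extractor_backward(dp[id, ], par, cfg, fw[[id]]$cache)
    ext_grads <- if (is.null(ext_grads)) bk$grads else ecfusion:::tree_add(ext_grads, bk$grads)
  }
  hf <- ecfusion:::head_forward(X_frozen, par$head, cfg, prev_override = targets[1:3])
  head_grads <- vector("list", 4L)
  for (j in 1:4) {
    dZ <- hf$probs[[j]] - targets[[j]]
    head_grads[[j]] <- ecfusion:::mlp_backward_logits(dZ, par$head[[j]], hf$caches[[j]])$grads
  }
  names(head_grads) <- names(par$head)
  grads <- list(extractor = ext_grads, head = head_grads)

  # ten random leaves spanning extractor and head
  leaf_paths <- list(
    list("extractor", "gfe", 1L, "layer1", "Wq"),
    list("extractor", "gfe", 2L, "layer2", "Wo"),
    list("extractor", "gfe", 3L, "layer1", "Wv"),
    list("extractor", "gfe", 1L, "layer2", "ln_g"),
    list("extractor", "lfe", 1L, "conv", 2L, "W"),
    list("extractor", "lfe", 3L, "mlp", "W2"),
    list("extractor", "lfe", 2L, "conv", 1L, "b"),
    list("head", "mlp1", "W1"),
    list("head", "mlp3", "W1"),
    list("head", "mlp4", "W2"))
  get_leaf <- function(x, path) Reduce(`[[`, path, x)
  nudge <- function(x, path, idx, delta) {
    purrr::modify_in(x, path, function(m) { m[idx] <- m[idx] + delta; m })
  }
  withr::local_seed(77)
  eps <- 1e-5
  for (path in leaf_paths) {
    leaf <- get_leaf(par, path)
    idx <- sample(length(leaf), 1L)
    an <- get_leaf(grads, path)[idx]
    loss_of <- if (path[[1]] == "extractor") loss_phase1 else loss_phase2
    fd <- (loss_of(nudge(par, path, idx, eps)) -
             loss_of(nudge(par, path, idx, -eps))) / (2 * eps)
    expect_equal(an, fd, tolerance = 1e-4)
  }
})
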