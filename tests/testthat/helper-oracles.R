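# Straight-line reference implementations (loops, no vectorized shortcuts)
# used as independent oracles, plus small in-code fixtures.

# scaled dot-product attention by explicit loops
oracle_attention <- function(Q, K, V) {
  Lq <- nrow(Q); Lk <- nrow(K); d <- ncol(Q)
  out <- matrix(0, Lq, ncol(V))
  W <- matrix(0, Lq, Lk)
  for (i in seq_len(Lq)) {
    logits <- numeric(Lk)
    for (j in seq_len(Lk)) {
      acc <- 0
      for (m in seq_len(d)) acc <- acc + Q[i, m] * K[j, m]
      logits[j] <- acc / sqrt(d)
    }
    e <- exp(logits - max(logits))
    w <- e / sum(e)
    W[i, ] <- w
    for (j in seq_len(Lk)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  list(output = out, weights = W)
}

# layer normalization by loops (population variance over features, eps 1e-5)
oracle_layernorm <- function(X, g, b) {
  out <- X
  for (i in seq_len(nrow(X))) {
    mu <- mean(X[i, ])
    v <- mean((X[i, ] - mu)^2)
    out[i, ] <- g * (X[i, ] - mu) / sqrt(v + 1e-5) + b
  }
  out
}

# one multi-head cross-attention layer by composing the single-head oracle
oracle_cross_attention <- function(Xq, Xkv, p, n_heads) {
  N <- ncol(Xq)
  nh <- N / n_heads
  Q <- Xq %*% p$Wq; K <- Xkv %*% p$Wk; V <- Xkv %*% p$Wv
  O <- matrix(0, nrow(Xq), N)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * nh + 1):(h * nh)
    O[, cols] <- oracle_attention(Q[, cols, drop = FALSE],
                                  K[, cols, drop = FALSE],
                                  V[, cols, drop = FALSE])$output
  }
  oracle_layernorm(Xq + O %*% p$Wo, p$ln_g, p$ln_b)
}

# same-padded 1-D convolution by explicit sliding-window sums
oracle_conv1d <- function(X, W, b) {
  k <- dim(W)[1]; r <- (k - 1) / 2
  L <- nrow(X); C_in <- ncol(X); C_out <- dim(W)[3]
  Y <- matrix(0, L, C_out)
  for (t in seq_len(L)) {
    for (co in seq_len(C_out)) {
      acc <- b[co]
      for (o in seq_len(k)) {
        src <- t + o - r - 1
        if (src >= 1 && src <= L) {
          for (ci in seq_len(C_in)) acc <- acc + X[src, ci] * W[o, ci, co]
        }
      }
      Y[t, co] <- acc
    }
  }
  Y
}

# one local block by composing the conv oracle with an explicit MLP
oracle_lfe <- function(X, p) {
  Xc <- do.call(cbind, lapply(p$conv, function(cp) oracle_conv1d(X, cp$W, cp$b)))
  H <- pmax(sweep(Xc %*% p$mlp$W1, 2, p$mlp$b1, `+`), 0)
  sweep(H %*% p$mlp$W2, 2, p$mlp$b2, `+`)
}

# full extractor forward built only from the oracles above
oracle_extract <- function(pair, params, config) {
  s <- pair$seq; t <- pair$tdi
  if (config$zero_seq) s <- s * 0
  if (config$zero_tdi) t <- t * 0
  s0 <- s; t0 <- t
  seq_hats <- list()
  for (i in seq_len(config$n_blocks)) {
    gp <- params$extractor$gfe[[i]]
    t <- oracle_cross_attention(t, s, gp$layer1, config$n_heads)
    s <- oracle_cross_attention(s, t, gp$layer2, config$n_heads)
    seq_hats[[i]] <- s
  }
  X <- cbind(s0, t0)
  local <- NULL
  for (i in seq_len(config$n_blocks)) {
    local <- oracle_lfe(X, params$extractor$lfe[[i]])
    if (i < config$n_blocks) X <- cbind(seq_hats[[i]], local)
  }
  fused <- cbind(seq_hats[[config$n_blocks]], local)
  list(fused = fused, pooled = colMeans(fused))
}

# scalar-loop multi-level BCE with the same clamping as the implementation
oracle_bce <- function(pred, target, eps = 1e-7) {
  total <- 0
  for (j in 1:4) {
    for (i in seq_along(pred[[j]])) {
      p <- min(max(pred[[j]][i], eps), 1 - eps)
      y <- target[[j]][i]
      total <- total - (y * log(p) + (1 - y) * log(1 - p))
    }
  }
  total
}

# random attention-layer parameters at width N
random_attention_params <- function(N) {
  list(Wq = matrix(rnorm(N * N, sd = 0.3), N), Wk = matrix(rnorm(N * N, sd = 0.3), N),
       Wv = matrix(rnorm(N * N, sd = 0.3), N), Wo = matrix(rnorm(N * N, sd = 0.3), N),
       ln_g = runif(N, 0.5, 1.5), ln_b = rnorm(N, sd = 0.1))
}

# a small, fully in-code dataset (no generator) with two families of two
# leaves each; used where tests need hand-checkable labels
tiny_dataset <- function(n_per_class = 3L, L = 6L, N = 8L, seed = 42L) {
  withr::with_seed(seed, {
    ecs <- c("1.1.1.1", "1.1.1.2", "2.7.7.7", "2.7.7.8")
    protos <- lapply(ecs, function(e) matrix(rnorm(N, sd = 2), 1))
    proteins <- list()
    labels <- list()
    idx <- 0L
    for (ci in seq_along(ecs)) {
      for (r in seq_len(n_per_class)) {
        idx <- idx + 1L
        id <- sprintf("t%03d", idx)
        emb <- matrix(rep(protos[[ci]], each = L), L, N) + matrix(rnorm(L * N, sd = 0.3), L, N)
        proteins[[id]] <- list(id = id,
                               sequence = paste(sample(LETTERS[1:20], L, TRUE), collapse = ""),
                               tdi_sequence = paste(sample(LETTERS[1:20], L, TRUE), collapse = ""),
                               seq = emb,
                               tdi = emb + matrix(rnorm(L * N, sd = 0.3), L, N),
                               ec = ecs[ci])
        labels[[id]] <- tibble::tibble(protein_id = id, ec = ecs[ci])
      }
    }
    ecfusion:::new_ec_dataset(proteins, dplyr::bind_rows(labels))
  })
}
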