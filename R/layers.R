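# Differentiable layer primitives for the dual-pathway feature extractor.
#
# Every layer comes as a forward that returns its output plus a cache, and a
# backward that maps the output gradient to input and parameter gradients.
# All computation is double precision and single-threaded; two identical
# forwards are bit-identical.

row_softmax <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `Softmax(Q K' / sqrt(d_k)) V`: each output row is a convex combination of
#' the value rows, weighted by the query-key similarities of that query.
#'
#' @param Q Query matrix, `L_q x d`.
#' @param K Key matrix, `L_k x d`.
#' @param V Value matrix, `L_k x d_v`.
#' @param return_weights Also return the attention weight matrix.
#' @return The `L_q x d_v` output matrix; if `return_weights`, a list with
#'   `output` and `weights` (`L_q x L_k`, rows summing to 1).
#' @export
scaled_dot_attention <- function(Q, K, V, return_weights = FALSE) {
  stopifnot(is.matrix(Q), is.matrix(K), is.matrix(V),
            ncol(Q) == ncol(K), nrow(K) == nrow(V))
  if (!all(is.finite(Q)) || !all(is.finite(K)) || !all(is.finite(V))) {
    stop("non-finite attention inputs", call. = FALSE)
  }
  A <- row_softmax(Q %*% t(K) / sqrt(ncol(Q)))
  out <- A %*% V
  if (return_weights) list(output = out, weights = A) else out
}

# backward through O = A V, A = softmax(QK'/s): returns dQ, dK, dV given dO
# and the cached A.
attention_backward <- function(dO, Q, K, V, A) {
  s <- sqrt(ncol(Q))
  dA <- dO %*% t(V)
  dV <- t(A) %*% dO
  dZ <- A * (dA - rowSums(dA * A))
  list(dQ = (dZ %*% K) / s, dK = (t(dZ) %*% Q) / s, dV = dV)
}

# --- layer normalization (per residue row, over the N features) ------------

LN_EPS <- 1e-5

layernorm_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv_sd
  out <- sweep(xhat, 2L, g, `*`)
  out <- sweep(out, 2L, b, `+`)
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd))
}

layernorm_backward <- function(dOut, g, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dOut, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dX = dX, dg = colSums(dOut * xhat), db = colSums(dOut))
}

# --- multi-head cross-attention layer --------------------------------------

# params: Wq, Wk, Wv, Wo (N x N), ln_g, ln_b (N). Heads are column blocks of
# width N/h. Residual connection to the query stream, then layer norm.
cross_attention_forward <- function(Xq, Xkv, p, n_heads) {
  N <- ncol(Xq)
  nh <- N %/% n_heads
  if (nh * n_heads != N) stop("feature width not divisible by head count", call. = FALSE)
  Q <- Xq %*% p$Wq; K <- Xkv %*% p$Wk; V <- Xkv %*% p$Wv
  s <- sqrt(nh)
  A <- vector("list", n_heads)
  O <- matrix(0, nrow(Xq), N)
  for (i in seq_len(n_heads)) {
    cols <- ((i - 1L) * nh + 1L):(i * nh)
    Ai <- row_softmax(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / s)
    A[[i]] <- Ai
    O[, cols] <- Ai %*% V[, cols, drop = FALSE]
  }
  proj <- O %*% p$Wo
  R <- Xq + proj
  ln <- layernorm_forward(R, p$ln_g, p$ln_b)
  list(out = ln$out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, A = A, O = O,
                    ln = ln$cache, n_heads = n_heads, nh = nh))
}

cross_attention_backward <- function(dOut, p, cache) {
  lb <- layernorm_backward(dOut, p$ln_g, cache$ln)
  dR <- lb$dX
  dXq <- dR                               # residual branch
  dWo <- t(cache$O) %*% dR
  dO <- dR %*% t(p$Wo)
  nh <- cache$nh
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (i in seq_len(cache$n_heads)) {
    cols <- ((i - 1L) * nh + 1L):(i * nh)
    ab <- attention_backward(dO[, cols, drop = FALSE],
                             cache$Q[, cols, drop = FALSE],
                             cache$K[, cols, drop = FALSE],
                             cache$V[, cols, drop = FALSE],
                             cache$A[[i]])
    dQ[, cols] <- ab$dQ; dK[, cols] <- ab$dK; dV[, cols] <- ab$dV
  }
  dXq <- dXq + dQ %*% t(p$Wq)
  dXkv <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(Wq = t(cache$Xq) %*% dQ,
                Wk = t(cache$Xkv) %*% dK,
                Wv = t(cache$Xkv) %*% dV,
                Wo = dWo, ln_g = lb$dg, ln_b = lb$db)
  list(dXq = dXq, dXkv = dXkv, grads = grads)
}

#' Multi-head cross-attention between two per-residue streams
#'
#' One cross-attention layer of a global feature extraction (GFE) block: the
#' query stream attends over the key/value stream with `h` heads (per-head
#' projections of width `N/h`), head outputs are concatenated and projected,
#' residual-added to the query stream and layer-normalized. The updated query
#' stream is returned.
#'
#' @param query_feats `L x N` matrix of the stream being updated.
#' @param kv_feats `L x N` matrix providing keys and values.
#' @param params Layer parameters (`Wq`, `Wk`, `Wv`, `Wo`, `ln_g`, `ln_b`),
#'   e.g. one `$gfe[[i]]$layer1` element of [init_model_params()].
#' @param n_heads Number of attention heads; must divide `N`.
#' @return Updated `L x N` matrix.
#' @export
cross_attention <- function(query_feats, kv_feats, params, n_heads = 1L) {
  stopifnot(is.matrix(query_feats), is.matrix(kv_feats),
            ncol(query_feats) == ncol(kv_feats))
  cross_attention_forward(query_feats, kv_feats, params, n_heads)$out
}

# --- multi-kernel 1-D convolution block (LFE) ------------------------------

# One conv branch: kernel size k (odd), input X (L x C_in), weights W as an
# array (k, C_in, C_out), bias b. Same padding along the length axis:
# Y[t, ] = b + sum_o X[t + o - r - 1, ] %*% W[o, , ] with zero rows off-range.
conv1d_forward <- function(X, W, b) {
  k <- dim(W)[1L]; r <- (k - 1L) %/% 2L
  L <- nrow(X); C_out <- dim(W)[3L]
  Y <- matrix(rep(b, each = L), L, C_out)
  for (o in seq_len(k)) {
    off <- o - r - 1L
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    if (!any(ok)) next
    Y[ok, ] <- Y[ok, ] + X[src[ok], , drop = FALSE] %*% W[o, , ]
  }
  Y
}

conv1d_backward <- function(dY, X, W) {
  k <- dim(W)[1L]; r <- (k - 1L) %/% 2L
  L <- nrow(X)
  dW <- array(0, dim(W))
  dX <- matrix(0, L, ncol(X))
  for (o in seq_len(k)) {
    off <- o - r - 1L
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    if (!any(ok)) next
    dW[o, , ] <- t(X[src[ok], , drop = FALSE]) %*% dY[ok, , drop = FALSE]
    dX[src[ok], ] <- dX[src[ok], ] + dY[ok, , drop = FALSE] %*% t(W[o, , ])
  }
  list(dW = dW, dX = dX, db = colSums(dY))
}

#' One branch of a local feature extraction block
#'
#' A 1-D convolution along the residue axis with same padding: the channels of
#' the two stacked input streams (2N per position) are mapped to N output
#' channels with a window of `k` positions.
#'
#' @param X `L x C_in` input matrix (positions by channels).
#' @param W Weight array of dimension `(k, C_in, C_out)`.
#' @param b Bias vector of length `C_out`.
#' @return `L x C_out` matrix.
#' @export
conv1d_same <- function(X, W, b) {
  stopifnot(is.matrix(X), length(dim(W)) == 3L, dim(W)[2L] == ncol(X),
            dim(W)[1L] %% 2L == 1L)
  conv1d_forward(X, W, b)
}

relu <- function(x) x * (x > 0)

# LFE block: X is L x 2N (the channel-stacked stream pair); three parallel
# convolutions (kernel sizes from config) map 2N -> N each, their outputs are
# concatenated to L x 3N and a per-position MLP (3N -> 3N relu -> N) fuses
# them.
lfe_forward <- function(X, p) {
  branches <- lapply(p$conv, function(cp) conv1d_forward(X, cp$W, cp$b))
  Xc <- do.call(cbind, branches)
  H_pre <- sweep(Xc %*% p$mlp$W1, 2L, p$mlp$b1, `+`)
  H <- relu(H_pre)
  out <- sweep(H %*% p$mlp$W2, 2L, p$mlp$b2, `+`)
  list(out = out, cache = list(X = X, Xc = Xc, H_pre = H_pre, H = H))
}

lfe_backward <- function(dOut, p, cache) {
  dW2 <- t(cache$H) %*% dOut
  db2 <- colSums(dOut)
  dH <- dOut %*% t(p$mlp$W2)
  dH_pre <- dH * (cache$H_pre > 0)
  dW1 <- t(cache$Xc) %*% dH_pre
  db1 <- colSums(dH_pre)
  dXc <- dH_pre %*% t(p$mlp$W1)
  n_out <- ncol(cache$Xc) %/% length(p$conv)
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  conv_grads <- vector("list", length(p$conv))
  for (i in seq_along(p$conv)) {
    cols <- ((i - 1L) * n_out + 1L):(i * n_out)
    cb <- conv1d_backward(dXc[, cols, drop = FALSE], cache$X, p$conv[[i]]$W)
    conv_grads[[i]] <- list(W = cb$dW, b = cb$db)
    dX <- dX + cb$dX
  }
  list(dX = dX, grads = list(conv = conv_grads,
                             mlp = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
}

#' Local feature extraction block
#'
#' Applies the three parallel same-padded 1-D convolutions (kernel sizes from
#' the model configuration, by default 7, 9 and 11) to a channel-stacked pair
#' of per-residue streams, concatenates the branch outputs and fuses them with
#' a per-position MLP back to width N.
#'
#' @param input Either a `L x 2N` matrix (already channel-stacked) or a list
#'   of two `L x N` matrices that will be stacked.
#' @param params One `$lfe[[i]]` element of [init_model_params()].
#' @return `L x N` output matrix.
#' @export
lfe_block <- function(input, params) {
  if (is.list(input) && !is.matrix(input)) input <- do.call(cbind, input)
  stopifnot(is.matrix(input), nrow(input) >= 1L)
  lfe_forward(input, params)$out
}

#' One global feature extraction block
#'
#' Two cross-attention layers: the 3Di stream is first updated with the
#' sequence stream as key/value source, then the sequence stream is updated
#' attending over the freshly updated 3Di stream. With
#' `paper_subscripts = TRUE` the query/key-value roles within each layer are
#' swapped (the literal subscript order of the multi-head attention
#' definition), while the updated stream stays the same.
#'
#' @param seq,tdi `L x N` matrices for the two streams.
#' @param params One `$gfe[[i]]` element of [init_model_params()] (fields
#'   `layer1`, `layer2`).
#' @param n_heads Attention heads.
#' @param paper_subscripts Swap query and key/value roles in both layers.
#' @return List with updated `seq` and `tdi` matrices.
#' @export
gfe_block <- function(seq, tdi, params, n_heads = 1L, paper_subscripts = FALSE) {
  f <- gfe_forward(seq, tdi, params, n_heads, paper_subscripts)
  list(seq = f$seq, tdi = f$tdi)
}

gfe_forward <- function(seq, tdi, p, n_heads, paper_subscripts = FALSE) {
  if (paper_subscripts) {
    l1 <- cross_attention_forward(seq, tdi, p$layer1, n_heads)   # output updates 3Di
    tdi_hat <- l1$out
    l2 <- cross_attention_forward(tdi_hat, seq, p$layer2, n_heads)
    seq_hat <- l2$out
  } else {
    l1 <- cross_attention_forward(tdi, seq, p$layer1, n_heads)
    tdi_hat <- l1$out
    l2 <- cross_attention_forward(seq, tdi_hat, p$layer2, n_heads)
    seq_hat <- l2$out
  }
  list(seq = seq_hat, tdi = tdi_hat, cache = list(l1 = l1$cache, l2 = l2$cache))
}

# backward through one GFE block (spec query convention). d_seq/d_tdi are the
# gradients wrt the block outputs; returns gradients wrt the block inputs.
gfe_backward <- function(d_seq, d_tdi, p, cache, paper_subscripts = FALSE) {
  if (paper_subscripts) {
    b2 <- cross_attention_backward(d_seq, p$layer2, cache$l2)
    d_tdi_hat <- d_tdi + b2$dXq
    d_seq_in <- b2$dXkv
    b1 <- cross_attention_backward(d_tdi_hat, p$layer1, cache$l1)
    d_seq_in <- d_seq_in + b1$dXq
    d_tdi_in <- b1$dXkv
  } else {
    b2 <- cross_attention_backward(d_seq, p$layer2, cache$l2)
    d_seq_in <- b2$dXq
    d_tdi_hat <- d_tdi + b2$dXkv
    b1 <- cross_attention_backward(d_tdi_hat, p$layer1, cache$l1)
    d_tdi_in <- b1$dXq
    d_seq_in <- d_seq_in + b1$dXkv
  }
  list(d_seq = d_seq_in, d_tdi = d_tdi_in,
       grads = list(layer1 = b1$grads, layer2 = b2$grads))
}
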