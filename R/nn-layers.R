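# Low-level neural-network primitives: forward passes paired with hand-derived
# backward passes. Token sequences are stored as (B*N) x D matrices with rows
# in batch-major order (row (b-1)*N + n holds token n of sample b); spatial
# maps as (H, W, C, B) arrays. Every *_fwd returns list(out, cache) and the
# matching *_bwd consumes (cache, dout) and returns list(dx, <param grads>).

LN_EPS <- 1e-6

# Truncated normal draws (resampling outside +/- 2 sd), the standard ViT
# weight initialization (sigma = 0.02).
trunc_normal <- function(n, sd = 0.02) {
  lo <- pnorm(-2)
  hi <- pnorm(2)
  qnorm(runif(n, lo, hi)) * sd
}

init_linear <- function(d_in, d_out, bias = TRUE, sd = 0.02) {
  out <- list(W = matrix(trunc_normal(d_in * d_out, sd), d_in, d_out))
  if (bias) out$b <- numeric(d_out)
  out
}

init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

## ---- linear ---------------------------------------------------------------

linear_fwd <- function(x, p) {
  out <- x %*% p$W
  if (!is.null(p$b)) out <- sweep(out, 2, p$b, "+")
  list(out = out, cache = list(x = x, p = p))
}

linear_bwd <- function(cache, dout) {
  g <- list(W = crossprod(cache$x, dout))
  if (!is.null(cache$p$b)) g$b <- colSums(dout)
  list(dx = tcrossprod(dout, cache$p$W), grads = g)
}

## ---- layer normalization (over the feature axis, per row) ----------------

layernorm_fwd <- function(x, p = NULL, eps = LN_EPS) {
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowSums(xc * xc) / d
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- if (is.null(p)) xhat else sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, p = p))
}

layernorm_bwd <- function(cache, dout) {
  xhat <- cache$xhat
  d <- ncol(xhat)
  grads <- NULL
  dxhat <- if (is.null(cache$p)) {
    dout
  } else {
    grads <- list(g = colSums(dout * xhat), b = colSums(dout))
    sweep(dout, 2, cache$p$g, "*")
  }
  m1 <- rowSums(dxhat) / d
  m2 <- rowSums(dxhat * xhat) / d
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, grads = grads)
}

## ---- activations ----------------------------------------------------------

gelu_fwd <- function(x) list(out = x * pnorm(x), cache = x)
gelu_bwd <- function(cache, dout) dout * (pnorm(cache) + cache * dnorm(cache))

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, cache = list(x = x, s = s))
}
silu_bwd <- function(cache, dout) {
  s <- cache$s
  dout * (s * (1 + cache$x * (1 - s)))
}

## ---- dropout (inverted; identity when p = 0 or not training) --------------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- array(runif(length(x)) >= p, dim = dim(x) %||% length(x))
  scale <- 1 / (1 - p)
  list(out = x * keep * scale, cache = list(keep = keep, scale = scale))
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache$keep * cache$scale
}

## ---- row-wise softmax ------------------------------------------------------

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

## ---- 1x1 convolution on (H, W, C, B) --------------------------------------

conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  hw <- d[1] * d[2]
  cin <- d[3]
  b <- d[4]
  cout <- ncol(p$W)
  out <- array(0, c(d[1], d[2], cout, b))
  xm_list <- vector("list", b)
  for (i in seq_len(b)) {
    xm <- matrix(x[, , , i, drop = FALSE], hw, cin)
    y <- xm %*% p$W
    if (!is.null(p$b)) y <- sweep(y, 2, p$b, "+")
    out[, , , i] <- array(y, c(d[1], d[2], cout))
    xm_list[[i]] <- xm
  }
  list(out = out, cache = list(xm = xm_list, p = p, dims = d))
}

conv1x1_bwd <- function(cache, dout) {
  d <- cache$dims
  hw <- d[1] * d[2]
  b <- d[4]
  W <- cache$p$W
  dW <- matrix(0, nrow(W), ncol(W))
  db <- if (is.null(cache$p$b)) NULL else numeric(ncol(W))
  dx <- array(0, d)
  for (i in seq_len(b)) {
    dy <- matrix(dout[, , , i, drop = FALSE], hw, ncol(W))
    dW <- dW + crossprod(cache$xm[[i]], dy)
    if (!is.null(db)) db <- db + colSums(dy)
    dx[, , , i] <- array(tcrossprod(dy, W), c(d[1], d[2], nrow(W)))
  }
  g <- list(W = dW)
  if (!is.null(db)) g$b <- db
  list(dx = dx, grads = g)
}

## ---- patch extraction (im2col for the strided patch-embedding conv) --------
# Returns, per sample, a (num_patches x P*P*C) matrix. Patch order is
# row-major over the patch grid (grid row varies slowest along rows is FALSE:
# token k = grid_row * Gw + grid_col + 1, i.e. grid column fastest), matching
# tokens_to_spatial(). Within a patch, pixels flatten column-major over
# (patch_row, patch_col, channel).
extract_patches <- function(img, patch) {
  d <- dim(img)
  gh <- d[1] %/% patch
  gw <- d[2] %/% patch
  out <- matrix(0, gh * gw, patch * patch * d[3])
  k <- 1L
  for (r in seq_len(gh)) {
    rows <- ((r - 1) * patch + 1):(r * patch)
    for (cc in seq_len(gw)) {
      cols <- ((cc - 1) * patch + 1):(cc * patch)
      out[k, ] <- as.vector(img[rows, cols, ])
      k <- k + 1L
    }
  }
  out
}

## ---- same-padded max pool (kernel k, stride 1) on (H, W, C, B) -------------
# Forward tracks, per output cell, which of the k*k shifted inputs supplied
# the maximum (first-wins on ties) so the backward pass can route gradients.

maxpool_same_fwd <- function(x, k, track = TRUE) {
  d <- dim(x)
  pad <- (k - 1) %/% 2
  hp <- d[1] + 2 * pad
  wp <- d[2] + 2 * pad
  xp <- array(-Inf, c(hp, wp, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  best <- array(-Inf, d)
  arg <- if (track) array(0L, d) else NULL
  off <- 0L
  for (dy in 0:(k - 1)) {
    for (dx_ in 0:(k - 1)) {
      off <- off + 1L
      cand <- xp[dy + seq_len(d[1]), dx_ + seq_len(d[2]), , , drop = FALSE]
      better <- cand > best
      best[better] <- cand[better]
      if (track) arg[better] <- off
    }
  }
  list(out = best, cache = list(arg = arg, k = k, dims = d, pad = pad))
}

maxpool_same_bwd <- function(cache, dout) {
  d <- cache$dims
  k <- cache$k
  pad <- cache$pad
  hp <- d[1] + 2 * pad
  wp <- d[2] + 2 * pad
  dxp <- array(0, c(hp, wp, d[3], d[4]))
  off <- 0L
  for (dy in 0:(k - 1)) {
    for (dx_ in 0:(k - 1)) {
      off <- off + 1L
      sel <- cache$arg == off
      if (any(sel)) {
        idx_h <- dy + seq_len(d[1])
        idx_w <- dx_ + seq_len(d[2])
        sub <- dxp[idx_h, idx_w, , , drop = FALSE]
        sub[sel] <- sub[sel] + dout[sel]
        dxp[idx_h, idx_w, , ] <- sub
      }
    }
  }
  dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
}

## ---- multi-head self-attention --------------------------------------------
# params: qkv (W: D x 3D, b), proj (W: D x D, b). x: (B*N) x D.

attention_fwd <- function(x, p, n_tokens, num_heads, scale,
                          attn_dropout = 0, dropout = 0, training = FALSE) {
  d_model <- ncol(x)
  b <- nrow(x) / n_tokens
  dh <- d_model %/% num_heads
  qkv_lin <- linear_fwd(x, p$qkv)
  qkv <- qkv_lin$out                        # (B*N) x 3D
  o <- matrix(0, nrow(x), d_model)
  probs <- vector("list", b)
  masks <- vector("list", b)
  for (bi in seq_len(b)) {
    rows <- ((bi - 1) * n_tokens + 1):(bi * n_tokens)
    pb <- vector("list", num_heads)
    mb <- vector("list", num_heads)
    for (h in seq_len(num_heads)) {
      cq <- (h - 1) * dh + seq_len(dh)
      q <- qkv[rows, cq, drop = FALSE]
      kk <- qkv[rows, d_model + cq, drop = FALSE]
      v <- qkv[rows, 2 * d_model + cq, drop = FALSE]
      s <- tcrossprod(q, kk) * scale
      pr <- softmax_rows(s)
      dp <- dropout_fwd(pr, attn_dropout, training)
      o[rows, cq] <- dp$out %*% v
      pb[[h]] <- pr
      mb[h] <- list(dp$cache)          # keep NULL entries (eval mode)
    }
    probs[[bi]] <- pb
    masks[[bi]] <- mb
  }
  proj <- linear_fwd(o, p$proj)
  dp_out <- dropout_fwd(proj$out, dropout, training)
  list(out = dp_out$out,
       cache = list(qkv = qkv, qkv_lin = qkv_lin$cache, probs = probs,
                    masks = masks, proj = proj$cache, out_mask = dp_out$cache,
                    n_tokens = n_tokens, num_heads = num_heads, scale = scale,
                    d_model = d_model))
}

attention_bwd <- function(cache, dout) {
  n <- cache$n_tokens
  d_model <- cache$d_model
  dh <- d_model %/% cache$num_heads
  b <- nrow(dout) / n
  dproj_in <- dropout_bwd(cache$out_mask, dout)
  pr_b <- linear_bwd(cache$proj, dproj_in)
  do_ <- pr_b$dx
  dqkv <- matrix(0, nrow(dout), 3 * d_model)
  for (bi in seq_len(b)) {
    rows <- ((bi - 1) * n + 1):(bi * n)
    for (h in seq_len(cache$num_heads)) {
      cq <- (h - 1) * dh + seq_len(dh)
      q <- cache$qkv[rows, cq, drop = FALSE]
      kk <- cache$qkv[rows, d_model + cq, drop = FALSE]
      v <- cache$qkv[rows, 2 * d_model + cq, drop = FALSE]
      pr <- cache$probs[[bi]][[h]]
      msk <- cache$masks[[bi]][[h]]
      pd <- if (is.null(msk)) pr else pr * msk$keep * msk$scale
      doh <- do_[rows, cq, drop = FALSE]
      dpd <- tcrossprod(doh, v)
      dv <- crossprod(pd, doh)
      dpr <- dropout_bwd(msk, dpd)
      ds <- pr * (dpr - rowSums(dpr * pr))
      dq <- (ds %*% kk) * cache$scale
      dk <- crossprod(ds, q) * cache$scale
      dqkv[rows, cq] <- dq
      dqkv[rows, d_model + cq] <- dk
      dqkv[rows, 2 * d_model + cq] <- dv
    }
  }
  qkv_b <- linear_bwd(cache$qkv_lin, dqkv)
  list(dx = qkv_b$dx,
       grads = list(qkv = qkv_b$grads, proj = pr_b$grads))
}

## ---- transformer block (pre-norm residual) ---------------------------------
# params: ln1, attn (qkv, proj), ln2, fc1, fc2.

transformer_block_fwd <- function(x, p, n_tokens, num_heads, scale,
                                  dropout = 0, attn_dropout = 0,
                                  training = FALSE) {
  ln1 <- layernorm_fwd(x, p$ln1)
  att <- attention_fwd(ln1$out, p$attn, n_tokens, num_heads, scale,
                       attn_dropout = attn_dropout, dropout = dropout,
                       training = training)
  x1 <- x + att$out
  ln2 <- layernorm_fwd(x1, p$ln2)
  f1 <- linear_fwd(ln2$out, p$fc1)
  g1 <- gelu_fwd(f1$out)
  d1 <- dropout_fwd(g1$out, dropout, training)
  f2 <- linear_fwd(d1$out, p$fc2)
  d2 <- dropout_fwd(f2$out, dropout, training)
  out <- x1 + d2$out
  if (!is_finite_all(out)) {
    stop_caspnet("non-finite activations inside a transformer block")
  }
  list(out = out,
       cache = list(ln1 = ln1$cache, att = att$cache, ln2 = ln2$cache,
                    f1 = f1$cache, g1 = g1$cache, d1 = d1$cache,
                    f2 = f2$cache, d2 = d2$cache))
}

transformer_block_bwd <- function(cache, dout) {
  dx1 <- dout
  dmlp <- dropout_bwd(cache$d2, dout)
  f2b <- linear_bwd(cache$f2, dmlp)
  dg1 <- dropout_bwd(cache$d1, f2b$dx)
  df1 <- gelu_bwd(cache$g1, dg1)
  f1b <- linear_bwd(cache$f1, df1)
  ln2b <- layernorm_bwd(cache$ln2, f1b$dx)
  dx1 <- dx1 + ln2b$dx
  attb <- attention_bwd(cache$att, dx1)
  ln1b <- layernorm_bwd(cache$ln1, attb$dx)
  dx <- dx1 + ln1b$dx
  list(dx = dx,
       grads = list(ln1 = ln1b$grads, attn = attb$grads, ln2 = ln2b$grads,
                    fc1 = f1b$grads, fc2 = f2b$grads))
}

## ---- batch normalization over channels of (H, W, C, B) ---------------------
# Training mode uses batch statistics and returns updated running buffers in
# the cache; evaluation mode standardizes with the stored running statistics.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

batchnorm_fwd <- function(x, p, buf, training) {
  d <- dim(x)
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), n, d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    new_buf <- list(mean = (1 - BN_MOMENTUM) * buf$mean + BN_MOMENTUM * mu,
                    var = (1 - BN_MOMENTUM) * buf$var +
                      BN_MOMENTUM * v * n / max(1, n - 1))
  } else {
    mu <- buf$mean
    v <- buf$var
    new_buf <- buf
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, "*")
  ym <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  out <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out,
       cache = list(xhat = xhat, inv = inv, p = p, dims = d,
                    training = training, new_buf = new_buf))
}

batchnorm_bwd <- function(cache, dout) {
  d <- cache$dims
  n <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), n, d[3])
  xhat <- cache$xhat
  dg <- colSums(dym * xhat)
  db <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$p$g, "*")
  if (cache$training) {
    dxm <- sweep(dxhat - rep(1, n) %o% (db_ <- colMeans(dxhat)) -
                   xhat * (rep(1, n) %o% colMeans(dxhat * xhat)),
                 2, cache$inv, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$inv, "*")
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, grads = list(g = dg, b = db))
}

## ---- conv unit: 1x1 conv (+ optional BN) + SiLU ----------------------------

convunit_fwd <- function(x, p, buf = NULL, training = FALSE) {
  cv <- conv1x1_fwd(x, p$conv)
  h <- cv$out
  bn_cache <- NULL
  if (!is.null(p$bn)) {
    bn <- batchnorm_fwd(h, p$bn, buf, training)
    h <- bn$out
    bn_cache <- bn$cache
  }
  act <- silu_fwd(h)
  list(out = act$out,
       cache = list(conv = cv$cache, bn = bn_cache, act = act$cache))
}

convunit_bwd <- function(cache, dout) {
  dh <- silu_bwd(cache$act, dout)
  g <- list()
  if (!is.null(cache$bn)) {
    bnb <- batchnorm_bwd(cache$bn, dh)
    dh <- bnb$dx
    g$bn <- bnb$grads
  }
  cvb <- conv1x1_bwd(cache$conv, dh)
  g$conv <- cvb$grads
  list(dx = cvb$dx, grads = g)
}
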