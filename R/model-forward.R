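# Staged forward/backward execution of the CASPNet pipeline. The forward pass
# records one entry per stage (name, type, cache); the backward pass walks the
# records in reverse, dispatching on type, and can stop early to expose the
# gradient at an intermediate feature map (used by Grad-CAM).

as_image_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) {
    stop_caspnet("images must be an (H, W, C) or (H, W, C, B) array")
  }
  x
}

# tokens: (B, N, D) array <-> batch-major (B*N) x D matrix
mat_from_tokens <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2, 1, 3)), d[1] * d[2], d[3])
}

tokens_from_mat <- function(mat, b, n) {
  aperm(array(mat, c(n, b, ncol(mat))), c(2, 1, 3))
}

## ---- stage implementations -------------------------------------------------

st_patch_embed_fwd <- function(x, p, patch) {
  d <- dim(x)
  if (d[1] %% patch != 0 || d[2] %% patch != 0) {
    stop_caspnet(sprintf(
      "image height (%d) and width (%d) must both be divisible by patch size %d",
      d[1], d[2], patch))
  }
  b <- d[4]
  np <- (d[1] %/% patch) * (d[2] %/% patch)
  dd <- ncol(p$W)
  tok <- matrix(0, b * np, dd)
  pm_list <- vector("list", b)
  for (i in seq_len(b)) {
    pm <- extract_patches(array(x[, , , i], d[1:3]), patch)
    y <- pm %*% p$W
    if (!is.null(p$b)) y <- sweep(y, 2, p$b, "+")
    tok[((i - 1) * np + 1):(i * np), ] <- y
    pm_list[[i]] <- pm
  }
  ln <- layernorm_fwd(tok, NULL)             # non-affine token normalization
  list(out = ln$out,
       cache = list(pm = pm_list, ln = ln$cache, b = b, np = np, p = p))
}

st_patch_embed_bwd <- function(cache, dout) {
  lnb <- layernorm_bwd(cache$ln, dout)
  dtok <- lnb$dx
  p <- cache$p
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  db <- if (is.null(p$b)) NULL else numeric(ncol(p$W))
  np <- cache$np
  for (i in seq_len(cache$b)) {
    dy <- dtok[((i - 1) * np + 1):(i * np), , drop = FALSE]
    dW <- dW + crossprod(cache$pm[[i]], dy)
    if (!is.null(db)) db <- db + colSums(dy)
  }
  g <- list(W = dW)
  if (!is.null(db)) g$b <- db
  list(dx = NULL, grads = g)
}

st_add_cls_pos_fwd <- function(tok, p, b, np, dropout, training) {
  n <- np + 1L
  if (nrow(p$pos) != n) {
    stop_caspnet(sprintf(
      "token count %d + CLS does not match positional embedding rows %d",
      np, nrow(p$pos)))
  }
  dd <- ncol(tok)
  cls_rows <- (seq_len(b) - 1L) * n + 1L
  patch_rows <- setdiff(seq_len(b * n), cls_rows)
  out <- matrix(0, b * n, dd)
  out[cls_rows, ] <- rep(p$cls, each = b)
  out[patch_rows, ] <- tok
  posidx <- rep(seq_len(n), times = b)
  out <- out + p$pos[posidx, , drop = FALSE]
  dp <- dropout_fwd(out, dropout, training)
  list(out = dp$out,
       cache = list(drop = dp$cache, cls_rows = cls_rows,
                    patch_rows = patch_rows, posidx = posidx, n = n))
}

st_add_cls_pos_bwd <- function(cache, dout) {
  dd <- dropout_bwd(cache$drop, dout)
  dpos <- rowsum(dd, cache$posidx)
  dimnames(dpos) <- NULL
  dcls <- colSums(dd[cache$cls_rows, , drop = FALSE])
  dx <- dd[cache$patch_rows, , drop = FALSE]
  list(dx = dx, grads = list(cls = dcls, pos = dpos))
}

st_tok2spat_fwd <- function(tok, b, n, has_cls) {
  np <- n - as.integer(has_cls)
  g <- sqrt(np)
  if (g != floor(g)) {
    stop_caspnet(sprintf(
      "cannot reshape %d patch tokens onto a square grid (not a perfect square)",
      np))
  }
  g <- as.integer(g)
  dd <- ncol(tok)
  out <- array(0, c(g, g, dd, b))
  for (i in seq_len(b)) {
    rows <- ((i - 1) * n + 1):(i * n)
    if (has_cls) rows <- rows[-1]
    xb <- tok[rows, , drop = FALSE]
    out[, , , i] <- aperm(array(xb, c(g, g, dd)), c(2, 1, 3))
  }
  list(out = out, cache = list(b = b, n = n, g = g, dd = dd,
                               has_cls = has_cls))
}

st_tok2spat_bwd <- function(cache, dout) {
  b <- cache$b
  n <- cache$n
  g <- cache$g
  dd <- cache$dd
  dtok <- matrix(0, b * n, dd)
  for (i in seq_len(b)) {
    rows <- ((i - 1) * n + 1):(i * n)
    if (cache$has_cls) rows <- rows[-1]
    a <- aperm(array(dout[, , , i], c(g, g, dd)), c(2, 1, 3))
    dtok[rows, ] <- matrix(a, g * g, dd)
  }
  list(dx = dtok, grads = NULL)
}

st_take_cls_fwd <- function(tok, b, n) {
  cls_rows <- (seq_len(b) - 1L) * n + 1L
  list(out = tok[cls_rows, , drop = FALSE],
       cache = list(b = b, n = n, dd = ncol(tok), cls_rows = cls_rows))
}

st_take_cls_bwd <- function(cache, dout) {
  dtok <- matrix(0, cache$b * cache$n, cache$dd)
  dtok[cache$cls_rows, ] <- dout
  list(dx = dtok, grads = NULL)
}

st_csp_fwd <- function(x, p, cfg, buf, training) {
  d <- dim(x)
  if (d[3] != nrow(p$b1$conv$W)) {
    stop_caspnet(sprintf("CSP block expects %d input channels, got %d",
                         nrow(p$b1$conv$W), d[3]))
  }
  b1 <- convunit_fwd(x, p$b1, buf$b1, training)
  b2 <- convunit_fwd(x, p$b2, buf$b2, training)
  np <- d[1] * d[2]
  mid <- ncol(p$b2$conv$W)
  t2s <- vector("list", d[4])
  tok <- matrix(0, d[4] * np, mid)
  for (i in seq_len(d[4])) {
    a <- aperm(array(b2$out[, , , i], c(d[1], d[2], mid)), c(2, 1, 3))
    tok[((i - 1) * np + 1):(i * np), ] <- matrix(a, np, mid)
  }
  heads <- csp_heads(cfg)
  scale <- 1 / sqrt(mid %/% heads)
  blk <- transformer_block_fwd(tok, p$b2_block, np, heads, scale,
                               dropout = cfg$dropout,
                               attn_dropout = cfg$attn_dropout,
                               training = training)
  b2s <- array(0, c(d[1], d[2], mid, d[4]))
  for (i in seq_len(d[4])) {
    xb <- blk$out[((i - 1) * np + 1):(i * np), , drop = FALSE]
    b2s[, , , i] <- aperm(array(xb, c(d[2], d[1], mid)), c(2, 1, 3))
  }
  cat_ <- array(0, c(d[1], d[2], 2L * mid, d[4]))
  cat_[, , seq_len(mid), ] <- b1$out
  cat_[, , mid + seq_len(mid), ] <- b2s
  mg <- convunit_fwd(cat_, p$merge, buf$merge, training)
  list(out = mg$out,
       cache = list(b1 = b1$cache, b2 = b2$cache, blk = blk$cache,
                    merge = mg$cache, dims = d, mid = mid, np = np))
}

st_csp_bwd <- function(cache, dout) {
  d <- cache$dims
  mid <- cache$mid
  np <- cache$np
  mgb <- convunit_bwd(cache$merge, dout)
  dcat <- mgb$dx
  db1 <- dcat[, , seq_len(mid), , drop = FALSE]
  db2s <- dcat[, , mid + seq_len(mid), , drop = FALSE]
  dtok <- matrix(0, d[4] * np, mid)
  for (i in seq_len(d[4])) {
    a <- aperm(array(db2s[, , , i], c(d[1], d[2], mid)), c(2, 1, 3))
    dtok[((i - 1) * np + 1):(i * np), ] <- matrix(a, np, mid)
  }
  blkb <- transformer_block_bwd(cache$blk, dtok)
  db2 <- array(0, c(d[1], d[2], mid, d[4]))
  for (i in seq_len(d[4])) {
    xb <- blkb$dx[((i - 1) * np + 1):(i * np), , drop = FALSE]
    db2[, , , i] <- aperm(array(xb, c(d[2], d[1], mid)), c(2, 1, 3))
  }
  b1b <- convunit_bwd(cache$b1, db1)
  b2b <- convunit_bwd(cache$b2, db2)
  list(dx = b1b$dx + b2b$dx,
       grads = list(b1 = b1b$grads, b2 = b2b$grads, b2_block = blkb$grads,
                    merge = mgb$grads))
}

st_sppf_fwd <- function(x, p, cfg, buf, training) {
  d <- dim(x)
  if (d[3] != nrow(p$conv1$conv$W)) {
    stop_caspnet(sprintf("SPPF block expects %d input channels, got %d",
                         nrow(p$conv1$conv$W), d[3]))
  }
  c1 <- convunit_fwd(x, p$conv1, buf$conv1, training)
  k <- cfg$sppf_kernel
  m1 <- maxpool_same_fwd(c1$out, k)
  m2 <- maxpool_same_fwd(m1$out, k)
  m3 <- maxpool_same_fwd(m2$out, k)
  mid <- ncol(p$conv1$conv$W)
  cat_ <- array(0, c(d[1], d[2], 4L * mid, d[4]))
  cat_[, , seq_len(mid), ] <- c1$out
  cat_[, , mid + seq_len(mid), ] <- m1$out
  cat_[, , 2 * mid + seq_len(mid), ] <- m2$out
  cat_[, , 3 * mid + seq_len(mid), ] <- m3$out
  c2 <- convunit_fwd(cat_, p$conv2, buf$conv2, training)
  list(out = c2$out,
       cache = list(c1 = c1$cache, m1 = m1$cache, m2 = m2$cache,
                    m3 = m3$cache, c2 = c2$cache, mid = mid))
}

st_sppf_bwd <- function(cache, dout) {
  c2b <- convunit_bwd(cache$c2, dout)
  mid <- cache$mid
  dcat <- c2b$dx
  dy0 <- dcat[, , seq_len(mid), , drop = FALSE]
  dy1 <- dcat[, , mid + seq_len(mid), , drop = FALSE]
  dy2 <- dcat[, , 2 * mid + seq_len(mid), , drop = FALSE]
  dy3 <- dcat[, , 3 * mid + seq_len(mid), , drop = FALSE]
  dy2 <- dy2 + maxpool_same_bwd(cache$m3, dy3)
  dy1 <- dy1 + maxpool_same_bwd(cache$m2, dy2)
  dy0 <- dy0 + maxpool_same_bwd(cache$m1, dy1)
  c1b <- convunit_bwd(cache$c1, dy0)
  list(dx = c1b$dx, grads = list(conv1 = c1b$grads, conv2 = c2b$grads))
}

st_gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  out <- matrix(0, d[4], d[3])
  for (i in seq_len(d[4])) {
    out[i, ] <- colMeans(matrix(x[, , , i], hw, d[3]))
  }
  list(out = out, cache = list(dims = d))
}

st_gap_bwd <- function(cache, dout) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dx <- array(0, d)
  for (i in seq_len(d[4])) {
    dx[, , , i] <- array(rep(dout[i, ] / hw, each = hw), d[1:3])
  }
  list(dx = dx, grads = NULL)
}

st_head_fwd <- function(feat, p, dropout, training) {
  if (ncol(feat) != length(p$ln$g)) {
    stop_caspnet(sprintf(
      "classification head expects %d features, got %d",
      length(p$ln$g), ncol(feat)))
  }
  fcs <- grep("^fc", names(p), value = TRUE)
  nfc <- length(fcs)
  ln <- layernorm_fwd(feat, p$ln)
  h <- ln$out
  caches <- vector("list", nfc)
  for (i in seq_len(nfc)) {
    lin <- linear_fwd(h, p[[fcs[i]]])
    if (i < nfc) {
      act <- gelu_fwd(lin$out)
      dp <- dropout_fwd(act$out, dropout, training)
      h <- dp$out
      caches[[i]] <- list(lin = lin$cache, act = act$cache, drop = dp$cache)
    } else {
      h <- lin$out
      caches[[i]] <- list(lin = lin$cache)
    }
  }
  list(out = h, cache = list(ln = ln$cache, fcs = caches, fc_names = fcs))
}

st_head_bwd <- function(cache, dout) {
  nfc <- length(cache$fcs)
  g <- list()
  dh <- dout
  for (i in rev(seq_len(nfc))) {
    cc <- cache$fcs[[i]]
    if (i < nfc) {
      dh <- dropout_bwd(cc$drop, dh)
      dh <- gelu_bwd(cc$act, dh)
    }
    lb <- linear_bwd(cc$lin, dh)
    g[[cache$fc_names[i]]] <- lb$grads
    dh <- lb$dx
  }
  lnb <- layernorm_bwd(cache$ln, dh)
  g$ln <- lnb$grads
  list(dx = lnb$dx, grads = g)
}

## ---- full pipeline ---------------------------------------------------------

# Runs the variant's pipeline. Returns list(logits, records, shapes) where
# records carry per-stage caches (only populated when keep_cache = TRUE) and
# shapes the per-stage output dimensions.
caspnet_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                            collect = FALSE) {
  cfg <- model$cfg
  p <- model$params
  x <- as_image_batch(x)
  b <- dim(x)[4]
  records <- list()
  shapes <- list()
  outputs <- list()
  keep <- keep_cache || training
  push <- function(name, type, res, path = NULL) {
    records[[length(records) + 1L]] <<- list(
      name = name, type = type, path = path,
      cache = if (keep) res$cache else NULL)
    shapes[[name]] <<- dim(res$out) %||% c(length(res$out))
    if (collect) outputs[[name]] <<- res$out
    res$out
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_caspnet(sprintf("stage '%s': %s", name, conditionMessage(e)))
    })
  }

  h <- run_stage("patch_embed",
                 push("patch_embed", "patch_embed",
                      st_patch_embed_fwd(x, p$patch_embed, cfg$patch_size),
                      "patch_embed"))
  np <- nrow(h) / b
  if (cfg$variant %in% c("full", "vit_only", "vit_csp")) {
    h <- run_stage("add_cls_pos",
                   push("add_cls_pos", "add_cls_pos",
                        st_add_cls_pos_fwd(h, p, b, np, cfg$dropout, training)))
    n <- np + 1L
    for (i in seq_len(cfg$depth)) {
      nm <- paste0("block_", i)
      h <- run_stage(nm,
                     push(nm, "block",
                          transformer_block_fwd(
                            h, p$blocks[[i]], n, cfg$num_heads,
                            cfg$attn_scale, dropout = cfg$dropout,
                            attn_dropout = cfg$attn_dropout,
                            training = training),
                          c("blocks", names(p$blocks)[i])))
    }
    h <- run_stage("final_ln",
                   push("final_ln", "final_ln",
                        layernorm_fwd(h, p$final_ln), "final_ln"))
    if (cfg$variant == "vit_only") {
      h <- push("take_cls", "take_cls", st_take_cls_fwd(h, b, n))
    } else {
      h <- run_stage("tokens_to_spatial",
                     push("tokens_to_spatial", "tok2spat",
                          st_tok2spat_fwd(h, b, n, TRUE)))
    }
  } else {
    h <- run_stage("tokens_to_spatial",
                   push("tokens_to_spatial", "tok2spat",
                        st_tok2spat_fwd(h, b, np, FALSE)))
  }
  if (cfg$variant %in% c("full", "vit_csp", "csp_sppf_only")) {
    h <- run_stage("csp",
                   push("csp", "csp",
                        st_csp_fwd(h, p$csp, cfg, model$buffers$csp, training),
                        "csp"))
    if (cfg$variant != "vit_csp") {
      h <- run_stage("sppf",
                     push("sppf", "sppf",
                          st_sppf_fwd(h, p$sppf, cfg, model$buffers$sppf,
                                      training),
                          "sppf"))
    }
    h <- push("gap", "gap", st_gap_fwd(h))
  }
  logits <- run_stage("head",
                      push("head", "head",
                           st_head_fwd(h, p$head, cfg$dropout, training),
                           "head"))
  list(logits = logits, records = records, shapes = shapes,
       outputs = if (collect) outputs else NULL)
}

# Walks records in reverse. `stop_before` names a stage: the walk halts when
# that stage would be processed next and returns the gradient flowing into it
# (i.e. the gradient of the loss w.r.t. that stage's OUTPUT is returned just
# after its successor is processed).
caspnet_backward <- function(model, fwd, dlogits, stop_after = NULL) {
  grads <- list()
  dh <- dlogits
  recs <- fwd$records
  for (i in rev(seq_along(recs))) {
    r <- recs[[i]]
    if (!is.null(stop_after) && r$name == stop_after) {
      return(list(grads = grads, dstage = dh, stage = stop_after))
    }
    res <- switch(r$type,
      patch_embed = st_patch_embed_bwd(r$cache, dh),
      add_cls_pos = st_add_cls_pos_bwd(r$cache, dh),
      block = transformer_block_bwd(r$cache, dh),
      final_ln = layernorm_bwd(r$cache, dh),
      take_cls = st_take_cls_bwd(r$cache, dh),
      tok2spat = st_tok2spat_bwd(r$cache, dh),
      csp = st_csp_bwd(r$cache, dh),
      sppf = st_sppf_bwd(r$cache, dh),
      gap = st_gap_bwd(r$cache, dh),
      head = st_head_bwd(r$cache, dh),
      stop_caspnet("unknown stage type: ", r$type))
    dh <- res$dx
    if (!is.null(res$grads)) {
      if (identical(r$type, "add_cls_pos")) {
        grads[["cls"]] <- res$grads$cls
        grads[["pos"]] <- res$grads$pos
      } else {
        prefix <- paste(r$path, collapse = ".")
        flat <- flatten_params(res$grads, prefix)
        for (nm in names(flat)) {
          grads[[nm]] <- if (is.null(grads[[nm]])) flat[[nm]] else
            grads[[nm]] + flat[[nm]]
        }
      }
    }
  }
  list(grads = grads, dstage = NULL, stage = NULL)
}

## ---- exported module operations -------------------------------------------

#' Patch embedding
#'
#' Cuts each image into non-overlapping `patch_size` x `patch_size` patches
#' (row-major over the patch grid), projects each flattened patch with the
#' model's learned linear map, and normalizes every token over the embedding
#' axis (non-affine LayerNorm). A 224x224x3 input with patch 16 yields 196
#' tokens of dimension 768.
#'
#' @param model A `caspnet` model.
#' @param images `(H, W, C)` or `(H, W, C, B)` array; H and W must be
#'   divisible by the configured patch size.
#' @param tokens A `(B, N, D)` token array.
#' @param training Logical; enables dropout where the operation has any.
#' @return `embed_patches()`: a `(B, N, D)` token array;
#'   `add_cls_and_pos()`: a `(B, N + 1, D)` array with the class token at
#'   position 1 and positional embeddings added.
#' @export
embed_patches <- function(model, images) {
  x <- as_image_batch(images)
  res <- st_patch_embed_fwd(x, model$params$patch_embed,
                            model$cfg$patch_size)
  tokens_from_mat(res$out, dim(x)[4], nrow(res$out) / dim(x)[4])
}

#' @rdname embed_patches
#' @export
add_cls_and_pos <- function(model, tokens, training = FALSE) {
  stopifnot(length(dim(tokens)) == 3L)
  b <- dim(tokens)[1]
  np <- dim(tokens)[2]
  res <- st_add_cls_pos_fwd(mat_from_tokens(tokens), model$params, b, np,
                            model$cfg$dropout, training)
  tokens_from_mat(res$out, b, np + 1L)
}

#' Apply one transformer block
#'
#' Pre-norm residual form: `x <- x + MHSA(LN(x)); x <- x + MLP(LN(x))`, with
#' per-head attention weights `softmax(Q K^T * scale)` and a GELU MLP
#' expanding D to `mlp_ratio * D` and back.
#'
#' @param tokens `(B, N, D)` token array.
#' @param params A block parameter list with components `ln1`,
#'   `attn = list(qkv = list(W, b), proj = list(W, b))`, `ln2`, `fc1`, `fc2`
#'   (the structure stored in `model$params$blocks[[i]]`).
#' @param num_heads Number of attention heads (must divide D).
#' @param scale Attention logit scale; defaults to `1/sqrt(D / num_heads)`.
#' @param dropout,attn_dropout Dropout probabilities (training mode only).
#' @param training Logical.
#' @return Token array of the same shape.
#' @export
transformer_block <- function(tokens, params, num_heads, scale = NULL,
                              dropout = 0, attn_dropout = 0,
                              training = FALSE) {
  stopifnot(length(dim(tokens)) == 3L)
  d <- dim(tokens)[3]
  if (d %% num_heads != 0) {
    stop_caspnet(sprintf("token dim %d not divisible by num_heads %d",
                         d, num_heads))
  }
  scale <- scale %||% (1 / sqrt(d %/% num_heads))
  res <- transformer_block_fwd(mat_from_tokens(tokens), params,
                               dim(tokens)[2], num_heads, scale,
                               dropout = dropout,
                               attn_dropout = attn_dropout,
                               training = training)
  tokens_from_mat(res$out, dim(tokens)[1], dim(tokens)[2])
}

#' Run the transformer encoder
#'
#' Applies the model's `depth` transformer blocks in sequence (the final
#' encoder LayerNorm is a separate stage of the full pipeline and is not
#' applied here, so composing [transformer_block()] manually reproduces this
#' function exactly).
#'
#' @inheritParams embed_patches
#' @return Token array of the same shape as the input.
#' @export
run_encoder <- function(model, tokens, training = FALSE) {
  stopifnot(length(dim(tokens)) == 3L)
  cfg <- model$cfg
  h <- mat_from_tokens(tokens)
  n <- dim(tokens)[2]
  for (i in seq_len(cfg$depth)) {
    res <- tryCatch(
      transformer_block_fwd(h, model$params$blocks[[i]], n, cfg$num_heads,
                            cfg$attn_scale, dropout = cfg$dropout,
                            attn_dropout = cfg$attn_dropout,
                            training = training),
      error = function(e) {
        stop_caspnet(sprintf("encoder block %d: %s", i, conditionMessage(e)))
      })
    h <- res$out
  }
  tokens_from_mat(h, dim(tokens)[1], n)
}

#' Token-to-grid reshape (inverse patch embedding) and its inverse
#'
#' `tokens_to_spatial()` discards the class token (when `cls = TRUE`), lays
#' the remaining N - 1 tokens row-major onto a square grid (token k, counted
#' 1..196 among patch tokens, lands at grid row `(k-1) %/% 14`, column
#' `(k-1) %% 14` in the default geometry) and returns a channel map. The
#' operation has no trainable parameters and `spatial_to_tokens()` inverts
#' it exactly.
#'
#' @param tokens `(B, N, D)` token array; `N - cls` must be a perfect square.
#' @param cls Logical; drop the leading class token first.
#' @param x Spatial map `(H, W, C, B)`.
#' @return `tokens_to_spatial()`: an `(H, W, D, B)` array with H = W =
#'   `sqrt(N - cls)`; `spatial_to_tokens()`: a `(B, H*W, C)` token array.
#' @export
tokens_to_spatial <- function(tokens, cls = TRUE) {
  stopifnot(length(dim(tokens)) == 3L)
  res <- st_tok2spat_fwd(mat_from_tokens(tokens), dim(tokens)[1],
                         dim(tokens)[2], cls)
  res$out
}

#' @rdname tokens_to_spatial
#' @export
spatial_to_tokens <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  np <- d[1] * d[2]
  tok <- array(0, c(d[4], np, d[3]))
  for (i in seq_len(d[4])) {
    a <- aperm(array(x[, , , i], d[1:3]), c(2, 1, 3))
    tok[i, , ] <- matrix(a, np, d[3])
  }
  tok
}

#' CSP and SPPF blocks
#'
#' `csp_block()` runs the cross-stage-partial fusion: two parallel 1x1
#' conv units reduce the input channels to the mid width; branch 2 is
#' additionally flattened to tokens and passed through one transformer block
#' before both branches are concatenated and merged by a 1x1 conv unit back
#' to the input width. `sppf_block()` is spatial-pyramid-pooling-fast: a 1x1
#' reduction followed by three cascaded same-padded max pools (kernel 5,
#' stride 1), channel concatenation of all four maps and a 1x1 merge conv.
#' Conv units are Conv -> SiLU (optionally Conv -> BN -> SiLU).
#'
#' @param model A `caspnet` model whose variant contains the block.
#' @param x Spatial map `(H, W, C, B)` with C equal to the configured width.
#' @param training Logical.
#' @return Spatial map of identical shape.
#' @export
csp_block <- function(model, x, training = FALSE) {
  if (is.null(model$params$csp)) {
    stop_caspnet("this model variant has no CSP block")
  }
  st_csp_fwd(x, model$params$csp, model$cfg, model$buffers$csp, training)$out
}

#' @rdname csp_block
#' @export
sppf_block <- function(model, x, training = FALSE) {
  if (is.null(model$params$sppf)) {
    stop_caspnet("this model variant has no SPPF block")
  }
  st_sppf_fwd(x, model$params$sppf, model$cfg, model$buffers$sppf,
              training)$out
}

#' Global average pooling
#'
#' Arithmetic mean over both spatial dimensions, per channel and sample.
#'
#' @param x Spatial map `(H, W, C, B)`.
#' @return A `(B, C)` feature matrix.
#' @export
global_average_pool <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  st_gap_fwd(x)$out
}

#' Classification head
#'
#' LayerNorm, then the configured stack of linear layers with GELU and
#' dropout between them (default 768 -> 512 -> 256 -> K). Returns raw
#' logits; no softmax is applied.
#'
#' @param model A `caspnet` model.
#' @param features `(B, D)` feature matrix.
#' @param training Logical.
#' @return `(B, K)` logit matrix.
#' @export
classification_head <- function(model, features, training = FALSE) {
  st_head_fwd(features, model$params$head, model$cfg$dropout, training)$out
}

#' Full forward pass
#'
#' Runs the model variant's complete pipeline on a batch of preprocessed
#' images and returns the class logits. Deterministic in evaluation mode.
#'
#' @param model A `caspnet` model.
#' @param images `(H, W, C)` or `(H, W, C, B)` array of standardized images.
#' @param training Logical; enables dropout.
#' @param collect Logical; when `TRUE` the result carries the per-stage
#'   output shapes as attribute `"shapes"`.
#' @return `(B, K)` logit matrix.
#' @export
forward_caspnet <- function(model, images, training = FALSE,
                            collect = FALSE) {
  fw <- caspnet_forward(model, images, training = training,
                        keep_cache = FALSE, collect = FALSE)
  out <- fw$logits
  if (collect) attr(out, "shapes") <- fw$shapes
  out
}

#' Predict classes or probabilities
#'
#' @param object A `caspnet` model.
#' @param newdata An image array (`(H, W, C)` or `(H, W, C, B)`, values in
#'   `[0, 1]` unless `preprocess = FALSE`) or a dataset returned by
#'   [load_dataset()].
#' @param type `"class"` (default), `"prob"` or `"logit"`.
#' @param batch_size Mini-batch size for the forward passes.
#' @param preprocess Apply [eval_transform()] (resize to the model geometry
#'   and standardize) before the forward pass.
#' @param ... Unused.
#' @return Class indices (integer, 1-based), a probability matrix, or a
#'   logit matrix, one row per image.
#' @export
predict.caspnet <- function(object, newdata, type = c("class", "prob",
                                                      "logit"),
                            batch_size = 16L, preprocess = TRUE, ...) {
  type <- match.arg(type)
  side <- object$cfg$image_size
  if (inherits(newdata, "image_set")) {
    imgs <- load_images(newdata, side)
  } else if (preprocess) {
    x <- as_image_batch(newdata)
    nb <- dim(x)[4]
    imgs <- array(0, c(side, side, dim(x)[3], nb))
    for (i in seq_len(nb)) {
      imgs[, , , i] <- eval_transform(array(x[, , , i], dim(x)[1:3]),
                                      size = side)
    }
  } else {
    imgs <- as_image_batch(newdata)
  }
  nb <- dim(imgs)[4]
  logits <- NULL
  for (start in seq(1L, nb, by = batch_size)) {
    idx <- start:min(nb, start + batch_size - 1L)
    lg <- caspnet_forward(object, imgs[, , , idx, drop = FALSE])$logits
    logits <- rbind(logits, lg)
  }
  switch(type,
         logit = logits,
         prob = softmax_rows(logits),
         class = max.col(logits, ties.method = "first"))
}
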