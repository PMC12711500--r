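test_that("patch embedding matches an explicit patch-loop oracle", {
  m <- tiny_model()
  set.seed(11)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  tok <- embed_patches(m, x)
  expect_equal(dim(tok), c(2L, 16L, 32L))

  w <- m$params$patch_embed$W
  b <- m$params$patch_embed$b
  for (bi in 1:2) {
    k <- 0L
    for (r in 0:3) {
      for (cc in 0:3) {
        k <- k + 1L
        patch <- x[(r * 8 + 1):(r * 8 + 8), (cc * 8 + 1):(cc * 8 + 8), , bi]
        v <- as.vector(patch) %*% w + b
        z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-6)
        expect_equal(as.vector(tok[bi, k, ]), as.vector(z),
                     tolerance = 1e-5)
      }
    }
  }

  # a 32x32 image with patch 16 yields (32/16)^2 = 4 tokens
  m16 <- caspnet(config = arch_config(image_size = 32, patch_size = 16,
                                      embed_dim = 16, depth = 1,
                                      num_heads = 2, csp_mid = 8,
                                      sppf_mid = 8, head_hidden = c(8, 4),
                                      num_classes = 2), seed = 1)
  expect_equal(dim(embed_patches(m16, x))[2], 4L)
  expect_error(embed_patches(m, array(0, c(30, 32, 3, 1))), "30")
})

test_that("class token and positional embedding behave as specified", {
  m <- tiny_model()
  tok <- embed_patches(m, array(rnorm(32 * 32 * 3), c(32, 32, 3, 1)))
  out <- add_cls_and_pos(m, tok)
  expect_equal(dim(out), c(1L, 17L, 32L))

  # zero cls/pos in eval mode: the patch tokens pass through unchanged
  m0 <- m
  m0$params$cls[] <- 0
  m0$params$pos[] <- 0
  out0 <- add_cls_and_pos(m0, tok)
  expect_equal(out0[, -1, , drop = FALSE], tok)
  expect_equal(sum(abs(out0[1, 1, ])), 0)

  # token-count mismatch with the stored positional table
  expect_error(add_cls_and_pos(m, tok[, 1:9, , drop = FALSE]),
               "positional")

  # train-mode dropout: ~10% of activations zeroed, the rest scaled 1/0.9
  m1 <- m0
  big <- array(1, c(1, 17, 32))
  ndraw <- 200L
  zeros <- 0L
  total <- 0L
  set.seed(99)
  for (i in seq_len(ndraw)) {
    o <- add_cls_and_pos(m1, big[, -1, , drop = FALSE] + 0, training = TRUE)
    op <- o[, -1, , drop = FALSE]          # patch tokens (cls is zero anyway)
    zeros <- zeros + sum(op == 0)
    total <- total + length(op)
    expect_true(all(abs(op[op != 0] - 1 / 0.9) < 1e-12))
  }
  p_hat <- zeros / total
  sigma <- sqrt(0.1 * 0.9 / total)
  expect_true(abs(p_hat - 0.1) < 3 * sigma + 1e-6)
})

test_that("attention matches a loop-based softmax(QK^T/sqrt(d)) V oracle", {
  # 2-token toy with hand-set 4-dim single-head weights
  set.seed(5)
  d <- 4L
  params <- list(qkv = list(W = matrix(round(rnorm(d * 3 * d), 1), d, 3 * d),
                            b = round(rnorm(3 * d), 1)),
                 proj = list(W = diag(d), b = numeric(d)))
  x <- matrix(round(rnorm(2 * d), 1), 2, d)
  res <- caspnet:::attention_fwd(x, params, n_tokens = 2L, num_heads = 1L,
                                 scale = 1 / sqrt(d))
  want <- oracle_attention(x,
                           params$qkv$W[, 1:d], params$qkv$b[1:d],
                           params$qkv$W[, d + 1:d], params$qkv$b[d + 1:d],
                           params$qkv$W[, 2 * d + 1:d],
                           params$qkv$b[2 * d + 1:d],
                           1 / sqrt(d))
  expect_equal(res$out, want, tolerance = 1e-6)

  # attention rows are probability distributions
  m <- tiny_model()
  tok <- matrix(rnorm(3 * 17 * 32), 3 * 17, 32)
  att <- caspnet:::attention_fwd(tok, m$params$blocks[[1]]$attn,
                                 n_tokens = 17L, num_heads = 2L,
                                 scale = m$cfg$attn_scale)
  for (bp in att$cache$probs) {
    for (pr in bp) {
      expect_true(all(pr >= 0))
      expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
    }
  }

  # single token: softmax over one key is 1, so out = proj(value(x))
  x1 <- matrix(rnorm(d), 1, d)
  res1 <- caspnet:::attention_fwd(x1, params, n_tokens = 1L, num_heads = 1L,
                                  scale = 1 / sqrt(d))
  v1 <- x1 %*% params$qkv$W[, 2 * d + 1:d] + params$qkv$b[2 * d + 1:d]
  expect_equal(res1$out, v1 %*% params$proj$W, tolerance = 1e-8)
})

test_that("encoder composes transformer blocks and preserves shape", {
  m <- tiny_model()
  set.seed(2)
  tok <- array(rnorm(2 * 17 * 32), c(2, 17, 32))
  enc <- run_encoder(m, tok)
  expect_equal(dim(enc), dim(tok))

  manual <- tok
  for (i in 1:2) {
    manual <- transformer_block(manual, m$params$blocks[[i]],
                                num_heads = m$cfg$num_heads,
                                scale = m$cfg$attn_scale)
  }
  expect_equal(enc, manual, tolerance = 1e-6)
})

test_that("token-to-grid reshape is row-major, invertible and parameter-free", {
  set.seed(7)
  b <- 2L
  n <- 17L
  d <- 5L
  tok <- array(rnorm(b * n * d), c(b, n, d))
  sp <- tokens_to_spatial(tok, cls = TRUE)
  expect_equal(dim(sp), c(4L, 4L, d, b))
  # patch token k (1-indexed) lands at grid (floor((k-1)/4), (k-1) mod 4)
  for (k in 1:16) {
    r <- (k - 1) %/% 4 + 1L
    cc <- (k - 1) %% 4 + 1L
    expect_equal(sp[r, cc, , 1], tok[1, k + 1L, ])
  }
  # exact round trip
  back <- spatial_to_tokens(sp)
  expect_identical(back, tok[, -1, , drop = FALSE] + 0)

  expect_error(tokens_to_spatial(tok[, 1:6, , drop = FALSE], cls = TRUE),
               "perfect square")

  # the reshape adds no trainable parameters: the full pipeline's count
  # equals the sum over its parameterized modules alone
  m <- tiny_model()
  expect_equal(count_parameters(m),
               sum(vapply(caspnet:::flatten_params(m$params), length,
                          numeric(1))))
})

test_that("CSP block: shape, zero propagation and parameter count", {
  m <- tiny_model()
  x <- array(rnorm(4 * 4 * 32 * 2), c(4, 4, 32, 2))
  out <- csp_block(m, x)
  expect_equal(dim(out), dim(x))

  # zero input with zero biases stays zero through both branches
  m0 <- m
  fp <- caspnet:::flatten_params(m0$params)
  for (nm in grep("^csp\\.", names(fp), value = TRUE)) {
    if (endsWith(nm, ".b") || endsWith(nm, ".g")) {
      if (endsWith(nm, ".b")) fp[[nm]][] <- 0
    }
  }
  m0$params <- caspnet:::unflatten_params(fp, m0$params)
  z <- csp_block(m0, array(0, dim(x)))
  expect_equal(max(abs(z)), 0)

  # parameter count of the default-width block: hand-summed 2,955,648
  mfull <- cached("csp_count_model", {
    caspnet("csp_sppf_only", arch_config(), seed = 1)
  })
  expect_equal(caspnet:::param_breakdown(mfull)[["csp"]], 2955648)
  expect_error(csp_block(m, array(0, c(4, 4, 7, 1))), "channels")
})

test_that("SPPF cascade equals single pools with effective kernels 9 and 13", {
  set.seed(13)
  x <- array(rnorm(14 * 14 * 4 * 1), c(14, 14, 4, 1))
  m1 <- caspnet:::maxpool_same_fwd(x, 5)$out
  m2 <- caspnet:::maxpool_same_fwd(m1, 5)$out
  m3 <- caspnet:::maxpool_same_fwd(m2, 5)$out
  expect_equal(m1, oracle_window_max(x, 5), tolerance = 1e-12)
  expect_equal(m2, oracle_window_max(x, 9), tolerance = 1e-12)
  expect_equal(m3, oracle_window_max(x, 13), tolerance = 1e-12)

  # constant map: every pooled map equals the input exactly
  const <- array(3.5, c(6, 6, 2, 1))
  expect_equal(caspnet:::maxpool_same_fwd(const, 5)$out, const)

  m <- tiny_model()
  out <- sppf_block(m, array(rnorm(4 * 4 * 32 * 3), c(4, 4, 32, 3)))
  expect_equal(dim(out), c(4L, 4L, 32L, 3L))

  # concat width before the merge conv is 4 x mid (1536 at default width)
  expect_equal(nrow(m$params$sppf$conv2$conv$W), 4L * m$cfg$sppf_mid)
  mdef <- cached("csp_count_model", caspnet("csp_sppf_only", arch_config(),
                                            seed = 1))
  expect_equal(nrow(mdef$params$sppf$conv2$conv$W), 1536L)
  expect_equal(caspnet:::param_breakdown(mdef)[["sppf"]], 1475712)
})

test_that("global average pooling is the per-channel arithmetic mean", {
  set.seed(3)
  x <- array(rnorm(2 * 2 * 3 * 1), c(2, 2, 3, 1))
  g <- global_average_pool(x)
  for (ch in 1:3) {
    expect_equal(g[1, ch],
                 (x[1, 1, ch, 1] + x[1, 2, ch, 1] + x[2, 1, ch, 1] +
                    x[2, 2, ch, 1]) / 4)
  }
  const <- array(2.25, c(5, 5, 4, 2))
  expect_equal(global_average_pool(const), matrix(2.25, 2, 4))
})

test_that("classification head: widths, zero-weight logits, parameter count", {
  m <- tiny_model()
  f <- matrix(rnorm(3 * 32), 3, 32)
  lg <- classification_head(m, f)
  expect_equal(dim(lg), c(3L, 2L))

  # all-zero weights and biases give zero logits, i.e. uniform softmax
  m0 <- m
  fp <- caspnet:::flatten_params(m0$params)
  for (nm in grep("^head\\.", names(fp), value = TRUE)) fp[[nm]][] <- 0
  m0$params <- caspnet:::unflatten_params(fp, m0$params)
  lg0 <- classification_head(m0, f)
  expect_equal(max(abs(lg0)), 0)
  expect_equal(caspnet:::softmax_rows(lg0)[1, ], rep(0.5, 2))

  # default head 768 -> 512 -> 256 -> 5: hand-summed 527,877
  mdef <- cached("csp_count_model", caspnet("csp_sppf_only", arch_config(),
                                            seed = 1))
  expect_equal(caspnet:::param_breakdown(mdef)[["head"]], 527877)
  expect_error(classification_head(m, matrix(0, 1, 7)), "features")
})

test_that("full forward: shapes, determinism, batch equivariance", {
  m <- tiny_model()
  set.seed(21)
  x <- array(rnorm(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  lg <- forward_caspnet(m, x, collect = TRUE)
  expect_equal(dim(lg), c(3L, 2L))
  expect_true(all(is.finite(lg)))
  sh <- attr(lg, "shapes")
  expect_equal(sh$tokens_to_spatial, c(4L, 4L, 32L, 3L))
  expect_equal(sh$gap, c(3L, 32L))

  # eval mode is bitwise deterministic
  expect_identical(as.vector(forward_caspnet(m, x)),
                   as.vector(forward_caspnet(m, x)))

  # permuting the batch permutes the logits identically
  perm <- c(3L, 1L, 2L)
  lg_p <- forward_caspnet(m, x[, , , perm, drop = FALSE])
  expect_equal(lg_p, lg[perm, ], tolerance = 1e-12, ignore_attr = TRUE)

  # softmax rows are unit-sum probability vectors
  pr <- caspnet:::softmax_rows(lg)
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-6)
})

test_that("ablation variants share the config and differ as specified", {
  for (v in c("full", "vit_only", "csp_sppf_only", "vit_csp")) {
    mv <- tiny_model(v)
    x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    lg <- forward_caspnet(mv, x)
    expect_equal(dim(lg), c(2L, 2L))
  }
  # vit_csp = full minus the SPPF block's parameters
  m_full <- tiny_model("full")
  m_nos <- tiny_model("vit_csp")
  sppf_n <- sum(vapply(caspnet:::flatten_params(m_full$params["sppf"]),
                       length, numeric(1)))
  expect_equal(count_parameters(m_full) - count_parameters(m_nos), sppf_n)

  # csp_sppf_only carries no encoder: no blocks, cls or pos entries
  m_conv <- tiny_model("csp_sppf_only")
  expect_false(any(c("blocks", "cls", "pos", "final_ln") %in%
                     names(m_conv$params)))
  expect_true("b2_block" %in% names(m_conv$params$csp))

  # vit_only keeps no conv stage
  m_vit <- tiny_model("vit_only")
  expect_false(any(c("csp", "sppf") %in% names(m_vit$params)))
})

test_that("checkpoints round-trip bitwise", {
  m <- tiny_model(seed = 9)
  path <- tempfile(fileext = ".rds")
  save_caspnet(m, path)
  m2 <- load_caspnet(path)
  expect_identical(m$params, m2$params)
  expect_equal(unclass(m$cfg), unclass(m2$cfg))
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(forward_caspnet(m, x), forward_caspnet(m2, x))
  unlink(path)
})
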