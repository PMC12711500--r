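# Shared fixtures and independent oracles for the test suite.

# A depth-reduced configuration small enough for oracle comparisons.
tiny_cfg <- function(...) {
  args <- list(image_size = 32L, patch_size = 8L, embed_dim = 32L,
               depth = 2L, num_heads = 2L, csp_mid = 16L, sppf_mid = 16L,
               head_hidden = c(32L, 16L), num_classes = 2L)
  do.call(arch_config, utils::modifyList(args, list(...)))
}

tiny_model <- function(variant = "full", seed = 1L, ...) {
  caspnet(variant = variant, config = tiny_cfg(...), seed = seed)
}

# Session-level cache (fixture trees, trained models) so expensive objects
# are built once.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

two_class_fixture <- function() {
  cached("two_class_fixture", {
    dir <- file.path(tempdir(), "caspnet-two-class")
    set <- generate_fixtures(fixture_profile("two_class"), dir)
    list(dir = dir, set = set, manifest = attr(set, "manifest"))
  })
}

# Overfit run shared by the learning-sanity and Grad-CAM localization tests:
# image 56 px, patch 8 (7x7 grid), embed 32, depth 2 -- a depth-reduced
# configuration trained 200 steps on the 64-image two-class fixture.
overfit_fit <- function() {
  cached("overfit_fit", {
    fx <- two_class_fixture()
    side <- 56L
    n <- length(fx$set)
    imgs <- array(0, c(side, side, 3L, n))
    for (i in seq_len(n)) {
      imgs[, , , i] <- eval_transform(read_image(fx$set$items$path[i]),
                                      size = side)
    }
    labels <- fx$set$items$class_idx
    cfg <- arch_config(image_size = side, patch_size = 8L, embed_dim = 32L,
                       depth = 2L, num_heads = 2L, csp_mid = 16L,
                       sppf_mid = 16L, head_hidden = c(32L, 16L),
                       num_classes = 2L)
    model <- caspnet(config = cfg, seed = 42L)
    # the published peak learning rate; it reaches perfect training
    # accuracy within the step budget without driving the loss so far
    # toward zero that the feature maps degenerate for Grad-CAM
    tcfg <- training_config(max_lr = 1e-3, batch_size = 16L, epochs = 50L,
                            seed = 7L)
    fit <- caspnet_train(model, list(images = imgs, labels = labels),
                         config = tcfg, steps = 200L)
    list(fit = fit, images = imgs, labels = labels, fx = fx, side = side)
  })
}

# ---- independent oracles ---------------------------------------------------

# explicit-loop scaled dot-product attention: X (n x d), one head set
oracle_attention <- function(x, wq, bq, wk, bk, wv, bv, scale) {
  n <- nrow(x)
  q <- x %*% wq + matrix(bq, n, length(bq), byrow = TRUE)
  k <- x %*% wk + matrix(bk, n, length(bk), byrow = TRUE)
  v <- x %*% wv + matrix(bv, n, length(bv), byrow = TRUE)
  out <- matrix(0, n, ncol(v))
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(q[i, ] * k[j, ]) * scale
    p <- exp(s - max(s))
    p <- p / sum(p)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + p[j] * v[j, ]
  }
  out
}

# brute-force same-padded sliding-window maximum, kernel k (odd)
oracle_window_max <- function(x, k) {
  d <- dim(x)
  r <- (k - 1) %/% 2
  out <- array(-Inf, d)
  for (b in seq_len(d[4])) {
    for (ch in seq_len(d[3])) {
      for (i in seq_len(d[1])) {
        for (j in seq_len(d[2])) {
          ii <- max(1, i - r):min(d[1], i + r)
          jj <- max(1, j - r):min(d[2], j + r)
          out[i, j, ch, b] <- max(x[ii, jj, ch, b])
        }
      }
    }
  }
  out
}

# per-sample brute-force metrics for class ci
oracle_class_metrics <- function(truth, pred, ci) {
  tp <- sum(truth == ci & pred == ci)
  fp <- sum(truth != ci & pred == ci)
  fn <- sum(truth == ci & pred != ci)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

# Mann-Whitney AUC by exhaustive pair enumeration (ties credit 1/2)
oracle_mw_auc <- function(score, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# hand-coded AdamW recurrence on a vector parameter
oracle_adamw <- function(theta, grads_list, lr, b1, b2, eps, lambda) {
  m <- 0 * theta
  v <- 0 * theta
  t <- 0
  for (g in grads_list) {
    t <- t + 1
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps) - lr * lambda * theta
  }
  theta
}
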