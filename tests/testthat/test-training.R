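test_that("cross-entropy matches closed forms and hand computation", {
  # uniform prediction over C classes costs log(C), for several C
  for (k in c(2L, 5L, 9L)) {
    expect_equal(cross_entropy(matrix(0, 3, k), rep(1L, 3))$loss, log(k),
                 tolerance = 1e-12)
  }
  # logits (2, 1, 0), label 1: -log(e^2 / (e^2 + e^1 + e^0)) = 0.40761
  ce <- cross_entropy(matrix(c(2, 1, 0), 1, 3), 1L)
  expect_equal(ce$loss, -log(exp(2) / sum(exp(c(2, 1, 0)))),
               tolerance = 1e-12)
  expect_equal(round(ce$loss, 5), 0.40761)
  # perfect prediction drives the loss to zero
  expect_lt(cross_entropy(matrix(c(50, 0, 0), 1, 3), 1L)$loss, 1e-20)
  # probability rows are normalized
  ce2 <- cross_entropy(matrix(rnorm(12), 4, 3), c(1L, 2L, 3L, 1L))
  expect_equal(rowSums(ce2$probs), rep(1, 4), tolerance = 1e-6)
  # labels are validated per sample
  expect_error(cross_entropy(matrix(0, 2, 3), c(1L, 7L)), "sample 2")
})

test_that("cross-entropy gradient matches finite differences", {
  set.seed(17)
  logits <- matrix(rnorm(4 * 3), 4, 3)
  labels <- c(1L, 3L, 2L, 2L)
  g <- caspnet:::cross_entropy_grad(logits, labels)
  eps <- 1e-6
  for (i in 1:4) {
    for (j in 1:3) {
      lp <- logits
      lp[i, j] <- lp[i, j] + eps
      lm <- logits
      lm[i, j] <- lm[i, j] - eps
      fd <- (cross_entropy(lp, labels)$loss -
               cross_entropy(lm, labels)$loss) / (2 * eps)
      expect_equal(g[i, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("weight-decay penalty: closed form, zero case, reshape invariance", {
  expect_equal(weight_decay_penalty(c(3, 4), 0.1), 2.5)
  expect_equal(weight_decay_penalty(rnorm(100), 0), 0)
  v <- rnorm(12)
  expect_equal(weight_decay_penalty(v, 0.3),
               weight_decay_penalty(matrix(v, 3, 4), 0.3))
  expect_equal(weight_decay_penalty(list(a = v[1:6],
                                         b = matrix(v[7:12], 2, 3)), 0.3),
               weight_decay_penalty(v, 0.3))
  # model form excludes norms, biases and embeddings from decay
  m <- tiny_model()
  flat <- caspnet:::flatten_params(m$params)
  keep <- caspnet:::decay_mask(names(flat))
  manual <- 0.05 * sum(vapply(flat[keep], function(a) sum(a^2), numeric(1)))
  expect_equal(weight_decay_penalty(m, 0.05), manual)
  expect_false(any(grepl("ln|cls|pos|\\.b$", names(flat)[keep])))
})

test_that("AdamW single-step and pure-decay closed forms hold", {
  cfg <- training_config()
  # zero gradient, zero state: update is pure decay, 1 - lr*lambda
  st <- adamw_init(list(W = 1))
  st2 <- adamw_step(st, list(W = 0), lr = 0.001, cfg)
  expect_equal(st2$params$W, 1 - 0.001 * 0.05 * 1, tolerance = 1e-15)
  expect_equal(st2$params$W, 0.99995)

  # first step with g = 0.5, lambda = 0: mhat = 0.5, vhat = 0.25,
  # update ~ -lr * 0.5 / (0.5 + eps) ~ -lr
  cfg0 <- training_config(weight_decay = 0)
  st <- adamw_init(list(W = 0))
  st <- adamw_step(st, list(W = 0.5), lr = 0.001, cfg0)
  expect_equal(st$m$W, 0.05, tolerance = 1e-12)
  expect_equal(st$v$W, 0.00025, tolerance = 1e-12)   # pre-correction
  expect_equal(st$params$W, -0.001 * 0.5 / (0.5 + cfg0$epsilon),
               tolerance = 1e-12)
  expect_equal(st$params$W, -0.001, tolerance = 1e-6)

  # non-finite gradients are rejected with the group name
  expect_error(adamw_step(adamw_init(list(bad = 1)), list(bad = NaN),
                          0.01, cfg), "bad")
})

test_that("AdamW trajectory matches an independent recurrence oracle", {
  cfg <- training_config(weight_decay = 0.04)
  set.seed(23)
  theta0 <- rnorm(5)
  grads <- lapply(1:10, function(i) rnorm(5))
  st <- adamw_init(list(W = theta0))
  for (g in grads) st <- adamw_step(st, list(W = g), lr = 0.01, cfg)
  want <- oracle_adamw(theta0, grads, 0.01, 0.9, 0.999, 1e-8, 0.04)
  expect_equal(st$params$W, want, tolerance = 1e-10)

  # with lambda = 0 AdamW reduces to Adam (oracle with no decay term)
  cfg0 <- training_config(weight_decay = 0)
  st0 <- adamw_init(list(W = theta0))
  for (g in grads) st0 <- adamw_step(st0, list(W = g), lr = 0.01, cfg0)
  adam <- oracle_adamw(theta0, grads, 0.01, 0.9, 0.999, 1e-8, 0)
  expect_equal(st0$params$W, adam, tolerance = 1e-12)
})

test_that("one-cycle schedule: endpoints, peak, unimodality, continuity", {
  cfg <- training_config()
  total <- 500L
  expect_equal(one_cycle_lr(0, total, cfg), 1e-4)
  expect_equal(one_cycle_lr(0.1 * total, total, cfg), 1e-3)
  expect_equal(one_cycle_lr(total, total, cfg), 1e-5, tolerance = 1e-12)

  lr <- one_cycle_lr(0:total, total, cfg)
  peak <- which.max(lr)
  expect_true(all(diff(lr[1:peak]) >= -1e-15))          # rises once
  expect_true(all(diff(lr[peak:length(lr)]) <= 1e-15))  # then falls
  # step bound from the cosine derivative: the warmup segment is steepest
  bound <- pi * (cfg$max_lr - cfg$final_lr) / (2 * 0.1 * total) + 1e-12
  expect_true(all(abs(diff(lr)) <= bound))
  expect_error(one_cycle_lr(-1, total, cfg), "lie in")
  expect_error(one_cycle_lr(total + 1, total, cfg), "lie in")
})

test_that("training configuration invariants are enforced", {
  expect_error(training_config(initial_lr = 0), "initial_lr")
  expect_error(training_config(initial_lr = 2e-3), "initial_lr")
  expect_error(training_config(final_lr = 5e-4), "final_lr")
  expect_error(training_config(weight_decay = -1), "weight_decay")
  expect_error(training_config(betas = c(0.9, 1)), "betas")
  expect_error(training_config(epsilon = 0), "epsilon")
})

test_that("seeded training is fully deterministic and traces the schedule", {
  set.seed(41)
  n <- 12L
  imgs <- array(rnorm(16 * 16 * 3 * n), c(16, 16, 3, n))
  labels <- rep(1:2, each = 6)
  cfg <- arch_config(image_size = 16L, patch_size = 8L, embed_dim = 16L,
                     depth = 1L, num_heads = 2L, csp_mid = 8L,
                     sppf_mid = 8L, head_hidden = c(16L, 8L),
                     num_classes = 2L)
  tcfg <- training_config(max_lr = 3e-3, batch_size = 4L, epochs = 4L,
                          seed = 11L)
  run <- function() {
    caspnet_train(caspnet(config = cfg, seed = 5L),
                  list(images = imgs, labels = labels),
                  val = list(images = imgs, labels = labels),
                  config = tcfg)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$lr_trace, f2$lr_trace)
  expect_identical(caspnet:::flatten_params(f1$model$params),
                   caspnet:::flatten_params(f2$model$params))

  # one history row per epoch; lr trace equals the schedule pointwise
  expect_equal(nrow(f1$history), 4L)
  total <- f1$total_steps
  expect_equal(f1$lr_trace,
               one_cycle_lr(seq_len(total) - 1, total, tcfg))
  # the logged epoch-end lr is the last step's lr of that epoch
  expect_equal(f1$history$lr[4], f1$lr_trace[total])
  # validation columns are populated
  expect_true(all(is.finite(f1$history$val_loss)))

  # resuming from the checkpoint restores shapes and the forward pass
  path <- tempfile(fileext = ".rds")
  save_caspnet(f1$best_model, path)
  m2 <- load_caspnet(path)
  x <- imgs[, , , 1:2, drop = FALSE]
  expect_identical(forward_caspnet(f1$best_model, x),
                   forward_caspnet(m2, x))
  unlink(path)
  # empty training split is rejected
  expect_error(caspnet_train(caspnet(config = cfg, seed = 1),
                             list(images = array(0, c(16, 16, 3, 0)),
                                  labels = integer(0))),
               "empty")
})
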