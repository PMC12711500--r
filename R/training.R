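#' Training configuration
#'
#' The published recipe: AdamW with maximum learning rate 1e-3 and decoupled
#' weight decay 0.05, batch size 128, 450 epochs, seed 1337, and a one-cycle
#' cosine schedule that starts at 1e-4, peaks at 1e-3 after the first 10% of
#' optimizer steps and anneals to 1e-5. The exponential-decay rates and
#' epsilon take the standard Adam defaults.
#'
#' @param max_lr,initial_lr,final_lr One-cycle anchors
#'   (`0 < initial_lr <= max_lr`, `final_lr <= initial_lr`).
#' @param warmup_fraction Fraction of total steps spent rising to `max_lr`.
#' @param weight_decay Decoupled decay coefficient lambda (>= 0).
#' @param betas Length-2 vector `(beta1, beta2)`, both in (0, 1).
#' @param epsilon Numerical-stability constant (> 0).
#' @param batch_size,epochs,seed Loop controls.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_lr = 1e-3, initial_lr = 1e-4,
                            final_lr = 1e-5, warmup_fraction = 0.1,
                            weight_decay = 0.05, betas = c(0.9, 0.999),
                            epsilon = 1e-8, batch_size = 128L,
                            epochs = 450L, seed = 1337L) {
  if (initial_lr <= 0 || initial_lr > max_lr) {
    stop_caspnet("need 0 < initial_lr <= max_lr")
  }
  if (final_lr > initial_lr) stop_caspnet("need final_lr <= initial_lr")
  if (weight_decay < 0) stop_caspnet("weight_decay must be >= 0")
  if (any(betas <= 0) || any(betas >= 1)) {
    stop_caspnet("betas must lie in (0, 1)")
  }
  if (epsilon <= 0) stop_caspnet("epsilon must be > 0")
  check_prob(warmup_fraction, "warmup_fraction")
  structure(list(max_lr = max_lr, initial_lr = initial_lr,
                 final_lr = final_lr, warmup_fraction = warmup_fraction,
                 weight_decay = weight_decay, betas = betas,
                 epsilon = epsilon,
                 batch_size = check_count(batch_size, "batch_size"),
                 epochs = check_count(epochs, "epochs"),
                 seed = check_count(seed, "seed", min = 0)),
            class = "training_config")
}

#' Multi-class cross-entropy loss
#'
#' Per-sample loss `-log softmax(logits)[label]` (the one-hot form of the
#' categorical cross-entropy), reduced by the batch mean. Numerically
#' stabilized by max subtraction.
#'
#' @param logits `(B, C)` logit matrix.
#' @param labels Integer class labels in `1..C` (or a factor).
#' @return A list with `loss` (batch mean), `per_sample` and `probs`
#'   (softmax rows).
#' @examples
#' cross_entropy(matrix(0, 1, 5), 1L)$loss  # log(5)
#' @export
cross_entropy <- function(logits, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  n <- nrow(logits)
  if (length(labels) != n) {
    stop_caspnet("one label per logit row required")
  }
  bad <- which(labels < 1L | labels > ncol(logits))
  if (length(bad)) {
    stop_caspnet(sprintf("label out of range [1, %d] for sample %d",
                         ncol(logits), bad[1]))
  }
  if (!is_finite_all(logits)) stop_caspnet("non-finite logits")
  m <- apply(logits, 1, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  per <- lse - z[cbind(seq_len(n), labels)]
  list(loss = mean(per), per_sample = per, probs = exp(z - lse))
}

# d loss / d logits for the mean-reduced cross-entropy
cross_entropy_grad <- function(logits, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  p <- softmax_rows(logits)
  n <- nrow(logits)
  p[cbind(seq_len(n), labels)] <- p[cbind(seq_len(n), labels)] - 1
  p / n
}

#' Weight-decay penalty (reporting quantity)
#'
#' Returns `lambda * sum(w^2)` over the decayed parameter groups. Decay is
#' applied inside the optimizer step (decoupled form), so this penalty is
#' never added to the gradient; it is reported so the regularized total loss
#' can be logged. For a `caspnet` model the standard exclusions apply:
#' normalization gains/offsets, biases, and the class/positional embeddings
#' are not decayed (only arrays named `W` are).
#'
#' @param w A numeric vector/array, a (possibly nested) list of arrays, or a
#'   `caspnet` model.
#' @param lambda Decay coefficient (>= 0).
#' @return The scalar penalty.
#' @examples
#' weight_decay_penalty(c(3, 4), 0.1)  # 2.5
#' @export
weight_decay_penalty <- function(w, lambda) {
  if (lambda < 0) stop_caspnet("lambda must be >= 0")
  if (inherits(w, "caspnet")) {
    flat <- flatten_params(w$params)
    flat <- flat[decay_mask(names(flat))]
    return(lambda * sum(vapply(flat, function(a) sum(a^2), numeric(1))))
  }
  if (is.list(w)) {
    flat <- flatten_params(w)
    return(lambda * sum(vapply(flat, function(a) sum(a^2), numeric(1))))
  }
  lambda * sum(w^2)
}

# TRUE for parameters subject to decoupled weight decay: conv/linear kernels
# only (every such array is named "W"); biases, norm parameters and the
# class/positional embeddings are excluded.
decay_mask <- function(nms) {
  vapply(strsplit(nms, ".", fixed = TRUE),
         function(parts) parts[length(parts)] == "W", logical(1))
}

#' AdamW optimizer step
#'
#' Implements the decoupled-decay update: with `m <- b1 m + (1-b1) g`,
#' `v <- b2 v + (1-b2) g^2` and bias-corrected `mhat = m/(1-b1^t)`,
#' `vhat = v/(1-b2^t)`, parameters move by
#' `theta <- theta - lr * mhat / (sqrt(vhat) + eps) - lr * lambda * theta`,
#' the decay term applied only where `decay` is `TRUE`.
#'
#' @param state Optimizer state from [adamw_init()]; carries `t`, `m`, `v`
#'   and the current parameters `params` (a flat named list of arrays).
#' @param grads Flat named list of gradients matching `state$params`.
#' @param lr Learning rate for this step (> 0).
#' @param cfg A [training_config()] (betas, epsilon, weight_decay).
#' @param decay Logical vector over parameter names; defaults to the
#'   standard exclusion rule (see [weight_decay_penalty()]).
#' @return The updated state.
#' @export
adamw_step <- function(state, grads, lr, cfg,
                       decay = decay_mask(names(state$params))) {
  if (lr <= 0) stop_caspnet("lr must be > 0")
  b1 <- cfg$betas[1]
  b2 <- cfg$betas[2]
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (i in seq_along(state$params)) {
    nm <- names(state$params)[i]
    g <- grads[[nm]]
    if (is.null(g)) next
    if (!is_finite_all(g)) {
      stop_caspnet("non-finite gradient for parameter group '", nm, "'")
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    upd <- lr * mhat / (sqrt(vhat) + cfg$epsilon)
    if (decay[i] && cfg$weight_decay > 0) {
      upd <- upd + lr * cfg$weight_decay * state$params[[nm]]
    }
    state$params[[nm]] <- state$params[[nm]] - upd
  }
  state
}

#' @rdname adamw_step
#' @param params Flat named list of parameter arrays to optimize.
#' @export
adamw_init <- function(params) {
  zeros <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  list(t = 0L, m = zeros, v = zeros, params = params)
}

#' One-cycle cosine learning-rate schedule
#'
#' Phase 1 (the first `warmup_fraction` of steps) cosine-interpolates from
#' `initial_lr` up to `max_lr`; phase 2 cosine-anneals from `max_lr` down to
#' `final_lr`. The curve is continuous at the phase boundary, rises once and
#' falls once.
#'
#' @param step Step index (0-based), `0 <= step <= total_steps`; vectorized.
#' @param total_steps Total optimizer steps (>= 2).
#' @param cfg A [training_config()].
#' @return Learning rate(s).
#' @examples
#' cfg <- training_config()
#' one_cycle_lr(0, 100, cfg)    # 1e-4
#' one_cycle_lr(10, 100, cfg)   # 1e-3 (peak at 10% of training)
#' one_cycle_lr(100, 100, cfg)  # 1e-5
#' @export
one_cycle_lr <- function(step, total_steps, cfg = training_config()) {
  if (total_steps < 2) stop_caspnet("total_steps must be >= 2")
  if (any(step < 0 | step > total_steps)) {
    stop_caspnet(sprintf("step must lie in [0, %d]", total_steps))
  }
  w <- cfg$warmup_fraction * total_steps
  up <- cfg$max_lr - (cfg$max_lr - cfg$initial_lr) *
    (1 + cos(pi * pmin(step, w) / w)) / 2
  down <- cfg$final_lr + (cfg$max_lr - cfg$final_lr) *
    (1 + cos(pi * (pmax(step, w) - w) / (total_steps - w))) / 2
  ifelse(step <= w, up, down)
}

# forward a whole array of images in eval mode, batched
batched_logits <- function(model, images, batch_size = 32L) {
  n <- dim(images)[4]
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    out <- rbind(out,
                 caspnet_forward(model, images[, , , idx,
                                               drop = FALSE])$logits)
  }
  out
}

# pick up refreshed batch-norm running statistics after a training step
update_bn_buffers <- function(model, records) {
  if (!isTRUE(model$cfg$conv_batchnorm)) return(model)
  grab <- function(cache) cache$bn$new_buf
  for (r in records) {
    if (identical(r$type, "csp")) {
      model$buffers$csp$b1 <- grab(r$cache$b1) %||% model$buffers$csp$b1
      model$buffers$csp$b2 <- grab(r$cache$b2) %||% model$buffers$csp$b2
      model$buffers$csp$merge <- grab(r$cache$merge) %||%
        model$buffers$csp$merge
    } else if (identical(r$type, "sppf")) {
      model$buffers$sppf$conv1 <- grab(r$cache$c1) %||%
        model$buffers$sppf$conv1
      model$buffers$sppf$conv2 <- grab(r$cache$c2) %||%
        model$buffers$sppf$conv2
    }
  }
  model
}

# Normalize the two accepted training-data forms to list(images, labels).
# image_set input is loaded raw; tensor input is taken as preprocessed.
prepare_train_data <- function(data, side) {
  if (inherits(data, "image_set")) {
    raw <- lapply(data$items$path, read_image)
    list(raw = raw, labels = data$items$class_idx, preprocessed = FALSE)
  } else if (is.list(data) && !is.null(data$images)) {
    list(images = as_image_batch(data$images),
         labels = as.integer(data$labels), preprocessed = TRUE)
  } else {
    stop_caspnet("training data must be an image_set or list(images, labels)")
  }
}

#' Train a CASPNet model
#'
#' Seeded mini-batch training with AdamW (decoupled weight decay, standard
#' exclusions) and the per-step one-cycle schedule. When the training data
#' is an `image_set`, augmentation is re-sampled on the fly every epoch and
#' images are standardized; tensor input (`list(images, labels)` with images
#' `(H, W, C, N)`) is used as given. The checkpoint with the best validation
#' accuracy (training accuracy when no validation set is supplied) is
#' retained alongside the final weights.
#'
#' @param model A `caspnet` model (its initial weights are the starting
#'   point).
#' @param data Training data: an `image_set` or `list(images, labels)`
#'   (labels 1-based).
#' @param val Optional validation data in either form.
#' @param config A [training_config()].
#' @param steps Optional cap on total optimizer steps (overrides
#'   `config$epochs` as the schedule length).
#' @param augment_cfg An [augmentation_config()] or `NULL` to disable
#'   augmentation (tensor input is never augmented).
#' @param checkpoint_path Optional path; the best checkpoint is saved there.
#' @param verbose Print a line per epoch.
#' @return An object of class `caspnet_fit`: `model` (final), `best_model`,
#'   `history` (one row per epoch: epoch, lr, train_loss, train_acc,
#'   val_loss, val_acc), `lr_trace` (per step), `config`.
#' @export
caspnet_train <- function(model, data, val = NULL,
                          config = training_config(), steps = NULL,
                          augment_cfg = NULL, checkpoint_path = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "caspnet"))
  side <- model$cfg$image_size
  tr <- prepare_train_data(data, side)
  n <- length(tr$labels)
  if (n == 0L) stop_caspnet("training split is empty")
  va <- if (!is.null(val)) prepare_train_data(val, side) else NULL
  va_images <- NULL
  if (!is.null(va)) {
    va_images <- if (va$preprocessed) {
      va$images
    } else {
      arr <- array(0, c(side, side, 3L, length(va$labels)))
      for (i in seq_along(va$raw)) {
        arr[, , , i] <- eval_transform(va$raw[[i]], size = side)
      }
      arr
    }
  }
  batches_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- steps %||% (config$epochs * batches_per_epoch)
  n_epochs <- ceiling(total_steps / batches_per_epoch)
  flat <- flatten_params(model$params)
  opt <- adamw_init(flat)
  dmask <- decay_mask(names(flat))
  history <- NULL
  lr_trace <- numeric(0)
  best <- list(acc = -Inf, params = model$params, buffers = model$buffers)
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(n_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      ep_seen <- 0L
      last_lr <- NA_real_
      for (bi in seq_len(batches_per_epoch)) {
        if (step >= total_steps) break
        idx <- perm[((bi - 1L) * config$batch_size + 1L):
                      min(bi * config$batch_size, n)]
        if (tr$preprocessed) {
          xb <- tr$images[, , , idx, drop = FALSE]
        } else {
          xb <- array(0, c(side, side, 3L, length(idx)))
          for (j in seq_along(idx)) {
            im <- tr$raw[[idx[j]]]
            im <- if (!is.null(augment_cfg)) {
              standardize_image(augment(im, augment_cfg))
            } else {
              eval_transform(im, size = side)
            }
            xb[, , , j] <- im
          }
        }
        yb <- tr$labels[idx]
        fw <- caspnet_forward(model, xb, training = TRUE)
        ce <- cross_entropy(fw$logits, yb)
        bw <- caspnet_backward(model, fw, cross_entropy_grad(fw$logits, yb))
        lr <- one_cycle_lr(step, total_steps, config)
        opt <- adamw_step(opt, bw$grads, lr, config, dmask)
        model$params <- unflatten_params(opt$params, model$params)
        model <- update_bn_buffers(model, fw$records)
        step <- step + 1L
        lr_trace <- c(lr_trace, lr)
        last_lr <- lr
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fw$logits, ties.method = "first") == yb)
        ep_seen <- ep_seen + length(idx)
      }
      if (ep_seen == 0L) break
      train_loss <- ep_loss / ep_seen
      train_acc <- ep_correct / ep_seen
      val_loss <- NA_real_
      val_acc <- NA_real_
      if (!is.null(va_images)) {
        lg <- batched_logits(model, va_images)
        vce <- cross_entropy(lg, va$labels)
        val_loss <- vce$loss
        val_acc <- mean(max.col(lg, ties.method = "first") == va$labels)
      }
      sel_acc <- if (is.na(val_acc)) train_acc else val_acc
      # ties go to the later epoch: among equally accurate checkpoints the
      # most-trained one is kept
      if (sel_acc >= best$acc) {
        best <- list(acc = sel_acc, params = model$params,
                     buffers = model$buffers)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = last_lr, train_loss = train_loss,
        train_acc = train_acc, val_loss = val_loss, val_acc = val_acc))
      if (verbose) {
        message(sprintf(
          "epoch %3d  lr %.2e  loss %.4f  acc %.3f  val_acc %s",
          epoch, last_lr, train_loss, train_acc,
          ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
      if (step >= total_steps) break
    }
  })
  best_model <- model
  best_model$params <- best$params
  best_model$buffers <- best$buffers
  if (!is.null(checkpoint_path)) save_caspnet(best_model, checkpoint_path)
  structure(list(model = model, best_model = best_model, history = history,
                 lr_trace = lr_trace, config = config,
                 total_steps = total_steps),
            class = "caspnet_fit")
}

#' @export
print.caspnet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("caspnet_fit: %d epoch(s), %d optimizer step(s)\n",
              nrow(h), length(x$lr_trace)))
  cat(sprintf("  final train loss %.4f, accuracy %.3f\n",
              h$train_loss[nrow(h)], h$train_acc[nrow(h)]))
  if (!all(is.na(h$val_acc))) {
    cat(sprintf("  best validation accuracy %.3f\n",
                max(h$val_acc, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
predict.caspnet_fit <- function(object, newdata, ...) {
  predict(object$best_model, newdata, ...)
}

#' @export
plot.caspnet_fit <- function(x, ...) {
  h <- x$history
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss")
  if (!all(is.na(h$val_loss))) lines(h$epoch, h$val_loss, lty = 2)
  plot(seq_along(x$lr_trace) - 1, x$lr_trace, type = "l", xlab = "step",
       ylab = "learning rate", main = "one-cycle schedule")
  invisible(x)
}
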