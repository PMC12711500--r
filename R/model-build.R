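#' Build a CASPNet model (or one of its ablation variants)
#'
#' Constructs the hybrid classifier: a ViT-Base-style token encoder bridged
#' into CSP and SPPF convolutional blocks by a parameter-free token-to-grid
#' reshape, finished by global average pooling and a fully-connected head.
#' Weights are initialized with a truncated normal (sigma = 0.02, clipped at
#' two standard deviations); biases and LayerNorm offsets start at zero,
#' LayerNorm gains at one.
#'
#' The four variants mirror the ablation roster:
#' \describe{
#'   \item{full}{patch embed -> +CLS/pos -> 12 blocks -> final LN -> reshape
#'     -> CSP -> SPPF -> GAP -> head.}
#'   \item{vit_only}{encoder only; the CLS token feeds the head.}
#'   \item{vit_csp}{full without the SPPF block.}
#'   \item{csp_sppf_only}{patch-embedding conv as a strided stem (no CLS or
#'     positional path) -> reshape -> CSP -> SPPF -> GAP -> head.}
#' }
#'
#' @param variant Variant name; overrides `config$variant` when given.
#' @param config An [arch_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `caspnet` with elements `cfg`, `params`
#'   (nested list of weight arrays), `buffers` (batch-norm running statistics
#'   when enabled) and `n_params`.
#' @examples
#' m <- caspnet(config = arch_config(image_size = 32, patch_size = 16,
#'                                   embed_dim = 16, depth = 1, num_heads = 2,
#'                                   csp_mid = 8, sppf_mid = 8,
#'                                   head_hidden = c(8, 4), num_classes = 2))
#' count_parameters(m)
#' @export
caspnet <- function(variant = NULL, config = arch_config(), seed = NULL) {
  if (!inherits(config, "arch_config")) {
    stop_caspnet("'config' must be an arch_config object")
  }
  if (!is.null(variant)) {
    valid <- c("full", "vit_only", "csp_sppf_only", "vit_csp")
    if (!variant %in% valid) {
      stop_caspnet(sprintf("unknown variant '%s'; valid variants: %s",
                           variant, paste(valid, collapse = ", ")))
    }
    config$variant <- variant
  }
  cfg <- config
  model <- with_seed(seed, build_params(cfg))
  model$cfg <- cfg
  model$n_params <- sum(vapply(flatten_params(model$params), length,
                               numeric(1)))
  class(model) <- "caspnet"
  model
}

#' @rdname caspnet
#' @param name Variant name (`build_variant()` is an alias of [caspnet()]
#'   with the variant argument first).
#' @export
build_variant <- function(name, config = arch_config(), seed = NULL) {
  caspnet(variant = name, config = config, seed = seed)
}

# Number of heads of the CSP branch-2 transformer: keeps head_dim at the
# backbone's value where possible (384 / 64 = 6 heads in the default).
csp_heads <- function(cfg) max(1L, cfg$csp_mid %/% cfg$head_dim)

init_block <- function(d, mlp_ratio) {
  hidden <- as.integer(round(d * mlp_ratio))
  list(
    ln1 = init_layernorm(d),
    attn = list(qkv = init_linear(d, 3L * d),
                proj = init_linear(d, d)),
    ln2 = init_layernorm(d),
    fc1 = init_linear(d, hidden),
    fc2 = init_linear(hidden, d)
  )
}

init_convunit <- function(cin, cout, batchnorm = FALSE) {
  p <- list(conv = init_linear(cin, cout))
  if (batchnorm) p$bn <- list(g = rep(1, cout), b = numeric(cout))
  p
}

build_params <- function(cfg) {
  d <- cfg$embed_dim
  has_vit <- cfg$variant %in% c("full", "vit_only", "vit_csp")
  has_conv <- cfg$variant %in% c("full", "vit_csp", "csp_sppf_only")
  has_sppf <- cfg$variant %in% c("full", "csp_sppf_only")
  p <- list()
  buf <- list()
  p$patch_embed <- init_linear(cfg$patch_size^2 * cfg$in_channels, d)
  if (has_vit) {
    p$cls <- trunc_normal(d)
    p$pos <- matrix(trunc_normal((cfg$num_patches + 1L) * d),
                    cfg$num_patches + 1L, d)
    p$blocks <- lapply(seq_len(cfg$depth), function(i)
      init_block(d, cfg$mlp_ratio))
    names(p$blocks) <- paste0("b", seq_len(cfg$depth))
    p$final_ln <- init_layernorm(d)
  }
  if (has_conv) {
    p$csp <- list(
      b1 = init_convunit(d, cfg$csp_mid, cfg$conv_batchnorm),
      b2 = init_convunit(d, cfg$csp_mid, cfg$conv_batchnorm),
      b2_block = init_block(cfg$csp_mid, cfg$mlp_ratio),
      merge = init_convunit(2L * cfg$csp_mid, d, cfg$conv_batchnorm)
    )
    if (cfg$conv_batchnorm) {
      buf$csp <- list(b1 = bn_buffers(cfg$csp_mid),
                      b2 = bn_buffers(cfg$csp_mid),
                      merge = bn_buffers(d))
    }
  }
  if (has_sppf) {
    p$sppf <- list(
      conv1 = init_convunit(d, cfg$sppf_mid, cfg$conv_batchnorm),
      conv2 = init_convunit(4L * cfg$sppf_mid, d, cfg$conv_batchnorm)
    )
    if (cfg$conv_batchnorm) {
      buf$sppf <- list(conv1 = bn_buffers(cfg$sppf_mid),
                       conv2 = bn_buffers(d))
    }
  }
  widths <- c(d, cfg$head_hidden, cfg$num_classes)
  p$head <- c(list(ln = init_layernorm(d)),
              lapply(seq_len(length(widths) - 1L), function(i)
                init_linear(widths[i], widths[i + 1L])))
  names(p$head) <- c("ln", paste0("fc", seq_len(length(widths) - 1L)))
  list(params = p, buffers = buf)
}

bn_buffers <- function(c) list(mean = numeric(c), var = rep(1, c))

#' Count trainable parameters
#'
#' Sums the element counts of every trainable weight array in the model.
#' Batch-norm running statistics (buffers) are excluded.
#'
#' @param model A `caspnet` model.
#' @return Integer-valued parameter count.
#' @examples
#' # a bare linear layer 768 -> 5 with bias has 768 * 5 + 5 = 3845 parameters
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "caspnet"))
  sum(vapply(flatten_params(model$params), length, numeric(1)))
}

# Per-module parameter breakdown used by summary() and the ablation report.
param_breakdown <- function(model) {
  top <- model$params
  vapply(names(top), function(nm)
    sum(vapply(flatten_params(top[nm]), length, numeric(1))), numeric(1))
}

#' Count forward-pass FLOPs
#'
#' Analytic multiply-accumulate count for one image: one MAC is one FLOP,
#' summed over convolution, linear and attention matrix products (the QK^T
#' and attention-times-V products included). Normalizations, activations,
#' pooling and element-wise operations are excluded from the count.
#'
#' @param model A `caspnet` model.
#' @param image_size Input edge in pixels; defaults to the model's configured
#'   geometry.
#' @return FLOP count (numeric, per image).
#' @export
count_flops <- function(model, image_size = NULL) {
  cfg <- model$cfg
  side <- image_size %||% cfg$image_size
  if (side %% cfg$patch_size != 0) {
    stop_caspnet(sprintf("image_size (%d) not divisible by patch_size (%d)",
                         side, cfg$patch_size))
  }
  g <- side %/% cfg$patch_size
  np <- g^2
  d <- cfg$embed_dim
  block_flops <- function(n, dm, ratio) {
    hidden <- round(dm * ratio)
    n * dm * (3 * dm) +      # fused QKV projection
      2 * n^2 * dm +         # QK^T and P %*% V across all heads
      n * dm * dm +          # output projection
      2 * n * dm * hidden    # MLP in + out
  }
  total <- np * (cfg$patch_size^2 * cfg$in_channels) * d  # patch conv
  has_vit <- cfg$variant %in% c("full", "vit_only", "vit_csp")
  has_conv <- cfg$variant %in% c("full", "vit_csp", "csp_sppf_only")
  has_sppf <- cfg$variant %in% c("full", "csp_sppf_only")
  if (has_vit) {
    total <- total + cfg$depth * block_flops(np + 1, d, cfg$mlp_ratio)
  }
  if (has_conv) {
    total <- total +
      2 * np * d * cfg$csp_mid +                   # two CSP branch convs
      block_flops(np, cfg$csp_mid, cfg$mlp_ratio) + # branch-2 transformer
      np * (2 * cfg$csp_mid) * d                   # merge conv
  }
  if (has_sppf) {
    total <- total +
      np * d * cfg$sppf_mid +                      # SPPF input conv
      np * (4 * cfg$sppf_mid) * d                  # SPPF merge conv
  }
  widths <- c(d, cfg$head_hidden, cfg$num_classes)
  total <- total + sum(widths[-length(widths)] * widths[-1])
  total
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the architecture configuration,
#' all weight arrays and batch-norm buffers; loading reconstructs the model
#' with bitwise-identical parameters.
#'
#' @param model A `caspnet` model.
#' @param path File path for the snapshot.
#' @return `save_caspnet()` returns `path` invisibly; `load_caspnet()`
#'   returns the restored `caspnet` model.
#' @export
save_caspnet <- function(model, path) {
  stopifnot(inherits(model, "caspnet"))
  saveRDS(list(format = "caspnet-checkpoint-1", cfg = unclass(model$cfg),
               params = model$params, buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_caspnet
#' @export
load_caspnet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "caspnet-checkpoint-1")) {
    stop_caspnet("not a caspnet checkpoint: ", path)
  }
  model <- list(params = obj$params, buffers = obj$buffers,
                cfg = structure(obj$cfg, class = "arch_config"))
  model$n_params <- sum(vapply(flatten_params(model$params), length,
                               numeric(1)))
  class(model) <- "caspnet"
  model
}

#' @export
print.caspnet <- function(x, ...) {
  cat(sprintf("CASPNet model (variant '%s')\n", x$cfg$variant))
  cat(sprintf("  %s parameters, %.3f GFLOPs per %dx%d image\n",
              format(count_parameters(x), big.mark = ","),
              count_flops(x) / 1e9, x$cfg$image_size, x$cfg$image_size))
  print(x$cfg)
  invisible(x)
}

#' @export
summary.caspnet <- function(object, ...) {
  br <- param_breakdown(object)
  out <- list(variant = object$cfg$variant,
              breakdown = br,
              total = sum(br),
              flops = count_flops(object),
              image_size = object$cfg$image_size)
  class(out) <- "summary.caspnet"
  out
}

#' @export
print.summary.caspnet <- function(x, ...) {
  cat(sprintf("CASPNet '%s' variant -- parameter accounting\n", x$variant))
  for (nm in names(x$breakdown)) {
    cat(sprintf("  %-12s %14s\n", nm,
                format(x$breakdown[[nm]], big.mark = ",")))
  }
  cat(sprintf("  %-12s %14s  (%.2f M)\n", "total",
              format(x$total, big.mark = ","), x$total / 1e6))
  cat(sprintf("  FLOPs at %d px: %.3f G (MAC convention)\n",
              x$image_size, x$flops / 1e9))
  invisible(x)
}
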