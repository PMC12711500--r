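#' Architectural configuration for CASPNet
#'
#' Collects every architectural hyperparameter of the hybrid model. The
#' defaults are the published configuration: 224x224x3 input, 16-pixel
#' patches, a ViT-Base encoder (embed dim 768, 12 blocks, 12 heads,
#' MLP ratio 4), CSP/SPPF mid-width 384, SPPF pooling kernel 5 and a
#' LayerNorm + 768-512-256-K fully-connected classification head.
#'
#' @param image_size Input height/width in pixels; must be divisible by
#'   `patch_size`.
#' @param patch_size Patch edge in pixels (default 16).
#' @param in_channels Image channels (3 for RGB).
#' @param embed_dim Token dimension D of the encoder (768).
#' @param depth Number of transformer blocks (12).
#' @param num_heads Attention heads; `embed_dim` must be divisible by it.
#' @param mlp_ratio Hidden expansion of the block MLP (4.0 gives 768->3072).
#' @param qkv_bias Use bias in the fused query/key/value projection.
#' @param dropout,attn_dropout Dropout probabilities for activations and
#'   attention weights (both 0.1, applied in training mode only).
#' @param num_classes Output classes (5 for the SIPAKMED roster).
#' @param csp_mid Per-branch channel width of the CSP block (384).
#' @param sppf_mid Channel width of the SPPF input branch (384).
#' @param sppf_kernel Max-pool kernel of the SPPF cascade (5, stride 1,
#'   "same" padding).
#' @param head_hidden Integer vector of hidden widths of the classification
#'   head, default `c(512, 256)`.
#' @param variant One of `"full"`, `"vit_only"`, `"csp_sppf_only"`,
#'   `"vit_csp"` (the ablation roster).
#' @param conv_batchnorm Logical; add batch-norm to the conv units. Off by
#'   default (conv units are Conv -> SiLU), which keeps the full model at
#'   90.76 M trainable parameters.
#'
#' @return An object of class `arch_config` (a validated list).
#' @examples
#' cfg <- arch_config()
#' cfg$embed_dim / cfg$num_heads  # head_dim = 64
#' @export
arch_config <- function(image_size = 224L,
                        patch_size = 16L,
                        in_channels = 3L,
                        embed_dim = 768L,
                        depth = 12L,
                        num_heads = 12L,
                        mlp_ratio = 4.0,
                        qkv_bias = TRUE,
                        dropout = 0.1,
                        attn_dropout = 0.1,
                        num_classes = 5L,
                        csp_mid = 384L,
                        sppf_mid = 384L,
                        sppf_kernel = 5L,
                        head_hidden = c(512L, 256L),
                        variant = c("full", "vit_only", "csp_sppf_only",
                                    "vit_csp"),
                        conv_batchnorm = FALSE) {
  variant <- match.arg(variant)
  cfg <- list(
    image_size = check_count(image_size, "image_size"),
    patch_size = check_count(patch_size, "patch_size"),
    in_channels = check_count(in_channels, "in_channels"),
    embed_dim = check_count(embed_dim, "embed_dim"),
    depth = check_count(depth, "depth"),
    num_heads = check_count(num_heads, "num_heads"),
    mlp_ratio = mlp_ratio,
    qkv_bias = isTRUE(qkv_bias),
    dropout = check_prob(dropout, "dropout"),
    attn_dropout = check_prob(attn_dropout, "attn_dropout"),
    num_classes = check_count(num_classes, "num_classes"),
    csp_mid = check_count(csp_mid, "csp_mid"),
    sppf_mid = check_count(sppf_mid, "sppf_mid"),
    sppf_kernel = check_count(sppf_kernel, "sppf_kernel"),
    head_hidden = vapply(head_hidden, check_count, integer(1),
                         name = "head_hidden"),
    variant = variant,
    conv_batchnorm = isTRUE(conv_batchnorm)
  )
  if (cfg$image_size %% cfg$patch_size != 0) {
    stop_caspnet(sprintf(
      "image_size (%d) must be divisible by patch_size (%d)",
      cfg$image_size, cfg$patch_size))
  }
  if (cfg$embed_dim %% cfg$num_heads != 0) {
    stop_caspnet(sprintf(
      "embed_dim (%d) must be divisible by num_heads (%d)",
      cfg$embed_dim, cfg$num_heads))
  }
  if (!is.numeric(mlp_ratio) || mlp_ratio <= 0) {
    stop_caspnet("'mlp_ratio' must be a positive scalar")
  }
  cfg$grid <- cfg$image_size %/% cfg$patch_size     # tokens per image edge
  cfg$num_patches <- cfg$grid^2
  cfg$head_dim <- cfg$embed_dim %/% cfg$num_heads
  cfg$attn_scale <- 1 / sqrt(cfg$head_dim)
  structure(cfg, class = "arch_config")
}

#' @export
print.arch_config <- function(x, ...) {
  cat("CASPNet architecture configuration\n")
  cat(sprintf("  input   : %dx%dx%d, patch %d -> %d tokens of dim %d\n",
              x$image_size, x$image_size, x$in_channels, x$patch_size,
              x$num_patches, x$embed_dim))
  cat(sprintf("  encoder : depth %d, heads %d (head_dim %d, scale %.3f), mlp x%.1f\n",
              x$depth, x$num_heads, x$head_dim, x$attn_scale, x$mlp_ratio))
  cat(sprintf("  conv    : CSP mid %d, SPPF mid %d (k=%d cascade)\n",
              x$csp_mid, x$sppf_mid, x$sppf_kernel))
  cat(sprintf("  head    : LN(%d) -> %s -> %d classes\n", x$embed_dim,
              paste(x$head_hidden, collapse = " -> "), x$num_classes))
  cat(sprintf("  variant : %s\n", x$variant))
  invisible(x)
}
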