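#' Feature map container
#'
#' A rank-3 tensor flowing through network blocks, stored as an array with
#' dimensions height x width x channels, together with its pyramid level and
#' its stride in input pixels per cell.
#'
#' @param values numeric array of dim `(H, W, C)`.
#' @param level pyramid level identifier (e.g. `"P3"`), or an integer.
#' @param stride pixels per cell relative to the network input.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(values, level = NA, stride = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            all(dim(values) >= 1L))
  structure(list(values = values, level = level, stride = stride),
            class = "feature_map")
}

fm_values <- function(x) {
  if (inherits(x, "feature_map")) x$values else x
}

fm_like <- function(values, template) {
  if (inherits(template, "feature_map")) {
    feature_map(values, template$level, template$stride)
  } else {
    values
  }
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map %dx%dx%d level=%s stride=%s>\n",
              d[1], d[2], d[3], as.character(x$level),
              as.character(x$stride)))
  invisible(x)
}

#' Transformer encoder configuration
#'
#' @param embed_dim token embedding width; must equal the channel count of
#'   the maps the block is applied to and be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param mlp_ratio hidden-width multiplier of the feed-forward sub-layer.
#' @param use_positional_embedding add a learnable positional embedding to
#'   the flattened tokens.  Off by default: without positions the block is
#'   permutation-equivariant over cells, a property the tests exploit.
#' @param dropout dropout probability (kept for interface completeness; the
#'   blocks run in evaluation mode and dropout is never applied).
#' @param n_tokens token count, required only when the positional embedding
#'   is enabled at construction time.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(embed_dim, n_heads = 1L, mlp_ratio = 2,
                               use_positional_embedding = FALSE,
                               dropout = 0, n_tokens = NULL) {
  embed_dim <- as.integer(embed_dim)
  n_heads <- as.integer(n_heads)
  if (embed_dim %% n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  structure(list(embed_dim = embed_dim, n_heads = n_heads,
                 mlp_ratio = mlp_ratio,
                 use_positional_embedding = use_positional_embedding,
                 dropout = dropout, n_tokens = n_tokens),
            class = "transformer_config")
}

#' Create a transformer encoder block
#'
#' Multi-head self-attention and an MLP feed-forward sub-layer, each wrapped
#' in a residual connection (pre-norm ordering).  The block operates on a
#' feature map by flattening its cells to tokens and reshaping back.
#'
#' @param config a [transformer_config()].
#' @param seed optional RNG seed for weight initialisation.
#' @return A block usable with [transformer_encoder()].
#' @export
new_transformer_encoder <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layer_transformer(config)
}

#' Apply a transformer encoder block to a feature map
#'
#' @param x a [feature_map()] or an `(H, W, C)` array with `C` equal to the
#'   block's embedding width.
#' @param block a block from [new_transformer_encoder()].
#' @return Same type and shape as `x`.
#' @export
transformer_encoder <- function(x, block) {
  v <- fm_values(x)
  if (dim(v)[3] != block$d) {
    stop(sprintf("channel count %d does not match embed_dim %d",
                 dim(v)[3], block$d))
  }
  ctx <- ad_ctx(grad = FALSE)
  out <- fwd_transformer(block, ctx, ad_const(v))
  fm_like(out$value, x)
}

#' Involution configuration
#'
#' @param kernel_size odd spatial kernel size K; the K x K kernel is
#'   generated per position from the input and shared across the channels of
#'   a group (spatially specific, channel invariant).
#' @param groups number of channel groups sharing a kernel.
#' @param reduction_ratio bottleneck divisor of the kernel-generating
#'   function.
#' @param stride output sampling stride.
#' @return An `involution_config` list.
#' @export
involution_config <- function(kernel_size = 3L, groups = 1L,
                              reduction_ratio = 4L, stride = 1L) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  structure(list(kernel_size = kernel_size, groups = as.integer(groups),
                 reduction_ratio = as.integer(reduction_ratio),
                 stride = as.integer(stride)),
            class = "involution_config")
}

#' Create an involution block
#'
#' @param channels channel count of the maps the block is applied to; must
#'   be divisible by `config$groups`.
#' @param config an [involution_config()].
#' @param seed optional RNG seed for weight initialisation.
#' @export
new_involution <- function(channels, config = involution_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layer_involution(as.integer(channels), config)
}

#' Apply an involution block to a feature map
#'
#' @param x a [feature_map()] or `(H, W, C)` array.
#' @param block a block from [new_involution()].
#' @return Same type as `x`; spatial size follows the block's stride.
#' @export
involution <- function(x, block) {
  v <- fm_values(x)
  if (dim(v)[3] != block$channels) {
    stop("channel count does not match the block")
  }
  ctx <- ad_ctx(grad = FALSE)
  out <- fwd_involution(block, ctx, ad_const(v))
  fm_like(out$value, x)
}

#' Create a channel feature fusion with involution (CFFI) block
#'
#' Bridges the top backbone map and the neck: a 1x1 convolution reduces the
#' input to `width` channels, a 1x1 involution aggregates spatial
#' information on the reduced map, and the two branches are concatenated,
#' giving `2 * width` output channels at unchanged spatial size.
#'
#' @param c_in input channel count (the top backbone map).
#' @param width branch width; at full scale 768, scaled by the model's width
#'   multiplier at desk scale.
#' @param seed optional RNG seed.
#' @export
new_cffi <- function(c_in, width = 768L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layer_cffi(as.integer(c_in), as.integer(width))
}

#' Apply a CFFI block
#'
#' @param c5 the highest-level backbone feature map.
#' @param block a block from [new_cffi()].
#' @return A map with `2 * width` channels and unchanged spatial size.
#' @export
cffi <- function(c5, block) {
  ctx <- ad_ctx(grad = FALSE)
  out <- fwd_cffi(block, ctx, ad_const(fm_values(c5)))
  fm_like(out$value, c5)
}

#' Create an adaptively spatial feature fusion (ASFF) head
#'
#' Holds, for every target level, the rescalers that bring the other two
#' levels to that level's resolution and channel count, and a 1x1 control
#' convolution producing one logit map per source.  The softmax over the
#' three logits at each position yields fusion weights in `[0, 1]` summing
#' to 1.
#'
#' @param channels integer vector of channel counts for levels 1..3
#'   (fine to coarse).
#' @param seed optional RNG seed.
#' @export
new_asff <- function(channels, seed = NULL) {
  stopifnot(length(channels) == 3L)
  if (!is.null(seed)) set.seed(seed)
  levels <- lapply(1:3, function(l) layer_asff_level(as.integer(channels), l))
  structure(list(levels = levels, channels = as.integer(channels)),
            class = "wv_asff")
}

#' Rescale a feature map between pyramid levels
#'
#' Same level: identity.  Coarse to fine: 1x1 channel projection then
#' nearest-neighbour interpolation by the octave factor.  Fine to coarse by
#' one octave: 3x3 stride-2 convolution.  By two octaves: stride-2 max
#' pooling followed by the stride-2 convolution.
#'
#' @param asff an [new_asff()] head.
#' @param x feature map (or array) at level `from_level`.
#' @param from_level,to_level integer levels in 1..3 (fine to coarse);
#'   gaps above two octaves are unsupported.
#' @export
asff_rescale <- function(asff, x, from_level, to_level) {
  if (abs(from_level - to_level) > 2L) {
    stop("level gap of more than 2 octaves is unsupported")
  }
  ly <- asff$levels[[to_level]]$rescalers[[from_level]]
  ctx <- ad_ctx(grad = FALSE)
  out <- fwd_rescale(ly, ctx, ad_const(fm_values(x)))
  fm_like(out$value, x)
}

#' Compute ASFF fusion weights
#'
#' @param asff an [new_asff()] head.
#' @param maps list of three feature maps (levels 1..3, fine to coarse), not
#'   yet rescaled; they are rescaled internally to `level`.
#' @param level target level in 1..3.
#' @return An `asff_weights` object with per-position `alpha`, `beta`,
#'   `gamma` matrices, the pre-softmax `lambda_logits`, and the rescaled
#'   source maps.
#' @export
asff_weights <- function(asff, maps, level) {
  ctx <- ad_ctx(grad = FALSE)
  nodes <- lapply(maps, function(m) ad_const(fm_values(m)))
  res <- fwd_asff_level(asff$levels[[level]], ctx, nodes)
  w <- res$weights$value
  structure(list(alpha = w[, , 1], beta = w[, , 2], gamma = w[, , 3],
                 lambda_logits = res$logits$value,
                 rescaled = lapply(res$rescaled, function(n) n$value),
                 level = level),
            class = "asff_weights")
}

#' Fuse three same-shape feature maps with ASFF weights
#'
#' At every position and channel the output is the alpha/beta/gamma-weighted
#' sum of the three sources.
#'
#' @param maps list of three arrays or feature maps of identical shape
#'   (already rescaled to the target level).
#' @param weights an `asff_weights` object (or any list with `alpha`,
#'   `beta`, `gamma` matrices of the maps' spatial size).
#' @export
asff_fuse <- function(maps, weights) {
  vals <- lapply(maps, fm_values)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1)))) {
    stop("the three maps must share one shape")
  }
  w <- list(weights$alpha, weights$beta, weights$gamma)
  out <- array(0, dim = d)
  for (i in 1:3) out <- out + sweep(vals[[i]], c(1, 2), w[[i]], "*")
  fm_like(out, maps[[1]])
}
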