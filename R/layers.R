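## Parameterised layers.  A layer is an environment holding plain numeric
## arrays; during a forward pass parameters are wrapped in tape nodes through
## a pass context (ad_ctx), so that gradient accumulation and the optimizer
## can find them again.  Layers are environments on purpose: the optimizer
## updates them in place.

.layer_uid <- new.env(parent = emptyenv())
.layer_uid$n <- 0L

new_layer <- function(class, ...) {
  .layer_uid$n <- .layer_uid$n + 1L
  ly <- new.env(parent = emptyenv())
  ly$uid <- .layer_uid$n
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = ly)
  class(ly) <- c(class, "wv_layer")
  ly
}

ad_ctx <- function(grad = TRUE) {
  ctx <- new.env(parent = emptyenv())
  ctx$grad <- grad
  ctx$cache <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx
}

## Wrap (and cache) a layer parameter as a tape node for this pass.
p_node <- function(ctx, ly, field) {
  key <- paste0(ly$uid, ":", field)
  nd <- ctx$cache[[key]]
  if (is.null(nd)) {
    nd <- ad_node(get(field, envir = ly))
    ctx$cache[[key]] <- nd
    ctx$params[[length(ctx$params) + 1L]] <- list(layer = ly, field = field,
                                                 node = nd)
  }
  nd
}

## SGD with momentum over every parameter touched in the pass.  Gradients
## are clipped to a global L2 norm first: without normalisation layers a
## single outlier step can blow the activations up and the run never
## recovers.
sgd_step <- function(ctx, lr, momentum = 0.9, weight_decay = 0,
                     max_grad_norm = 5) {
  gscale <- 1
  if (is.finite(max_grad_norm) && max_grad_norm > 0) {
    sq <- 0
    for (p in ctx$params) {
      if (!is.null(p$node$grad)) sq <- sq + sum(p$node$grad^2)
    }
    gnorm <- sqrt(sq)
    if (gnorm > max_grad_norm) gscale <- max_grad_norm / gnorm
  }
  for (p in ctx$params) {
    g <- p$node$grad
    if (is.null(g)) next
    g <- g * gscale
    if (weight_decay > 0) g <- g + weight_decay * get(p$field, envir = p$layer)
    mkey <- paste0(".m_", p$field)
    m <- if (exists(mkey, envir = p$layer, inherits = FALSE)) {
      get(mkey, envir = p$layer)
    } else 0
    m <- momentum * m + g
    assign(mkey, m, envir = p$layer)
    assign(p$field, get(p$field, envir = p$layer) - lr * m, envir = p$layer)
  }
  invisible(NULL)
}

## Fields of a layer that hold trainable parameters (everything else is
## structural metadata: kernel size, stride, child layers, ...).
.trainable_fields <- c("w", "b", "g", "pos")

## Recursively collect wv_layer environments from a nested structure,
## descending into child layers; ls() keeps the order deterministic.
collect_layers <- function(x, acc = NULL) {
  if (inherits(x, "wv_layer")) {
    acc <- c(acc, list(x))
    for (nm in ls(x)) {
      v <- get(nm, envir = x)
      if (inherits(v, "wv_layer") || is.list(v)) {
        acc <- collect_layers(v, acc)
      }
    }
    return(acc)
  }
  if (is.list(x)) for (el in x) acc <- collect_layers(el, acc)
  acc
}

n_parameters <- function(x) {
  total <- 0
  for (ly in collect_layers(x)) {
    for (nm in intersect(.trainable_fields, ls(ly))) {
      total <- total + length(get(nm, envir = ly))
    }
  }
  total
}

## Zero a named subset of parameter fields across all layers in a structure
## (used in tests, e.g. the identity property of residual blocks).
zero_layer_params <- function(x, fields) {
  for (ly in collect_layers(x)) {
    for (nm in intersect(fields, ls(ly))) {
      v <- get(nm, envir = ly)
      if (is.numeric(v)) assign(nm, v * 0, envir = ly)
    }
  }
  invisible(x)
}

## ---- conv -------------------------------------------------------------

layer_conv <- function(cin, cout, k = 1L, stride = 1L, pad = NULL,
                       act = TRUE) {
  if (is.null(pad)) pad <- k %/% 2L
  w <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  new_layer("wv_conv", w = w, b = numeric(cout),
            k = k, stride = stride, pad = pad, act = act)
}

fwd_conv <- function(ly, ctx, x) {
  y <- op_conv2d(x, p_node(ctx, ly, "w"), p_node(ctx, ly, "b"),
                 stride = ly$stride, pad = ly$pad)
  if (ly$act) op_silu(y) else y
}

layer_linear <- function(din, dout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(1 / din)
  new_layer("wv_linear",
            w = matrix(stats::rnorm(din * dout, sd = sd), din, dout),
            b = numeric(dout))
}

fwd_linear <- function(ly, ctx, x) {
  op_add_rowbias(op_matmul(x, p_node(ctx, ly, "w")), p_node(ctx, ly, "b"))
}

layer_layernorm <- function(d) {
  new_layer("wv_layernorm", g = rep(1, d), b = numeric(d))
}

fwd_layernorm <- function(ly, ctx, x) {
  op_layernorm_rows(x, p_node(ctx, ly, "g"), p_node(ctx, ly, "b"))
}

## ---- CSP building blocks ---------------------------------------------

layer_bottleneck <- function(c) {
  new_layer("wv_bottleneck",
            cv1 = layer_conv(c, c, 1L),
            cv2 = layer_conv(c, c, 3L))
}

fwd_bottleneck <- function(ly, ctx, x) {
  op_add(x, fwd_conv(ly$cv2, ctx, fwd_conv(ly$cv1, ctx, x)))
}

## Cross-stage-partial block: two 1x1 projections, one carrying a stack of
## residual bottlenecks (or a transformer encoder when the block sits at the
## backend of the backbone), re-joined by concat + 1x1.
layer_csp <- function(cin, cout, n = 1L, transformer = FALSE,
                      tcfg = NULL) {
  ch <- cout %/% 2L
  inner <- if (transformer) {
    cfg <- tcfg
    cfg$embed_dim <- ch
    list(layer_transformer(cfg))
  } else {
    lapply(seq_len(n), function(i) layer_bottleneck(ch))
  }
  new_layer("wv_csp",
            cv1 = layer_conv(cin, ch, 1L),
            cv2 = layer_conv(cin, ch, 1L),
            cv3 = layer_conv(2L * ch, cout, 1L),
            inner = inner, transformer = transformer)
}

fwd_csp <- function(ly, ctx, x) {
  a <- fwd_conv(ly$cv1, ctx, x)
  for (blk in ly$inner) {
    a <- if (ly$transformer) fwd_transformer(blk, ctx, a)
         else fwd_bottleneck(blk, ctx, a)
  }
  b <- fwd_conv(ly$cv2, ctx, x)
  fwd_conv(ly$cv3, ctx, op_concat_c(list(a, b)))
}

## ---- transformer encoder ---------------------------------------------

layer_transformer <- function(cfg) {
  d <- cfg$embed_dim
  stopifnot(d %% cfg$n_heads == 0L)
  hidden <- as.integer(round(d * cfg$mlp_ratio))
  ly <- new_layer("wv_transformer",
                  ln1 = layer_layernorm(d),
                  wq = layer_linear(d, d), wk = layer_linear(d, d),
                  wv = layer_linear(d, d), wo = layer_linear(d, d),
                  ln2 = layer_layernorm(d),
                  mlp1 = layer_linear(d, hidden),
                  mlp2 = layer_linear(hidden, d),
                  n_heads = cfg$n_heads, d = d,
                  use_pos = isTRUE(cfg$use_positional_embedding))
  if (ly$use_pos && !is.null(cfg$n_tokens)) {
    ly$pos <- matrix(stats::rnorm(cfg$n_tokens * d, sd = 0.02),
                     cfg$n_tokens, d)
  }
  ly
}

## Pre-norm residual ordering: x + MHSA(LN(x)); then x + MLP(LN(x)).
fwd_transformer_tokens <- function(ly, ctx, tok) {
  d <- ly$d
  h <- ly$n_heads
  dh <- d %/% h
  if (ly$use_pos) {
    if (is.null(ly$pos) || nrow(ly$pos) != nrow(tok$value)) {
      stop("positional embedding size does not match token count")
    }
    tok <- op_add(tok, p_node(ctx, ly, "pos"))
  }
  xn <- fwd_layernorm(ly$ln1, ctx, tok)
  q <- fwd_linear(ly$wq, ctx, xn)
  k <- fwd_linear(ly$wk, ctx, xn)
  v <- fwd_linear(ly$wv, ctx, xn)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- (i - 1L) * dh + seq_len(dh)
    qi <- op_slice_cols(q, cols)
    ki <- op_slice_cols(k, cols)
    vi <- op_slice_cols(v, cols)
    att <- op_softmax_rows(op_scale(op_matmul(qi, op_transpose(ki)),
                                    1 / sqrt(dh)))
    heads[[i]] <- op_matmul(att, vi)
  }
  merged <- if (h == 1L) heads[[1]] else op_concat_cols(heads)
  x1 <- op_add(tok, fwd_linear(ly$wo, ctx, merged))
  x1n <- fwd_layernorm(ly$ln2, ctx, x1)
  mlp <- fwd_linear(ly$mlp2, ctx, op_silu(fwd_linear(ly$mlp1, ctx, x1n)))
  op_add(x1, mlp)
}

fwd_transformer <- function(ly, ctx, x) {
  d <- dim(x$value)
  tok <- op_map_to_tokens(x)
  out <- fwd_transformer_tokens(ly, ctx, tok)
  op_tokens_to_map(out, d[1], d[2])
}

## ---- involution -------------------------------------------------------

## Kernel generation Phi: 1x1 reduce (C -> C/r, SiLU) then 1x1 expand to
## K*K*G kernel channels, both sampled at the output stride.  The generated
## kernel at each position is shared across the channels of a group.
layer_involution <- function(channels, cfg) {
  K <- cfg$kernel_size
  G <- cfg$groups
  if (K %% 2L == 0L) stop("involution kernel size must be odd")
  if (channels %% G != 0L) stop("channels must be divisible by groups")
  cr <- max(1L, channels %/% cfg$reduction_ratio)
  new_layer("wv_involution",
            reduce = layer_conv(channels, cr, 1L, stride = cfg$stride),
            span = layer_conv(cr, K * K * G, 1L, act = FALSE),
            K = K, G = G, stride = cfg$stride, channels = channels)
}

fwd_involution <- function(ly, ctx, x) {
  ker <- fwd_conv(ly$span, ctx, fwd_conv(ly$reduce, ctx, x))
  op_involution_apply(x, ker, ly$K, ly$G, stride = ly$stride,
                      pad = ly$K %/% 2L)
}

## Apply a fixed (non-generated) kernel map; used to probe the operator, e.g.
## with a delta kernel that must reproduce the input exactly.
involution_apply_fixed <- function(x, kernels, K, G, stride = 1L) {
  out <- op_involution_apply(ad_const(x), ad_const(kernels),
                             K, G, stride = stride, pad = K %/% 2L)
  out$value
}

## ---- CFFI -------------------------------------------------------------

## Channel feature fusion with involution: 1x1 convolution reduces the top
## backbone map to `width` channels; a 1x1 involution aggregates spatial
## information on that map; the two branches are concatenated (2 * width).
layer_cffi <- function(cin, width,
                       inv_cfg = involution_config(kernel_size = 1L)) {
  new_layer("wv_cffi",
            conv = layer_conv(cin, width, 1L),
            inv = layer_involution(width, inv_cfg),
            width = width)
}

fwd_cffi <- function(ly, ctx, x) {
  a <- fwd_conv(ly$conv, ctx, x)
  b <- fwd_involution(ly$inv, ctx, a)
  op_concat_c(list(a, b))
}

## ---- ASFF -------------------------------------------------------------

## One rescaler per (from, to) level pair.  Levels are ordered fine -> coarse
## (level 1 = stride 8).  Going coarse -> fine: 1x1 channel projection then
## nearest-neighbour interpolation; fine -> coarse by one octave: 3x3
## stride-2 convolution; by two octaves: stride-2 max pooling first.
layer_asff_rescaler <- function(cfrom, cto, octaves) {
  if (octaves == 0L) {
    new_layer("wv_rescale", kind = "identity", octaves = 0L)
  } else if (octaves > 0L) {  # coarse -> fine: upsample
    new_layer("wv_rescale", kind = "up", octaves = octaves,
              proj = layer_conv(cfrom, cto, 1L))
  } else if (octaves == -1L) {
    new_layer("wv_rescale", kind = "down1", octaves = -1L,
              conv = layer_conv(cfrom, cto, 3L, stride = 2L, pad = 1L))
  } else if (octaves == -2L) {
    new_layer("wv_rescale", kind = "down2", octaves = -2L,
              conv = layer_conv(cfrom, cto, 3L, stride = 2L, pad = 1L))
  } else {
    stop("level gap of more than 2 octaves is unsupported")
  }
}

fwd_rescale <- function(ly, ctx, x) {
  switch(ly$kind,
    identity = x,
    up = op_upsample_nearest(fwd_conv(ly$proj, ctx, x), 2L^ly$octaves),
    down1 = fwd_conv(ly$conv, ctx, x),
    down2 = fwd_conv(ly$conv, ctx, op_maxpool(x, 2L, 2L))
  )
}

## ASFF head for one target level: rescalers for the three sources plus the
## 1x1 control convolution producing one logit map per source; the softmax
## over sources gives the per-position fusion weights.
layer_asff_level <- function(channels, level) {
  cl <- channels[level]
  rescalers <- lapply(1:3, function(n) {
    layer_asff_rescaler(channels[n], cl, octaves = n - level)
  })
  new_layer("wv_asff_level",
            rescalers = rescalers,
            control = layer_conv(3L * cl, 3L, 1L, act = FALSE),
            level = level, channels = cl)
}

## Returns list(fused, weights) where weights is the (H, W, 3) softmax map.
fwd_asff_level <- function(ly, ctx, maps) {
  resc <- lapply(1:3, function(n) fwd_rescale(ly$rescalers[[n]], ctx,
                                              maps[[n]]))
  logits <- fwd_conv(ly$control, ctx, op_concat_c(resc))
  wts <- op_softmax_c(logits)
  fused <- op_add(op_add(op_mul_bcast(resc[[1]], op_channel(wts, 1L)),
                         op_mul_bcast(resc[[2]], op_channel(wts, 2L))),
                  op_mul_bcast(resc[[3]], op_channel(wts, 3L)))
  list(fused = fused, weights = wts, logits = logits, rescaled = resc)
}
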