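wv <- asNamespace("weedvision")

test_that("transformer encoder preserves shape and validates channels", {
  blk <- new_transformer_encoder(transformer_config(embed_dim = 8L,
                                                    n_heads = 2L), seed = 1L)
  x <- feature_map(array(rnorm(4 * 5 * 8), c(4, 5, 8)), level = "C5",
                   stride = 32)
  y <- transformer_encoder(x, blk)
  expect_s3_class(y, "feature_map")
  expect_equal(dim(y$values), c(4, 5, 8))
  bad <- array(0, c(4, 5, 6))
  expect_error(transformer_encoder(bad, blk), "embed_dim")
  expect_error(transformer_config(embed_dim = 6L, n_heads = 4L),
               "divisible")
})

test_that("without positions the encoder is permutation-equivariant", {
  set.seed(2)
  blk <- new_transformer_encoder(transformer_config(embed_dim = 4L,
                                                    n_heads = 2L))
  tok <- matrix(rnorm(6 * 4), 6, 4)
  perm <- c(4, 1, 6, 3, 2, 5)
  ctx <- wv$ad_ctx(grad = FALSE)
  out1 <- wv$fwd_transformer_tokens(blk, ctx, wv$ad_const(tok))$value
  ctx2 <- wv$ad_ctx(grad = FALSE)
  out2 <- wv$fwd_transformer_tokens(blk, ctx2,
                                    wv$ad_const(tok[perm, ]))$value
  expect_equal(out2, out1[perm, ], tolerance = 1e-12)
})

test_that("a 2-token 1-head encoder matches explicit Q,K,V arithmetic", {
  set.seed(3)
  blk <- new_transformer_encoder(transformer_config(embed_dim = 2L,
                                                    n_heads = 1L,
                                                    mlp_ratio = 2))
  x <- matrix(c(0.3, -0.7, 1.1, 0.4), 2, 2)
  ctx <- wv$ad_ctx(grad = FALSE)
  got <- wv$fwd_transformer_tokens(blk, ctx, wv$ad_const(x))$value

  ln <- function(m, g, b, eps = 1e-5) {
    t(apply(m, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)
    })) * rep(g, each = nrow(m)) + rep(b, each = nrow(m))
  }
  silu <- function(z) z / (1 + exp(-z))
  xn <- ln(x, blk$ln1$g, blk$ln1$b)
  q <- xn %*% blk$wq$w + rep(blk$wq$b, each = 2)
  k <- xn %*% blk$wk$w + rep(blk$wk$b, each = 2)
  v <- xn %*% blk$wv$w + rep(blk$wv$b, each = 2)
  scores <- q %*% t(k) / sqrt(2)
  att <- exp(scores) / rowSums(exp(scores))
  x1 <- x + (att %*% v) %*% blk$wo$w + rep(blk$wo$b, each = 2)
  x1n <- ln(x1, blk$ln2$g, blk$ln2$b)
  mlp <- silu(x1n %*% blk$mlp1$w + rep(blk$mlp1$b, each = 2)) %*%
    blk$mlp2$w + rep(blk$mlp2$b, each = 2)
  want <- x1 + mlp
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("zeroed attention and MLP weights leave the residual identity", {
  blk <- new_transformer_encoder(transformer_config(embed_dim = 4L,
                                                    n_heads = 1L), seed = 4L)
  for (sub in list(blk$wq, blk$wk, blk$wv, blk$wo, blk$mlp1, blk$mlp2)) {
    wv$zero_layer_params(sub, c("w", "b"))
  }
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_equal(transformer_encoder(x, blk), x, tolerance = 1e-12)
})

test_that("involution with a fixed delta kernel is the identity", {
  set.seed(5)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  K <- 3L
  ker <- array(0, c(6, 6, K * K))
  # centre tap (g=0, kw=1, kh=1 zero-based) lives in channel kw*K + kh = 4
  ker[, , 5] <- 1
  y <- wv$involution_apply_fixed(x, ker, K, 1L)
  expect_equal(y, x, tolerance = 1e-14)
})

test_that("1x1 involution is per-position group-shared channel scaling", {
  set.seed(6)
  blk <- new_involution(4L, involution_config(kernel_size = 1L, groups = 2L,
                                              reduction_ratio = 2L))
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  y <- involution(x, blk)
  # recompute the generated kernels with plain matrix arithmetic
  silu <- function(z) z / (1 + exp(-z))
  C <- 4L; Cr <- dim(blk$reduce$w)[4]
  xm <- matrix(x, ncol = C)
  red <- silu(xm %*% matrix(blk$reduce$w, C, Cr) +
                rep(blk$reduce$b, each = 25))
  ker <- red %*% matrix(blk$span$w, Cr, 2) + rep(blk$span$b, each = 25)
  want <- array(0, dim(x))
  for (c in 1:4) {
    g <- if (c <= 2) 1 else 2
    want[, , c] <- x[, , c] * array(ker[, g], c(5, 5))
  }
  expect_equal(y, want, tolerance = 1e-12)
})

test_that("involution equals a nested-loop oracle on a random input", {
  set.seed(7)
  blk <- new_involution(4L, involution_config(kernel_size = 3L, groups = 1L))
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  y <- involution(x, blk)
  # generate the kernel map through the block, then apply by hand
  ctx <- wv$ad_ctx(grad = FALSE)
  ker <- wv$fwd_conv(blk$span, ctx,
                     wv$fwd_conv(blk$reduce, ctx, wv$ad_const(x)))$value
  K <- 3L
  want <- array(0, dim(x))
  for (c in 1:4) for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (kh in 1:K) for (kw in 1:K) {
      hi <- i + kh - 2; wi <- j + kw - 2
      if (hi >= 1 && hi <= 5 && wi >= 1 && wi <= 5) {
        acc <- acc + ker[i, j, (kw - 1) * K + kh] * x[hi, wi, c]
      }
    }
    want[i, j, c] <- acc
  }
  expect_equal(y, want, tolerance = 1e-12)
})

test_that("involution kernels are shared within a channel group", {
  set.seed(8)
  blk <- new_involution(4L, involution_config(kernel_size = 3L, groups = 1L))
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  x[, , 2] <- x[, , 1]  # duplicated channel in the same group
  y <- involution(x, blk)
  expect_identical(y[, , 1], y[, , 2])
  expect_error(involution_config(kernel_size = 2L), "odd")
  expect_error(new_involution(5L, involution_config(groups = 2L)),
               "divisible")
})

test_that("cffi concatenates a conv and an involution branch", {
  blk <- new_cffi(16L, width = 8L, seed = 9L)
  x <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  y <- cffi(x, blk)
  expect_equal(dim(y), c(4, 4, 16))  # 2 * width
  # zero input with zero biases gives an all-zero output (linearity)
  wv$zero_layer_params(blk, "b")
  y0 <- cffi(array(0, c(4, 4, 16)), blk)
  expect_equal(max(abs(y0)), 0)
})

test_that("asff rescaling honours the level shape contracts", {
  asff <- new_asff(c(4L, 8L, 16L), seed = 10L)
  x3 <- array(rnorm(16 * 16 * 4), c(16, 16, 4))   # level 1, stride 8
  x5 <- array(rnorm(4 * 4 * 16), c(4, 4, 16))     # level 3, stride 32
  expect_identical(asff_rescale(asff, x3, 1, 1), x3)
  up <- asff_rescale(asff, x5, 3, 1)
  expect_equal(dim(up), c(16, 16, 4))
  down2 <- asff_rescale(asff, x3, 1, 3)
  expect_equal(dim(down2), c(4, 4, 16))
  down1 <- asff_rescale(asff, x3, 1, 2)
  expect_equal(dim(down1), c(8, 8, 8))
  expect_error(asff_rescale(asff, x3, 1, 4), "octaves")
})

test_that("the max-pooling stage matches a window-max oracle", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  got <- wv$op_maxpool(wv$ad_const(x), 2L, 2L)$value
  want <- array(0, c(4, 4, 3))
  for (c in 1:3) for (i in 1:4) for (j in 1:4) {
    want[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  }
  expect_equal(got, want)
})

test_that("asff weights are a softmax: in [0,1], summing to one", {
  asff <- new_asff(c(4L, 8L, 16L), seed = 12L)
  set.seed(13)
  maps <- list(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
               array(rnorm(4 * 4 * 8), c(4, 4, 8)),
               array(rnorm(2 * 2 * 16), c(2, 2, 16)))
  for (level in 1:3) {
    w <- asff_weights(asff, maps, level)
    expect_true(all(w$alpha >= 0 & w$alpha <= 1))
    expect_true(all(w$beta >= 0 & w$beta <= 1))
    expect_true(all(w$gamma >= 0 & w$gamma <= 1))
    expect_equal(w$alpha + w$beta + w$gamma,
                 matrix(1, nrow(w$alpha), ncol(w$alpha)),
                 tolerance = 1e-6)
  }
})

test_that("equal logits fuse to the arithmetic mean", {
  set.seed(14)
  maps <- lapply(1:3, function(i) array(rnorm(3 * 3 * 2), c(3, 3, 2)))
  w <- list(alpha = matrix(1 / 3, 3, 3), beta = matrix(1 / 3, 3, 3),
            gamma = matrix(1 / 3, 3, 3))
  fused <- asff_fuse(maps, w)
  expect_equal(fused, (maps[[1]] + maps[[2]] + maps[[3]]) / 3,
               tolerance = 1e-12)
})

test_that("asff fusion equals a per-position loop oracle", {
  set.seed(15)
  maps <- lapply(1:3, function(i) array(rnorm(2 * 2 * 2), c(2, 2, 2)))
  logits <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  e <- exp(logits)
  wts <- list(alpha = e[, , 1], beta = e[, , 2], gamma = e[, , 3])
  z <- wts$alpha + wts$beta + wts$gamma
  wts <- lapply(wts, function(m) m / z)
  fused <- asff_fuse(maps, wts)
  for (i in 1:2) for (j in 1:2) for (c in 1:2) {
    want <- wts$alpha[i, j] * maps[[1]][i, j, c] +
      wts$beta[i, j] * maps[[2]][i, j, c] +
      wts$gamma[i, j] * maps[[3]][i, j, c]
    expect_equal(fused[i, j, c], want, tolerance = 1e-12)
  }
  expect_error(asff_fuse(list(maps[[1]], maps[[2]],
                              array(0, c(3, 3, 2))), wts), "shape")
})

test_that("one dominant logit selects a single source", {
  sm <- wv$op_softmax_c(wv$ad_const(array(c(50, 0, 0), c(1, 1, 3))))$value
  expect_gt(sm[1, 1, 1], 1 - 1e-9)
  expect_lt(max(sm[1, 1, 2:3]), 1e-9)
})

test_that("blocks are deterministic given parameters and input", {
  blk <- new_transformer_encoder(transformer_config(embed_dim = 4L),
                                 seed = 16L)
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_identical(transformer_encoder(x, blk), transformer_encoder(x, blk))
  inv <- new_involution(4L, seed = 17L)
  expect_identical(involution(x, inv), involution(x, inv))
})
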