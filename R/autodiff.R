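## Minimal reverse-mode automatic differentiation on plain R arrays.
##
## A node is an environment holding a value, an accumulated gradient, its
## parent nodes and a backward closure that maps the node's output gradient
## to a list of parent gradients.  Node ids increase in creation order, so
## creation order is a topological order of the tape and backward() can just
## sweep ids downwards.  Feature maps are arrays with dim (H, W, C); token
## matrices are (n_tokens x dim).

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_reset_ids <- function() .ad$id <- 0L

ad_node <- function(value, parents = list(), backward = NULL) {
  # force the promises first: nested op calls must create their nodes before
  # this one takes its id, or creation order stops being topological
  force(value)
  force(parents)
  force(backward)
  .ad$id <- .ad$id + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .ad$id
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  class(node) <- "ad_node"
  node
}

ad_const <- function(value) ad_node(value)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

## Seeds each root node with its gradient, then runs the chain rule over the
## whole reachable tape in reverse creation order.
ad_backward <- function(roots, seeds) {
  if (inherits(roots, "ad_node")) {
    roots <- list(roots)
    seeds <- list(seeds)
  }
  seen <- new.env(parent = emptyenv())
  stack <- roots
  nodes <- list()
  while (length(stack) > 0L) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  for (i in seq_along(roots)) ad_accum(roots[[i]], seeds[[i]])
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  for (n in nodes[ord]) {
    if (is.null(n$backward) || is.null(n$grad)) next
    pg <- n$backward(n$grad)
    for (i in seq_along(n$parents)) {
      if (!is.null(pg[[i]])) ad_accum(n$parents[[i]], pg[[i]])
    }
  }
  invisible(NULL)
}

## ---- elementwise ops --------------------------------------------------

op_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_scale <- function(a, s) {
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

op_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_silu <- function(a) {
  x <- a$value
  s <- 1 / (1 + exp(-x))
  y <- x * s
  ad_node(y, list(a), function(g) list(g * (s * (1 + x * (1 - s)))))
}

op_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

## ---- feature-map (H, W, C) ops ---------------------------------------

op_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  xv <- x$value
  out <- cpp_conv2d_fw(xv, w$value, b$value, as.integer(stride), as.integer(pad))
  H <- dim(xv)[1]; W <- dim(xv)[2]
  K <- dim(w$value)[1]
  ad_node(out, list(x, w, b), function(g) {
    list(
      cpp_conv2d_bw_x(g, w$value, H, W, as.integer(stride), as.integer(pad)),
      cpp_conv2d_bw_w(g, xv, K, as.integer(stride), as.integer(pad)),
      colSums(matrix(g, ncol = dim(g)[3]))
    )
  })
}

op_involution_apply <- function(x, ker, K, G, stride = 1L, pad = 0L) {
  xv <- x$value; kv <- ker$value
  out <- cpp_involution_fw(xv, kv, as.integer(K), as.integer(G),
                           as.integer(stride), as.integer(pad))
  ad_node(out, list(x, ker), function(g) {
    bw <- cpp_involution_bw(g, xv, kv, as.integer(K), as.integer(G),
                            as.integer(stride), as.integer(pad))
    list(bw$gx, bw$gk)
  })
}

op_maxpool <- function(x, k = 2L, stride = 2L) {
  xv <- x$value
  fw <- cpp_maxpool_fw(xv, as.integer(k), as.integer(stride))
  d <- dim(xv)
  ad_node(fw$out, list(x), function(g) {
    list(cpp_maxpool_bw(g, fw$arg, d[1], d[2], d[3]))
  })
}

op_upsample_nearest <- function(x, factor = 2L) {
  xv <- x$value
  d <- dim(xv)
  hi <- rep(seq_len(d[1]), each = factor)
  wi <- rep(seq_len(d[2]), each = factor)
  out <- xv[hi, wi, , drop = FALSE]
  ad_node(out, list(x), function(g) {
    gh <- dim(g)[1]; gw <- dim(g)[2]
    bh <- rep(seq_len(d[1]), each = factor)
    bw <- rep(seq_len(d[2]), each = factor)
    gx <- array(0, dim = d)
    for (a in seq_len(factor)) {
      for (b in seq_len(factor)) {
        gx <- gx + g[seq(a, gh, by = factor), seq(b, gw, by = factor), ,
                     drop = FALSE]
      }
    }
    list(gx)
  })
}

op_concat_c <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  d1 <- dim(vals[[1]])
  out <- array(0, dim = c(d1[1], d1[2], sum(cs)))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  ad_node(out, nodes, function(g) {
    res <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      res[[i]] <- g[, , at + seq_len(cs[i]), drop = FALSE]
      at <- at + cs[i]
    }
    res
  })
}

## Softmax across the channel dimension of an (H, W, C) map (used for the
## per-position fusion weights, C = number of sources).
op_softmax_c <- function(x) {
  xv <- x$value
  m <- apply(xv, c(1, 2), max)
  e <- exp(sweep(xv, c(1, 2), m, "-"))
  z <- apply(e, c(1, 2), sum)
  s <- sweep(e, c(1, 2), z, "/")
  ad_node(s, list(x), function(g) {
    dot <- apply(g * s, c(1, 2), sum)
    list(s * sweep(g, c(1, 2), dot, "-"))
  })
}

## Select channel i of an (H, W, C) map, keeping (H, W, 1).
op_channel <- function(x, i) {
  d <- dim(x$value)
  ad_node(x$value[, , i, drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, , i] <- g
    list(gx)
  })
}

## Multiply every channel of map x by a single-channel weight map w (H, W, 1).
op_mul_bcast <- function(x, w) {
  xv <- x$value
  wv <- w$value[, , 1]
  out <- sweep(xv, c(1, 2), wv, "*")
  ad_node(out, list(x, w), function(g) {
    gw <- apply(g * xv, c(1, 2), sum)
    dim(gw) <- c(dim(xv)[1], dim(xv)[2], 1)
    list(sweep(g, c(1, 2), wv, "*"), gw)
  })
}

## ---- token-matrix (N x D) ops (transformer) ---------------------------

op_map_to_tokens <- function(x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  ad_node(matrix(x$value, nrow = n, ncol = d[3]), list(x), function(g) {
    list(array(g, dim = d))
  })
}

op_tokens_to_map <- function(x, H, W) {
  D <- ncol(x$value)
  ad_node(array(x$value, dim = c(H, W, D)), list(x), function(g) {
    list(matrix(g, nrow = H * W, ncol = D))
  })
}

op_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

op_transpose <- function(a) {
  ad_node(t(a$value), list(a), function(g) list(t(g)))
}

op_add_rowbias <- function(a, b) {
  ad_node(sweep(a$value, 2, b$value, "+"), list(a, b), function(g) {
    list(g, colSums(g))
  })
}

op_softmax_rows <- function(a) {
  x <- a$value
  m <- apply(x, 1, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

op_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  D <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  y <- sweep(xh, 2, gamma$value, "*")
  y <- sweep(y, 2, beta$value, "+")
  ad_node(y, list(a, gamma, beta), function(g) {
    gg <- sweep(g, 2, gamma$value, "*")
    m1 <- rowMeans(gg)
    m2 <- rowMeans(gg * xh)
    list((gg - m1 - xh * m2) * inv,
         colSums(g * xh),
         colSums(g))
  })
}

op_slice_cols <- function(a, cols) {
  D <- ncol(a$value)
  ad_node(a$value[, cols, drop = FALSE], list(a), function(g) {
    gx <- matrix(0, nrow = nrow(g), ncol = D)
    gx[, cols] <- g
    list(gx)
  })
}

op_concat_cols <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), numeric(1))
  ad_node(do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(g) {
    res <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      res[[i]] <- g[, at + seq_len(widths[i]), drop = FALSE]
      at <- at + widths[i]
    }
    res
  })
}
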