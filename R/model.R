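#' Detector configuration
#'
#' A width/depth-configurable single-stage detector: CSP backbone (with a
#' transformer encoder block at its backend), PANet-style top-down +
#' bottom-up neck optionally bridged by CFFI, and a three-scale prediction
#' head optionally fused by ASFF.  The three block toggles are independent
#' so the ablation grid is constructible.
#'
#' @param input_size square input size in pixels, divisible by 32.
#' @param width_multiple,depth_multiple channel and repeat scaling of the
#'   full-scale topology; the desk-scale defaults (0.125 / 0.33) keep a
#'   forward pass in the tens of milliseconds on one CPU.
#' @param n_classes number of object classes (crop, weed).
#' @param anchors list of three matrices (one per level, fine to coarse),
#'   each `n_anchors x 2` of `(w, h)` pixel pairs.
#' @param strides per-level strides, `c(8, 16, 32)`.
#' @param use_transformer,use_cffi,use_asff block toggles.
#' @param seed RNG seed for weight initialisation.
#' @export
model_config <- function(input_size = 96L,
                         width_multiple = 0.125,
                         depth_multiple = 0.33,
                         n_classes = 2L,
                         anchors = NULL,
                         strides = c(8L, 16L, 32L),
                         use_transformer = TRUE,
                         use_cffi = TRUE,
                         use_asff = TRUE,
                         seed = 1L) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) {
    stop("input_size must be divisible by 32")
  }
  if (is.null(anchors)) {
    anchors <- list(
      matrix(c(5, 5, 8, 8, 12, 12), ncol = 2, byrow = TRUE),
      matrix(c(16, 16, 22, 22, 30, 30), ncol = 2, byrow = TRUE),
      matrix(c(40, 40, 56, 56, 76, 76), ncol = 2, byrow = TRUE))
  }
  stopifnot(length(anchors) == 3L,
            all(vapply(anchors, function(a) all(a > 0), logical(1))))
  structure(list(input_size = input_size,
                 width_multiple = width_multiple,
                 depth_multiple = depth_multiple,
                 n_classes = as.integer(n_classes),
                 anchors = anchors,
                 strides = as.integer(strides),
                 use_transformer = isTRUE(use_transformer),
                 use_cffi = isTRUE(use_cffi),
                 use_asff = isTRUE(use_asff),
                 seed = seed),
            class = "model_config")
}

make_divisible <- function(x, d = 4L) max(d, as.integer(round(x / d) * d))

#' Build a detector from a configuration
#'
#' @param config a [model_config()].  Weight initialisation is seeded by
#'   `config$seed`, so the same configuration always yields identical
#'   initial parameters.
#' @return A `wv_detector` object.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  wm <- config$width_multiple
  dm <- config$depth_multiple
  ch <- vapply(c(64, 128, 256, 512, 1024),
               function(x) make_divisible(x * wm), integer(1))
  reps <- vapply(c(3, 6, 9, 3), function(x) max(1L, as.integer(round(x * dm))),
                 integer(1))
  c1 <- ch[1]; c2 <- ch[2]; c3 <- ch[3]; c4 <- ch[4]; c5 <- ch[5]
  tcfg <- transformer_config(embed_dim = c5 %/% 2L, n_heads = 2L,
                             mlp_ratio = 2)
  backbone <- list(
    stem = layer_conv(3L, c1, 3L, stride = 2L),
    down1 = layer_conv(c1, c2, 3L, stride = 2L),
    csp1 = layer_csp(c2, c2, reps[1]),
    down2 = layer_conv(c2, c3, 3L, stride = 2L),
    csp2 = layer_csp(c3, c3, reps[2]),
    down3 = layer_conv(c3, c4, 3L, stride = 2L),
    csp3 = layer_csp(c4, c4, reps[3]),
    down4 = layer_conv(c4, c5, 3L, stride = 2L),
    csp4 = layer_csp(c5, c5, reps[4],
                     transformer = config$use_transformer, tcfg = tcfg))
  wcffi <- make_divisible(768 * wm)
  cffi_block <- if (config$use_cffi) layer_cffi(c5, wcffi) else NULL
  top_ch <- if (config$use_cffi) 2L * wcffi else c5
  neck <- list(
    lat5 = layer_conv(top_ch, c4, 1L),
    csp_n4 = layer_csp(2L * c4, c4, 1L),
    lat4 = layer_conv(c4, c3, 1L),
    csp_n3 = layer_csp(2L * c3, c3, 1L),
    down_p3 = layer_conv(c3, c3, 3L, stride = 2L),
    csp_p4 = layer_csp(2L * c3, c4, 1L),
    down_p4 = layer_conv(c4, c4, 3L, stride = 2L),
    csp_p5 = layer_csp(2L * c4, c5, 1L))
  head_ch <- c(c3, c4, c5)
  na <- nrow(config$anchors[[1]])
  nout <- na * (5L + config$n_classes)
  asff <- if (config$use_asff) {
    lapply(1:3, function(l) layer_asff_level(head_ch, l))
  } else NULL
  predict <- lapply(head_ch, function(cl) {
    layer_conv(cl, nout, 1L, act = FALSE)
  })
  structure(list(config = config, backbone = backbone, cffi = cffi_block,
                 neck = neck, asff = asff, predict = predict,
                 channels = ch, head_channels = head_ch),
            class = "wv_detector")
}

#' @export
print.wv_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<wv_detector input=%d width=%.3g depth=%.3g ",
                     "transformer=%s cffi=%s asff=%s params=%d>\n"),
              cfg$input_size, cfg$width_multiple, cfg$depth_multiple,
              cfg$use_transformer, cfg$use_cffi, cfg$use_asff,
              n_parameters(unclass(x))))
  invisible(x)
}

## Forward pass on one image; x is an (H, W, 3) array scaled to [0, 1].
## Returns a list of three prediction nodes (fine to coarse).
detector_forward <- function(model, x, ctx) {
  bb <- model$backbone
  h <- fwd_conv(bb$stem, ctx, ad_const(x))
  h <- fwd_csp(bb$csp1, ctx, fwd_conv(bb$down1, ctx, h))
  p3_in <- fwd_csp(bb$csp2, ctx, fwd_conv(bb$down2, ctx, h))   # stride 8
  p4_in <- fwd_csp(bb$csp3, ctx, fwd_conv(bb$down3, ctx, p3_in))  # 16
  c5 <- fwd_csp(bb$csp4, ctx, fwd_conv(bb$down4, ctx, p4_in))  # 32
  top <- if (!is.null(model$cffi)) fwd_cffi(model$cffi, ctx, c5) else c5
  nk <- model$neck
  lat5 <- fwd_conv(nk$lat5, ctx, top)
  n4 <- fwd_csp(nk$csp_n4, ctx,
                op_concat_c(list(op_upsample_nearest(lat5, 2L), p4_in)))
  lat4 <- fwd_conv(nk$lat4, ctx, n4)
  p3 <- fwd_csp(nk$csp_n3, ctx,
                op_concat_c(list(op_upsample_nearest(lat4, 2L), p3_in)))
  p4 <- fwd_csp(nk$csp_p4, ctx,
                op_concat_c(list(fwd_conv(nk$down_p3, ctx, p3), lat4)))
  p5 <- fwd_csp(nk$csp_p5, ctx,
                op_concat_c(list(fwd_conv(nk$down_p4, ctx, p4), lat5)))
  maps <- list(p3, p4, p5)
  if (!is.null(model$asff)) {
    maps <- lapply(1:3, function(l) {
      fwd_asff_level(model$asff[[l]], ctx, maps)$fused
    })
  }
  lapply(1:3, function(l) fwd_conv(model$predict[[l]], ctx, maps[[l]]))
}

#' Run the detector on one image
#'
#' @param model a [build_model()] detector.
#' @param pixels `(H, W, 3)` array of 8-bit intensities; must match the
#'   configured input size.
#' @return List of three prediction arrays, each
#'   `(H/stride, W/stride, n_anchors * (5 + n_classes))`.
#' @export
predict_raw <- function(model, pixels) {
  d <- dim(pixels)
  if (d[1] != model$config$input_size || d[2] != model$config$input_size) {
    stop("image size does not match the configured input size")
  }
  ctx <- ad_ctx(grad = FALSE)
  lapply(detector_forward(model, pixels / 255, ctx), function(n) n$value)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Decode raw predictions to scored boxes (pre-NMS)
#'
#' The usual anchor transform: the box centre is
#' `(2 sigmoid(t_xy) - 0.5 + cell) * stride`, the size is
#' `(2 sigmoid(t_wh))^2 * anchor`, and the confidence is the product of the
#' objectness and class sigmoids.  Each anchor emits its best class.
#'
#' @param preds list of three prediction arrays from [predict_raw()].
#' @param config the [model_config()] used to produce them.
#' @param image_id id attached to the returned rows.
#' @return data.frame with `image_id`, `class_id`, `conf`, `x1`, `y1`,
#'   `x2`, `y2` (pixels).
#' @export
decode <- function(preds, config, image_id = "img") {
  nc <- config$n_classes
  out <- list()
  for (l in 1:3) {
    p <- preds[[l]]
    s <- config$strides[l]
    anchors <- config$anchors[[l]]
    na <- nrow(anchors)
    Hl <- dim(p)[1]; Wl <- dim(p)[2]
    gx <- matrix(seq_len(Wl) - 1, Hl, Wl, byrow = TRUE)
    gy <- matrix(seq_len(Hl) - 1, Hl, Wl)
    for (a in seq_len(na)) {
      base <- (a - 1L) * (5L + nc)
      bx <- (2 * sigmoid(p[, , base + 1]) - 0.5 + gx) * s
      by <- (2 * sigmoid(p[, , base + 2]) - 0.5 + gy) * s
      bw <- (2 * sigmoid(p[, , base + 3]))^2 * anchors[a, 1]
      bh <- (2 * sigmoid(p[, , base + 4]))^2 * anchors[a, 2]
      obj <- sigmoid(p[, , base + 5])
      cls <- array(sigmoid(p[, , base + 5 + seq_len(nc)]),
                   dim = c(Hl, Wl, nc))
      best <- apply(cls, c(1, 2), which.max)
      bestp <- apply(cls, c(1, 2), max)
      out[[length(out) + 1L]] <- data.frame(
        image_id = image_id,
        class_id = as.integer(best) - 1L,
        conf = as.numeric(obj * bestp),
        x1 = as.numeric(bx - bw / 2), y1 = as.numeric(by - bh / 2),
        x2 = as.numeric(bx + bw / 2), y2 = as.numeric(by + bh / 2))
    }
  }
  do.call(rbind, out)
}

#' Greedy class-wise non-maximum suppression
#'
#' Keeps the highest-confidence box, removes same-class boxes overlapping
#' it above the IoU threshold, and repeats.  Survivors come back sorted by
#' descending confidence.
#'
#' @param dets data.frame with `class_id`, `conf`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_threshold suppression threshold.
#' @param conf_threshold minimum confidence kept.
#' @export
nms <- function(dets, iou_threshold = 0.45, conf_threshold = 0.25) {
  dets <- dets[dets$conf >= conf_threshold, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  keep <- list()
  for (cl in unique(dets$class_id)) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    d <- d[order(-d$conf), , drop = FALSE]
    n <- nrow(d)
    alive <- rep(TRUE, n)
    area <- (d$x2 - d$x1) * (d$y2 - d$y1)
    for (i in seq_len(n)) {
      if (!alive[i]) next
      later <- alive & seq_len(n) > i
      if (!any(later)) next
      j <- which(later)
      iw <- pmax(0, pmin(d$x2[i], d$x2[j]) - pmax(d$x1[i], d$x1[j]))
      ih <- pmax(0, pmin(d$y2[i], d$y2[j]) - pmax(d$y1[i], d$y1[j]))
      inter <- iw * ih
      iou <- ifelse(area[i] + area[j] - inter > 0,
                    inter / (area[i] + area[j] - inter), 0)
      alive[j[iou > iou_threshold]] <- FALSE
    }
    keep[[length(keep) + 1L]] <- d[alive, , drop = FALSE]
  }
  out <- do.call(rbind, keep)
  out[order(-out$conf), , drop = FALSE]
}

## ---- loss -------------------------------------------------------------

## Complete IoU between two (cx, cy, w, h) boxes.
ciou_xywh <- function(a, b, eps = 1e-9) {
  ax1 <- a[1] - a[3] / 2; ax2 <- a[1] + a[3] / 2
  ay1 <- a[2] - a[4] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; bx2 <- b[1] + b[3] / 2
  by1 <- b[2] - b[4] / 2; by2 <- b[2] + b[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  union <- a[3] * a[4] + b[3] * b[4] - inter + eps
  iou <- inter / union
  cw <- max(ax2, bx2) - min(ax1, bx1)
  chh <- max(ay2, by2) - min(ay1, by1)
  c2 <- cw^2 + chh^2 + eps
  rho2 <- (a[1] - b[1])^2 + (a[2] - b[2])^2
  v <- (4 / pi^2) * (atan(b[3] / (b[4] + eps)) - atan(a[3] / (a[4] + eps)))^2
  alpha <- v / (1 - iou + v + eps)
  iou - rho2 / c2 - alpha * v
}

decode_one_box <- function(traw, cell_xy, stride, anchor) {
  c((2 * sigmoid(traw[1]) - 0.5 + cell_xy[1]) * stride,
    (2 * sigmoid(traw[2]) - 0.5 + cell_xy[2]) * stride,
    (2 * sigmoid(traw[3]))^2 * anchor[1],
    (2 * sigmoid(traw[4]))^2 * anchor[2])
}

## Anchor/cell assignment following the usual single-stage convention: a gt
## box matches every anchor within a factor-4 w/h ratio on its level, on its
## own grid cell plus the nearest neighbour cell in x and in y.
build_targets <- function(truth_px, config) {
  res <- list()
  if (nrow(truth_px) == 0) return(res)
  for (l in 1:3) {
    s <- config$strides[l]
    anchors <- config$anchors[[l]]
    Hl <- config$input_size %/% s
    for (ti in seq_len(nrow(truth_px))) {
      b <- truth_px[ti, ]
      for (a in seq_len(nrow(anchors))) {
        rw <- b$w / anchors[a, 1]; rh <- b$h / anchors[a, 2]
        if (max(rw, 1 / rw, rh, 1 / rh) >= 4) next
        gx <- b$cx / s; gy <- b$cy / s
        cx0 <- floor(gx); cy0 <- floor(gy)
        cells <- list(c(cx0, cy0))
        if (gx - cx0 < 0.5 && cx0 >= 1) {
          cells <- c(cells, list(c(cx0 - 1, cy0)))
        } else if (gx - cx0 >= 0.5 && cx0 < Hl - 1) {
          cells <- c(cells, list(c(cx0 + 1, cy0)))
        }
        if (gy - cy0 < 0.5 && cy0 >= 1) {
          cells <- c(cells, list(c(cx0, cy0 - 1)))
        } else if (gy - cy0 >= 0.5 && cy0 < Hl - 1) {
          cells <- c(cells, list(c(cx0, cy0 + 1)))
        }
        for (cell in cells) {
          if (cell[1] < 0 || cell[1] >= Hl || cell[2] < 0 ||
              cell[2] >= Hl) next
          res[[length(res) + 1L]] <- list(level = l, anchor = a,
                                          cell = cell, truth = ti)
        }
      }
    }
  }
  res
}

bce_with_logits <- function(x, t) {
  # numerically stable: max(x,0) - x*t + log1p(exp(-|x|))
  pmax(x, 0) - x * t + log1p(exp(-abs(x)))
}

#' Composite detection loss (and its gradients)
#'
#' Box regression (1 - complete-IoU over assigned anchors), objectness
#' binary cross-entropy over all cells (per-level balance 4 / 1 / 0.4) and
#' classification binary cross-entropy over assigned anchors, combined as
#' `0.05 box + 1.0 obj + 0.5 cls`.  The box-term gradient with respect to
#' the four raw activations is taken by central finite differences through
#' the complete-IoU (step 1e-4); the cross-entropy gradients are analytic.
#'
#' @param preds list of three raw prediction arrays.
#' @param truth data.frame of ground-truth boxes in normalized center
#'   format (`class_id`, `cx`, `cy`, `w`, `h`).
#' @param config the [model_config()].
#' @return List with `box`, `obj`, `cls`, `total` (all finite, >= 0) and
#'   `grads`, a list of gradient arrays matching `preds`.
#' @export
detection_loss <- function(preds, truth, config) {
  nc <- config$n_classes
  isz <- config$input_size
  truth_px <- if (nrow(truth) > 0) {
    data.frame(class_id = truth$class_id, cx = truth$cx * isz,
               cy = truth$cy * isz, w = truth$w * isz, h = truth$h * isz)
  } else truth
  targets <- build_targets(truth_px, config)
  grads <- lapply(preds, function(p) array(0, dim = dim(p)))
  obj_t <- lapply(preds, function(p) array(0, dim = dim(p)))
  # box term weighted well above the usual full-scale gain: with one image
  # per step and few assigned anchors the localisation gradient is otherwise
  # too small to move the raw activations in a short desk-scale run
  w_box <- 1.0; w_obj <- 1.0; w_cls <- 0.5
  balance <- c(4.0, 1.0, 0.4)
  loss_box <- 0; loss_cls <- 0
  nt <- length(targets)
  hfd <- 1e-4
  for (tg in targets) {
    l <- tg$level; a <- tg$anchor
    p <- preds[[l]]
    base <- (a - 1L) * (5L + nc)
    i <- tg$cell[2] + 1L  # row (y)
    j <- tg$cell[1] + 1L  # col (x)
    traw <- p[i, j, base + 1:4]
    gt <- unlist(truth_px[tg$truth, c("cx", "cy", "w", "h")])
    anc <- config$anchors[[l]][a, ]
    f0 <- 1 - ciou_xywh(decode_one_box(traw, tg$cell, config$strides[l], anc),
                        gt)
    loss_box <- loss_box + f0
    for (k in 1:4) {
      tp <- traw; tm <- traw
      tp[k] <- tp[k] + hfd; tm[k] <- tm[k] - hfd
      fp <- 1 - ciou_xywh(decode_one_box(tp, tg$cell, config$strides[l], anc),
                          gt)
      fm <- 1 - ciou_xywh(decode_one_box(tm, tg$cell, config$strides[l], anc),
                          gt)
      grads[[l]][i, j, base + k] <- grads[[l]][i, j, base + k] +
        w_box * (fp - fm) / (2 * hfd) / max(1, nt)
    }
    obj_t[[l]][i, j, base + 5] <- 1
    cls_idx <- base + 5 + seq_len(nc)
    one_hot <- as.numeric(seq_len(nc) - 1L == truth_px$class_id[tg$truth])
    xcls <- p[i, j, cls_idx]
    loss_cls <- loss_cls + sum(bce_with_logits(xcls, one_hot))
    grads[[l]][i, j, cls_idx] <- grads[[l]][i, j, cls_idx] +
      w_cls * (sigmoid(xcls) - one_hot) / max(1, nt)
  }
  loss_obj <- 0
  for (l in 1:3) {
    nc5 <- 5L + nc
    na <- nrow(config$anchors[[l]])
    obj_idx <- as.vector(outer(5L, (seq_len(na) - 1L) * nc5, "+"))
    x <- preds[[l]][, , obj_idx, drop = FALSE]
    t <- obj_t[[l]][, , obj_idx, drop = FALSE]
    n <- length(x)
    loss_obj <- loss_obj + balance[l] * mean(bce_with_logits(x, t))
    grads[[l]][, , obj_idx] <- grads[[l]][, , obj_idx] +
      w_obj * balance[l] * (sigmoid(x) - t) / n
  }
  box <- w_box * loss_box / max(1, nt)
  cls <- w_cls * loss_cls / max(1, nt)
  obj <- w_obj * loss_obj
  total <- box + obj + cls
  if (!is.finite(total)) {
    bad <- c(box = box, obj = obj, cls = cls)
    stop("non-finite detection loss in component(s): ",
         paste(names(bad)[!is.finite(bad)], collapse = ", "))
  }
  list(box = box, obj = obj, cls = cls, total = total, grads = grads)
}

## ---- training ---------------------------------------------------------

#' Train the detector with SGD
#'
#' Plain stochastic gradient descent with momentum, one image per step, on
#' a single CPU thread; deterministic given the seed (the model must have
#' been built with a seeded configuration).  Logs per-epoch mean loss
#' components and, if a validation set is given, mAP@0.5 before and after
#' training.
#'
#' @param model a [build_model()] detector (updated in place).
#' @param train_images list of [annotated_image()] at the configured input
#'   size.
#' @param val_images optional held-out list for mAP evaluation.
#' @param epochs,lr,momentum,weight_decay optimizer hyperparameters.
#' @param max_grad_norm global L2 gradient-clipping threshold.
#' @param seed RNG seed for data ordering.
#' @param conf_threshold confidence cut used in the validation evaluation.
#' @param verbose print per-epoch losses.
#' @return A `train_state` list: `history` data.frame (epoch, box, obj,
#'   cls, total), `val_map50_before`, `val_map50_after`, hyperparameters
#'   and seed.
#' @export
train_detector <- function(model, train_images, val_images = NULL,
                           epochs = 30L, lr = 5e-3, momentum = 0.9,
                           weight_decay = 0, max_grad_norm = 5,
                           seed = 1L, conf_threshold = 0.1,
                           verbose = FALSE) {
  stopifnot(length(train_images) > 0)
  val_before <- if (!is.null(val_images)) {
    evaluate_model(model, val_images, conf_threshold = conf_threshold)$map50
  } else NA_real_
  set.seed(seed)
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(train_images))
    comp <- c(box = 0, obj = 0, cls = 0, total = 0)
    for (ii in ord) {
      im <- train_images[[ii]]
      ctx <- ad_ctx()
      pred_nodes <- detector_forward(model, im$pixels / 255, ctx)
      ls <- detection_loss(lapply(pred_nodes, function(n) n$value),
                           im$boxes, model$config)
      ad_backward(pred_nodes, ls$grads)
      sgd_step(ctx, lr, momentum, weight_decay, max_grad_norm)
      comp <- comp + c(ls$box, ls$obj, ls$cls, ls$total)
    }
    comp <- comp / length(train_images)
    history <- rbind(history,
                     data.frame(epoch = ep, box = comp[1], obj = comp[2],
                                cls = comp[3], total = comp[4],
                                row.names = NULL))
    if (verbose) {
      message(sprintf("epoch %3d  box %.4f  obj %.4f  cls %.4f  total %.4f",
                      ep, comp[1], comp[2], comp[3], comp[4]))
    }
  }
  val_after <- if (!is.null(val_images)) {
    evaluate_model(model, val_images, conf_threshold = conf_threshold)$map50
  } else NA_real_
  structure(list(history = history, epochs = epochs, seed = seed,
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 val_map50_before = val_before, val_map50_after = val_after),
            class = "train_state")
}

#' Detect objects in images
#'
#' @param model a trained detector.
#' @param images an [annotated_image()], a raw pixel array, or a list of
#'   either.
#' @param conf_threshold,iou_threshold NMS parameters.
#' @return data.frame of detections across the images.
#' @export
detect_objects <- function(model, images, conf_threshold = 0.25,
                           iou_threshold = 0.45) {
  if (inherits(images, "annotated_image") ||
      (is.array(images) && length(dim(images)) == 3L)) {
    images <- list(images)
  }
  out <- list()
  for (k in seq_along(images)) {
    im <- images[[k]]
    px <- if (inherits(im, "annotated_image")) im$pixels else im
    id <- if (inherits(im, "annotated_image")) im$image_id else
      sprintf("img_%03d", k)
    preds <- predict_raw(model, px)
    d <- nms(decode(preds, model$config, image_id = id),
             iou_threshold = iou_threshold,
             conf_threshold = conf_threshold)
    out[[k]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate a detector on annotated images
#'
#' Runs detection at a permissive confidence threshold and scores the
#' result with the full metrics suite.
#'
#' @param model detector.
#' @param images list of [annotated_image()].
#' @param conf_threshold NMS confidence cut (kept low so the
#'   precision-recall sweep sees the full ranking).
#' @param iou_threshold NMS suppression threshold.
#' @export
evaluate_model <- function(model, images, conf_threshold = 0.1,
                           iou_threshold = 0.45) {
  dets <- detect_objects(model, images, conf_threshold = conf_threshold,
                         iou_threshold = iou_threshold)
  isz <- model$config$input_size
  truths <- do.call(rbind, lapply(images, function(im) {
    if (nrow(im$boxes) == 0) return(NULL)
    cbind(image_id = im$image_id,
          yolo_to_xyxy(im$boxes, isz, isz))
  }))
  evaluate_detections(dets, truths,
                      classes = seq_len(model$config$n_classes) - 1L)
}

#' Save / load detector weights
#'
#' Checkpoints store every layer parameter (flattened), the configuration
#' and the RNG-relevant metadata as an RDS file.
#'
#' @param model detector.
#' @param path checkpoint file.
#' @export
save_weights <- function(model, path) {
  lys <- collect_layers(unclass(model))
  params <- lapply(lys, function(ly) {
    fields <- intersect(.trainable_fields, ls(ly))
    stats::setNames(lapply(fields, function(nm) get(nm, envir = ly)), fields)
  })
  saveRDS(list(config = model$config, params = params), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  lys <- collect_layers(unclass(model))
  stopifnot(length(lys) == length(ck$params))
  for (i in seq_along(lys)) {
    for (nm in names(ck$params[[i]])) {
      assign(nm, ck$params[[i]][[nm]], envir = lys[[i]])
    }
  }
  model
}
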