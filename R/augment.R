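#' Region-growing configuration
#'
#' @param connectivity 4 or 8 pixel neighbourhood.
#' @param color_distance_threshold maximum Euclidean RGB distance to the
#'   seed pixel's colour (0..441 scale for 8-bit images).  The criterion is
#'   fixed at the seed colour rather than a running region mean, which makes
#'   the grown region independent of the neighbour visiting order.
#' @param seed_strategy `"max_excess_green"` (pick the pixel of maximum
#'   2G - R - B inside the candidate region) or `"manual"`.
#' @param max_region_pixels upper bound on the region size; exceeding it is
#'   an error naming the bound.
#' @export
region_grow_config <- function(connectivity = 8L,
                               color_distance_threshold = 60,
                               seed_strategy = c("max_excess_green",
                                                 "manual"),
                               max_region_pixels = 50000L) {
  stopifnot(connectivity %in% c(4L, 8L), color_distance_threshold >= 0)
  structure(list(connectivity = as.integer(connectivity),
                 color_distance_threshold = color_distance_threshold,
                 seed_strategy = match.arg(seed_strategy),
                 max_region_pixels = as.integer(max_region_pixels)),
            class = "region_grow_config")
}

#' Region growing from a seed pixel
#'
#' Breadth-first growth over the configured connectivity, absorbing
#' neighbours whose Euclidean RGB distance to the seed pixel's colour is at
#' most the threshold.
#'
#' @param image `(H, W, 3)` array.
#' @param seed_point `(row, col)` 1-based pixel coordinate inside the image.
#' @param config a [region_grow_config()].
#' @return Logical `(H, W)` mask containing the seed.
#' @export
region_grow <- function(image, seed_point, config = region_grow_config()) {
  d <- dim(image)
  if (seed_point[1] < 1 || seed_point[1] > d[1] ||
      seed_point[2] < 1 || seed_point[2] > d[2]) {
    stop("seed point lies outside the image")
  }
  mask <- cpp_region_grow(image, as.integer(seed_point[1]) - 1L,
                          as.integer(seed_point[2]) - 1L,
                          config$color_distance_threshold,
                          config$connectivity,
                          config$max_region_pixels)
  if (isTRUE(attr(mask, "overflow"))) {
    stop(sprintf("region exceeded max_region_pixels = %d",
                 config$max_region_pixels))
  }
  attr(mask, "overflow") <- NULL
  mask
}

#' Weed patch
#'
#' An irregular set of weed pixels extracted from a sub-image: RGB values,
#' the binary mask (a single connected component), the tight bounding box
#' and the originating image id.
#'
#' @param pixels `(h, w, 3)` array cropped to the mask's tight extent.
#' @param mask logical `(h, w)` matrix with at least one TRUE pixel.
#' @param bbox original-image pixel bbox `c(hmin, hmax, wmin, wmax)`.
#' @param origin_image id of the source image.
#' @export
weed_patch <- function(pixels, mask, bbox, origin_image = "") {
  stopifnot(any(mask), identical(dim(pixels)[1:2], dim(mask)))
  if (!any(mask[1, ]) || !any(mask[nrow(mask), ]) ||
      !any(mask[, 1]) || !any(mask[, ncol(mask)])) {
    stop("weed patch bbox is not tight around the mask")
  }
  structure(list(pixels = pixels, mask = mask, bbox = bbox,
                 origin_image = origin_image),
            class = "weed_patch")
}

#' Extract weed patches from a weed-only sub-image
#'
#' For every weed box the seed pixel is chosen by the configured strategy
#' (maximum excess-green inside the box by default), the weed is segmented
#' by region growing restricted to the box, and the result is cropped to its
#' tight extent.  Boxes whose segmentation comes out empty (no vegetation at
#' the seed) are reported in the `failed` attribute rather than silently
#' dropped.
#'
#' @param subimage an [annotated_image()] containing only weed-class boxes.
#' @param config a [region_grow_config()].
#' @return List of [weed_patch()] objects; attribute `failed` holds indices
#'   of boxes whose segmentation failed.
#' @export
extract_weed_patches <- function(subimage, config = region_grow_config()) {
  stopifnot(inherits(subimage, "annotated_image"))
  if (any(subimage$boxes$class_id != 1L)) {
    stop("sub-image must contain only weed-class boxes")
  }
  d <- dim(subimage$pixels)
  H <- d[1]; W <- d[2]
  patches <- list()
  failed <- integer()
  for (i in seq_len(nrow(subimage$boxes))) {
    b <- subimage$boxes[i, ]
    h1 <- max(1L, floor((b$cy - b$h / 2) * H) + 1L)
    h2 <- min(H, ceiling((b$cy + b$h / 2) * H))
    w1 <- max(1L, floor((b$cx - b$w / 2) * W) + 1L)
    w2 <- min(W, ceiling((b$cx + b$w / 2) * W))
    crop <- subimage$pixels[h1:h2, w1:w2, , drop = FALSE]
    exg <- excess_green(crop)
    if (config$seed_strategy == "max_excess_green") {
      sp <- which(exg == max(exg), arr.ind = TRUE)[1, ]
    } else {
      sp <- c(nrow(crop) %/% 2L + 1L, ncol(crop) %/% 2L + 1L)
    }
    if (exg[sp[1], sp[2]] <= 0) {
      failed <- c(failed, i)
      next
    }
    m <- region_grow(crop, sp, config)
    bb <- mask_bbox_px(m)
    patches[[length(patches) + 1L]] <- weed_patch(
      crop[bb["hmin"]:bb["hmax"], bb["wmin"]:bb["wmax"], , drop = FALSE],
      m[bb["hmin"]:bb["hmax"], bb["wmin"]:bb["wmax"], drop = FALSE],
      bbox = c(hmin = h1 + bb[["hmin"]] - 1L, hmax = h1 + bb[["hmax"]] - 1L,
               wmin = w1 + bb[["wmin"]] - 1L, wmax = w1 + bb[["wmax"]] - 1L),
      origin_image = subimage$image_id)
  }
  attr(patches, "failed") <- failed
  patches
}

#' Paste configuration for pixel-level synthesization
#'
#' @param n_paste_per_image number of weed patches pasted into each image.
#' @param max_overlap_iou maximum IoU of a pasted patch's box against any
#'   existing (or previously pasted) box.
#' @param scale_jitter multiplicative `(min, max)` resize range applied to
#'   the patch (nearest-neighbour).
#' @param flip allow random horizontal flips of the patch.
#' @param seed RNG seed.
#' @export
paste_config <- function(n_paste_per_image = 2L, max_overlap_iou = 0.05,
                         scale_jitter = c(1, 1), flip = FALSE, seed = 1L) {
  stopifnot(n_paste_per_image >= 0L, max_overlap_iou >= 0,
            max_overlap_iou <= 1, all(scale_jitter > 0))
  structure(list(n_paste_per_image = as.integer(n_paste_per_image),
                 max_overlap_iou = max_overlap_iou,
                 scale_jitter = scale_jitter, flip = flip, seed = seed),
            class = "paste_config")
}

resize_patch_nn <- function(patch, s) {
  d <- dim(patch$mask)
  nh <- max(1L, round(d[1] * s))
  nw <- max(1L, round(d[2] * s))
  hi <- pmin(d[1], pmax(1L, round((seq_len(nh) - 0.5) / nh * d[1] + 0.5)))
  wi <- pmin(d[2], pmax(1L, round((seq_len(nw) - 0.5) / nw * d[2] + 0.5)))
  list(pixels = patch$pixels[hi, wi, , drop = FALSE],
       mask = patch$mask[hi, wi, drop = FALSE])
}

#' Synthesize an image by pasting weed patches
#'
#' Places `n_paste_per_image` patches sampled from the bank into the base
#' image by rejection sampling: a placement is accepted only when the
#' patch's box is fully inside the image and overlaps every existing box by
#' at most `max_overlap_iou`.  Pasted pixels replace the background only
#' under the patch mask; all original pixels outside pasted masks and all
#' original annotations are preserved verbatim.  Deterministic given
#' `config$seed`.
#'
#' @param base an [annotated_image()] with provenance `"original"`.
#' @param bank non-empty list of [weed_patch()] objects (unless no paste is
#'   requested).
#' @param config a [paste_config()].
#' @param image_id id for the synthetic image.
#' @return A synthetic [annotated_image()] whose `source_id` is the base id.
#' @export
synthesize_image <- function(base, bank, config = paste_config(),
                             image_id = NULL) {
  stopifnot(inherits(base, "annotated_image"))
  n <- config$n_paste_per_image
  if (n > 0L && length(bank) == 0L) stop("patch bank is empty")
  if (is.null(image_id)) image_id <- paste0(base$image_id, "_syn")
  set.seed(config$seed)
  d <- dim(base$pixels)
  H <- d[1]; W <- d[2]
  px <- base$pixels
  boxes <- base$boxes
  existing <- if (nrow(boxes) > 0) {
    lapply(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      c((b$cx - b$w / 2) * W, (b$cy - b$h / 2) * H,
        (b$cx + b$w / 2) * W, (b$cy + b$h / 2) * H)
    })
  } else list()
  max_attempts <- 100L
  for (k in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      patch <- bank[[sample.int(length(bank), 1L)]]
      s <- stats::runif(1, config$scale_jitter[1], config$scale_jitter[2])
      pp <- if (s == 1) list(pixels = patch$pixels, mask = patch$mask)
            else resize_patch_nn(patch, s)
      if (isTRUE(config$flip) && stats::runif(1) < 0.5) {
        pp$pixels <- pp$pixels[, rev(seq_len(ncol(pp$mask))), , drop = FALSE]
        pp$mask <- pp$mask[, rev(seq_len(ncol(pp$mask))), drop = FALSE]
      }
      ph <- nrow(pp$mask); pw <- ncol(pp$mask)
      if (ph > H || pw > W) next
      h0 <- sample.int(H - ph + 1L, 1L)
      w0 <- sample.int(W - pw + 1L, 1L)
      bb <- mask_bbox_px(pp$mask)
      cand <- c(w0 + bb[["wmin"]] - 2, h0 + bb[["hmin"]] - 2,
                w0 + bb[["wmax"]] - 1, h0 + bb[["hmax"]] - 1)
      ok <- all(vapply(existing, function(b) {
        box_iou_xyxy(cand, b) <= config$max_overlap_iou
      }, logical(1)))
      if (!ok) next
      rows <- h0:(h0 + ph - 1L)
      cols <- w0:(w0 + pw - 1L)
      for (ch in 1:3) {
        plane <- px[rows, cols, ch]
        plane[pp$mask] <- pp$pixels[, , ch][pp$mask]
        px[rows, cols, ch] <- plane
      }
      newbox <- data.frame(class_id = 1L,
                           cx = (cand[1] + cand[3]) / 2 / W,
                           cy = (cand[2] + cand[4]) / 2 / H,
                           w = (cand[3] - cand[1]) / W,
                           h = (cand[4] - cand[2]) / H)
      boxes <- rbind(boxes, newbox)
      existing[[length(existing) + 1L]] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(paste0("could not place pasted patch %d within ",
                          "max_overlap_iou = %g after %d attempts"),
                   k, config$max_overlap_iou, max_attempts))
    }
  }
  annotated_image(px, boxes, provenance = "synthetic",
                  source_id = base$image_id, image_id = image_id)
}

#' Build a weed patch bank from a corpus
#'
#' For every weed box in every image, crops a sub-image around the box
#' (plus margin), keeps only that weed's annotation and extracts the patch
#' by region growing — the corpus-level analogue of cropping weed-only
#' sub-images by hand.
#'
#' @param images list of [annotated_image()].
#' @param config a [region_grow_config()].
#' @param margin context pixels kept around each box.
#' @return List of [weed_patch()] objects.
#' @export
build_patch_bank <- function(images, config = region_grow_config(),
                             margin = 2L) {
  bank <- list()
  for (im in images) {
    wb <- im$boxes[im$boxes$class_id == 1L, , drop = FALSE]
    if (nrow(wb) == 0) next
    d <- dim(im$pixels)
    H <- d[1]; W <- d[2]
    for (i in seq_len(nrow(wb))) {
      b <- wb[i, ]
      h1 <- max(1L, floor((b$cy - b$h / 2) * H) + 1L - margin)
      h2 <- min(H, ceiling((b$cy + b$h / 2) * H) + margin)
      w1 <- max(1L, floor((b$cx - b$w / 2) * W) + 1L - margin)
      w2 <- min(W, ceiling((b$cx + b$w / 2) * W) + margin)
      ch <- h2 - h1 + 1L; cw <- w2 - w1 + 1L
      sub_box <- data.frame(class_id = 1L,
                            cx = (b$cx * W - w1 + 1) / cw,
                            cy = (b$cy * H - h1 + 1) / ch,
                            w = min(1, b$w * W / cw),
                            h = min(1, b$h * H / ch))
      sub <- annotated_image(im$pixels[h1:h2, w1:w2, , drop = FALSE],
                             sub_box, provenance = im$provenance,
                             source_id = im$source_id,
                             image_id = im$image_id)
      bank <- c(bank, extract_weed_patches(sub, config))
    }
  }
  bank
}

#' Crop:weed class ratio of a corpus
#'
#' @param corpus non-empty list of [annotated_image()] (or a corpus list
#'   with an `images` element).
#' @return List with `crop`, `weed` totals, `reduced` integer pair,
#'   `ratio` (crop/weed as a float) and `undefined` flag (TRUE when the
#'   corpus holds no weed boxes).
#' @export
class_ratio <- function(corpus) {
  if (!is.null(corpus$images)) corpus <- corpus$images
  stopifnot(length(corpus) > 0)
  cc <- class_counts(corpus)
  if (cc["weed"] == 0) {
    return(list(crop = unname(cc["crop"]), weed = 0L,
                reduced = c(NA_integer_, NA_integer_),
                ratio = NA_real_, undefined = TRUE))
  }
  g <- gcd2(cc["crop"], cc["weed"])
  list(crop = unname(cc["crop"]), weed = unname(cc["weed"]),
       reduced = unname(c(cc["crop"], cc["weed"]) %/% g),
       ratio = unname(cc["crop"] / cc["weed"]), undefined = FALSE)
}

gcd2 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  max(a, 1L)
}

#' Split specification
#'
#' @param ratios positive `(train, val, test)` weights, default 8:1:1.
#' @param seed RNG seed for the shuffle of unconstrained originals.
#' @export
split_spec <- function(ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  structure(list(ratios = ratios, seed = seed), class = "split_spec")
}

#' Leakage-safe dataset split
#'
#' Synthetic images and the originals they were derived from are confined
#' to the training split; the remaining originals are partitioned so that
#' validation and test approach the requested ratios of the full corpus as
#' closely as the constraint allows.  Deterministic given `spec$seed`.
#'
#' @param manifest manifest data.frame with columns id, provenance,
#'   source_id.
#' @param spec a [split_spec()].
#' @return The manifest with its `split` column filled in.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  syn <- manifest$provenance == "synthetic"
  if (any(syn & !nzchar(manifest$source_id))) {
    stop("every synthetic entry must carry a source_id")
  }
  unknown <- setdiff(manifest$source_id[syn], manifest$id)
  if (length(unknown) > 0) {
    stop("synthetic source_id(s) not present in the manifest: ",
         paste(unknown, collapse = ", "))
  }
  forced <- syn | manifest$id %in% manifest$source_id[syn]
  n <- nrow(manifest)
  free <- which(!forced)
  r <- spec$ratios / sum(spec$ratios)
  n_val <- round(n * r[2])
  n_test <- round(n * r[3])
  if (r[2] > 0) n_val <- max(1L, n_val)
  if (r[3] > 0) n_test <- max(1L, n_test)
  if (n_val + n_test > length(free)) {
    stop(sprintf(paste0("split infeasible: %d images are free after ",
                        "confining synthetic images and their sources to ",
                        "training, but val+test require %d"),
         length(free), n_val + n_test))
  }
  set.seed(spec$seed)
  ord <- free[sample.int(length(free))]
  split <- rep("train", n)
  if (n_val > 0) split[ord[seq_len(n_val)]] <- "val"
  if (n_test > 0) split[ord[n_val + seq_len(n_test)]] <- "test"
  manifest$split <- split
  manifest
}

#' Conventional geometric augmentation
#'
#' Random translation, rotation and scaling applied consistently to pixels
#' (nearest-neighbour resampling about the image centre) and boxes (corner
#' transform, axis-aligned hull, clipped to the image).  Boxes whose clipped
#' area falls below `min_box_px` squared pixels are dropped.
#'
#' @param image an [annotated_image()].
#' @param ops list with `translation` (max |shift| in pixels), `rotation`
#'   (max |angle| in degrees), `scaling` (`(min, max)` factor).
#' @param seed RNG seed; the sampled transform is deterministic given it.
#' @param min_box_px minimum surviving box side in pixels.
#' @return A transformed [annotated_image()].
#' @export
conventional_augment <- function(image,
                                 ops = list(translation = 10, rotation = 15,
                                            scaling = c(0.9, 1.1)),
                                 seed = 1L, min_box_px = 2) {
  stopifnot(inherits(image, "annotated_image"))
  set.seed(seed)
  dx <- if (ops$translation > 0) stats::runif(1, -ops$translation,
                                              ops$translation) else 0
  dy <- if (ops$translation > 0) stats::runif(1, -ops$translation,
                                              ops$translation) else 0
  ang <- if (ops$rotation > 0) stats::runif(1, -ops$rotation,
                                            ops$rotation) else 0
  sc <- if (length(ops$scaling) == 2L && diff(range(ops$scaling)) > 0) {
    stats::runif(1, ops$scaling[1], ops$scaling[2])
  } else ops$scaling[1]
  affine_augment(image, dx, dy, ang, sc, min_box_px)
}

## Deterministic core: rotate by ang (degrees) and scale about the centre,
## then translate by (dx, dy) pixels.
affine_augment <- function(image, dx, dy, ang, sc, min_box_px = 2) {
  d <- dim(image$pixels)
  H <- d[1]; W <- d[2]
  th <- ang * pi / 180
  cxc <- (W - 1) / 2; cyc <- (H - 1) / 2
  # inverse map: for each output pixel find its source
  ww <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  hh <- matrix(seq_len(H) - 1, H, W)
  xo <- ww - cxc - dx
  yo <- hh - cyc - dy
  xs <- (cos(-th) * xo - sin(-th) * yo) / sc + cxc
  ys <- (sin(-th) * xo + cos(-th) * yo) / sc + cyc
  si <- round(ys) + 1
  sj <- round(xs) + 1
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  out <- array(0, dim = d)
  soil <- c(118, 86, 62)
  idx <- cbind(si[ok], sj[ok])
  for (ch in 1:3) {
    plane <- matrix(soil[ch], H, W)
    src <- image$pixels[, , ch]
    plane[ok] <- src[idx]
    out[, , ch] <- plane
  }
  newboxes <- list()
  if (nrow(image$boxes) > 0) {
    for (i in seq_len(nrow(image$boxes))) {
      b <- image$boxes[i, ]
      x1 <- (b$cx - b$w / 2) * W; x2 <- (b$cx + b$w / 2) * W
      y1 <- (b$cy - b$h / 2) * H; y2 <- (b$cy + b$h / 2) * H
      cx4 <- c(x1, x2, x2, x1) - 0.5 - cxc
      cy4 <- c(y1, y1, y2, y2) - 0.5 - cyc
      nx <- (cos(th) * cx4 - sin(th) * cy4) * sc + cxc + dx + 0.5
      ny <- (sin(th) * cx4 + cos(th) * cy4) * sc + cyc + dy + 0.5
      bx1 <- max(0, min(nx)); bx2 <- min(W, max(nx))
      by1 <- max(0, min(ny)); by2 <- min(H, max(ny))
      if (bx2 - bx1 >= min_box_px && by2 - by1 >= min_box_px) {
        newboxes[[length(newboxes) + 1L]] <- data.frame(
          class_id = b$class_id,
          cx = (bx1 + bx2) / 2 / W, cy = (by1 + by2) / 2 / H,
          w = (bx2 - bx1) / W, h = (by2 - by1) / H)
      }
    }
  }
  boxes <- if (length(newboxes) > 0) do.call(rbind, newboxes) else {
    data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric())
  }
  annotated_image(out, boxes, provenance = image$provenance,
                  source_id = image$source_id,
                  image_id = paste0(image$image_id, "_aug"))
}
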