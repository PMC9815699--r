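#' Scene generation parameters
#'
#' Describes a synthetic top-down field scene: a soil-like background with
#' large roundish "crop" plants and small irregular "weed" plants, at the
#' roughly 17:3 crop:weed object imbalance typical of sugarbeet field
#' imagery.  Weed radii must stay strictly below crop radii — the scale gap
#' between the two classes is exactly what multi-scale fusion in the
#' detector addresses.
#'
#' @param image_size `(width, height)` in pixels.
#' @param n_crops,n_weeds object counts per scene.
#' @param crop_radius_range,weed_radius_range `(min, max)` object radii in
#'   pixels; the weed range must lie strictly below the crop range.
#' @param soil_texture_noise standard deviation of the Gaussian texture
#'   noise added to the soil background (intensity units, 0 disables).
#' @param vegetation_color_range list with `lo` and `hi` RGB triplets
#'   bounding the sampled plant colours; green-dominant by default so the
#'   excess-green index (2G - R - B) separates plants from soil.
#' @param min_object_separation minimum distance between object centres in
#'   pixels.
#' @param seed RNG seed making the scene reproducible.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_size = c(96L, 96L),
                         n_crops = 5L, n_weeds = 1L,
                         crop_radius_range = c(7, 12),
                         weed_radius_range = c(2, 4),
                         soil_texture_noise = 6,
                         vegetation_color_range = list(
                           lo = c(30, 110, 20), hi = c(90, 210, 80)),
                         min_object_separation = 4,
                         seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            n_crops >= 0L, n_weeds >= 0L,
            all(crop_radius_range > 0), all(weed_radius_range > 0))
  if (max(weed_radius_range) >= min(crop_radius_range)) {
    stop("weed_radius_range must lie strictly below crop_radius_range")
  }
  structure(list(image_size = as.integer(image_size),
                 n_crops = as.integer(n_crops),
                 n_weeds = as.integer(n_weeds),
                 crop_radius_range = crop_radius_range,
                 weed_radius_range = weed_radius_range,
                 soil_texture_noise = soil_texture_noise,
                 vegetation_color_range = vegetation_color_range,
                 min_object_separation = min_object_separation,
                 seed = seed),
            class = "scene_params")
}

#' Annotated image
#'
#' An RGB pixel array plus labeled bounding boxes in normalized center
#' format (the YOLO label convention) and provenance bookkeeping.
#'
#' @param pixels `(H, W, 3)` array of 8-bit intensities (0..255).
#' @param boxes data.frame with columns `class_id` (0 = crop, 1 = weed),
#'   `cx`, `cy`, `w`, `h`, all normalized to `[0, 1]`.
#' @param provenance `"original"` or `"synthetic"`.
#' @param source_id for synthetic images, the id of the original image they
#'   were derived from; empty otherwise.
#' @param image_id identifier.
#' @param object_pixels optional list of integer vectors giving, per box,
#'   the 1-based `(h + H*(w-1))` indices of that object's vegetation pixels.
#' @export
annotated_image <- function(pixels, boxes, provenance = "original",
                            source_id = "", image_id = "img",
                            object_pixels = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) > 0) {
    stopifnot(all(c("class_id", "cx", "cy", "w", "h") %in% names(boxes)))
    if (any(boxes$w <= 0 | boxes$h <= 0 | boxes$w > 1 | boxes$h > 1) ||
        any(boxes$cx < 0 | boxes$cx > 1 | boxes$cy < 0 | boxes$cy > 1)) {
      stop("boxes must satisfy 0 < w,h <= 1 and 0 <= cx,cy <= 1")
    }
  }
  if (identical(provenance, "synthetic") && !nzchar(source_id)) {
    stop("synthetic images must carry a non-empty source_id")
  }
  structure(list(pixels = pixels, boxes = boxes, provenance = provenance,
                 source_id = source_id, image_id = image_id,
                 object_pixels = object_pixels),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image %s %dx%d, %d boxes, %s>\n", x$image_id,
              d[2], d[1], nrow(x$boxes), x$provenance))
  invisible(x)
}

#' Excess-green vegetation index
#'
#' `2G - R - B` per pixel; positive values indicate vegetation on
#' soil-dominated scenes.
#'
#' @param pixels `(H, W, 3)` array.
#' @return An `(H, W)` matrix.
#' @export
excess_green <- function(pixels) {
  2 * pixels[, , 2] - pixels[, , 1] - pixels[, , 3]
}

clamp8 <- function(x) pmin(pmax(round(x), 0), 255)  # arg order keeps dim()

## Pixel mask (logical H x W) of one ellipse; 0-based pixel centres.
ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  hh <- matrix(seq_len(H) - 1, H, W) - cy
  ww <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) - cx
  u <- ww * cos(theta) + hh * sin(theta)
  v <- -ww * sin(theta) + hh * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

## Multi-lobed weed blob: union of a few small ellipses around a centre.
weed_mask <- function(H, W, cy, cx, radius) {
  n_lobes <- sample(3:5, 1)
  m <- matrix(FALSE, H, W)
  for (i in seq_len(n_lobes)) {
    ang <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0, radius * 0.7)
    r <- radius * stats::runif(1, 0.45, 0.95)
    m <- m | ellipse_mask(H, W, cy + off * sin(ang), cx + off * cos(ang),
                          r, r * stats::runif(1, 0.6, 1), ang)
  }
  m
}

mask_bbox_px <- function(mask) {
  hits <- which(mask, arr.ind = TRUE)
  c(hmin = min(hits[, 1]), hmax = max(hits[, 1]),
    wmin = min(hits[, 2]), wmax = max(hits[, 2]))
}

## Normalized center-format box from a pixel-index bbox (1-based indices,
## boxes span pixel edges).
bbox_to_yolo <- function(bb, H, W) {
  c(cx = (bb[["wmin"]] - 1 + bb[["wmax"]]) / 2 / W,
    cy = (bb[["hmin"]] - 1 + bb[["hmax"]]) / 2 / H,
    w = (bb[["wmax"]] - bb[["wmin"]] + 1) / W,
    h = (bb[["hmax"]] - bb[["hmin"]] + 1) / H)
}

box_iou_xyxy <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

#' Generate one synthetic field scene
#'
#' Paints a brown soil background with Gaussian texture noise, then places
#' `n_crops` green-dominant elliptical crop blobs and `n_weeds` small
#' multi-lobed weed blobs by rejection sampling.  Object pixel masks are
#' kept disjoint, every object lies fully inside the image, candidate boxes
#' overlapping an existing box above IoU 0.05 are rejected, and ground-truth
#' boxes are tight around each object's painted pixels.  Deterministic given
#' `params$seed`.
#'
#' @param params a [scene_params()].
#' @param image_id identifier for the returned image.
#' @return An [annotated_image()] with `object_pixels` filled in.
#' @export
generate_scene <- function(params, image_id = "scene") {
  stopifnot(inherits(params, "scene_params"))
  if (!is.null(params$seed) && !is.na(params$seed)) set.seed(params$seed)
  W <- params$image_size[1]
  H <- params$image_size[2]
  soil <- c(118, 86, 62)
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    base <- matrix(soil[ch], H, W)
    if (params$soil_texture_noise > 0) {
      base <- base + matrix(stats::rnorm(H * W, 0, params$soil_texture_noise),
                            H, W)
    }
    px[, , ch] <- base
  }
  px <- clamp8(px)

  owner <- matrix(0L, H, W)
  n_total <- params$n_crops + params$n_weeds
  classes <- c(rep(0L, params$n_crops), rep(1L, params$n_weeds))
  boxes_px <- list()
  centers <- list()
  object_pixels <- list()
  max_attempts <- 200L
  lo <- params$vegetation_color_range$lo
  hi <- params$vegetation_color_range$hi

  for (i in seq_len(n_total)) {
    cls <- classes[i]
    rng <- if (cls == 0L) params$crop_radius_range else params$weed_radius_range
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      radius <- stats::runif(1, rng[1], rng[2])
      margin <- radius + 2
      if (2 * margin >= min(H, W)) next
      cx <- stats::runif(1, margin, W - 1 - margin)
      cy <- stats::runif(1, margin, H - 1 - margin)
      sep_ok <- all(vapply(centers, function(ct) {
        sqrt((ct[1] - cx)^2 + (ct[2] - cy)^2) >=
          params$min_object_separation
      }, logical(1)))
      if (!sep_ok) next
      mask <- if (cls == 0L) {
        ellipse_mask(H, W, cy, cx, radius,
                     radius * stats::runif(1, 0.7, 1),
                     stats::runif(1, 0, pi))
      } else {
        weed_mask(H, W, cy, cx, radius)
      }
      if (!any(mask)) next
      bb <- mask_bbox_px(mask)
      cand <- c(bb[["wmin"]] - 1, bb[["hmin"]] - 1, bb[["wmax"]], bb[["hmax"]])
      iou_ok <- all(vapply(boxes_px, function(b) {
        box_iou_xyxy(cand, b) <= 0.05
      }, logical(1)))
      if (!iou_ok) next
      if (any(owner[mask] != 0L)) next  # keep object masks disjoint
      col <- stats::runif(3, lo, hi)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[mask] <- clamp8(col[ch])
        px[, , ch] <- plane
      }
      owner[mask] <- i
      boxes_px[[i]] <- cand
      centers[[i]] <- c(cx, cy)
      object_pixels[[i]] <- which(mask)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(paste0("could not place object %d (%s) after %d ",
                          "rejection-sampling attempts; relax ",
                          "min_object_separation (%g px), the overlap bound ",
                          "or the object counts"),
                   i, if (cls == 0L) "crop" else "weed", max_attempts,
                   params$min_object_separation))
    }
  }

  boxes <- if (n_total == 0L) {
    data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
               w = numeric(), h = numeric())
  } else {
    do.call(rbind, lapply(seq_len(n_total), function(i) {
      yb <- bbox_to_yolo(mask_bbox_from_px(boxes_px[[i]]), H, W)
      data.frame(class_id = classes[i], cx = yb[["cx"]], cy = yb[["cy"]],
                 w = yb[["w"]], h = yb[["h"]])
    }))
  }
  annotated_image(px, boxes, provenance = "original", source_id = "",
                  image_id = image_id, object_pixels = object_pixels)
}

## inverse of the cand layout used during placement
mask_bbox_from_px <- function(cand) {
  c(hmin = cand[[2]] + 1, hmax = cand[[4]],
    wmin = cand[[1]] + 1, wmax = cand[[3]])
}

#' Generate a corpus of synthetic scenes
#'
#' Per-image object counts are drawn so that the aggregate crop:weed counts
#' across the corpus match `class_ratio` within rounding; with the defaults
#' (6 objects per image) any corpus whose total object count is divisible by
#' the ratio total achieves it exactly — e.g. 20 images at 17:3 give
#' 102 crops and 18 weeds.
#'
#' @param n_images number of images (>= 1).
#' @param params a [scene_params()]; `n_crops + n_weeds` sets the objects
#'   per image, and `params$seed` seeds the whole corpus.
#' @param class_ratio `(crop, weed)` target ratio, default `c(17, 3)`.
#' @return List with `images` (list of [annotated_image()]) and `manifest`
#'   (data.frame with columns id, path, provenance, source_id, split).
#' @export
generate_corpus <- function(n_images, params = scene_params(),
                            class_ratio = c(17, 3)) {
  stopifnot(n_images >= 1)
  per_image <- params$n_crops + params$n_weeds
  total <- n_images * per_image
  t_crop <- round(total * class_ratio[1] / sum(class_ratio))
  t_weed <- total - t_crop
  base_c <- t_crop %/% n_images
  base_w <- t_weed %/% n_images
  # area feasibility: generous bound before attempting placement
  max_area <- prod(params$image_size) * 0.55
  worst <- (base_c + 1) * (2 * max(params$crop_radius_range) + 4)^2 +
    (base_w + 1) * (2 * max(params$weed_radius_range) + 4)^2
  if (worst > max_area) {
    stop("class_ratio infeasible for the per-image count bounds: ",
         "objects do not fit in the image")
  }
  set.seed(params$seed)
  extra_c <- rep(0L, n_images)
  extra_w <- rep(0L, n_images)
  rc <- t_crop - base_c * n_images
  rw <- t_weed - base_w * n_images
  if (rc > 0) extra_c[sample.int(n_images, rc)] <- 1L
  if (rw > 0) extra_w[sample.int(n_images, rw)] <- 1L
  seeds <- sample.int(2^31 - 10, n_images)
  images <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    p <- params
    p$n_crops <- base_c + extra_c[i]
    p$n_weeds <- base_w + extra_w[i]
    p$seed <- seeds[i]
    images[[i]] <- generate_scene(p, image_id = sprintf("orig_%04d", i))
  }
  manifest <- data.frame(
    id = vapply(images, function(im) im$image_id, character(1)),
    path = sprintf("images/%s.png",
                   vapply(images, function(im) im$image_id, character(1))),
    provenance = "original",
    source_id = "",
    split = NA_character_,
    stringsAsFactors = FALSE)
  list(images = images, manifest = manifest)
}

#' Class histogram of an annotated image or corpus
#' @param x an [annotated_image()] or a list of them.
#' @return Named integer vector `c(crop = ..., weed = ...)`.
#' @export
class_counts <- function(x) {
  if (inherits(x, "annotated_image")) x <- list(x)
  cls <- unlist(lapply(x, function(im) im$boxes$class_id))
  c(crop = sum(cls == 0L), weed = sum(cls == 1L))
}

## ---- disk formats -----------------------------------------------------

#' Write YOLO-format label file
#' @param boxes data.frame with class_id, cx, cy, w, h.
#' @param path output file.
#' @export
write_yolo_labels <- function(boxes, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
}

#' Read YOLO-format label file
#' @param path label file; may have 5 columns (ground truth) or 6 (with a
#'   trailing confidence column for predictions).
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    return(data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  }
  m <- as.matrix(utils::read.table(path))
  df <- data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                   w = m[, 4], h = m[, 5])
  if (ncol(m) >= 6) df$conf <- m[, 6]
  df
}

#' Write a corpus (images, labels, manifest) to a directory
#' @param corpus list with `images` and `manifest` as produced by
#'   [generate_corpus()].
#' @param dir output directory; `images/`, `labels/` and `manifest.tsv` are
#'   created inside.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  for (im in corpus$images) {
    png::writePNG(im$pixels / 255,
                  file.path(dir, "images", paste0(im$image_id, ".png")))
    write_yolo_labels(im$boxes,
                      file.path(dir, "labels", paste0(im$image_id, ".txt")))
  }
  write_manifest(corpus$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_corpus
#' @param manifest manifest data.frame.
#' @param path manifest file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character", "character"),
                    na.strings = NULL)
}

#' Load a corpus written by [write_corpus()]
#' @param dir corpus directory.
#' @export
read_corpus <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(file.path(dir, manifest$path[i])) * 255
    boxes <- read_yolo_labels(file.path(dir, "labels",
                                        paste0(manifest$id[i], ".txt")))
    annotated_image(px, boxes, provenance = manifest$provenance[i],
                    source_id = manifest$source_id[i],
                    image_id = manifest$id[i])
  })
  list(images = images, manifest = manifest)
}
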