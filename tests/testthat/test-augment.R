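test_that("region growing covers a uniform image and stops at an isolated seed", {
  img <- array(100, c(6, 7, 3))
  m <- region_grow(img, c(3, 3), region_grow_config(
    color_distance_threshold = 5))
  expect_true(all(m))
  # isolated seed: all 8 neighbours differ by more than the threshold
  img2 <- array(0, c(5, 5, 3))
  img2[3, 3, ] <- 200
  m2 <- region_grow(img2, c(3, 3), region_grow_config(
    color_distance_threshold = 10))
  expect_equal(sum(m2), 1L)
  expect_true(m2[3, 3])
})

test_that("region growing equals the breadth-first flood-fill oracle", {
  img <- two_blob_image()
  for (conn in c(4L, 8L)) {
    for (seed in list(c(4, 4), c(13, 11))) {
      cfg <- region_grow_config(connectivity = conn,
                                color_distance_threshold = 30)
      expect_equal(unclass(region_grow(img, seed, cfg)),
                   bfs_flood_oracle(img, seed, 30, conn),
                   ignore_attr = TRUE)
    }
  }
  # seed in blob A recovers exactly blob A's pixels
  m <- region_grow(img, c(4, 4), region_grow_config(
    color_distance_threshold = 30))
  truth <- matrix(FALSE, 20, 20)
  truth[3:8, 3:8] <- TRUE
  expect_equal(unclass(m), truth, ignore_attr = TRUE)
})

test_that("region growing is order-independent and enforces its bounds", {
  # fixed seed-colour criterion: 4- and 8-connectivity agree on a convex
  # blob, and the result never depends on traversal order by construction;
  # verify against the oracle on a noisy image
  set.seed(11)
  img <- array(runif(10 * 10 * 3, 0, 255), c(10, 10, 3))
  cfg <- region_grow_config(color_distance_threshold = 120)
  expect_equal(unclass(region_grow(img, c(5, 5), cfg)),
               bfs_flood_oracle(img, c(5, 5), 120, 8), ignore_attr = TRUE)
  expect_error(region_grow(img, c(50, 5), cfg), "outside")
  small <- region_grow_config(max_region_pixels = 3L,
                              color_distance_threshold = 500)
  expect_error(region_grow(img, c(5, 5), small), "max_region_pixels")
})

test_that("patch extraction returns one patch per weed and matches the oracle", {
  sc <- generate_scene(scene_params(image_size = c(128L, 128L),
                                    n_crops = 0L, n_weeds = 6L,
                                    weed_radius_range = c(3, 5),
                                    crop_radius_range = c(9, 12),
                                    soil_texture_noise = 0, seed = 21L))
  patches <- extract_weed_patches(sc, region_grow_config(
    color_distance_threshold = 40))
  expect_length(patches, 6L)
  expect_equal(attr(patches, "failed"), integer())
  for (p in patches) {
    expect_s3_class(p, "weed_patch")
    expect_equal(p$origin_image, sc$image_id)
    expect_true(any(p$mask))
  }
  # masks equal per-box flood fill: each patch's pixel set is its object's
  got <- lapply(patches, function(p) {
    hits <- which(p$mask, arr.ind = TRUE)
    sort((p$bbox[["wmin"]] + hits[, 2] - 2) * 128 + p$bbox[["hmin"]] +
           hits[, 1] - 1)
  })
  want <- lapply(sc$object_pixels[sc$boxes$class_id == 1L], sort)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
})

test_that("patch extraction rejects crop boxes and reports failures", {
  sc <- generate_scene(scene_params(seed = 2L))
  expect_error(extract_weed_patches(sc), "weed-class")
  # an image whose weed box contains no vegetation fails explicitly
  px <- array(50, c(30, 30, 3))
  boxes <- data.frame(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  img <- annotated_image(px, boxes, image_id = "flat")
  out <- extract_weed_patches(img)
  expect_length(out, 0L)
  expect_equal(attr(out, "failed"), 1L)
  # empty case
  empty <- annotated_image(px, boxes[0, ], image_id = "none")
  expect_length(extract_weed_patches(empty), 0L)
})

test_that("pasting adds exactly k weed boxes and leaves other pixels alone", {
  sc <- generate_scene(tiny_params(seed = 31L, n_crops = 2L, n_weeds = 2L))
  bank <- build_patch_bank(list(sc))
  expect_gte(length(bank), 2L)
  base_counts <- class_counts(sc)
  for (k in c(0L, 1L, 3L)) {
    syn <- synthesize_image(sc, bank, paste_config(n_paste_per_image = k,
                                                   seed = 5L))
    expect_equal(syn$provenance, "synthetic")
    expect_equal(syn$source_id, sc$image_id)
    cc <- class_counts(syn)
    expect_equal(unname(cc["crop"]), unname(base_counts["crop"]))
    expect_equal(unname(cc["weed"]), unname(base_counts["weed"]) + k)
    # original annotations preserved verbatim
    expect_identical(syn$boxes[seq_len(nrow(sc$boxes)), ], sc$boxes)
    if (k == 0L) expect_identical(syn$pixels, sc$pixels)
  }
  # pixels outside the pasted masks are untouched
  syn <- synthesize_image(sc, bank, paste_config(n_paste_per_image = 2L,
                                                 seed = 5L))
  changed <- which(syn$pixels != sc$pixels, arr.ind = TRUE)
  newb <- syn$boxes[-seq_len(nrow(sc$boxes)), ]
  H <- dim(sc$pixels)[1]; W <- dim(sc$pixels)[2]
  inside_new <- function(r, c) {
    any((c - 1) >= (newb$cx - newb$w / 2) * W - 1 &
        (c) <= (newb$cx + newb$w / 2) * W + 1 &
        (r - 1) >= (newb$cy - newb$h / 2) * H - 1 &
        (r) <= (newb$cy + newb$h / 2) * H + 1)
  }
  expect_true(all(mapply(inside_new, changed[, 1], changed[, 2])))
  # determinism
  syn2 <- synthesize_image(sc, bank, paste_config(n_paste_per_image = 2L,
                                                  seed = 5L))
  expect_identical(syn$pixels, syn2$pixels)
  expect_identical(syn$boxes, syn2$boxes)
})

test_that("impossible placements error with the attempt count", {
  sc <- generate_scene(tiny_params(seed = 31L, n_crops = 2L, n_weeds = 2L))
  bank <- build_patch_bank(list(sc))
  expect_error(synthesize_image(sc, list(), paste_config(1L)), "empty")
  # a patch larger than free space at IoU 0: overlap bound can never hold
  big <- weed_patch(array(90, c(90, 90, 3)) + array(rep(c(0, 60, 0),
                                                        each = 8100),
                                                    c(90, 90, 3)),
                    matrix(TRUE, 90, 90),
                    bbox = c(hmin = 1, hmax = 90, wmin = 1, wmax = 90),
                    origin_image = "big")
  expect_error(
    synthesize_image(sc, list(big),
                     paste_config(n_paste_per_image = 1L,
                                  max_overlap_iou = 0, seed = 2L)),
    "attempts")
})

test_that("class ratio reduces totals and flags the undefined case", {
  mk <- function(nc, nw) {
    boxes <- data.frame(class_id = c(rep(0L, nc), rep(1L, nw)),
                        cx = 0.5, cy = 0.5, w = 0.1, h = 0.1)
    annotated_image(array(0, c(8, 8, 3)), boxes, image_id = "x")
  }
  r <- class_ratio(list(mk(170, 0), mk(0, 30)))
  expect_equal(r$reduced, c(17L, 3L))
  expect_equal(class_ratio(list(mk(5, 5)))$reduced, c(1L, 1L))
  expect_equal(class_ratio(list(mk(170, 90)))$reduced, c(17L, 9L))
  u <- class_ratio(list(mk(5, 0)))
  expect_true(u$undefined)
  expect_true(is.na(u$ratio))
})

test_that("pasting weeds strictly decreases the crop:weed ratio", {
  sc <- generate_scene(tiny_params(seed = 31L, n_crops = 3L, n_weeds = 1L))
  bank <- build_patch_bank(list(sc))
  r0 <- class_ratio(list(sc))$ratio
  syn <- synthesize_image(sc, bank, paste_config(n_paste_per_image = 1L,
                                                 seed = 3L))
  r1 <- class_ratio(list(syn))$ratio
  expect_lt(r1, r0)
})

test_that("the dataset split is leakage-safe, complete and deterministic", {
  make_manifest <- function(n_orig, n_syn) {
    ids <- sprintf("o%03d", seq_len(n_orig))
    syn_src <- sample(ids, n_syn, replace = FALSE)
    data.frame(id = c(ids, sprintf("s%03d", seq_len(n_syn))),
               path = "p", provenance = c(rep("original", n_orig),
                                          rep("synthetic", n_syn)),
               source_id = c(rep("", n_orig), syn_src),
               split = NA_character_, stringsAsFactors = FALSE)
  }
  set.seed(1)
  man <- make_manifest(40, 10)
  out <- split_dataset(man, split_spec(c(8, 1, 1), seed = 3L))
  expect_equal(nrow(out), 50L)
  expect_setequal(unique(out$split), c("train", "val", "test"))
  expect_equal(sum(out$split == "val"), 5L)
  expect_equal(sum(out$split == "test"), 5L)
  protected <- c(out$id[out$provenance == "synthetic"],
                 out$source_id[out$provenance == "synthetic"])
  expect_true(all(out$split[out$id %in% protected] == "train"))
  # deterministic
  expect_identical(out, split_dataset(man, split_spec(c(8, 1, 1), seed = 3L)))
  # unconstrained 10-image 8:1:1
  man2 <- make_manifest(10, 0)
  out2 <- split_dataset(man2, split_spec(c(8, 1, 1), seed = 1L))
  expect_equal(as.integer(table(out2$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
})

test_that("split leakage invariant holds over 100 random seeds", {
  set.seed(99)
  ids <- sprintf("o%02d", 1:30)
  man <- data.frame(id = c(ids, sprintf("s%02d", 1:10)),
                    path = "p",
                    provenance = c(rep("original", 30), rep("synthetic", 10)),
                    source_id = c(rep("", 30), sample(ids, 10)),
                    split = NA_character_, stringsAsFactors = FALSE)
  protected <- c(man$id[man$provenance == "synthetic"],
                 man$source_id[man$provenance == "synthetic"])
  for (s in 1:100) {
    out <- split_dataset(man, split_spec(c(8, 1, 1), seed = s))
    expect_true(all(out$split[out$id %in% protected] == "train"))
    expect_equal(nrow(out), 40L)
  }
})

test_that("split errors are explicit", {
  man <- data.frame(id = c("a", "s1"), path = "p",
                    provenance = c("original", "synthetic"),
                    source_id = c("", "missing"), split = NA_character_,
                    stringsAsFactors = FALSE)
  expect_error(split_dataset(man), "not present")
  man2 <- data.frame(id = c("a", "b", "s1"), path = "p",
                     provenance = c("original", "original", "synthetic"),
                     source_id = c("", "", "a"), split = NA_character_,
                     stringsAsFactors = FALSE)
  expect_error(split_dataset(man2, split_spec(c(1, 1, 1))), "infeasible")
})

test_that("conventional augmentation is identity at identity ranges", {
  sc <- generate_scene(tiny_params(seed = 41L))
  out <- conventional_augment(sc, list(translation = 0, rotation = 0,
                                       scaling = c(1, 1)), seed = 1L)
  expect_equal(out$pixels, sc$pixels)
  expect_equal(out$boxes, sc$boxes, tolerance = 1e-12)
})

test_that("pure translation shifts box centres exactly", {
  sc <- generate_scene(scene_params(n_crops = 1L, n_weeds = 1L, seed = 42L))
  wv <- asNamespace("weedvision")
  out <- wv$affine_augment(sc, dx = 6, dy = -4, ang = 0, sc = 1)
  W <- dim(sc$pixels)[2]; H <- dim(sc$pixels)[1]
  expect_equal(out$boxes$cx, sc$boxes$cx + 6 / W, tolerance = 1e-12)
  expect_equal(out$boxes$cy, sc$boxes$cy - 4 / H, tolerance = 1e-12)
  expect_equal(out$boxes$w, sc$boxes$w, tolerance = 1e-12)
})

test_that("rotating 180 degrees twice recovers the original boxes", {
  sc <- generate_scene(tiny_params(seed = 43L))
  wv <- asNamespace("weedvision")
  once <- wv$affine_augment(sc, 0, 0, 180, 1)
  twice <- wv$affine_augment(once, 0, 0, 180, 1)
  W <- dim(sc$pixels)[2]
  expect_equal(twice$boxes$cx, sc$boxes$cx, tolerance = 1 / W)
  expect_equal(twice$boxes$cy, sc$boxes$cy, tolerance = 1 / W)
  expect_equal(twice$boxes$w, sc$boxes$w, tolerance = 2 / W)
  expect_equal(twice$pixels, sc$pixels)
})
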