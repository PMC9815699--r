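# Small fixtures built in code, shared across test files.

# A flat-colour two-blob image: a square blob A and a disjoint square blob B
# on a dark background, for region-growing tests.
two_blob_image <- function(H = 20, W = 20) {
  px <- array(30, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[3:8, 3:8] <- c(40, 180, 50)[ch]    # blob A
    plane[12:18, 10:16] <- c(60, 160, 40)[ch]  # blob B
    px[, , ch] <- plane
  }
  px
}

# Independent breadth-first flood-fill oracle over a colour-distance
# criterion to the seed pixel (plain R, no shared code with the package).
bfs_flood_oracle <- function(img, seed, threshold, connectivity = 8) {
  H <- dim(img)[1]; W <- dim(img)[2]
  sc <- img[seed[1], seed[2], ]
  ok <- matrix(FALSE, H, W)
  visited <- matrix(FALSE, H, W)
  queue <- list(seed)
  visited[seed[1], seed[2]] <- TRUE
  ok[seed[1], seed[2]] <- TRUE
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(nbrs))) {
      nh <- cur[1] + nbrs[k, 1]; nw <- cur[2] + nbrs[k, 2]
      if (nh < 1 || nh > H || nw < 1 || nw > W) next
      if (visited[nh, nw]) next
      if (sqrt(sum((img[nh, nw, ] - sc)^2)) <= threshold) {
        visited[nh, nw] <- TRUE
        ok[nh, nw] <- TRUE
        queue[[length(queue) + 1]] <- c(nh, nw)
      }
    }
  }
  ok
}

# Tiny deterministic scene parameter sets.
tiny_params <- function(seed = 1L, n_crops = 3L, n_weeds = 1L) {
  scene_params(image_size = c(96L, 96L), n_crops = n_crops,
               n_weeds = n_weeds, seed = seed)
}

# A small trained-model cache is deliberately avoided: every test builds
# what it needs so the suite stays order-independent.

# Random detection/truth tables for metric property tests.
random_boxes <- function(n, image_id = "im1", class_id = 0L, seed = 1L,
                         with_conf = TRUE) {
  set.seed(seed)
  x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
  df <- data.frame(image_id = image_id, class_id = class_id,
                   x1 = x1, y1 = y1,
                   x2 = x1 + runif(n, 2, 15), y2 = y1 + runif(n, 2, 15))
  if (with_conf) df$conf <- runif(n)
  df
}
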