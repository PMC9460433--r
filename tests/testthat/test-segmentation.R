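# Region-merging segmentation: fusion cost, engine behavior, local variance,
# scale profile, and equivalence with the exhaustive greedy oracle.

w_color_only <- seg_weights(w_color = 1)

test_that("fusion cost of identical adjacent pixels is zero (color only)", {
  a <- pixel_stats(1, 1, 5)
  b <- pixel_stats(1, 2, 5)
  expect_equal(fusion_cost(a, b, w_color_only, shared_edges = 1), 0)
})

test_that("fusion cost of single pixels 0 and 2 equals 2", {
  a <- pixel_stats(1, 1, 0)
  b <- pixel_stats(1, 2, 2)
  # population sd of {0, 2} is 1; n_merge = 2; parts contribute 0
  expect_equal(fusion_cost(a, b, w_color_only, shared_edges = 1), 2)
})

test_that("fusion cost is symmetric and matches a direct evaluation", {
  m <- matrix(c(0, 0, 1, 0, 2, 2, 1, 1, 2), 3, 3)
  sg <- segment(m, w_color_only, scale = 1)
  ids <- sg$segments$id
  w <- seg_weights(w_color = 0.6, w_smoothness = 0.3)
  checked <- 0
  for (a in ids) {
    sa <- segment_stats(sg, a)
    for (bc in names(sa$adjacency)) {
      b <- as.integer(bc)
      sb <- segment_stats(sg, b)
      cab <- fusion_cost(sa, sb, w)
      cba <- fusion_cost(sb, sa, w)
      expect_equal(cab, cba, tolerance = 1e-12)
      # direct evaluation, coded independently of fusion_cost
      nm <- sa$n + sb$n
      mu <- (sa$sum + sb$sum) / nm
      sdm <- sqrt(pmax((sa$sumsq + sb$sumsq) / nm - mu^2, 0))
      sda <- sqrt(pmax(sa$sumsq / sa$n - (sa$sum / sa$n)^2, 0))
      sdb <- sqrt(pmax(sb$sumsq / sb$n - (sb$sum / sb$n)^2, 0))
      dcol <- sum(nm * sdm - (sa$n * sda + sb$n * sdb))
      lm <- sa$l + sb$l - 2 * sa$adjacency[[bc]]
      bbm <- c(min(sa$bbox[1], sb$bbox[1]), max(sa$bbox[2], sb$bbox[2]),
               min(sa$bbox[3], sb$bbox[3]), max(sa$bbox[4], sb$bbox[4]))
      side <- function(bb) min(bb[2] - bb[1] + 1, bb[4] - bb[3] + 1)
      dsm <- nm * lm / side(bbm) -
        (sa$n * sa$l / side(sa$bbox) + sb$n * sb$l / side(sb$bbox))
      dcp <- nm * lm / sqrt(nm) -
        (sa$n * sa$l / sqrt(sa$n) + sb$n * sb$l / sqrt(sb$n))
      direct <- 0.6 * dcol + 0.4 * (0.3 * dsm + 0.7 * dcp)
      expect_equal(cab, direct, tolerance = 1e-12)
      # the color change is never negative
      expect_gte(dcol, -1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 2)
})

test_that("non-adjacent pairs are rejected", {
  a <- pixel_stats(1, 1, 0)
  b <- pixel_stats(5, 5, 1)
  expect_error(fusion_cost(a, b, w_color_only), "not adjacent")
  expect_error(fusion_cost(a, b, w_color_only, shared_edges = 0),
               "not adjacent")
})

test_that("uniform image collapses to one segment at any scale (color only)", {
  m <- matrix(7, 6, 6)
  for (s in c(0.5, 3, 100)) {
    sg <- segment(m, w_color_only, scale = s)
    expect_identical(nrow(sg$segments), 1L)
    expect_equal(sg$segments$n, 36)
  }
})

test_that("vanishing scale keeps one segment per pixel", {
  set.seed(3)
  m <- matrix(sample(0:255, 36), 6, 6)  # distinct values: all costs > 0
  sg <- segment(m, seg_weights(), scale = 1e-8)
  expect_identical(nrow(sg$segments), 36L)
})

test_that("a two-block image splits into its two blocks", {
  m <- matrix(0, 6, 6); m[, 4:6] <- 100
  sg <- segment(m, seg_weights(), scale = 20)
  expect_identical(nrow(sg$segments), 2L)
  expect_identical(sg$label_raster, canonical_labels(oracle_segment(
    m, seg_weights(), 20)))
  expect_true(all(sg$label_raster[, 1:3] == 1L))
  expect_true(all(sg$label_raster[, 4:6] == 2L))
})

test_that("partition invariants hold: labels cover, areas sum, connectivity", {
  set.seed(4)
  m <- matrix(sample(0:3, 100, replace = TRUE) * 40, 10, 10)
  for (s in c(5, 15, 40)) {
    sg <- segment(m, seg_weights(), scale = s)
    lab <- sg$label_raster
    expect_false(anyNA(lab))
    expect_setequal(unique(as.vector(lab)), sg$segments$id)
    expect_identical(sum(sg$segments$n), 100L)
    expect_true(segments_connected(lab))
    expect_true(all(sg$segments$perimeter >= 4))
    expect_true(all(sg$segments$bbox_short_side >= 1))
  }
})

test_that("segment count is non-increasing in scale", {
  set.seed(6)
  m <- matrix(rnorm(400, 100, 20), 20, 20)
  counts <- vapply(c(2, 5, 10, 20, 40, 80),
                   function(s) nrow(segment(m, seg_weights(), s)$segments),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("engine equals the exhaustive greedy oracle on random images", {
  set.seed(42)
  w <- seg_weights()
  for (i in 1:12) {
    m <- matrix(sample(0:2, 25, replace = TRUE), 5, 5)
    s <- sample(c(2, 4, 8), 1)
    expect_identical(segment(m, w, s)$label_raster,
                     canonical_labels(oracle_segment(m, w, s)),
                     label = paste("case", i))
  }
  # two-layer variant
  for (i in 1:6) {
    l1 <- matrix(sample(0:2, 25, replace = TRUE), 5, 5)
    l2 <- matrix(sample(0:2, 25, replace = TRUE), 5, 5)
    expect_identical(segment(list(l1, l2), w, 5)$label_raster,
                     canonical_labels(oracle_segment(list(l1, l2), w, 5)),
                     label = paste("two-layer case", i))
  }
})

test_that("nodata pixels stay unlabeled and are never merged", {
  m <- matrix(10, 4, 4)
  m[1, 1] <- NA
  sg <- segment(m, w_color_only, scale = 5)
  expect_true(is.na(sg$label_raster[1, 1]))
  expect_identical(sum(sg$segments$n), 15L)
})

test_that("local variance: zero for single-pixel segments, sd for a pool", {
  set.seed(8)
  m <- matrix(sample(0:255, 16), 4, 4)
  one_per_pixel <- segment(m, seg_weights(), scale = 1e-8)
  expect_equal(local_variance(one_per_pixel, m), 0)

  m2 <- matrix(c(0, 0, 2, 2), 2, 2)
  pooled <- segment(m2, w_color_only, scale = 10)
  expect_identical(nrow(pooled$segments), 1L)
  expect_equal(local_variance(pooled, m2), 1)  # population sd of {0,0,2,2}
})

test_that("LV grows with scale on a synthetic scene", {
  sc <- generate_scene(scene_config(rows = 96, cols = 96, seed = 7))
  s1 <- segment(sc$rgb, seg_weights(), 20)
  s2 <- segment(sc$rgb, seg_weights(), 80)
  expect_lte(local_variance(s1, sc$rgb$g), local_variance(s2, sc$rgb$g))
})

test_that("lv_roc peaks where within-object merging completes", {
  # 24 x 24 image tiled by 8 x 8 blocks of alternating means + mild noise:
  # the characteristic object size is one block
  set.seed(9)
  m <- matrix(0, 24, 24)
  for (bi in 0:2) for (bj in 0:2) {
    m[bi * 8 + 1:8, bj * 8 + 1:8] <- 120 * ((bi + bj) %% 2)
  }
  m <- m + matrix(rnorm(576, 0, 3), 24, 24)
  # candidate grid above the pixel-noise floor, as in practice
  pr <- lv_roc(m, seg_weights(), scales = c(3, 4, 5, 8, 12, 20, 40))
  sg <- segment(m, seg_weights(), pr$optimal_scale)
  # the ROC peak is the first scale that completes within-block merging
  # without crossing blocks: exactly the 9 blocks
  expect_identical(nrow(sg$segments), 9L)
  # and no segment mixes the two block populations
  feats <- sg$segments$mean_layer1
  expect_true(all(feats < 30 | feats > 90))
})

test_that("constant LV across scales is rejected with diagnostics", {
  m <- matrix(5, 8, 8)
  expect_error(
    suppressWarnings(lv_roc(m, w_color_only, scales = c(1, 2, 3))),
    "no ROC peak")
})

test_that("lv_roc validates the scale grid", {
  m <- matrix(rnorm(64), 8, 8)
  expect_error(lv_roc(m, seg_weights(), scales = c(10, 20)), "at least 3")
  expect_error(lv_roc(m, seg_weights(), scales = c(10, 10, 20)),
               "strictly increasing")
})

test_that("a discriminative terrain layer does not add boundary-straddling segments", {
  set.seed(10)
  # spectrally noisy image with no structure; terrain has two plateaus
  img <- matrix(rnorm(32 * 32, 100, 12), 32, 32)
  terr <- matrix(0, 32, 32); terr[17:32, ] <- 100
  straddle <- function(sg) {
    top <- unique(as.vector(sg$label_raster[1:16, ]))
    bottom <- unique(as.vector(sg$label_raster[17:32, ]))
    length(intersect(top, bottom))
  }
  s_without <- segment(list(img), seg_weights(), 30)
  s_with <- segment(list(img, terr), seg_weights(), 30)
  expect_lte(straddle(s_with), straddle(s_without))
  expect_identical(straddle(s_with), 0L)
})
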