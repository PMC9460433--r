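# 2D -> 3D transfer: point-in-polygon assignment, mapping error, VDVI purge,
# and the FVC arithmetic.

sq <- function(x0, y0, s = 1, class = "vegetation") {
  list(coords = rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s),
                      c(x0, y0 + s)),
       class = class)
}

test_that("points inside a unit square are assigned; N counts populated polys", {
  polys <- polygon_set(list(sq(0, 0)))
  cloud <- data.frame(x = c(0.5, 2), y = c(0.5, 2), z = 0,
                      R = 0L, G = 255L, B = 0L)
  res <- map_polygons(polys, cloud)
  expect_identical(res$vegetation_assigned, c(TRUE, FALSE))
  expect_identical(res$N, 1L)
  expect_identical(res$M, 1L)
  expect_equal(res$Q, 100)
})

test_that("boundary points count as inside", {
  polys <- polygon_set(list(sq(0, 0)))
  cloud <- data.frame(x = c(0, 1, 0.5, 0), y = c(0.5, 1, 0, 0), z = 0,
                      R = 0L, G = 0L, B = 0L)
  res <- map_polygons(polys, cloud)
  expect_true(all(res$vegetation_assigned))
})

test_that("dense clouds populate every polygon: N = M and Q = 100", {
  polys <- polygon_set(lapply(0:4, function(i) sq(2 * i, 0)))
  set.seed(30)
  cloud <- data.frame(x = runif(5000, 0, 9), y = runif(5000, 0, 1), z = 0,
                      R = 0L, G = 0L, B = 0L)
  res <- map_polygons(polys, cloud)
  expect_identical(res$N, res$M)
  expect_equal(res$Q, 100)
})

test_that("non-vegetation polygons are excluded from M", {
  polys <- polygon_set(list(sq(0, 0), sq(2, 0, class = "bare_land")))
  cloud <- data.frame(x = c(0.5, 2.5), y = c(0.5, 0.5), z = 0,
                      R = 0L, G = 0L, B = 0L)
  res <- map_polygons(polys, cloud)
  expect_identical(res$M, 1L)
  expect_identical(res$vegetation_assigned, c(TRUE, FALSE))
})

test_that("assignment matches a brute-force containment oracle", {
  set.seed(31)
  # random convex polygons via sorted angles around a center
  rand_poly <- function() {
    cx <- runif(1, 0, 10); cy <- runif(1, 0, 10)
    ang <- sort(runif(sample(3:8, 1), 0, 2 * pi))
    rad <- runif(length(ang), 0.5, 2)
    list(coords = cbind(cx + rad * cos(ang), cy + rad * sin(ang)),
         class = "vegetation")
  }
  # independent winding-number containment test (angle summation)
  winding_inside <- function(px, py, ring) {
    ring <- rbind(ring, ring[1, ])
    total <- 0
    for (i in seq_len(nrow(ring) - 1)) {
      a1 <- atan2(ring[i, 2] - py, ring[i, 1] - px)
      a2 <- atan2(ring[i + 1, 2] - py, ring[i + 1, 1] - px)
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      total <- total + d
    }
    abs(total) > pi  # ~2*pi inside, ~0 outside
  }
  polys <- replicate(5, rand_poly(), simplify = FALSE)
  cloud <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10), z = 0,
                      R = 0L, G = 0L, B = 0L)
  res <- map_polygons(polygon_set(polys), cloud)
  oracle <- vapply(seq_len(nrow(cloud)), function(i) {
    any(vapply(polys, function(p) {
      winding_inside(cloud$x[i], cloud$y[i], p$coords)
    }, logical(1)))
  }, logical(1))
  expect_identical(res$vegetation_assigned, oracle)
})

test_that("raster-backed segment polygons agree with direct pixel lookup", {
  sc <- generate_scene(scene_config(rows = 48, cols = 48, seed = 8))
  sg <- segment(sc$rgb, seg_weights(), 30)
  cls <- segment_majority_labels(sg, truth_classes(sc))
  polys <- segment_polygons(sg, cls, sc$rgb$transform)
  res <- map_polygons(polys, sc$cloud)
  px <- fvcmap:::world_to_pixel(sc$rgb$transform, sc$cloud$x, sc$cloud$y)
  lab <- sg$label_raster[cbind(px$row, px$col)]
  expect_identical(res$vegetation_assigned,
                   cls[lab] == "vegetation")
  expect_identical(res$M, sum(cls == "vegetation"))
  expect_lte(res$N, res$M)
})

test_that("empty clouds are rejected", {
  polys <- polygon_set(list(sq(0, 0)))
  expect_error(map_polygons(polys, data.frame(x = numeric(0),
                                              y = numeric(0))),
               "empty")
})

test_that("mapping error reproduces the worked percentages", {
  expect_equal(mapping_error(1019, 998), 97.9392, tolerance = 1e-4)
  expect_equal(mapping_error(50, 50), 100)
  expect_equal(mapping_error(50, 0), 0)
  expect_error(mapping_error(0, 0), "positive")
  expect_error(mapping_error(10, 11), "0 <= N <= M")
})

make_mapping <- function(vdvi_green = 0.3, n_green = 50, n_gray = 50) {
  # green points (G dominant) and gray points (VDVI 0)
  g <- 255; rb <- round(g * (1 - vdvi_green) / (1 + vdvi_green))
  cloud <- data.frame(
    x = runif(n_green + n_gray), y = runif(n_green + n_gray), z = 0,
    R = c(rep(rb, n_green), rep(100L, n_gray)),
    G = c(rep(g, n_green), rep(100L, n_gray)),
    B = c(rep(rb, n_green), rep(100L, n_gray)))
  polys <- polygon_set(list(sq(0, 0)))
  map_polygons(polys, cloud)
}

test_that("purge keeps everything above an explicit threshold", {
  set.seed(33)
  res <- make_mapping(n_gray = 0)
  out <- purge_bare_points(res, threshold = 0)
  expect_identical(out$vegetation_point_count, res$vegetation_point_count)
})

test_that("auto purge removes the gray half of a bimodal mixture", {
  set.seed(34)
  res <- make_mapping()
  out <- purge_bare_points(res, threshold = "auto")
  expect_true(out$purge$applied)
  expect_identical(out$vegetation_point_count, 50L)
  vd <- fvcmap:::vi_values("VDVI", out$cloud$R, out$cloud$G, out$cloud$B)
  expect_true(all(vd[out$vegetation_assigned] > 0.2))
})

test_that("auto purge leaves a unimodal vegetation distribution alone", {
  set.seed(35)
  res <- make_mapping(n_gray = 0)
  # add mild noise so VDVI is a single bump
  res$cloud$R <- pmin(255, pmax(0, res$cloud$R + sample(-8:8, 50, TRUE)))
  res$cloud$B <- pmin(255, pmax(0, res$cloud$B + sample(-8:8, 50, TRUE)))
  out <- purge_bare_points(res, threshold = "auto")
  expect_false(out$purge$applied)
  expect_identical(out$vegetation_point_count, res$vegetation_point_count)
})

test_that("a threshold above the maximum removes everything, with a warning", {
  set.seed(36)
  res <- make_mapping()
  expect_warning(out <- purge_bare_points(res, threshold = 1.1),
                 "empty vegetation")
  expect_identical(out$vegetation_point_count, 0L)
})

test_that("purge never increases the vegetation count", {
  set.seed(37)
  res <- make_mapping()
  for (thr in list("auto", 0, 0.1, 0.5)) {
    out <- suppressWarnings(purge_bare_points(res, threshold = thr))
    expect_lte(out$vegetation_point_count, res$vegetation_point_count)
  }
})

test_that("otsu splits a two-spike sample between the spikes", {
  x <- c(rep(0, 100), rep(1, 100))
  ot <- otsu_threshold(x)
  expect_gt(ot$threshold, 0.1)
  expect_lt(ot$threshold, 0.9)
  expect_gt(ot$separability, 0.95)
})

test_that("fvc reproduces the worked example and its bounds", {
  expect_equal(round(fvc(138618519, 384410757), 2), 36.06)
  expect_equal(fvc(0, 10), 0)
  expect_equal(fvc(10, 10), 100)
  expect_error(fvc(1, 0), "positive")
  expect_error(fvc(11, 10), "between")
  # monotone in the vegetation count
  expect_lt(fvc(3, 10), fvc(4, 10))
})
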