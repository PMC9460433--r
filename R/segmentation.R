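# Multi-resolution segmentation: weighted color/shape homogeneity criterion,
# deterministic greedy region merging, local-variance scale diagnostics.

#' Segmentation weights
#'
#' The merge criterion is `C = w_color * dh_color + w_shape * dh_shape`, where
#' the color term is the layer-weighted increase of area-scaled standard
#' deviation and the shape term mixes a smoothness component (perimeter over
#' bounding-box short side) and a compactness component (perimeter over the
#' square root of area), both area-weighted.
#'
#' Defaults: spectral information dominates (`w_color` 0.7), compactness 0.6
#' vs smoothness 0.4.
#'
#' @param w_color,w_shape Spectral vs shape weight; must sum to 1.
#' @param w_smoothness,w_compactness Shape sub-weights; must sum to 1.
#' @param layer_weights Optional nonnegative per-layer weights (recycled
#'   checks happen at [segment()] time); default equal weight 1 per layer.
#' @return Object of class `seg_weights`.
#' @export
seg_weights <- function(w_color = 0.7, w_shape = 1 - w_color,
                        w_smoothness = 0.4, w_compactness = 1 - w_smoothness,
                        layer_weights = NULL) {
  if (any(c(w_color, w_shape, w_smoothness, w_compactness) < 0)) {
    stop("weights must be nonnegative")
  }
  if (abs(w_color + w_shape - 1) > 1e-9) stop("w_color + w_shape must be 1")
  if (abs(w_smoothness + w_compactness - 1) > 1e-9) {
    stop("w_smoothness + w_compactness must be 1")
  }
  if (!is.null(layer_weights) && any(layer_weights < 0)) {
    stop("layer weights must be nonnegative")
  }
  structure(list(w_color = w_color, w_shape = w_shape,
                 w_smoothness = w_smoothness, w_compactness = w_compactness,
                 layer_weights = layer_weights),
            class = "seg_weights")
}

# population sd from running sums
seg_sd_ <- function(s, sq, n) {
  m <- s / n
  v <- sq / n - m * m
  v[v < 0] <- 0
  sqrt(v)
}

#' Fusion cost of merging two adjacent segments
#'
#' Evaluates the homogeneity-change criterion for a candidate merge. Each
#' segment is described by area `n`, perimeter `l` (exposed unit edges),
#' bounding box `bbox = c(rmin, rmax, cmin, cmax)` (pixel indices), and
#' per-layer running `sum` and `sumsq`. The color term is
#' `sum_c w_c * (n_m * sd_m - (n1 * sd1 + n2 * sd2))` with population standard
#' deviations; the shape term combines smoothness (`n * l / b`, `b` the
#' bounding-box short side) and compactness (`n * l / sqrt(n)`) differences.
#' The cost is symmetric in its two arguments and nonnegative up to rounding.
#'
#' @param a,b Segment stats: lists with `n`, `l`, `bbox`, `sum`, `sumsq`, and
#'   optionally `id` and `adjacency` (named vector of shared edge counts).
#' @param w A [seg_weights()].
#' @param shared_edges Number of unit edges on the common boundary; if `NULL`,
#'   looked up in `a$adjacency` by `b$id`. Non-adjacent pairs are an error.
#' @return The scalar fusion cost.
#' @export
fusion_cost <- function(a, b, w, shared_edges = NULL) {
  stopifnot(inherits(w, "seg_weights"))
  if (is.null(shared_edges)) {
    if (!is.null(a$adjacency) && !is.null(b$id)) {
      shared_edges <- unname(a$adjacency[as.character(b$id)])
    }
    if (is.null(shared_edges) || is.na(shared_edges)) {
      stop("segments are not adjacent (no shared edges found)")
    }
  }
  if (shared_edges < 1) stop("segments are not adjacent")
  nlay <- length(a$sum)
  lw <- w$layer_weights
  if (is.null(lw)) lw <- rep(1, nlay)
  stopifnot(length(b$sum) == nlay, length(lw) == nlay)
  na <- a$n; nb <- b$n; nm <- na + nb
  dcolor <- 0
  for (k in seq_len(nlay)) {
    sdm <- seg_sd_(a$sum[k] + b$sum[k], a$sumsq[k] + b$sumsq[k], nm)
    dcolor <- dcolor +
      lw[k] * (nm * sdm - (na * seg_sd_(a$sum[k], a$sumsq[k], na) +
                             nb * seg_sd_(b$sum[k], b$sumsq[k], nb)))
  }
  lm <- a$l + b$l - 2 * shared_edges
  hm <- max(a$bbox[2], b$bbox[2]) - min(a$bbox[1], b$bbox[1]) + 1
  wm <- max(a$bbox[4], b$bbox[4]) - min(a$bbox[3], b$bbox[3]) + 1
  bm <- min(hm, wm)
  ba <- min(a$bbox[2] - a$bbox[1] + 1, a$bbox[4] - a$bbox[3] + 1)
  bb <- min(b$bbox[2] - b$bbox[1] + 1, b$bbox[4] - b$bbox[3] + 1)
  dsmooth <- nm * lm / bm - (na * a$l / ba + nb * b$l / bb)
  dcompact <- nm * lm / sqrt(nm) - (na * a$l / sqrt(na) + nb * b$l / sqrt(nb))
  w$w_color * dcolor +
    w$w_shape * (w$w_smoothness * dsmooth + w$w_compactness * dcompact)
}

# normalize layers argument: rgb_raster -> list(r, g, b); matrix -> list of 1
as_layer_list <- function(layers) {
  if (inherits(layers, "rgb_raster")) {
    return(list(R = layers$r, G = layers$g, B = layers$b))
  }
  if (is.matrix(layers)) return(list(layers))
  if (is.list(layers) && length(layers) &&
      all(vapply(layers, is.matrix, logical(1)))) {
    return(layers)
  }
  stop("layers must be an rgb_raster, a matrix, or a list of matrices")
}

#' Multi-resolution segmentation by region merging
#'
#' Starts from single-pixel segments and merges bottom-up: while the minimum
#' [fusion_cost()] over all adjacent pairs is below `scale^2`, that pair is
#' merged (deterministic greedy with fixed tie-breaks: lowest pair ids win,
#' the surviving segment keeps the lower id, pixel scan order is row-major).
#' Every executed merge is a local mutual-best merge. Pixels that are `NA` in
#' any layer are excluded and labeled `NA`.
#'
#' @param layers An [rgb_raster()], a single matrix, or a list of matrices on
#'   one grid.
#' @param w A [seg_weights()].
#' @param scale Positive scale parameter; a merge is admitted while its cost
#'   is below `scale^2`.
#' @return Object of class `fvc_segmentation`: `label_raster` (integer matrix,
#'   labels 1..K in row-major first-appearance order), `segments` (data frame
#'   with `id`, `n`, `perimeter`, `bbox_short_side`, per-layer `mean_*` and
#'   `sd_*`), `adjacency` (list of named shared-edge-count vectors), `scale`,
#'   `weights`, `layer_names`.
#' @export
segment <- function(layers, w = seg_weights(), scale) {
  lay <- as_layer_list(layers)
  if (!length(lay)) stop("at least one layer is required")
  if (missing(scale) || scale <= 0) stop("scale must be positive")
  stopifnot(inherits(w, "seg_weights"))
  dims <- lapply(lay, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all layers must share one grid")
  }
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  lw <- w$layer_weights
  if (is.null(lw)) lw <- rep(1, length(lay))
  if (length(lw) != length(lay)) {
    stop("layer_weights length must match the number of layers")
  }
  # row-major pixel order
  lmat <- vapply(lay, function(m) as.numeric(t(m)), numeric(nr * nc))
  lmat <- matrix(lmat, nrow = nr * nc)
  valid <- rowSums(is.na(lmat)) == 0
  if (!any(valid)) stop("no valid pixels")
  lmat[!valid, ] <- 0
  raw <- .merge_engine(lmat, nr, nc, as.numeric(lw),
                       w$w_color, w$w_shape, w$w_smoothness, w$w_compactness,
                       scale^2, valid)
  # canonical relabel: 1..K in row-major first-appearance order
  first <- !duplicated(raw) & !is.na(raw)
  key <- raw[first]
  lab_rm <- match(raw, key)
  label_raster <- matrix(NA_integer_, nr, nc)
  label_raster[cbind(rep(seq_len(nr), each = nc), rep(seq_len(nc), nr))] <- lab_rm
  res <- structure(
    list(label_raster = label_raster, scale = scale, weights = w,
         layer_names = if (is.null(names(lay))) {
           paste0("layer", seq_along(lay))
         } else names(lay)),
    class = "fvc_segmentation"
  )
  st <- segment_statistics(label_raster, lay)
  res$segments <- st$segments
  res$adjacency <- st$adjacency
  res
}

#' @export
print.fvc_segmentation <- function(x, ...) {
  cat(sprintf("<fvc_segmentation> %d segments at scale %g (%d x %d px)\n",
              nrow(x$segments), x$scale,
              nrow(x$label_raster), ncol(x$label_raster)))
  invisible(x)
}

# Per-segment statistics and shared-edge adjacency from a label raster.
segment_statistics <- function(label_raster, lay) {
  nr <- nrow(label_raster); nc <- ncol(label_raster)
  labv <- as.vector(label_raster)
  ok <- !is.na(labv)
  ids <- sort(unique(labv[ok]))
  n <- tabulate(labv[ok], nbins = max(ids))[ids]

  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  rmin <- tapply(rows[ok], labv[ok], min)[as.character(ids)]
  rmax <- tapply(rows[ok], labv[ok], max)[as.character(ids)]
  cmin <- tapply(cols[ok], labv[ok], min)[as.character(ids)]
  cmax <- tapply(cols[ok], labv[ok], max)[as.character(ids)]

  # exposed unit edges: neighbor off-grid, nodata, or different label
  perim <- numeric(max(ids))
  edge_pairs <- NULL
  for (d in c("up", "down", "left", "right")) {
    nb <- switch(d,
      up    = rbind(matrix(NA_integer_, 1, nc), label_raster[-nr, , drop = FALSE]),
      down  = rbind(label_raster[-1, , drop = FALSE], matrix(NA_integer_, 1, nc)),
      left  = cbind(matrix(NA_integer_, nr, 1), label_raster[, -nc, drop = FALSE]),
      right = cbind(label_raster[, -1, drop = FALSE], matrix(NA_integer_, nr, 1)))
    nbv <- as.vector(nb)
    exposed <- ok & (is.na(nbv) | nbv != labv)
    perim <- perim + tabulate(labv[exposed], nbins = max(ids))
    if (d %in% c("down", "right")) {
      sel <- ok & !is.na(nbv) & nbv != labv
      if (any(sel)) {
        edge_pairs <- rbind(edge_pairs, cbind(labv[sel], nbv[sel]))
      }
    }
  }
  adjacency <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(edge_pairs)) {
    a <- pmin(edge_pairs[, 1], edge_pairs[, 2])
    b <- pmax(edge_pairs[, 1], edge_pairs[, 2])
    tab <- table(a, b)
    nzi <- which(tab > 0, arr.ind = TRUE)
    an <- as.integer(rownames(tab))[nzi[, 1]]
    bn <- as.integer(colnames(tab))[nzi[, 2]]
    cnt <- tab[nzi]
    for (i in seq_along(an)) {
      ai <- as.character(an[i]); bi <- as.character(bn[i])
      adjacency[[ai]][bi] <- cnt[i]
      adjacency[[bi]][ai] <- cnt[i]
    }
  }

  seg <- data.frame(id = ids, n = n, perimeter = perim[ids],
                    bbox_short_side = pmin(rmax - rmin + 1, cmax - cmin + 1),
                    rmin = as.integer(rmin), rmax = as.integer(rmax),
                    cmin = as.integer(cmin), cmax = as.integer(cmax))
  lname <- names(lay)
  if (is.null(lname)) lname <- paste0("layer", seq_along(lay))
  for (k in seq_along(lay)) {
    v <- as.vector(lay[[k]])
    s <- rowsum(v[ok], labv[ok])[as.character(ids), 1]
    sq <- rowsum(v[ok]^2, labv[ok])[as.character(ids), 1]
    seg[[paste0("sum_", lname[k])]] <- s
    seg[[paste0("sumsq_", lname[k])]] <- sq
    seg[[paste0("mean_", lname[k])]] <- s / n
    seg[[paste0("sd_", lname[k])]] <- seg_sd_(s, sq, n)
  }
  rownames(seg) <- NULL
  list(segments = seg, adjacency = adjacency)
}

#' Extract one segment's stats as a list usable with [fusion_cost()]
#'
#' @param seg An `fvc_segmentation`.
#' @param id Segment id.
#' @return List with `id`, `n`, `l`, `bbox`, `sum`, `sumsq`, `adjacency`.
#' @export
segment_stats <- function(seg, id) {
  stopifnot(inherits(seg, "fvc_segmentation"))
  row <- seg$segments[seg$segments$id == id, , drop = FALSE]
  if (!nrow(row)) stop("no segment with id ", id)
  ln <- seg$layer_names
  list(id = id, n = row$n, l = row$perimeter,
       bbox = c(row$rmin, row$rmax, row$cmin, row$cmax),
       sum = unlist(row[paste0("sum_", ln)], use.names = FALSE),
       sumsq = unlist(row[paste0("sumsq_", ln)], use.names = FALSE),
       adjacency = seg$adjacency[[as.character(id)]])
}

#' Mean local variance of a segmentation
#'
#' Mean over segments of the per-segment population standard deviation of
#' `layer`; single-pixel segments contribute 0.
#'
#' @param seg An `fvc_segmentation`.
#' @param layer Numeric matrix on the segmentation grid.
#' @return Scalar mean local variance.
#' @export
local_variance <- function(seg, layer) {
  stopifnot(inherits(seg, "fvc_segmentation"))
  if (!all(dim(layer) == dim(seg$label_raster))) {
    stop("layer must be on the segmentation grid")
  }
  labv <- as.vector(seg$label_raster)
  ok <- !is.na(labv) & !is.na(as.vector(layer))
  v <- as.vector(layer)[ok]
  g <- labv[ok]
  n <- tabulate(g)
  ids <- which(n > 0)
  s <- rowsum(v, g)[, 1]
  sq <- rowsum(v^2, g)[, 1]
  mean(seg_sd_(s, sq, n[ids]))
}

#' Local-variance rate-of-change (LV-ROC) scale profile
#'
#' Segments the input at every candidate scale, records the mean local
#' variance LV (averaged over the spectral `layers`), and computes the rate of
#' change `ROC(L) = (LV(L) - LV(L_prev)) / LV(L_prev) * 100`. The optimal
#' scale is the global ROC peak (the first scale carries no ROC). Scales where
#' the previous LV is zero are skipped with a warning. Optional
#' `terrain_layers` (e.g. elevation, slope) are appended as additional
#' weighted layers of the merge criterion.
#'
#' @param layers Spectral layers ([rgb_raster()] or list of matrices).
#' @param w A [seg_weights()]; its `layer_weights`, if set, must cover
#'   spectral plus terrain layers.
#' @param scales Increasing vector of at least 3 candidate scales (the
#'   conventional grid starts at 10 with step 10).
#' @param terrain_layers Optional named list of terrain matrices.
#' @return Object of class `scale_profile`: data frame `profile` with
#'   `scale`, `lv`, `roc`, plus `optimal_scale` and the segment counts.
#' @export
lv_roc <- function(layers, w = seg_weights(), scales = seq(10, 100, by = 10),
                   terrain_layers = NULL) {
  if (length(scales) < 3) stop("at least 3 scales are required")
  if (any(diff(scales) <= 0)) stop("scales must be strictly increasing")
  lay <- as_layer_list(layers)
  all_lay <- c(lay, terrain_layers)
  nspec <- length(lay)
  lv <- nseg <- rep(NA_real_, length(scales))
  for (i in seq_along(scales)) {
    sg <- segment(all_lay, w, scales[i])
    lv[i] <- mean(vapply(lay, function(m) local_variance(sg, m), numeric(1)))
    nseg[i] <- nrow(sg$segments)
  }
  roc <- rep(NA_real_, length(scales))
  for (i in seq_along(scales)[-1]) {
    if (lv[i - 1] == 0) {
      warning("LV is zero at scale ", scales[i - 1],
              "; ROC undefined at scale ", scales[i], " (skipped)")
      next
    }
    roc[i] <- (lv[i] - lv[i - 1]) / lv[i - 1] * 100
  }
  if (all(!is.finite(roc) | roc == 0, na.rm = TRUE) || all(is.na(roc))) {
    stop("no ROC peak: LV is constant (or undefined) across scales; ",
         "LV values: ", paste(signif(lv, 6), collapse = ", "))
  }
  opt <- scales[which.max(roc)]
  structure(
    list(profile = data.frame(scale = scales, lv = lv, roc = roc,
                              n_segments = nseg),
         optimal_scale = opt),
    class = "scale_profile"
  )
}

#' @export
print.scale_profile <- function(x, ...) {
  cat("<scale_profile> optimal scale:", x$optimal_scale, "\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}
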