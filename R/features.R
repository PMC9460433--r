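# Object features for classification and per-segment majority labels.

#' Per-segment feature table
#'
#' One row per segment: per-band mean and standard deviation, mean of the
#' chosen vegetation index, mean elevation and slope when supplied, and the
#' segment area (pixel count).
#'
#' @param seg An `fvc_segmentation`.
#' @param rgb The segmented [rgb_raster()].
#' @param index A `vi_raster` (the chosen classification index).
#' @param elevation,slope Optional terrain matrices on the same grid.
#' @return Data frame keyed by `id`.
#' @export
segment_features <- function(seg, rgb, index, elevation = NULL, slope = NULL) {
  stopifnot(inherits(seg, "fvc_segmentation"), inherits(rgb, "rgb_raster"))
  labv <- as.vector(seg$label_raster)
  ok <- !is.na(labv)
  ids <- sort(unique(labv[ok]))
  g <- labv[ok]
  n <- tabulate(g, nbins = max(ids))[ids]
  mean_by <- function(m) rowsum(as.vector(m)[ok], g)[, 1] / n
  sd_by <- function(m) {
    v <- as.vector(m)[ok]
    seg_sd_(rowsum(v, g)[, 1], rowsum(v^2, g)[, 1], n)
  }
  out <- data.frame(id = ids, n = n,
                    mean_R = mean_by(rgb$r), sd_R = sd_by(rgb$r),
                    mean_G = mean_by(rgb$g), sd_G = sd_by(rgb$g),
                    mean_B = mean_by(rgb$b), sd_B = sd_by(rgb$b))
  vi <- if (inherits(index, "vi_raster")) index$values else index
  viv <- as.vector(vi)
  okv <- ok & is.finite(viv)
  mvi <- rep(NA_real_, length(ids))
  if (any(okv)) {
    s <- rowsum(viv[okv], labv[okv])
    mvi[match(as.integer(rownames(s)), ids)] <-
      s[, 1] / tabulate(labv[okv], nbins = max(ids))[as.integer(rownames(s))]
  }
  out$mean_index <- mvi
  if (!is.null(elevation)) out$mean_elevation <- mean_by(elevation)
  if (!is.null(slope)) out$mean_slope <- mean_by(slope)
  # a segment entirely of nodata index pixels would carry NA; keep the table
  # complete by falling back to the global mean
  if (anyNA(out$mean_index)) {
    out$mean_index[is.na(out$mean_index)] <- mean(viv[okv])
  }
  rownames(out) <- NULL
  out
}

#' Majority reference class per segment
#'
#' @param seg An `fvc_segmentation`.
#' @param truth Character matrix of per-pixel classes (or coded matrix with a
#'   `levels` attribute) on the segmentation grid.
#' @return Character vector, one class per segment (ties broken by canonical
#'   class order).
#' @export
segment_majority_labels <- function(seg, truth) {
  stopifnot(inherits(seg, "fvc_segmentation"))
  if (!is.character(truth)) {
    lv <- attr(truth, "levels")
    if (is.null(lv)) lv <- fvc_classes()
    truth <- matrix(lv[truth], nrow(truth), ncol(truth))
  }
  if (!all(dim(truth) == dim(seg$label_raster))) {
    stop("truth must be on the segmentation grid")
  }
  labv <- as.vector(seg$label_raster)
  ok <- !is.na(labv) & !is.na(as.vector(truth))
  cls <- c(intersect(fvc_classes(), unique(truth[ok])),
           sort(setdiff(unique(truth[ok]), fvc_classes())))
  ci <- match(as.vector(truth)[ok], cls)
  ids <- sort(unique(labv[ok]))
  counts <- matrix(0L, length(ids), length(cls))
  tab <- table(factor(labv[ok], levels = ids), factor(ci, levels = seq_along(cls)))
  counts[] <- as.integer(tab)
  cls[max.col(counts, ties.method = "first")]
}
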