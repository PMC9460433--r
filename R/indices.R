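# Visible-band vegetation indices and the index-selection diagnostics.

vi_table <- list(
  NGRDI  = list(range = c(-1, 1)),
  NGBDI  = list(range = c(-1, 1)),
  MRBVI  = list(range = c(-1, 1)),
  MGRVI  = list(range = c(-1, 1)),
  RGBVI  = list(range = c(-1, 1)),
  ExG    = list(range = c(-1, 2)),
  CIVE   = list(range = c(17, 20)),
  VDVI   = list(range = c(-1, 1)),
  EGRBDI = list(range = c(-1, 1))
)

#' Names of the supported visible-band vegetation indices
#' @return Character vector of the nine index names.
#' @export
vi_names <- function() names(vi_table)

#' Theoretical range of a visible-band index
#' @param index_name One of [vi_names()].
#' @return Numeric length-2 closed interval.
#' @export
vi_theoretical_range <- function(index_name) {
  vi_table[[match_vi(index_name)]]$range
}

match_vi <- function(index_name) {
  if (length(index_name) != 1 || !index_name %in% names(vi_table)) {
    stop("unknown index '", paste(index_name, collapse = ","),
         "'; valid names: ", paste(names(vi_table), collapse = ", "))
  }
  index_name
}

# Core formula evaluation on numeric vectors; returns NA where the
# denominator vanishes (0 is a meaningful index value, so it is not used as a
# fill). ExG and CIVE use chromatic coordinates r = R/(R+G+B) etc.
vi_values <- function(index_name, R, G, B) {
  zap <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  switch(index_name,
    NGRDI  = zap(G - R, G + R),
    NGBDI  = zap(G - B, G + B),
    MRBVI  = zap(R^2 - B^2, R^2 + B^2),
    MGRVI  = zap(G^2 - R^2, G^2 + R^2),
    RGBVI  = zap(G^2 - B * R, G^2 + B * R),
    ExG    = {
      s <- R + G + B
      ifelse(s == 0, NA_real_, (2 * G - R - B) / s)
    },
    CIVE   = {
      s <- R + G + B
      ifelse(s == 0, NA_real_,
             0.44 * (R / s) - 0.88 * (G / s) + 0.385 * (B / s) + 18.78745)
    },
    VDVI   = zap(2 * G - R - B, 2 * G + R + B),
    EGRBDI = zap((2 * G)^2 - B * R, (2 * G)^2 + B * R),
    stop("unhandled index ", index_name)
  )
}

#' Compute a visible-band vegetation index raster
#'
#' Evaluates the index formula per pixel on real-valued bands. Pixels where
#' the formula's denominator is zero (e.g. R = G = B = 0) and nodata pixels
#' are set to `NA`.
#'
#' @param raster An [rgb_raster()].
#' @param index_name One of [vi_names()].
#' @return An object of class `vi_raster`: list with `index_name`, `values`
#'   (numeric matrix), `theoretical_range`, and the source `transform`.
#' @export
compute_index <- function(raster, index_name) {
  stopifnot(inherits(raster, "rgb_raster"))
  index_name <- match_vi(index_name)
  v <- vi_values(index_name, as.numeric(raster$r), as.numeric(raster$g),
                 as.numeric(raster$b))
  v[as.vector(raster$nodata_mask)] <- NA_real_
  structure(
    list(index_name = index_name,
         values = matrix(v, nrow(raster$r), ncol(raster$r)),
         theoretical_range = vi_table[[index_name]]$range,
         transform = raster$transform),
    class = "vi_raster"
  )
}

#' @export
print.vi_raster <- function(x, ...) {
  cat(sprintf("<vi_raster> %s, %d x %d px, range [%.4g, %.4g] (theory [%g, %g])\n",
              x$index_name, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              x$theoretical_range[1], x$theoretical_range[2]))
  invisible(x)
}

#' Per-class mean and standard deviation of an index
#'
#' Computes, for every class present in `labels`, the mean and population
#' standard deviation of the index over that class's finite pixels. Classes
#' with no labeled finite pixel are absent from the result (not reported as
#' zero).
#'
#' @param vi A `vi_raster` (or plain numeric matrix).
#' @param labels Class raster: character/integer/factor matrix aligned with
#'   the index grid.
#' @return Data frame of class `class_error_stats` with columns `class`,
#'   `mean`, `sd`, `n`.
#' @export
class_error_stats <- function(vi, labels) {
  v <- if (inherits(vi, "vi_raster")) vi$values else vi
  if (is.factor(labels)) labels <- as.character(labels)
  lab <- if (is.character(labels)) labels else {
    lv <- attr(labels, "levels")
    if (is.null(lv)) lv <- fvc_classes()
    matrix(lv[labels], nrow(labels), ncol(labels))
  }
  if (!all(dim(v) == dim(lab))) stop("labels must align with the index grid")
  keep <- is.finite(v) & !is.na(lab)
  cls <- intersect(c(fvc_classes(), sort(unique(lab[keep]))), unique(lab[keep]))
  out <- do.call(rbind, lapply(cls, function(cl) {
    x <- v[keep & lab == cl]
    m <- mean(x)
    data.frame(class = cl, mean = m,
               sd = sqrt(mean((x - m)^2)),  # population sd
               n = length(x))
  }))
  class(out) <- c("class_error_stats", "data.frame")
  out
}

#' Gray histogram of an index raster
#'
#' Counts finite pixels into `bins` equal-width bins spanning the index's
#' theoretical range (the default), so that index images with very different
#' occupied sub-ranges are binned on comparable grids. Values are clamped into
#' the range before counting, so counts always sum to the number of finite
#' pixels.
#'
#' @param vi A `vi_raster`, or a numeric vector/matrix (then `range` must be
#'   given).
#' @param bins Number of bins (default 256).
#' @param range Length-2 interval to bin over; defaults to the index's
#'   theoretical range.
#' @param smooth_window Moving-average window (bins) used downstream by the
#'   peak detector; stored with the histogram (default 5).
#' @return Object of class `vi_histogram`: list with `index_name`,
#'   `bin_edges`, `mids`, `counts`, `smooth_window`.
#' @export
vi_histogram <- function(vi, bins = 256, range = NULL, smooth_window = 5) {
  if (inherits(vi, "vi_raster")) {
    if (is.null(range)) range <- vi$theoretical_range
    nm <- vi$index_name
    v <- vi$values
  } else {
    if (is.null(range)) stop("range must be supplied for plain numeric input")
    nm <- NA_character_
    v <- vi
  }
  if (bins < 2) stop("need at least 2 bins")
  v <- v[is.finite(v)]
  v <- pmin(pmax(v, range[1]), range[2])
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(idx, nbins = bins)
  structure(
    list(index_name = nm, bin_edges = edges,
         mids = (edges[-1] + edges[-length(edges)]) / 2,
         counts = counts, smooth_window = smooth_window),
    class = "vi_histogram"
  )
}

#' Detect major peaks and bimodality of an index histogram
#'
#' The histogram is smoothed with a centered moving average
#' (`hist$smooth_window` bins). Local maxima (plateau-aware) are kept as major
#' peaks when their topographic prominence is at least `prominence_frac` times
#' the maximum smoothed count, and peaks closer than `min_separation_frac`
#' times the occupied data range (span of nonzero raw bins) are collapsed onto
#' the most prominent one. An all-equal histogram has zero peaks.
#'
#' @param hist A [vi_histogram()].
#' @param prominence_frac Minimum prominence as a fraction of the maximum
#'   smoothed count (default 0.05).
#' @param min_separation_frac Minimum peak separation as a fraction of the
#'   occupied data range (default 0.1).
#' @return List with `n_major_peaks`, `peak_positions`, `is_bimodal`
#'   (`n_major_peaks == 2`).
#' @export
bimodality <- function(hist, prominence_frac = 0.05,
                       min_separation_frac = 0.1) {
  stopifnot(inherits(hist, "vi_histogram"))
  cnt <- hist$counts
  if (length(cnt) < 2) stop("need at least 2 bins")
  if (max(cnt) == min(cnt)) {  # all-equal counts: no structure
    return(list(n_major_peaks = 0L, peak_positions = numeric(0),
                is_bimodal = FALSE))
  }
  w <- hist$smooth_window
  sm <- as.numeric(stats::filter(cnt, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  n <- length(sm)
  if (max(sm) == min(sm)) {
    return(list(n_major_peaks = 0L, peak_positions = numeric(0),
                is_bimodal = FALSE))
  }
  nz <- which(cnt > 0)
  drange <- hist$mids[max(nz)] - hist$mids[min(nz)]

  # plateau-aware local maxima
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]) {
      j <- i
      while (j < n && sm[j + 1] == sm[i]) j <- j + 1L
      if (j == n || sm[j + 1] < sm[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks)) {
    return(list(n_major_peaks = 0L, peak_positions = numeric(0),
                is_bimodal = FALSE))
  }
  prominence <- vapply(peaks, function(p) {
    lmin <- if (any(sm[1:p] > sm[p])) {
      k <- max(which(sm[1:p] > sm[p])); min(sm[k:p])
    } else 0
    rmin <- if (any(sm[p:n] > sm[p])) {
      k <- p - 1L + min(which(sm[p:n] > sm[p])); min(sm[p:k])
    } else 0
    sm[p] - max(lmin, rmin)
  }, numeric(1))
  keep <- prominence >= prominence_frac * max(sm)
  peaks <- peaks[keep]; prominence <- prominence[keep]
  # enforce separation greedily by descending prominence
  sel <- integer(0)
  for (p in peaks[order(-prominence, peaks)]) {
    if (!length(sel) ||
        all(abs(hist$mids[p] - hist$mids[sel]) >=
              min_separation_frac * drange)) {
      sel <- c(sel, p)
    }
  }
  pos <- sort(hist$mids[sel])
  list(n_major_peaks = length(sel), peak_positions = pos,
       is_bimodal = length(sel) == 2L)
}
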