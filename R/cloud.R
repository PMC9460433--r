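# 2D -> 3D label transfer: map classified vegetation objects onto an
# RGB-attributed point cloud, compute the mapping error Q, purge residual
# bare-soil points, and report fractional vegetation cover.

#' Classified planar polygons
#'
#' @param polygons List of polygons; each is a list with `coords` (two-column
#'   x,y matrix of ring vertices, closed or open) and `class` (character).
#' @return Object of class `fvc_polygons`.
#' @export
polygon_set <- function(polygons) {
  for (p in polygons) {
    if (!is.matrix(p$coords) || ncol(p$coords) != 2 || nrow(p$coords) < 3) {
      stop("each polygon needs a two-column coords matrix with >= 3 vertices")
    }
    if (is.null(p$class)) stop("each polygon needs a class")
  }
  structure(list(polygons = polygons), class = "fvc_polygons")
}

#' Vegetation objects of a segmentation as implicit pixel-aligned polygons
#'
#' Each segment of the requested classes is one planar object; containment of
#' a point is exact point-in-(rectilinear-)polygon evaluated through the label
#' raster (the polygon boundary follows pixel edges, and boundary points fall
#' into the pixel they touch).
#'
#' @param seg An `fvc_segmentation`.
#' @param class_of_segment Character vector giving each segment's class (in
#'   `seg$segments$id` order).
#' @param transform Grid transform of the segmented raster (see
#'   [rgb_raster()]).
#' @param keep Classes to retain as target objects (default `"vegetation"`).
#' @return Object of class `fvc_segment_polygons` with `M` retained objects.
#' @export
segment_polygons <- function(seg, class_of_segment, transform,
                             keep = "vegetation") {
  stopifnot(inherits(seg, "fvc_segmentation"))
  ids <- seg$segments$id
  if (length(class_of_segment) != length(ids)) {
    stop("class_of_segment must give one class per segment")
  }
  veg_ids <- ids[class_of_segment %in% keep]
  structure(list(label_raster = seg$label_raster, transform = transform,
                 veg_ids = veg_ids, M = length(veg_ids)),
            class = "fvc_segment_polygons")
}

# Ray-casting point-in-polygon with inclusive boundary: points exactly on an
# edge or vertex count as inside. Vectorized over points.
point_in_polygon <- function(px, py, ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- rbind(ring, ring[1, ])
  }
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    # boundary test: collinear and within the segment bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_edge <- on_edge | (abs(cross) <= 1e-12 *
                            (abs(x2 - x1) + abs(y2 - y1) + 1) &
                          px >= pmin(x1, x2) - 1e-15 &
                          px <= pmax(x1, x2) + 1e-15 &
                          py >= pmin(y1, y2) - 1e-15 &
                          py <= pmax(y1, y2) + 1e-15)
    # crossing test (half-open rule avoids double-counting vertices)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) / (y2 - y1) * (x2 - x1))
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Map classified polygons onto a point cloud
#'
#' A point is vegetation-assigned iff its planimetric (x, y) position falls
#' inside a retained vegetation polygon (boundary inclusive). `N` counts the
#' vegetation polygons containing at least one point; `Q = N / M * 100` is the
#' mapping error statistic.
#'
#' @param polys An [polygon_set()] or [segment_polygons()] object.
#' @param cloud Data frame with at least `x`, `y` (and typically `z`, `R`,
#'   `G`, `B`).
#' @return Object of class `mapping_result`: `M`, `N`, `Q`,
#'   `vegetation_assigned` (logical per point), `vegetation_point_count`,
#'   `total_count`, and the `cloud`.
#' @export
map_polygons <- function(polys, cloud) {
  if (is.null(cloud) || !nrow(cloud)) stop("empty point cloud")
  stopifnot(all(c("x", "y") %in% names(cloud)))
  UseMethod("map_polygons")
}

#' @export
map_polygons.fvc_polygons <- function(polys, cloud) {
  veg <- Filter(function(p) identical(p$class, "vegetation"), polys$polygons)
  M <- length(veg)
  assigned <- rep(FALSE, nrow(cloud))
  populated <- logical(M)
  for (i in seq_along(veg)) {
    hit <- point_in_polygon(cloud$x, cloud$y, veg[[i]]$coords)
    populated[i] <- any(hit)
    assigned <- assigned | hit
  }
  new_mapping_result(M, sum(populated), assigned, cloud)
}

#' @export
map_polygons.fvc_segment_polygons <- function(polys, cloud) {
  tr <- polys$transform
  inside <- in_footprint(tr, cloud$x, cloud$y)
  lab <- rep(NA_integer_, nrow(cloud))
  if (any(inside)) {
    px <- world_to_pixel(tr, cloud$x[inside], cloud$y[inside])
    lab[inside] <- polys$label_raster[cbind(px$row, px$col)]
  }
  assigned <- !is.na(lab) & lab %in% polys$veg_ids
  populated <- intersect(polys$veg_ids, unique(lab[assigned]))
  new_mapping_result(polys$M, length(populated), assigned, cloud)
}

new_mapping_result <- function(M, N, assigned, cloud) {
  structure(
    list(M = M, N = N, Q = if (M > 0) mapping_error(M, N) else NA_real_,
         vegetation_assigned = assigned,
         vegetation_point_count = sum(assigned),
         total_count = nrow(cloud), cloud = cloud),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> M %d, N %d, Q %.2f%%; %d / %d vegetation points (FVC %.2f%%)\n",
              x$M, x$N, x$Q, x$vegetation_point_count, x$total_count,
              fvc(x$vegetation_point_count, x$total_count)))
  invisible(x)
}

#' Mapping error of the 2D-to-3D vegetation transfer
#'
#' `Q = N / M * 100`, with `M` the number of vegetation planar objects and `N`
#' the number of them that received at least one mapped point.
#'
#' @param M Positive count of vegetation polygons.
#' @param N Count of mapped vegetation polygons, `0 <= N <= M`.
#' @return Percentage `Q`.
#' @export
mapping_error <- function(M, N) {
  if (M <= 0) stop("M must be positive")
  if (N < 0 || N > M) stop("N must satisfy 0 <= N <= M")
  N / M * 100
}

#' Otsu threshold of a numeric sample
#'
#' Exhaustive between-class-variance maximization on a binned histogram.
#' Returns the threshold and the separability ratio (between-class variance at
#' the optimum over total variance), a bimodality indicator in \[0, 1\].
#'
#' @param x Numeric values (non-finite dropped).
#' @param bins Number of histogram bins (default 256).
#' @return List with `threshold` and `separability`.
#' @export
otsu_threshold <- function(x, bins = 256) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  if (min(x) == max(x)) {
    return(list(threshold = min(x), separability = 0))
  }
  edges <- seq(min(x), max(x), length.out = bins + 1)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins)
  cnt <- tabulate(idx, nbins = bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  p <- cnt / sum(cnt)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  valid <- w0 > 0 & w0 < 1
  between <- rep(-Inf, bins)
  between[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  mx <- max(between)
  k <- round(mean(which(between == mx)))  # midpoint of a tied plateau
  total <- sum(p * (mids - mu_t)^2)
  list(threshold = edges[k + 1], separability = mx / total)
}

#' Purge residual bare-soil points from the vegetation assignment
#'
#' Computes per-point VDVI from the point RGB and reassigns vegetation points
#' whose VDVI falls below the threshold. With `threshold = "auto"` the
#' threshold is the Otsu split of VDVI over the vegetation-assigned points,
#' applied only when the Otsu separability indicates two populations
#' (`separability >= min_separability`); a clearly unimodal VDVI distribution
#' (pure vegetation) is left untouched.
#'
#' @param mapping A [map_polygons()] result whose cloud carries `R`, `G`, `B`.
#' @param threshold `"auto"` or a numeric VDVI cutoff.
#' @param min_separability Otsu separability required before the automatic
#'   threshold is applied (default 0.8).
#' @return The updated `mapping_result` (never more vegetation points than
#'   before); a warning is emitted if no vegetation point survives.
#' @export
purge_bare_points <- function(mapping, threshold = "auto",
                              min_separability = 0.8) {
  stopifnot(inherits(mapping, "mapping_result"))
  cl <- mapping$cloud
  if (!all(c("R", "G", "B") %in% names(cl))) {
    stop("cloud points must carry R, G, B")
  }
  veg <- mapping$vegetation_assigned
  if (!any(veg)) return(mapping)
  vdvi <- vi_values("VDVI", cl$R[veg], cl$G[veg], cl$B[veg])
  if (identical(threshold, "auto")) {
    ot <- otsu_threshold(vdvi[is.finite(vdvi)])
    if (ot$separability < min_separability) {
      mapping$purge <- list(applied = FALSE, threshold = NA_real_,
                            separability = ot$separability, removed = 0L)
      return(mapping)
    }
    threshold <- ot$threshold
    sep <- ot$separability
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    sep <- NA_real_
  }
  drop <- !is.finite(vdvi) | vdvi < threshold
  keep_idx <- which(veg)[!drop]
  assigned <- rep(FALSE, nrow(cl))
  assigned[keep_idx] <- TRUE
  if (!any(assigned)) {
    warning("all vegetation points fall below the VDVI threshold; ",
            "empty vegetation set returned")
  }
  out <- new_mapping_result(mapping$M, mapping$N, assigned, cl)
  out$purge <- list(applied = TRUE, threshold = threshold,
                    separability = sep, removed = sum(drop))
  out
}

#' Fractional vegetation cover from point counts
#'
#' `FVC = 100 * vegetation_point_count / total_count` percent.
#'
#' @param vegetation_point_count Count of vegetation points,
#'   `0 <= vegetation_point_count <= total_count`.
#' @param total_count Positive total point count.
#' @return FVC in percent.
#' @export
fvc <- function(vegetation_point_count, total_count) {
  if (total_count <= 0) stop("total_count must be positive")
  if (vegetation_point_count < 0 || vegetation_point_count > total_count) {
    stop("vegetation_point_count must be between 0 and total_count")
  }
  100 * vegetation_point_count / total_count
}
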