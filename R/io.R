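# Plain-format I/O: TIFF rasters with JSON georeferencing sidecars, CSV point
# clouds (LAS stand-in), GeoJSON polygons, JSON reports.

#' Write a raster to TIFF with a JSON georeferencing sidecar
#'
#' 8-bit data (an [rgb_raster()] or a matrix flagged `bit8 = TRUE`) is stored
#' as 8-bit TIFF; other matrices are min-max scaled into a 32-bit TIFF with
#' the scaling recorded in the sidecar `<path>.json`.
#'
#' @param x An [rgb_raster()] or a numeric matrix.
#' @param path Output TIFF path.
#' @param transform Grid transform (taken from `x` when it is an
#'   `rgb_raster`).
#' @param bit8 Store a matrix as 8-bit \[0, 255\] instead of scaled float.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(x, path, transform = NULL, bit8 = FALSE) {
  if (inherits(x, "rgb_raster")) {
    transform <- x$transform
    arr <- array(c(x$r, x$g, x$b) / 255, dim = c(dim(x$r), 3))
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    meta <- list(kind = "rgb", scale = list(min = 0, max = 255))
  } else {
    stopifnot(is.matrix(x))
    if (is.null(transform)) stop("transform is required for matrix input")
    if (bit8) {
      tiff::writeTIFF(x / 255, path, bits.per.sample = 8L)
      meta <- list(kind = "band8", scale = list(min = 0, max = 255))
    } else {
      lo <- min(x); hi <- max(x)
      sc <- if (hi > lo) (x - lo) / (hi - lo) else x * 0
      tiff::writeTIFF(sc, path, bits.per.sample = 32L)
      meta <- list(kind = "band", scale = list(min = lo, max = hi))
    }
  }
  meta$transform <- transform[c("rows", "cols", "pixel_size",
                                "x_origin", "y_origin")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return An [rgb_raster()] or a numeric matrix with a `transform` attribute.
#' @export
read_raster_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tr <- as.list(meta$transform)
  img <- tiff::readTIFF(path)
  if (identical(meta$kind, "rgb")) {
    return(rgb_raster(round(img[, , 1] * 255), round(img[, , 2] * 255),
                      round(img[, , 3] * 255),
                      pixel_size = tr$pixel_size, x_origin = tr$x_origin,
                      y_origin = tr$y_origin))
  }
  lo <- meta$scale$min; hi <- meta$scale$max
  m <- if (identical(meta$kind, "band8")) round(img * 255) else {
    img * (hi - lo) + lo
  }
  attr(m, "transform") <- tr
  m
}

#' Write / read a point cloud as CSV (x, y, z, R, G, B)
#'
#' @param cloud Data frame with columns `x, y, z, R, G, B`.
#' @param path CSV path.
#' @return `path` / the cloud data frame.
#' @export
write_cloud_csv <- function(cloud, path) {
  utils::write.csv(cloud, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  utils::read.csv(path)
}

#' Write classified polygons as GeoJSON
#'
#' @param polys An [polygon_set()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  stopifnot(inherits(polys, "fvc_polygons"))
  features <- lapply(polys$polygons, function(p) {
    ring <- p$coords
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(class = p$class),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON polygons into a [polygon_set()]
#'
#' Only simple `Polygon` outer rings with a `class` property are supported.
#'
#' @param path GeoJSON path.
#' @return An `fvc_polygons` object.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(v) {
      c(v[[1]], v[[2]])
    }))
    list(coords = ring, class = f$properties$class)
  })
  polygon_set(polys)
}

#' Write a synthetic scene to a directory
#'
#' Writes `rgb.tif`, `elevation.tif`, `slope.tif`, `truth_mask.tif` (with JSON
#' sidecars), `cloud.csv`, and `scene.json` (configuration + truth FVC).
#'
#' @param scene An `fvc_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "fvc_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- scene$rgb$transform
  write_raster_tiff(scene$rgb, file.path(dir, "rgb.tif"))
  write_raster_tiff(scene$elevation, file.path(dir, "elevation.tif"), tr)
  write_raster_tiff(scene$slope, file.path(dir, "slope.tif"), tr)
  tm <- scene$truth_mask
  attr(tm, "levels") <- NULL
  storage.mode(tm) <- "double"
  write_raster_tiff(tm, file.path(dir, "truth_mask.tif"), tr, bit8 = TRUE)
  write_cloud_csv(scene$cloud, file.path(dir, "cloud.csv"))
  cfg <- scene$config
  jsonlite::write_json(
    list(rows = cfg$rows, cols = cfg$cols, pixel_size = cfg$pixel_size,
         class_fractions = as.list(cfg$class_fractions), relief = cfg$relief,
         point_density = cfg$point_density, noise_sd = cfg$noise_sd,
         blob_scale = cfg$blob_scale, seed = cfg$seed,
         classes = fvc_classes(), truth_fvc = scene$truth_fvc),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write every artifact of a pipeline run to a directory
#'
#' @param run An `fvc_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "fvc_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scene(run$scene, file.path(dir, "scene"))
  tr <- run$scene$rgb$transform
  idx <- run$indices[[run$report$chosen_index]]
  write_raster_tiff(idx$values, file.path(dir, "index.tif"), tr)
  lab <- run$segmentation$label_raster
  storage.mode(lab) <- "double"
  write_raster_tiff(lab, file.path(dir, "segments.tif"), tr)
  utils::write.csv(run$segmentation$segments,
                   file.path(dir, "segments.csv"), row.names = FALSE)
  feats <- run$features
  feats$label <- run$labels
  feats$predicted <- run$predicted
  feats$train <- run$train
  utils::write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
  cm <- run$evaluation$confusion
  utils::write.csv(as.data.frame.matrix(unclass(cm)),
                   file.path(dir, "confusion.csv"))
  cl <- run$mapping$cloud
  cl$vegetation <- run$mapping$vegetation_assigned
  write_cloud_csv(cl, file.path(dir, "cloud_classified.csv"))
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(dir)
}
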