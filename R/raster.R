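# Raster containers. Grids are plain R matrices (rows = image rows, north-up:
# world y decreases with row). Georeferencing is a simple affine transform:
# world coordinates are taken at pixel centers.

#' Create a georeferenced RGB raster
#'
#' Bands are stored as numeric matrices with 8-bit values in \[0, 255\]. The
#' geotransform places the grid north-up: the world x of column j is
#' `x_origin + (j - 0.5) * pixel_size` and the world y of row i is
#' `y_origin - (i - 0.5) * pixel_size`, i.e. `(x_origin, y_origin)` is the
#' outer corner of the top-left pixel.
#'
#' @param r,g,b Numeric matrices of equal dimension with values in \[0, 255\].
#' @param pixel_size Ground sampling distance in meters per pixel.
#' @param x_origin,y_origin World coordinates of the top-left corner.
#' @param nodata_mask Optional logical matrix, `TRUE` where the pixel is void.
#' @return An object of class `rgb_raster`.
#' @export
rgb_raster <- function(r, g, b, pixel_size = 0.08, x_origin = 0,
                       y_origin = nrow(r) * pixel_size, nodata_mask = NULL) {
  stopifnot(is.matrix(r), is.matrix(g), is.matrix(b))
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b))) {
    stop("all three bands must share dimensions")
  }
  rng <- range(c(r, g, b), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("band values must lie in [0, 255]")
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, nrow(r), ncol(r))
  }
  stopifnot(identical(dim(nodata_mask), dim(r)))
  structure(
    list(r = r, g = g, b = b,
         transform = grid_transform(nrow(r), ncol(r), pixel_size,
                                    x_origin, y_origin),
         nodata_mask = nodata_mask),
    class = "rgb_raster"
  )
}

grid_transform <- function(rows, cols, pixel_size, x_origin, y_origin) {
  stopifnot(pixel_size > 0)
  list(rows = rows, cols = cols, pixel_size = pixel_size,
       x_origin = x_origin, y_origin = y_origin)
}

#' @export
print.rgb_raster <- function(x, ...) {
  tr <- x$transform
  cat(sprintf("<rgb_raster> %d x %d px, %.3g m/px, origin (%.6g, %.6g)\n",
              tr$rows, tr$cols, tr$pixel_size, tr$x_origin, tr$y_origin))
  invisible(x)
}

#' Dimensions of an RGB raster
#' @param x An `rgb_raster`.
#' @return Integer vector `c(rows, cols)`.
#' @export
dim.rgb_raster <- function(x) dim(x$r)

# World coordinates of pixel centers (vectorized over row/col indices).
pixel_center_xy <- function(transform, row, col) {
  list(x = transform$x_origin + (col - 0.5) * transform$pixel_size,
       y = transform$y_origin - (row - 0.5) * transform$pixel_size)
}

# Row/col of the pixel containing world (x, y); points exactly on a pixel
# boundary fall into the pixel to the right/below, and the far footprint edge
# is clamped into the last row/col so boundary points remain inside.
world_to_pixel <- function(transform, x, y) {
  col <- floor((x - transform$x_origin) / transform$pixel_size) + 1L
  row <- floor((transform$y_origin - y) / transform$pixel_size) + 1L
  list(row = pmin(pmax(row, 1L), transform$rows),
       col = pmin(pmax(col, 1L), transform$cols))
}

# Is (x, y) within the raster footprint (boundary inclusive)?
in_footprint <- function(transform, x, y) {
  x >= transform$x_origin &
    x <= transform$x_origin + transform$cols * transform$pixel_size &
    y <= transform$y_origin &
    y >= transform$y_origin - transform$rows * transform$pixel_size
}
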