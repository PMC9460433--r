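# Synthetic tailings-impoundment scene generator: blob-shaped class regions,
# class-calibrated RGB, stepped terrain, and an RGB-attributed point cloud.

#' Default per-class spectral model
#'
#' Class RGB means were calibrated by least squares so that the nine
#' visible-band index values computed from them approximate published
#' per-class index statistics for a phosphate tailings site (vegetation
#' moderately green, bare land reddish brown, tailing sand bright gray, water
#' dark blue-green). Within-class variation is decomposed into three
#' components, all in 8-bit digital numbers:
#' \describe{
#'   \item{sd_bright}{common brightness fluctuation of all three bands;
#'     ratio-type indices are insensitive to it.}
#'   \item{sd_rb}{anti-correlated red/blue fluctuation; it broadens indices
#'     contrasting R against B (MRBVI, MGRVI, NGRDI) while leaving the
#'     green-difference indices (VDVI, ExG) nearly untouched, reproducing the
#'     published ordering of per-class standard deviations.}
#'   \item{sd_iid}{independent per-band noise, the floor for every index.}
#' }
#' This is a calibration, not ground truth.
#'
#' @return Named list (one entry per class) of lists with elements `mean`
#'   (length-3 RGB), `sd_bright`, `sd_rb`, `sd_iid`.
#' @export
default_spectral_model <- function() {
  list(
    vegetation   = list(mean = c(96.04, 98.15, 75.81),
                        sd_bright = 8,  sd_rb = 15,   sd_iid = 1.8),
    bare_land    = list(mean = c(168.42, 149.17, 112.41),
                        sd_bright = 8,  sd_rb = 13.5, sd_iid = 2.4),
    tailing_sand = list(mean = c(194.49, 197.56, 187.94),
                        sd_bright = 10, sd_rb = 11,   sd_iid = 2.5),
    water        = list(mean = c(52.58, 67.21, 60.21),
                        sd_bright = 5,  sd_rb = 12,   sd_iid = 1.5)
  )
}

#' Configuration of a synthetic scene
#'
#' @param rows,cols Grid size in pixels (`rows * cols >= 64`).
#' @param pixel_size Ground resolution in meters per pixel (default 0.08 m).
#' @param class_fractions Named numeric vector of target areal fractions for
#'   the four classes; nonnegative, summing to 1.
#' @param relief Elevation range of the stepped terrain, meters (default 140).
#' @param point_density Point-cloud density in points per square meter
#'   (default 214.36).
#' @param spectral_model Per-class RGB model, see [default_spectral_model()].
#' @param noise_sd Additional global per-band pixel noise (DN), default 0.
#' @param blob_scale Correlation length of the class-region random fields, in
#'   pixels; defaults to 1/16 of the shorter grid side (at least 4).
#' @param seed Integer RNG seed; equal seeds give identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(rows = 256, cols = 256, pixel_size = 0.08,
                         class_fractions = c(vegetation = 0.36,
                                             bare_land = 0.20,
                                             tailing_sand = 0.24,
                                             water = 0.20),
                         relief = 140, point_density = 214.36,
                         spectral_model = default_spectral_model(),
                         noise_sd = 0, blob_scale = NULL, seed = 1L) {
  if (rows * cols < 64) stop("grid must have at least 64 pixels")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (point_density <= 0) stop("point_density must be positive")
  cls <- fvc_classes()
  if (is.null(names(class_fractions)) ||
      !setequal(names(class_fractions), cls)) {
    stop("class_fractions must be named with: ", paste(cls, collapse = ", "))
  }
  class_fractions <- class_fractions[cls]
  if (any(class_fractions < 0)) stop("class fractions must be nonnegative")
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1")
  }
  if (relief < 0) stop("relief must be nonnegative")
  if (is.null(blob_scale)) blob_scale <- max(4, min(rows, cols) / 16)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pixel_size = pixel_size, class_fractions = class_fractions,
         relief = relief, point_density = point_density,
         spectral_model = spectral_model, noise_sd = noise_sd,
         blob_scale = blob_scale, seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Periodic Gaussian random field via FFT filtering of white noise; smooth,
# zero-mean, used only through its rank order (thresholding), so the marginal
# scale is irrelevant.
gaussian_field <- function(rows, cols, range_px) {
  z <- matrix(rnorm(rows * cols), rows, cols)
  ri <- c(0:floor(rows / 2), -(ceiling(rows / 2) - 1):-1)
  ci <- c(0:floor(cols / 2), -(ceiling(cols / 2) - 1):-1)
  # Gaussian transfer function (low-pass) on the torus
  hr <- exp(-2 * (pi * ri * range_px / rows)^2)
  hc <- exp(-2 * (pi * ci * range_px / cols)^2)
  H <- outer(hr, hc)
  Re(fft(fft(z) * H, inverse = TRUE)) / (rows * cols)
}

# Partition the grid into 4 blob-shaped classes hitting the requested
# fractions exactly (to one pixel): one field separates vegetation from the
# rest, a second field splits the remainder by conditional quantiles.
class_mask <- function(cfg) {
  n <- cfg$rows * cfg$cols
  fr <- cfg$class_fractions
  f1 <- gaussian_field(cfg$rows, cfg$cols, cfg$blob_scale)
  f2 <- gaussian_field(cfg$rows, cfg$cols, cfg$blob_scale)
  lab <- integer(n)
  n_veg <- round(fr["vegetation"] * n)
  ord1 <- order(f1, seq_len(n))   # deterministic tie-break by pixel index
  veg_idx <- ord1[seq_len(n_veg)]
  lab[veg_idx] <- 1L
  rest <- if (n_veg > 0) ord1[-seq_len(n_veg)] else ord1
  if (length(rest)) {
    rest <- rest[order(f2[rest], rest)]
    fr_rest <- fr[c("bare_land", "tailing_sand", "water")]
    n_rest <- length(rest)
    counts <- floor(fr_rest / sum(fr_rest) * n_rest)
    rem <- n_rest - sum(counts)
    if (rem > 0) {  # distribute the rounding remainder by largest fraction
      o <- order(-fr_rest)
      counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
    }
    bounds <- cumsum(counts)
    lab[rest[seq_len(bounds[1])]] <- 2L
    if (bounds[2] > bounds[1]) {
      lab[rest[(bounds[1] + 1):bounds[2]]] <- 3L
    }
    if (bounds[3] > bounds[2]) {
      lab[rest[(bounds[2] + 1):bounds[3]]] <- 4L
    }
  }
  matrix(lab, cfg$rows, cfg$cols)
}

# Stepped terrain: terraces descending along the row direction (the lawn-dam
# morphology), rescaled to span exactly `relief` meters.
stepped_elevation <- function(rows, cols, relief, n_steps = 8) {
  t <- (seq_len(rows) - 1) / max(rows - 1, 1)
  step <- floor(t * n_steps) / n_steps
  within <- (t * n_steps - floor(t * n_steps)) / n_steps
  prof <- step + 0.15 * within        # gentle ramp on each terrace
  if (max(prof) > 0) prof <- prof / max(prof)
  matrix(rep((1 - prof) * relief, cols), rows, cols)
}

#' Slope in degrees from an elevation grid
#'
#' Central differences with `pixel_size` spacing; one-sided differences at the
#' border rows/columns.
#'
#' @param elevation Numeric matrix of elevations (meters).
#' @param pixel_size Grid spacing in meters.
#' @return Matrix of slope angles in degrees.
#' @export
slope_from_elevation <- function(elevation, pixel_size) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  den_r <- ifelse(ip - im == 2, 2, 1) * pixel_size
  den_c <- ifelse(jp - jm == 2, 2, 1) * pixel_size
  dzdr <- (elevation[ip, , drop = FALSE] - elevation[im, , drop = FALSE]) / den_r
  dzdc <- sweep(elevation[, jp, drop = FALSE] - elevation[, jm, drop = FALSE],
                2, den_c, "/")
  atan(sqrt(dzdr^2 + dzdc^2)) * 180 / pi
}

#' Generate a synthetic tailings scene
#'
#' Produces blob-shaped contiguous class regions (two thresholded Gaussian
#' random fields) hitting the requested class fractions to within one pixel, a
#' stepped elevation ramp spanning `relief` meters with slope derived by
#' central differences, per-class RGB values drawn from the spectral model
#' (clipped to \[0, 255\] and rounded to 8-bit), and an RGB-consistent point
#' cloud. Identical seeds give identical scenes.
#'
#' @param config A [scene_config()].
#' @return An object of class `fvc_scene` with elements `rgb` (an
#'   [rgb_raster()]), `elevation`, `slope`, `truth_mask` (factor-coded integer
#'   matrix with `levels` attribute), `cloud` (data frame `x,y,z,R,G,B`),
#'   `truth_fvc` (percent of vegetation pixels), and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  cls <- fvc_classes()
  mask <- class_mask(config)

  nr <- config$rows; nc <- config$cols
  R <- G <- B <- matrix(0, nr, nc)
  for (k in seq_along(cls)) {
    idx <- which(mask == k)
    if (!length(idx)) next
    m <- config$spectral_model[[cls[k]]]
    kn <- length(idx)
    zb <- rnorm(kn) * m$sd_bright
    zr <- rnorm(kn) * m$sd_rb / sqrt(2)
    R[idx] <- m$mean[1] + zb + zr + rnorm(kn) * m$sd_iid
    G[idx] <- m$mean[2] + zb      + rnorm(kn) * m$sd_iid
    B[idx] <- m$mean[3] + zb - zr + rnorm(kn) * m$sd_iid
  }
  if (config$noise_sd > 0) {
    R <- R + rnorm(nr * nc) * config$noise_sd
    G <- G + rnorm(nr * nc) * config$noise_sd
    B <- B + rnorm(nr * nc) * config$noise_sd
  }
  clip8 <- function(x) pmin(pmax(round(x), 0), 255)
  rgb <- rgb_raster(clip8(R), clip8(G), clip8(B),
                    pixel_size = config$pixel_size)

  elevation <- stepped_elevation(nr, nc, config$relief)
  slope <- slope_from_elevation(elevation, config$pixel_size)

  cloud <- rasterize_cloud(rgb, elevation, density = config$point_density,
                           seed = config$seed + 1L)

  truth_fvc <- 100 * sum(mask == 1L) / (nr * nc)
  attr(mask, "levels") <- cls
  structure(
    list(rgb = rgb, elevation = elevation, slope = slope, truth_mask = mask,
         cloud = cloud, truth_fvc = truth_fvc, config = config),
    class = "fvc_scene"
  )
}

#' @export
print.fvc_scene <- function(x, ...) {
  cat(sprintf("<fvc_scene> %d x %d px @ %.3g m, %d cloud points, truth FVC %.2f%%\n",
              x$config$rows, x$config$cols, x$config$pixel_size,
              nrow(x$cloud), x$truth_fvc))
  invisible(x)
}

#' Sample an RGB-attributed point cloud over a raster footprint
#'
#' The number of points is Poisson with mean `footprint area (m^2) * density`;
#' planimetric positions are uniform over the footprint; each point's RGB is
#' copied from its enclosing pixel; z is bilinearly interpolated from the
#' elevation grid (values at pixel centers, clamped at the border).
#'
#' @param scene_rgb An [rgb_raster()].
#' @param elevation Elevation matrix on the same grid.
#' @param density Points per square meter (> 0).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `x, y, z, R, G, B`.
#' @export
rasterize_cloud <- function(scene_rgb, elevation, density, seed = 1L) {
  stopifnot(inherits(scene_rgb, "rgb_raster"))
  if (density <= 0) stop("density must be positive")
  tr <- scene_rgb$transform
  if (tr$rows < 1 || tr$cols < 1) stop("empty raster")
  stopifnot(nrow(elevation) == tr$rows, ncol(elevation) == tr$cols)
  set.seed(seed)
  area <- tr$rows * tr$cols * tr$pixel_size^2
  n <- rpois(1, area * density)
  x <- runif(n, tr$x_origin, tr$x_origin + tr$cols * tr$pixel_size)
  y <- runif(n, tr$y_origin - tr$rows * tr$pixel_size, tr$y_origin)
  px <- world_to_pixel(tr, x, y)
  lin <- cbind(px$row, px$col)
  z <- bilinear_at(elevation, tr, x, y)
  data.frame(x = x, y = y, z = z,
             R = scene_rgb$r[lin], G = scene_rgb$g[lin], B = scene_rgb$b[lin])
}

# Bilinear interpolation of a grid whose values sit at pixel centers; queries
# beyond the outermost centers are clamped (constant extrapolation).
bilinear_at <- function(grid, transform, x, y) {
  nr <- transform$rows; nc <- transform$cols
  gc <- (x - transform$x_origin) / transform$pixel_size + 0.5
  gr <- (transform$y_origin - y) / transform$pixel_size + 0.5
  gc <- pmin(pmax(gc, 1), nc)
  gr <- pmin(pmax(gr, 1), nr)
  r0 <- pmin(floor(gr), nr - 1); c0 <- pmin(floor(gc), nc - 1)
  if (nr == 1) r0 <- rep(1, length(gr))
  if (nc == 1) c0 <- rep(1, length(gc))
  fr <- gr - r0; fc <- gc - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  v00 <- grid[cbind(r0, c0)]; v10 <- grid[cbind(r1, c0)]
  v01 <- grid[cbind(r0, c1)]; v11 <- grid[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Per-pixel truth class raster as a factor matrix helper
#'
#' @param scene An `fvc_scene`.
#' @return Character matrix of class names.
#' @export
truth_classes <- function(scene) {
  cls <- attr(scene$truth_mask, "levels")
  matrix(cls[scene$truth_mask], nrow(scene$truth_mask), ncol(scene$truth_mask))
}
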