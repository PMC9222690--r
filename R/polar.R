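#' Discretized annular polar grid
#'
#' The swarm does not search the full image: the disc boundary is known to lie
#' in an annulus around the disc centre, so candidate points are laid out on a
#' polar grid of radii `r_min + delta_r * i` and angles `delta_theta * j`
#' around `center`.  The angular resolution is snapped so that the number of
#' angular columns is an exact multiple of `n_sectors`: the annulus is later
#' partitioned into `n_sectors` equal half-open sectors and every column must
#' belong to exactly one of them.  The effective `delta_theta` is therefore
#' `2 * pi / n_angular` with `n_angular = n_sectors * ceiling((2 * pi /
#' delta_theta) / n_sectors)`, i.e. never coarser than requested.
#'
#' Coordinates are 0-based image coordinates (x = column, y = row, origin
#' top-left); angles grow counterclockwise from the +x polar axis.
#'
#' @param center Numeric `(xc, yc)` in pixels.
#' @param r_min,r_max Inner and outer annulus radii in pixels, `0 < r_min <
#'   r_max`.
#' @param delta_r Radial step in pixels (default 1).
#' @param delta_theta Requested angular step in radians (default 1 degree).
#' @param n_sectors Number of angular sectors/subgroups `N` (default 50).
#' @return An object of class `polar_grid` with elements `center`, `r_min`,
#'   `r_max`, `delta_r`, `delta_theta`, `n_radial`, `n_angular`, `n_sectors`,
#'   `radii` and `angles`.
#' @examples
#' g <- polar_grid(c(10, 10), r_min = 1, r_max = 2, delta_r = 1,
#'                 delta_theta = pi / 2, n_sectors = 4)
#' g$n_radial * g$n_angular # 8 candidate points
#' @export
polar_grid <- function(center, r_min, r_max, delta_r = 1,
                       delta_theta = 2 * pi / 360, n_sectors = 50) {
  stopifnot(length(center) == 2, is.numeric(center))
  if (!(r_min > 0 && r_max > r_min)) {
    stop("need 0 < r_min < r_max")
  }
  if (delta_r <= 0 || delta_theta <= 0) stop("steps must be positive")
  if (n_sectors < 1) stop("`n_sectors` must be >= 1")
  n_radial <- floor((r_max - r_min) / delta_r) + 1L
  if (n_radial < 2L) stop("annulus too thin: need at least 2 radial rows")
  requested <- floor(2 * pi / delta_theta)
  n_angular <- as.integer(n_sectors * max(1L, ceiling(requested / n_sectors)))
  structure(
    list(
      center = as.numeric(center),
      r_min = r_min, r_max = r_max,
      delta_r = delta_r,
      delta_theta = 2 * pi / n_angular,
      n_radial = as.integer(n_radial),
      n_angular = n_angular,
      n_sectors = as.integer(n_sectors),
      radii = r_min + delta_r * (seq_len(n_radial) - 1),
      angles = 2 * pi / n_angular * (seq_len(n_angular) - 1)
    ),
    class = "polar_grid"
  )
}

#' Radial gradient fitness over a polar grid
#'
#' For every grid point the fitness is the magnitude of the radial directional
#' derivative of the (Gaussian pre-smoothed) scalar field, estimated by a
#' central difference of step `delta_r` along the ray from the grid centre,
#' with bilinear sampling at non-integer coordinates.  A bright disc on a
#' darker background produces a ridge of high fitness along its boundary,
#' which is what the swarm climbs.
#'
#' @param field Numeric matrix (e.g. the red channel), rows = y, columns = x.
#' @param grid A [polar_grid()].
#' @param sigma Standard deviation in pixels of the Gaussian pre-smoothing
#'   (default 2; 0 disables smoothing).
#' @return A `n_radial x n_angular` matrix of non-negative fitness values.
#' @export
radial_gradient <- function(field, grid, sigma = 2) {
  stopifnot(inherits(grid, "polar_grid"))
  h <- nrow(field)
  w <- ncol(field)
  xc <- grid$center[1]
  yc <- grid$center[2]
  reach <- grid$r_max + grid$delta_r
  if (xc - reach < 0 || xc + reach > w - 1 || yc - reach < 0 || yc + reach > h - 1) {
    stop("polar grid (including the central-difference reach) extends outside the field")
  }
  sm <- gaussian_blur(field, sigma)
  rr <- matrix(grid$radii, grid$n_radial, grid$n_angular)
  tt <- matrix(grid$angles, grid$n_radial, grid$n_angular, byrow = TRUE)
  ct <- cos(tt)
  st <- sin(tt)
  f_out <- sample_bilinear(sm, xc + (rr + grid$delta_r) * ct, yc + (rr + grid$delta_r) * st)
  f_in <- sample_bilinear(sm, xc + (rr - grid$delta_r) * ct, yc + (rr - grid$delta_r) * st)
  matrix(abs(f_out - f_in) / (2 * grid$delta_r), grid$n_radial, grid$n_angular)
}

#' Build the exploration area
#'
#' Assembles the full annular search space: resolves the centre, lays out the
#' polar grid, scores every grid point with the radial gradient of the red
#' channel, and partitions the angle range `[0, 2 * pi)` into `n_sectors`
#' half-open sectors (sector `i` covers `[2 * pi * (i - 1) / N,
#' 2 * pi * i / N)`), one per particle subgroup.
#'
#' With `center = "auto"` the centre is the centroid of the bright disc
#' region of the smoothed red channel (all pixels above the midpoint between
#' its median and maximum); the input ROI is assumed to be roughly
#' disc-centred.  The defaults tie the annulus to the image: `r_min = 0.3` and
#' `r_max = 0.7` of half the image width.
#'
#' @param image A standardized RGB array (see [standardize_roi()]).
#' @param center `"auto"` or numeric `(xc, yc)` in 0-based pixel coordinates.
#' @param r_min,r_max Annulus radii in pixels; `NULL` uses the defaults above.
#' @param delta_r,delta_theta,n_sectors Grid parameters, see [polar_grid()].
#' @param sigma Gaussian pre-smoothing for the gradient, see
#'   [radial_gradient()].
#' @return An object of class `exploration_area`: the `grid`, the `fitness`
#'   matrix, `n_sectors`, a `sector_bounds` tibble (`sector`, `theta_lo`,
#'   `theta_hi`), `image_dim` and the resolved `center`.
#' @export
build_exploration_area <- function(image, center = "auto",
                                   r_min = NULL, r_max = NULL,
                                   delta_r = 1, delta_theta = 2 * pi / 360,
                                   n_sectors = 50, sigma = 2) {
  red <- red_channel(image)
  h <- nrow(red)
  w <- ncol(red)
  r_min <- r_min %||% (0.3 * w / 2)
  r_max <- r_max %||% (0.7 * w / 2)
  if (identical(center, "auto")) {
    center <- bright_centroid(red)
  }
  center <- as.numeric(center)
  reach <- r_max + delta_r
  if (center[1] < reach || center[1] > w - 1 - reach ||
      center[2] < reach || center[2] > h - 1 - reach) {
    stop(sprintf(
      "resolved center (%.1f, %.1f) is closer than r_max (+ delta_r) = %.1f px to an image border",
      center[1], center[2], reach
    ))
  }
  grid <- polar_grid(center, r_min, r_max, delta_r, delta_theta, n_sectors)
  fitness <- radial_gradient(red, grid, sigma)
  bounds <- tibble::tibble(
    sector = seq_len(n_sectors),
    theta_lo = 2 * pi * (seq_len(n_sectors) - 1) / n_sectors,
    theta_hi = 2 * pi * seq_len(n_sectors) / n_sectors
  )
  structure(
    list(
      grid = grid,
      fitness = fitness,
      n_sectors = as.integer(n_sectors),
      sector_bounds = bounds,
      image_dim = c(h, w),
      center = center
    ),
    class = "exploration_area"
  )
}

# Centroid of the bright (disc) region: smooth heavily, then select all
# pixels above the midpoint of the median and the maximum.  A top-percentile
# selection would be biased toward the bright end of any illumination
# gradient; thresholding midway captures the whole disc symmetrically.
bright_centroid <- function(red) {
  sm <- gaussian_blur(red, 4)
  thr <- (stats::median(sm) + max(sm)) / 2
  sel <- which(sm >= thr, arr.ind = TRUE)
  c(mean(sel[, "col"]) - 1, mean(sel[, "row"]) - 1)
}

#' Fitness lookup for continuous polar positions
#'
#' The exploration area is a discrete point set, so a continuous particle
#' position is scored at its nearest grid point.  Any query outside the
#' annulus (`r < r_min` or `r > r_max`) has fitness exactly 0.
#'
#' @param area An [build_exploration_area()] result.
#' @param r,theta Numeric vectors of radii (pixels) and angles (radians).
#' @return Numeric vector of non-negative fitness values.
#' @export
area_fitness <- function(area, r, theta) {
  g <- area$grid
  i <- clamp(round((r - g$r_min) / g$delta_r), 0, g$n_radial - 1L)
  j <- round(theta / g$delta_theta) %% g$n_angular
  val <- area$fitness[cbind(i + 1, j + 1)]
  val[r < g$r_min | r > g$r_max] <- 0
  val
}

#' Sector index of an angle
#'
#' Sectors are half-open: angle `theta` belongs to sector
#' `floor(theta * N / (2 * pi)) + 1`, so the sector intervals partition
#' `[0, 2 * pi)` exactly.
#'
#' @param area An `exploration_area`.
#' @param theta Numeric vector of angles in radians.
#' @return Integer sector indices in `1..n_sectors`.
#' @export
sector_of <- function(area, theta) {
  n <- area$n_sectors
  as.integer(clamp(floor((theta %% (2 * pi)) * n / (2 * pi)), 0, n - 1L)) + 1L
}

#' @export
print.exploration_area <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<exploration_area> %d x %d grid (r in [%.1f, %.1f] px, %d sectors)\n",
    g$n_radial, g$n_angular, g$r_min, g$r_max, x$n_sectors
  ))
  cat(sprintf(
    "  center (%.1f, %.1f), delta_r = %g px, delta_theta = %.3f deg\n",
    x$center[1], x$center[2], g$delta_r, g$delta_theta * 180 / pi
  ))
  invisible(x)
}

#' Plot an exploration area fitness field
#'
#' @param object An `exploration_area`.
#' @param ... Unused.
#' @return A ggplot of the per-grid-point fitness in polar (radius x angle)
#'   layout.
#' @export
autoplot.exploration_area <- function(object, ...) {
  g <- object$grid
  df <- tibble::tibble(
    r = rep(g$radii, times = g$n_angular),
    theta = rep(g$angles, each = g$n_radial),
    fitness = as.vector(object$fitness)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$r, fill = .data$fitness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "angle (rad)", y = "radius (px)", fill = "|d/dr|",
      title = "Exploration-area radial-gradient fitness"
    )
}
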