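#' Specification of a synthetic fundus ROI
#'
#' Parameterizes the synthetic generator used for testing the pipeline
#' without any dataset: a bright quasi-elliptical disc on a darker
#' background, a brighter inner cup, dark vessel strokes crossing the disc
#' boundary, an illumination gradient and additive Gaussian noise, with the
#' exact ellipse interior as paired ground truth.  The red channel carries
#' the full contrast; green and blue carry 60% and 30% of it, mirroring the
#' channel behaviour of real fundus photographs.
#'
#' Defaults reflect the study conditions exercised throughout the test
#' suite: a 256 px ROI, disc semi-axes around 60 px (inside the default
#' annulus), contrast step 0.3, three vessels, and noise sigma 0.05.
#'
#' @param size Image side length in pixels.
#' @param center Disc centre `(x, y)` in 0-based pixels; default image
#'   centre.
#' @param a,b Disc semi-axes in pixels.
#' @param rotation Disc rotation in radians.
#' @param disc_contrast Red-channel step height of the disc in `[0, 1]`.
#' @param cup_a,cup_b Cup semi-axes (must fit inside the disc); defaults 45%
#'   of the disc axes.
#' @param cup_contrast Extra brightness of the cup.
#' @param vessel_count,vessel_width,vessel_darkness Number of vessel strokes,
#'   their width (px) and darkness (intensity subtracted).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param illumination Amplitude of a linear illumination gradient.
#' @param background Background red-channel level.
#' @param seed Integer seed; `NULL` resolves to a random seed at generation.
#' @return An object of class `fundus_spec` (a named list).
#' @export
fundus_spec <- function(size = 256,
                        center = c((size - 1) / 2, (size - 1) / 2),
                        a = 60, b = 55, rotation = 0,
                        disc_contrast = 0.3,
                        cup_a = 0.45 * a, cup_b = 0.45 * b,
                        cup_contrast = 0.15,
                        vessel_count = 3, vessel_width = 3,
                        vessel_darkness = 0.3,
                        noise_sd = 0.05,
                        illumination = 0.05,
                        background = 0.35,
                        seed = NULL) {
  spec <- list(
    size = as.integer(size), center = as.numeric(center),
    a = a, b = b, rotation = rotation,
    disc_contrast = disc_contrast,
    cup_a = cup_a, cup_b = cup_b, cup_contrast = cup_contrast,
    vessel_count = as.integer(vessel_count),
    vessel_width = vessel_width, vessel_darkness = vessel_darkness,
    noise_sd = noise_sd, illumination = illumination,
    background = background,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  if (spec$cup_a >= spec$a || spec$cup_b >= spec$b) {
    stop("cup semi-axes must be strictly smaller than the disc semi-axes")
  }
  if (spec$a <= 0 || spec$b <= 0) stop("disc semi-axes must be positive")
  structure(spec, class = "fundus_spec")
}

#' Generate a synthetic fundus ROI with ground truth
#'
#' Renders the [fundus_spec()] scene.  The disc and cup edges are feathered
#' over about 2 px so the radial gradient peaks exactly on the ellipse
#' boundary; the ground-truth mask is the exact (unfeathered) ellipse
#' interior.
#'
#' @param spec A [fundus_spec()].
#' @return A list of class `synthetic_fundus`: `image` (`size x size x 3`
#'   array in `[0, 1]`), `mask` (binary matrix), and `spec` with the resolved
#'   seed.
#' @examples
#' sf <- generate_fundus(fundus_spec(seed = 1, vessel_count = 0, noise_sd = 0))
#' sum(sf$mask) / (pi * 60 * 55) # close to 1
#' @export
generate_fundus <- function(spec) {
  stopifnot(inherits(spec, "fundus_spec"))
  if (is.null(spec$seed)) spec$seed <- sample.int(.Machine$integer.max, 1)
  set.seed(spec$seed)
  n <- spec$size
  xc <- spec$center[1]
  yc <- spec$center[2]
  dx <- matrix(0:(n - 1) - xc, n, n, byrow = TRUE)
  dy <- matrix(0:(n - 1) - yc, n, n)
  r_pix <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  # signed radial distance to a rotated ellipse boundary along each ray
  edge_dist <- function(ea, eb) {
    psi <- phi - spec$rotation
    rho <- ea * eb / sqrt((eb * cos(psi))^2 + (ea * sin(psi))^2)
    r_pix - rho
  }
  feather <- 1 # logistic scale; ~2 px visible transition
  disc_s <- stats::plogis(-edge_dist(spec$a, spec$b) / feather)
  cup_s <- stats::plogis(-edge_dist(spec$cup_a, spec$cup_b) / feather)
  illum_dir <- stats::runif(1, 0, 2 * pi)
  illum <- spec$illumination * (dx * cos(illum_dir) + dy * sin(illum_dir)) / n
  structure_field <- spec$disc_contrast * disc_s + spec$cup_contrast * cup_s + illum
  if (spec$vessel_count > 0) {
    vs <- render_vessels(spec, xc, yc)
    structure_field <- structure_field - spec$vessel_darkness * vs
  }
  img <- array(0, dim = c(n, n, 3L))
  gains <- c(1, 0.6, 0.3)
  bases <- spec$background * c(1, 0.55, 0.3)
  for (ch in 1:3) {
    plane <- bases[ch] + gains[ch] * structure_field
    if (spec$noise_sd > 0) {
      plane <- plane + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    }
    img[, , ch] <- clamp(plane, 0, 1)
  }
  psi <- phi - spec$rotation
  rho <- spec$a * spec$b / sqrt((spec$b * cos(psi))^2 + (spec$a * sin(psi))^2)
  mask <- (r_pix <= rho) * 1L
  structure(list(image = img, mask = mask, spec = spec), class = "synthetic_fundus")
}

# smoothed random-walk strokes entering the disc from outside the annulus,
# rendered as a Gaussian-profile intensity field in [0, 1]
render_vessels <- function(spec, xc, yc) {
  n <- spec$size
  v <- matrix(0, n, n)
  s <- spec$vessel_width / 2
  wr <- ceiling(3 * s)
  for (k in seq_len(spec$vessel_count)) {
    alpha <- stats::runif(1, 0, 2 * pi)
    r_start <- 0.95 * (n / 2)
    px <- xc + r_start * cos(alpha)
    py <- yc + r_start * sin(alpha)
    heading <- alpha + pi + stats::runif(1, -0.3, 0.3) # roughly toward centre
    for (step in seq_len(200)) {
      heading <- heading + stats::rnorm(1, sd = 0.12)
      px <- px + 1.5 * cos(heading)
      py <- py + 1.5 * sin(heading)
      if (px < 1 || px > n - 2 || py < 1 || py > n - 2) break
      if (sqrt((px - xc)^2 + (py - yc)^2) < 0.25 * min(spec$a, spec$b)) break
      x0 <- max(0, round(px) - wr)
      x1 <- min(n - 1, round(px) + wr)
      y0 <- max(0, round(py) - wr)
      y1 <- min(n - 1, round(py) + wr)
      gx <- x0:x1
      gy <- y0:y1
      d2 <- outer((gy - py)^2, (gx - px)^2, `+`)
      patch <- exp(-d2 / (2 * s^2))
      sub <- v[gy + 1, gx + 1, drop = FALSE]
      v[gy + 1, gx + 1] <- pmax(sub, patch)
    }
  }
  v
}

#' Generate a suite of synthetic fundus images
#'
#' Draws `n` independent scenes with disc radius, axis ratio and contrast
#' sampled from the given ranges, each with its own child seed so the suite
#' is reproducible from the manifest alone.  With `dir` set, images and
#' masks are written as PNG and the manifest as CSV; otherwise images and
#' masks are returned in list-columns.
#'
#' @param n Number of images.
#' @param ranges A named list of `c(lo, hi)` sampling ranges for `radius`
#'   (semi-axis `a`, px), `axis_ratio` (`b / a`) and `disc_contrast`.
#' @param seed Integer seed for the whole suite.
#' @param dir Output directory, or `NULL` to keep the suite in memory.
#' @param ... Further fixed [fundus_spec()] parameters (e.g. `vessel_count`,
#'   `noise_sd`).
#' @return A tibble manifest: `id`, all spec parameters, plus either `image`
#'   / `mask` list-columns or `image_path` / `mask_path`.
#' @export
generate_fundus_suite <- function(n,
                                  ranges = list(
                                    radius = c(45, 80),
                                    axis_ratio = c(1, 1),
                                    disc_contrast = c(0.3, 0.3)
                                  ),
                                  seed = NULL, dir = NULL, ...) {
  if (n < 1) stop("`n` must be >= 1")
  defaults <- list(radius = c(45, 80), axis_ratio = c(1, 1), disc_contrast = c(0.3, 0.3))
  ranges <- utils::modifyList(defaults, ranges)
  if (!is.null(seed)) set.seed(seed)
  draws <- tibble::tibble(
    id = seq_len(n),
    a = stats::runif(n, ranges$radius[1], ranges$radius[2]),
    ratio = stats::runif(n, ranges$axis_ratio[1], ranges$axis_ratio[2]),
    disc_contrast = stats::runif(n, ranges$disc_contrast[1], ranges$disc_contrast[2]),
    seed = sample.int(.Machine$integer.max, n)
  )
  rows <- purrr::pmap(draws, function(id, a, ratio, disc_contrast, seed) {
    spec <- fundus_spec(
      a = a, b = a * ratio, disc_contrast = disc_contrast, seed = seed, ...
    )
    sf <- generate_fundus(spec)
    row <- tibble::as_tibble(spec_fields(sf$spec))
    row$id <- id
    if (is.null(dir)) {
      row$image <- list(sf$image)
      row$mask <- list(sf$mask)
    } else {
      row$image_path <- file.path(dir, sprintf("fundus_%03d.png", id))
      row$mask_path <- file.path(dir, sprintf("mask_%03d.png", id))
    }
    list(row = row, sf = sf)
  })
  manifest <- dplyr::relocate(
    dplyr::bind_rows(purrr::map(rows, "row")), "id"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (k in seq_len(n)) {
      png::writePNG(rows[[k]]$sf$image, manifest$image_path[k])
      write_mask(rows[[k]]$sf$mask, manifest$mask_path[k])
      jsonlite::write_json(
        spec_fields(rows[[k]]$sf$spec),
        file.path(dir, sprintf("spec_%03d.json", k)),
        auto_unbox = TRUE, digits = NA
      )
    }
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  manifest
}

# flatten a fundus_spec to scalar fields for a manifest row
spec_fields <- function(spec) {
  list(
    size = spec$size,
    center_x = spec$center[1], center_y = spec$center[2],
    a = spec$a, b = spec$b, rotation = spec$rotation,
    disc_contrast = spec$disc_contrast,
    cup_a = spec$cup_a, cup_b = spec$cup_b, cup_contrast = spec$cup_contrast,
    vessel_count = spec$vessel_count, vessel_width = spec$vessel_width,
    vessel_darkness = spec$vessel_darkness,
    noise_sd = spec$noise_sd, illumination = spec$illumination,
    background = spec$background, seed = spec$seed
  )
}

#' Read a suite manifest back
#'
#' @param path Path to a `manifest.csv` written by [generate_fundus_suite()].
#' @return The manifest tibble.
#' @export
read_fundus_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Rebuild a [fundus_spec()] from a manifest row
#'
#' @param row A one-row data frame (or named list) of manifest columns.
#' @return The `fundus_spec`, identical to the one that generated the image.
#' @export
spec_from_manifest <- function(row) {
  fundus_spec(
    size = row$size, center = c(row$center_x, row$center_y),
    a = row$a, b = row$b, rotation = row$rotation,
    disc_contrast = row$disc_contrast,
    cup_a = row$cup_a, cup_b = row$cup_b, cup_contrast = row$cup_contrast,
    vessel_count = row$vessel_count, vessel_width = row$vessel_width,
    vessel_darkness = row$vessel_darkness,
    noise_sd = row$noise_sd, illumination = row$illumination,
    background = row$background, seed = row$seed
  )
}
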