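#' Standardize a fundus ROI image
#'
#' Resamples an RGB region-of-interest crop to a square `size` x `size` image
#' with a Lanczos kernel (`a = 4`, i.e. an 8 x 8 support), the resampling used
#' throughout the pipeline so that all downstream radii are expressed on a
#' common pixel scale.  Non-square inputs are resized anisotropically; no
#' letterboxing is applied.  When the input already has the target size the
#' resize is a no-op and the pixels are returned unchanged.
#'
#' @param image A numeric array of dimension `height x width x 3` (RGB).
#'   Values above 1 are taken to be 8-bit and are divided by 255.
#' @param size Output side length in pixels (default 256).
#' @return A `size x size x 3` array with values in `[0, 1]`.
#' @examples
#' img <- array(runif(32 * 48 * 3), dim = c(32, 48, 3))
#' std <- standardize_roi(img, size = 16)
#' dim(std)
#' @export
standardize_roi <- function(image, size = 256) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    nch <- if (length(dim(image)) == 3L) dim(image)[3] else 1L
    stop(sprintf("`image` must be an RGB array with 3 channels, got %d", nch))
  }
  if (any(dim(image)[1:2] < 1L)) stop("`image` must have at least one pixel")
  image <- as_unit_intensity(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  wr <- lanczos_weights(h, size)
  wc <- lanczos_weights(w, size)
  out <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) {
    out[, , ch] <- clamp(wr %*% image[, , ch] %*% t(wc), 0, 1)
  }
  out
}

#' Extract the red channel
#'
#' The optic disc has its strongest and cleanest contrast against the
#' surrounding retina in the red channel, so the gradient fitness field is
#' computed from it alone.
#'
#' @param image A standardized RGB array (see [standardize_roi()]).
#' @return A numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @export
red_channel <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be an RGB array with 3 channels")
  }
  as_unit_intensity(image)[, , 1L]
}

as_unit_intensity <- function(x) {
  if (max(x, na.rm = TRUE) > 1) x / 255 else x
}

lanczos_kernel <- function(x, a = 4) {
  out <- numeric(length(x))
  nz <- x != 0 & abs(x) < a
  out[x == 0] <- 1
  xs <- x[nz]
  out[nz] <- a * sin(pi * xs) * sin(pi * xs / a) / (pi^2 * xs^2)
  out
}

# Row-weight matrix mapping n_in samples to n_out with a Lanczos a = 4 kernel.
# Taps falling off either edge are clamped to the border sample; rows are
# renormalized so constants are preserved exactly.  n_in == n_out returns the
# identity so a same-size resize is pixel-identical.
lanczos_weights <- function(n_in, n_out, a = 4) {
  if (n_in == n_out) return(diag(n_in))
  scale <- n_in / n_out
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5 # 0-based source coordinate
  base <- floor(centers)
  w <- matrix(0, n_out, n_in)
  for (t in (-a + 1):a) {
    idx <- base + t
    wt <- lanczos_kernel(centers - idx, a)
    idx <- clamp(idx, 0, n_in - 1)
    tgt <- cbind(seq_len(n_out), idx + 1)
    w[tgt] <- w[tgt] + wt
  }
  w / rowSums(w)
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# separable Gaussian blur with replicated edges
gaussian_blur <- function(field, sigma = 2) {
  if (sigma <= 0) return(field)
  k <- gaussian_kernel1d(sigma)
  blur_rows <- function(m) {
    r <- (length(k) - 1L) / 2L
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (d in seq(-r, r)) {
      out <- out + k[d + r + 1] * m[clamp(seq_len(n) + d, 1L, n), , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(field))))
}
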