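# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# signed angular difference wrapped to [-pi, pi)
wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi

# coerce a polar position to an n x 2 matrix (col 1 = r, col 2 = theta)
as_position <- function(x, arg = "position") {
  if (is.data.frame(x)) {
    if (all(c("r", "theta") %in% names(x))) {
      x <- cbind(x$r, x$theta)
    } else {
      x <- as.matrix(x)
    }
  }
  if (is.null(dim(x))) {
    if (length(x) != 2L) {
      stop(sprintf("`%s` must be a length-2 vector (r, theta) or an n x 2 matrix", arg))
    }
    x <- matrix(x, 1L, 2L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) {
    stop(sprintf("`%s` must have two columns: radius and angle", arg))
  }
  storage.mode(x) <- "double"
  x
}

# bilinear sampling of a scalar field at continuous 0-based (x = column,
# y = row) coordinates; callers must keep samples inside the field
sample_bilinear <- function(field, x, y) {
  h <- nrow(field)
  w <- ncol(field)
  x <- as.vector(x)
  y <- as.vector(y)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1)) {
    stop("bilinear sample outside the field")
  }
  x0 <- clamp(floor(x), 0, w - 2)
  y0 <- clamp(floor(y), 0, h - 2)
  fx <- x - x0
  fy <- y - y0
  i0 <- y0 + 1
  j0 <- x0 + 1
  f00 <- field[cbind(i0, j0)]
  f01 <- field[cbind(i0, j0 + 1)]
  f10 <- field[cbind(i0 + 1, j0)]
  f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * f00 + fx * f01) + fy * ((1 - fx) * f10 + fx * f11)
}
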