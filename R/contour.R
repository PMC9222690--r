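#' Fit a dense closed boundary through the winning edge members
#'
#' The optic disc boundary varies from a circle to an irregular ellipse, so
#' two finishing curves are offered:
#'
#' * `"spline"`: a periodic cubic interpolation spline through the `N` member
#'   points in angular order (passes through every point exactly).
#' * `"ellipse"`: a direct least-squares conic fit constrained to an ellipse
#'   (the stable Halir–Flusser formulation of the Fitzgibbon method).
#'
#' @param points An `N x 2` matrix of x/y image coordinates in angular order
#'   (or a tibble with `x` and `y` columns).  `N >= 4` for the spline,
#'   `N >= 5` for the ellipse.
#' @param method `"spline"` or `"ellipse"`.
#' @param n_out Number of samples on the returned curve (default 360).
#' @return An `n_out x 2` matrix of x/y vertices of the closed polyline (the
#'   closing segment back to the first vertex is implicit).
#' @examples
#' th <- 2 * pi * (0:19) / 20
#' b <- fit_boundary(cbind(50 * cos(th), 50 * sin(th)), "spline")
#' range(sqrt(rowSums(b^2))) # stays close to 50
#' @export
fit_boundary <- function(points, method = c("spline", "ellipse"), n_out = 360) {
  method <- match.arg(method)
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  n <- nrow(points)
  if (method == "spline") {
    if (n < 4) stop("spline fitting needs at least 4 points")
    tt <- seq(0, n, length.out = n_out + 1)[-(n_out + 1)]
    xs <- stats::spline(0:n, c(points[, 1], points[1, 1]),
      method = "periodic", xout = tt
    )$y
    ys <- stats::spline(0:n, c(points[, 2], points[1, 2]),
      method = "periodic", xout = tt
    )$y
    cbind(x = xs, y = ys)
  } else {
    if (n < 5) stop("ellipse fitting needs at least 5 points")
    par <- fit_ellipse_direct(points[, 1], points[, 2])
    tt <- seq(0, 2 * pi, length.out = n_out + 1)[-(n_out + 1)]
    ct <- cos(par$angle)
    st <- sin(par$angle)
    ex <- par$a * cos(tt)
    ey <- par$b * sin(tt)
    cbind(
      x = par$center[1] + ex * ct - ey * st,
      y = par$center[2] + ex * st + ey * ct
    )
  }
}

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# variant): minimizes algebraic distance subject to 4ac - b^2 = 1.
fit_ellipse_direct <- function(x, y) {
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t3 <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(t3)) {
    stop("degenerate (collinear) points: ellipse fit failed; try method = \"spline\"")
  }
  m <- s1 + s2 %*% t3
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (!length(ok)) {
    stop("degenerate (collinear) points: ellipse fit failed; try method = \"spline\"")
  }
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, as.vector(t3 %*% a1)) # (A, B, C, D, E, F)
  ellipse_geometry(coef)
}

# conic coefficients (Ax^2 + Bxy + Cy^2 + Dx + Ey + F) -> geometric parameters
ellipse_geometry <- function(k) {
  a <- k[1]; b <- k[2] / 2; c <- k[3]; d <- k[4] / 2; f <- k[5] / 2; g <- k[6]
  den <- b^2 - a * c
  if (den >= 0) stop("conic is not an ellipse; try method = \"spline\"")
  x0 <- (c * d - b * f) / den
  y0 <- (a * f - b * d) / den
  num <- 2 * (a * f^2 + c * d^2 + g * b^2 - 2 * b * d * f - a * c * g)
  disc <- sqrt((a - c)^2 + 4 * b^2)
  axis1 <- sqrt(num / (den * (disc - (a + c))))
  axis2 <- sqrt(num / (den * (-disc - (a + c))))
  angle <- if (b == 0 && a < c) {
    0
  } else if (b == 0) {
    pi / 2
  } else {
    atan2(c - a - disc, 2 * b)
  }
  if (axis1 < axis2) {
    tmp <- axis1; axis1 <- axis2; axis2 <- tmp
    angle <- angle + pi / 2
  }
  list(center = c(x0, y0), a = axis1, b = axis2, angle = angle %% pi)
}

#' Rasterize a closed boundary to a binary mask
#'
#' Fills the interior of the closed polyline with the even-odd rule by
#' horizontal scanline; pixel centres sit at integer 0-based coordinates.
#' Self-intersecting boundaries are rejected, as is a boundary lying entirely
#' outside the image.
#'
#' @param boundary An `n x 2` matrix of x/y vertices (closing segment
#'   implicit).
#' @param dim Image dimension `c(height, width)` in pixels (a single number
#'   is taken as both).
#' @return An integer `height x width` matrix of 0/1.
#' @export
rasterize_mask <- function(boundary, dim) {
  boundary <- as.matrix(boundary)
  if (length(dim) == 1L) dim <- c(dim, dim)
  h <- dim[1]
  w <- dim[2]
  bx <- boundary[, 1]
  by <- boundary[, 2]
  if (all(bx < 0 | bx > w - 1 | by < 0 | by > h - 1)) {
    stop("boundary lies entirely outside the image")
  }
  if (self_intersects(boundary)) {
    stop("self-intersecting boundary cannot be rasterized")
  }
  x1 <- bx
  y1 <- by
  x2 <- c(bx[-1], bx[1])
  y2 <- c(by[-1], by[1])
  mask <- matrix(0L, h, w)
  rows <- seq(max(0, floor(min(by))), min(h - 1, ceiling(max(by))))
  for (y0 in rows) {
    crossing <- (y1 <= y0) != (y2 <= y0)
    if (!any(crossing)) next
    xc <- x1[crossing] + (y0 - y1[crossing]) *
      (x2[crossing] - x1[crossing]) / (y2[crossing] - y1[crossing])
    xc <- sort(xc)
    for (p in seq(1, length(xc) - 1, by = 2)) {
      a <- ceiling(max(0, xc[p]))
      b <- floor(min(w - 1, xc[p + 1]))
      if (b >= a) mask[y0 + 1, (a + 1):(b + 1)] <- 1L
    }
  }
  mask
}

# O(n^2) segment-pair intersection test with a bounding-box prefilter;
# adjacent segments (sharing a vertex) are skipped
self_intersects <- function(boundary) {
  n <- nrow(boundary)
  if (n < 4) return(FALSE)
  x1 <- boundary[, 1]
  y1 <- boundary[, 2]
  x2 <- c(x1[-1], x1[1])
  y2 <- c(y1[-1], y1[1])
  cross_sign <- function(ax, ay, bx, by, px, py) {
    sign((bx - ax) * (py - ay) - (by - ay) * (px - ax))
  }
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, n)
    j <- j[!(i == 1 & j == n)] # adjacent through the wrap
    if (!length(j)) next
    box <- pmin(x1[i], x2[i]) <= pmax(x1[j], x2[j]) &
      pmax(x1[i], x2[i]) >= pmin(x1[j], x2[j]) &
      pmin(y1[i], y2[i]) <= pmax(y1[j], y2[j]) &
      pmax(y1[i], y2[i]) >= pmin(y1[j], y2[j])
    j <- j[box]
    if (!length(j)) next
    d1 <- cross_sign(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
    d2 <- cross_sign(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- cross_sign(x1[j], y1[j], x2[j], y2[j], rep(x1[i], length(j)), rep(y1[i], length(j)))
    d4 <- cross_sign(x1[j], y1[j], x2[j], y2[j], rep(x2[i], length(j)), rep(y2[i], length(j)))
    if (any(d1 != d2 & d3 != d4 & d1 != 0 & d2 != 0 & d3 != 0 & d4 != 0)) {
      return(TRUE)
    }
  }
  FALSE
}
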