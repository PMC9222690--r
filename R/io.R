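#' Read a fundus ROI image
#'
#' Reads PNG (via \pkg{png}), TIFF (via \pkg{tiff}) or JPEG (via
#' \pkg{EBImage}, if installed) into an RGB array.  Grayscale inputs are
#' rejected; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return A `height x width x 3` array in `[0, 1]`.
#' @export
read_fundus_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG requires the 'EBImage' package")
      }
      aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("`", path, "` is not an RGB image (expected 3 channels)")
  }
  img[, , 1:3, drop = FALSE]
}

#' Read / write binary masks
#'
#' Masks are stored as single-channel PNG with values 0/255.  On reading, a
#' soft grayscale map (e.g. a multi-rater consensus) is binarized at
#' `threshold`.
#'
#' @param path PNG file path.
#' @param threshold Binarization threshold in `[0, 1]` (default 0.5; use the
#'   configured `truth_threshold` for soft ground truth).
#' @param mask A binary (0/1) matrix.
#' @return `read_mask()` returns an integer 0/1 matrix; `write_mask()`
#'   returns `path` invisibly.
#' @export
read_mask <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m >= threshold) * 1L
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0.5), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write a contour as JSON
#'
#' The contour is stored as a list of `(x, y)` vertices in angular order
#' starting at sector 1, in 0-based image coordinates.
#'
#' @param boundary An `n x 2` matrix of x/y vertices.
#' @param path JSON file path.
#' @return `read_contour_json()` returns the `n x 2` matrix;
#'   `write_contour_json()` returns `path` invisibly.
#' @export
write_contour_json <- function(boundary, path) {
  boundary <- as.matrix(boundary)
  jsonlite::write_json(
    list(vertices = lapply(seq_len(nrow(boundary)), function(i) {
      list(x = boundary[i, 1], y = boundary[i, 2])
    })),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_contour_json
#' @export
read_contour_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)$vertices
  cbind(x = v$x, y = v$y)
}
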