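#' Segment the optic disc in a fundus ROI
#'
#' The full pipeline: standardize the ROI, build the annular exploration area
#' over the red-channel radial gradient, run the subgroup swarm, finish the
#' winning boundary and rasterize its mask.  When ground truth is supplied
#' the result also carries a one-row metrics tibble.
#'
#' @param image An RGB array or an image file path.
#' @param config A [sepso_config()].
#' @param center `"auto"` or a `(x, y)` centre in 0-based pixels of the
#'   standardized image.
#' @param truth Optional ground-truth mask (matrix or file path; soft maps
#'   are binarized at `config$truth_threshold`).  Must match the
#'   standardized size.
#' @return A `sepso_result` (see [run_sepso()]) with the standardized
#'   `image` attached, and `metrics` when `truth` was given.
#' @examples
#' \donttest{
#' sf <- generate_fundus(fundus_spec(a = 60, b = 60, seed = 7))
#' cfg <- sepso_config(n_subgroups = 10, n_particles = 10,
#'                     iterations = 30, seed = 7)
#' res <- sepso_segment(sf$image, cfg, truth = sf$mask)
#' res$metrics$dice
#' }
#' @export
sepso_segment <- function(image, config = sepso_config(), center = "auto",
                          truth = NULL) {
  if (is.character(image)) image <- read_fundus_image(image)
  std <- standardize_roi(image, config$size)
  area <- build_exploration_area(
    std,
    center = center,
    r_min = config$r_min, r_max = config$r_max,
    delta_r = config$delta_r, delta_theta = config$delta_theta,
    n_sectors = config$n_subgroups, sigma = config$sigma
  )
  res <- run_sepso(area, config)
  res$image <- std
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read_mask(truth, config$truth_threshold)
    if (!identical(dim(truth), dim(res$mask))) {
      stop("`truth` must match the standardized image size ",
           paste(dim(res$mask), collapse = " x "))
    }
    res$metrics <- evaluate_masks(res$mask, truth,
      truth_threshold = config$truth_threshold
    )
  }
  res
}

#' @export
print.sepso_result <- function(x, ...) {
  cat(sprintf(
    "<sepso_result> edge fitness %.4f over %d subgroups (%d iterations)\n",
    x$edge_fitness, nrow(x$edge), nrow(x$trace)
  ))
  cat(sprintf("  mask area: %d px\n", sum(x$mask)))
  if (!is.null(x$metrics)) {
    cat(sprintf(
      "  vs truth: accuracy %.3f, Dice %.3f, overlap error %.3f\n",
      x$metrics$accuracy, x$metrics$dice, x$metrics$overlap_error
    ))
  }
  invisible(x)
}

#' Tidy the winning boundary members
#'
#' @param x A `sepso_result`.
#' @param ... Unused.
#' @return The edge tibble: one row per subgroup with polar (`r`, `theta`)
#'   and image (`x`, `y`) coordinates and per-member `fitness`.
#' @export
tidy.sepso_result <- function(x, ...) {
  x$edge
}

#' One-row summary of a segmentation
#'
#' @param x A `sepso_result`.
#' @param ... Unused.
#' @return A one-row tibble: swarm dimensions, final edge fitness, mask area,
#'   and (when truth was supplied) accuracy / Dice / overlap error.
#' @export
glance.sepso_result <- function(x, ...) {
  out <- tibble::tibble(
    n_subgroups = x$config$n_subgroups,
    n_particles = x$config$n_particles,
    iterations = x$config$iterations,
    edge_fitness = x$edge_fitness,
    mask_area = sum(x$mask),
    mean_radius = mean(x$edge$r)
  )
  if (!is.null(x$metrics)) {
    out$accuracy <- x$metrics$accuracy
    out$dice <- x$metrics$dice
    out$overlap_error <- x$metrics$overlap_error
  }
  out
}

#' Plot a segmentation result
#'
#' Shows the (red channel of the) standardized image with the winning edge
#' members and the fitted boundary overlaid.
#'
#' @param object A `sepso_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sepso_result <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$image)) {
    red <- red_channel(object$image)
    df <- tibble::tibble(
      x = rep(0:(ncol(red) - 1), each = nrow(red)),
      y = rep(0:(nrow(red) - 1), times = ncol(red)),
      value = as.vector(red)
    )
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)
    ) +
      ggplot2::scale_fill_gradient(low = "black", high = "tomato", guide = "none")
  }
  bd <- tibble::as_tibble(as.data.frame(object$boundary))
  p +
    ggplot2::geom_path(
      data = rbind(bd, bd[1, ]),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "cyan", linewidth = 0.8
    ) +
    ggplot2::geom_point(
      data = object$edge, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "yellow", size = 0.8
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", title = "Optic disc segmentation")
}

#' Plot the best-edge fitness trace
#'
#' @param result A `sepso_result`.
#' @return A ggplot of best edge fitness per iteration (non-decreasing).
#' @export
plot_trace <- function(result) {
  ggplot2::ggplot(
    result$trace,
    ggplot2::aes(x = .data$iteration, y = .data$best_edge_fitness)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "iteration", y = "best edge fitness",
      title = "Swarm convergence"
    )
}
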