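#' Parameter sweep over a synthetic suite
#'
#' Runs the full segmentation pipeline for every setting in a parameter grid
#' over every image of a suite, and reports mean overlap error, accuracy and
#' Dice per setting — the structure of a parameter-influence study (vary the
#' number of subgroups, the acceleration combination, or the inertia
#' schedule).
#'
#' Per-run seeds are derived deterministically from `config$seed` (or 0) and
#' the image id, so a sweep is reproducible and every setting sees the same
#' randomness.
#'
#' @param suite A manifest tibble from [generate_fundus_suite()] (in-memory
#'   list-columns or `image_path`/`mask_path` columns).
#' @param grid A data frame; each row is one setting, columns are
#'   [sepso_config()] field names (e.g. `n_subgroups`, `c_adjacent`,
#'   `omega_strategy`).
#' @param config Base configuration that the grid rows override.
#' @return A tibble: the grid columns plus `mean_overlap_error`,
#'   `mean_accuracy`, `mean_dice`, `n_images`.
#' @export
sepso_sweep <- function(suite, grid, config = sepso_config()) {
  stopifnot(nrow(grid) >= 1, nrow(suite) >= 1)
  base_seed <- config$seed %||% 0L
  purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    overrides <- as.list(grid[gi, , drop = FALSE])
    cfg <- update_config(config, overrides)
    per_image <- purrr::map_dfr(seq_len(nrow(suite)), function(k) {
      row <- suite[k, ]
      if ("image" %in% names(suite)) {
        img <- row$image[[1]]
        truth <- row$mask[[1]]
      } else {
        img <- read_fundus_image(row$image_path)
        truth <- read_mask(row$mask_path)
      }
      cfg_k <- update_config(cfg, seed = (base_seed + row$id) %% .Machine$integer.max)
      res <- sepso_segment(img, cfg_k, truth = truth)
      res$metrics
    })
    out <- tibble::as_tibble(overrides)
    out$mean_overlap_error <- mean(per_image$overlap_error)
    out$mean_accuracy <- mean(per_image$accuracy)
    out$mean_dice <- mean(per_image$dice)
    out$n_images <- nrow(per_image)
    out
  })
}
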