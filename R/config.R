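#' Swarm and pipeline configuration
#'
#' Collects every tunable of the pipeline.  Defaults are the best-performing
#' settings of the method: `N = 50` subgroups, `np = 30` particles per
#' subgroup, 100 iterations, `cp = cg = 1.7`, `ca = 0.3`, constant inertia
#' `omega = 0.8` (a chaotic-random schedule is also available).
#'
#' @param n_subgroups Number of subgroups / boundary points `N` (>= 3).
#' @param n_particles Particles per subgroup `np` (>= 2).
#' @param iterations Number of swarm iterations.
#' @param omega_strategy One of `"constant"`, `"linear"`, `"random"`,
#'   `"chaotic"` — see [inertia_weight()].
#' @param omega Constant inertia weight `c` (used by `"constant"`).
#' @param omega_max,omega_min Endpoints of the linearly descending schedule.
#' @param c_personal,c_global Cognitive and social acceleration `cp`, `cg`.
#' @param c_adjacent Adjacent-subgroup attraction `ca`.
#' @param velocity_clamp Per-step velocity limit as a fraction of the annulus
#'   extent: `|v_r| <= velocity_clamp * (r_max - r_min)` and `|v_theta| <=
#'   velocity_clamp * (2 * pi / N)`.
#' @param radius_only If `TRUE` particles move only radially; angles stay at
#'   the sector midpoints.
#' @param fit_method Contour finishing, `"spline"` (periodic cubic) or
#'   `"ellipse"` (direct least-squares).
#' @param size Standardized image side length in pixels.
#' @param r_min,r_max Annulus radii in pixels; `NULL` defaults to 30% / 70% of
#'   half the image width.
#' @param delta_r,delta_theta Polar grid steps (pixels / radians).
#' @param sigma Gaussian pre-smoothing of the red channel in pixels.
#' @param truth_threshold Binarization threshold for soft (multi-rater)
#'   ground-truth maps.
#' @param seed Integer seed driving all randomness of a run, or `NULL`.
#' @return An object of class `sepso_config` (a named list).
#' @examples
#' cfg <- sepso_config(n_subgroups = 10, iterations = 20, seed = 1)
#' cfg$n_subgroups
#' @export
sepso_config <- function(n_subgroups = 50,
                         n_particles = 30,
                         iterations = 100,
                         omega_strategy = c("constant", "linear", "random", "chaotic"),
                         omega = 0.8,
                         omega_max = 0.9,
                         omega_min = 0.4,
                         c_personal = 1.7,
                         c_global = 1.7,
                         c_adjacent = 0.3,
                         velocity_clamp = 0.2,
                         radius_only = FALSE,
                         fit_method = c("spline", "ellipse"),
                         size = 256,
                         r_min = NULL,
                         r_max = NULL,
                         delta_r = 1,
                         delta_theta = 2 * pi / 360,
                         sigma = 2,
                         truth_threshold = 0.75,
                         seed = NULL) {
  cfg <- list(
    n_subgroups = as.integer(n_subgroups),
    n_particles = as.integer(n_particles),
    iterations = as.integer(iterations),
    omega_strategy = match.arg(omega_strategy),
    omega = as.numeric(omega),
    omega_max = as.numeric(omega_max),
    omega_min = as.numeric(omega_min),
    c_personal = as.numeric(c_personal),
    c_global = as.numeric(c_global),
    c_adjacent = as.numeric(c_adjacent),
    velocity_clamp = as.numeric(velocity_clamp),
    radius_only = isTRUE(radius_only),
    fit_method = match.arg(fit_method),
    size = as.integer(size),
    r_min = if (is.null(r_min)) NULL else as.numeric(r_min),
    r_max = if (is.null(r_max)) NULL else as.numeric(r_max),
    delta_r = as.numeric(delta_r),
    delta_theta = as.numeric(delta_theta),
    sigma = as.numeric(sigma),
    truth_threshold = as.numeric(truth_threshold),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sepso_config(structure(cfg, class = "sepso_config"))
}

validate_sepso_config <- function(cfg) {
  if (cfg$n_subgroups < 3L) stop("`n_subgroups` must be >= 3")
  if (cfg$n_particles < 2L) stop("`n_particles` must be >= 2")
  if (cfg$iterations < 1L) stop("`iterations` must be >= 1")
  if (cfg$c_personal < 0 || cfg$c_global < 0 || cfg$c_adjacent < 0) {
    stop("acceleration coefficients `c_personal`, `c_global`, `c_adjacent` must be >= 0")
  }
  if (cfg$velocity_clamp <= 0) stop("`velocity_clamp` must be > 0")
  if (!is.null(cfg$r_min) && !is.null(cfg$r_max) && cfg$r_min >= cfg$r_max) {
    stop("need r_min < r_max")
  }
  if (cfg$truth_threshold < 0 || cfg$truth_threshold > 1) {
    stop("`truth_threshold` must be in [0, 1]")
  }
  cfg
}

#' @export
print.sepso_config <- function(x, ...) {
  cat(sprintf(
    "<sepso_config> N = %d, np = %d, %d iterations, omega = %s, cp = %g, cg = %g, ca = %g\n",
    x$n_subgroups, x$n_particles, x$iterations, x$omega_strategy,
    x$c_personal, x$c_global, x$c_adjacent
  ))
  invisible(x)
}

# merge named overrides into a config, re-validating
update_config <- function(cfg, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots))) {
    dots <- dots[[1]]
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$n_subgroups <- as.integer(cfg$n_subgroups)
  cfg$n_particles <- as.integer(cfg$n_particles)
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$size <- as.integer(cfg$size)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  validate_sepso_config(cfg)
}

#' Read / write a run configuration
#'
#' Configurations serialize losslessly to JSON or YAML (chosen by file
#' extension).  Unknown keys in a file are rejected rather than ignored, so a
#' typo in a config cannot silently fall back to a default.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param config A [sepso_config()].
#' @return `read_sepso_config()` returns a `sepso_config`;
#'   `write_sepso_config()` returns `path` invisibly.
#' @export
read_sepso_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config files must be .json, .yaml or .yml")
  )
  known <- names(formals(sepso_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sepso_config, raw)
}

#' @rdname read_sepso_config
#' @export
write_sepso_config <- function(config, path) {
  stopifnot(inherits(config, "sepso_config"))
  ext <- tolower(tools::file_ext(path))
  x <- config[!vapply(config, is.null, logical(1))]
  attributes(x) <- list(names = names(x))
  # %.17g keeps doubles bit-exact through the round trip
  verbatim17 <- function(v) {
    s <- sprintf("%.17g", v)
    class(s) <- "verbatim"
    s
  }
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17)),
    yaml = ,
    yml = yaml::write_yaml(x, path, handlers = list(numeric = verbatim17)),
    stop("config files must be .json, .yaml or .yml")
  )
  invisible(path)
}
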