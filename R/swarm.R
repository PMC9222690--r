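#' Inertia-weight schedules
#'
#' Four schedules for the velocity-persistence coefficient `omega`:
#'
#' * `"constant"`: `omega = c` (default 0.8).
#' * `"linear"`: linearly descending, `omega = omega_max - (omega_max -
#'   omega_min) * k / iter_max`.
#' * `"random"`: `omega = (1 + rand) / 2` with `rand ~ U(0, 1)`, so
#'   `omega` lies in `[0.5, 1]`.
#' * `"chaotic"`: chaotic-random; a logistic-map state `z` (seeded uniformly
#'   once per run) is advanced `z <- 4 z (1 - z)` on every call and
#'   `omega = 0.5 * z + 0.5 * rand`.
#'
#' The chaotic state is threaded explicitly: pass the returned `z` back in on
#' the next call.
#'
#' @param strategy One of `"constant"`, `"linear"`, `"random"`, `"chaotic"`.
#' @param k Iteration index, `0 <= k <= iter_max`.
#' @param iter_max Total number of iterations.
#' @param omega Constant value `c` for `"constant"`.
#' @param omega_max,omega_min Endpoints for `"linear"`.
#' @param z Logistic-map state for `"chaotic"`; `NULL` seeds it from `U(0,1)`.
#' @return A list with elements `omega` and `z` (the updated chaotic state,
#'   `NULL` for other strategies).
#' @examples
#' inertia_weight("linear", k = 0, iter_max = 100)$omega # omega_max
#' @export
inertia_weight <- function(strategy, k, iter_max,
                           omega = 0.8, omega_max = 0.9, omega_min = 0.4,
                           z = NULL) {
  if (k < 0 || k > iter_max) stop("need 0 <= k <= iter_max")
  switch(strategy,
    constant = list(omega = omega, z = NULL),
    linear = list(
      omega = omega_max - (omega_max - omega_min) * k / iter_max,
      z = NULL
    ),
    random = list(omega = (1 + stats::runif(1)) / 2, z = NULL),
    chaotic = {
      if (is.null(z)) z <- stats::runif(1)
      z <- 4 * z * (1 - z)
      list(omega = 0.5 * z + 0.5 * stats::runif(1), z = z)
    },
    stop(sprintf(
      "unknown inertia strategy '%s'; valid: constant, linear, random, chaotic",
      strategy
    ))
  )
}

#' Logistic-map trajectory
#'
#' Iterates `z <- 4 z (1 - z)`, the chaotic driver of the `"chaotic"` inertia
#' schedule.  For `z0` in `(0, 1)` away from the fixed points the trajectory
#' stays in `(0, 1)`.
#'
#' @param z0 Initial state in `(0, 1)`.
#' @param n Number of steps.
#' @return Numeric vector of the `n` successive states.
#' @export
logistic_map <- function(z0, n) {
  z <- numeric(n)
  cur <- z0
  for (i in seq_len(n)) {
    cur <- 4 * cur * (1 - cur)
    z[i] <- cur
  }
  z
}

#' Initialize the swarm
#'
#' Each of the `np` candidate boundaries (labels `j`) starts as a circle: one
#' radius `r_j ~ U(r_min, r_max)` is drawn per label and shared by all `N`
#' particles carrying that label, reflecting the near-circular prior on the
#' disc shape.  Angles start at the sector midpoints, velocities at zero;
#' personal bests are the initial positions and each subgroup best is its best
#' personal best.
#'
#' Draws from the current RNG stream; seed beforehand (or via
#' `config$seed` through [run_sepso()]) for reproducibility.
#'
#' @param area An [build_exploration_area()] result.
#' @param config A [sepso_config()].
#' @return An object of class `sepso_swarm`: matrices `r`, `theta`, `vr`,
#'   `vtheta`, `pp_r`, `pp_theta`, `pp_val` of dimension `N x np`, and
#'   vectors `gp_r`, `gp_theta`, `gp_val` of length `N`.
#' @export
initialize_swarm <- function(area, config) {
  n <- config$n_subgroups
  np <- config$n_particles
  if (n != area$n_sectors) {
    stop("`config$n_subgroups` must match the exploration area's sector count")
  }
  g <- area$grid
  r0 <- stats::runif(np, g$r_min, g$r_max)
  r <- matrix(r0, n, np, byrow = TRUE)
  mid <- (area$sector_bounds$theta_lo + area$sector_bounds$theta_hi) / 2
  theta <- matrix(mid, n, np)
  val <- matrix(area_fitness(area, as.vector(r), as.vector(theta)), n, np)
  best <- max.col(val, ties.method = "first")
  idx <- cbind(seq_len(n), best)
  structure(
    list(
      r = r, theta = theta,
      vr = matrix(0, n, np), vtheta = matrix(0, n, np),
      pp_r = r, pp_theta = theta, pp_val = val,
      gp_r = r[idx], gp_theta = theta[idx], gp_val = val[idx]
    ),
    class = "sepso_swarm"
  )
}

#' Velocity update with adjacent-subgroup attraction
#'
#' The modified velocity rule: the standard cognitive (`cp`, toward the
#' personal best) and social (`cg`, toward the subgroup best) terms are
#' augmented with two attraction terms (`ca`) toward the same-label particles
#' in the two adjacent subgroups, which regularizes the candidate boundary
#' against strong distractor gradients such as vessels:
#'
#' `V' = omega V + cp r1 (PP - X) + cg r2 (GP - X) + ca r3 (X_next - X) +
#'  ca r4 (X_prev - X)`
#'
#' Each `r*` is an independent `U(0, 1)` draw per term and per coordinate
#' component (radial first, then angular).  The two `ca` draws are made only
#' when `c_adjacent > 0`, so with `ca = 0` the rule consumes exactly the RNG
#' stream of the standard two-term update and reduces to it bit-for-bit.
#' Angular differences are wrapped signed differences.
#'
#' @param velocity,position,personal_best,subgroup_best,neighbor_next,neighbor_prev
#'   `n x 2` matrices (or length-2 vectors), column 1 radial, column 2
#'   angular.  `neighbor_next`/`neighbor_prev` are the same-label particles in
#'   subgroups `i + 1` / `i - 1` (indices wrap modulo `N`).
#' @param omega Inertia weight for this step.
#' @param c_personal,c_global,c_adjacent Acceleration coefficients.
#' @param v_max Optional length-2 clamp: the result is clamped component-wise
#'   to `[-v_max, v_max]`.  `NULL` leaves it unclamped.
#' @param rand Uniform generator `function(n)`; replaceable for testing.
#' @return The new velocity, `n x 2`.
#' @export
velocity_update <- function(velocity, position, personal_best, subgroup_best,
                            neighbor_next, neighbor_prev, omega,
                            c_personal = 1.7, c_global = 1.7, c_adjacent = 0.3,
                            v_max = NULL, rand = stats::runif) {
  v <- as_position(velocity, "velocity")
  x <- as_position(position, "position")
  pp <- as_position(personal_best, "personal_best")
  gp <- as_position(subgroup_best, "subgroup_best")
  nx <- as_position(neighbor_next, "neighbor_next")
  pv <- as_position(neighbor_prev, "neighbor_prev")
  n <- nrow(x)
  pdiff <- function(target) {
    cbind(target[, 1] - x[, 1], wrap_angle(target[, 2] - x[, 2]))
  }
  draw <- function() matrix(rand(2L * n), n, 2L)
  out <- omega * v +
    c_personal * draw() * pdiff(pp) +
    c_global * draw() * pdiff(gp)
  if (c_adjacent > 0) {
    out <- out +
      c_adjacent * draw() * pdiff(nx) +
      c_adjacent * draw() * pdiff(pv)
  }
  if (!is.null(v_max)) {
    out[, 1] <- clamp(out[, 1], -v_max[1], v_max[1])
    out[, 2] <- clamp(out[, 2], -v_max[2], v_max[2])
  }
  out
}

#' Position update with sector confinement
#'
#' `X' = X + V'`, then the particle is confined to its sub-search-space: the
#' radius is clamped to `[r_min, r_max]` and the angle to its sector interval
#' (the half-open upper bound is excluded by pinning one grid step inside,
#' at `theta_hi - delta_theta`).  A clamped component has its velocity zeroed.
#'
#' @param position,velocity `n x 2` matrices (or length-2 vectors).
#' @param area The `exploration_area`.
#' @param sector Integer vector of each particle's subgroup index.
#' @return A list with the new `position` and (possibly zeroed) `velocity`.
#' @export
position_update <- function(position, velocity, area, sector) {
  x <- as_position(position, "position") + as_position(velocity, "velocity")
  v <- as_position(velocity, "velocity")
  g <- area$grid
  lo <- area$sector_bounds$theta_lo[sector]
  hi <- area$sector_bounds$theta_hi[sector] - g$delta_theta
  hit_r <- x[, 1] < g$r_min | x[, 1] > g$r_max
  hit_t <- x[, 2] < lo | x[, 2] > hi
  x[, 1] <- clamp(x[, 1], g$r_min, g$r_max)
  x[, 2] <- clamp(x[, 2], lo, hi)
  v[hit_r, 1] <- 0
  v[hit_t, 2] <- 0
  list(position = x, velocity = v)
}

#' Personal-best update
#'
#' The personal best moves to the current position when the current fitness is
#' greater than **or equal to** the stored best (ties go to the newer
#' position); otherwise it is kept.  Personal-best fitness is therefore
#' non-decreasing over iterations.
#'
#' @param personal_best `n x 2` matrix of stored best positions.
#' @param personal_value Numeric vector of their fitness values.
#' @param position `n x 2` matrix of current positions.
#' @param value Numeric vector of current fitness values.
#' @return A list with the updated `position` matrix and `value` vector.
#' @export
update_personal_best <- function(personal_best, personal_value, position, value) {
  pp <- as_position(personal_best, "personal_best")
  x <- as_position(position, "position")
  repl <- value >= personal_value
  pp[repl, ] <- x[repl, , drop = FALSE]
  list(position = pp, value = ifelse(repl, value, personal_value))
}

#' Subgroup-best update
#'
#' The subgroup best is replaced by the best personal best in the subgroup
#' when that best is `>=` the stored value; ties between particles are broken
#' by the lowest label, so the update is deterministic.
#'
#' @param subgroup_best Length-2 vector, the stored best position.
#' @param subgroup_value Its fitness value.
#' @param personal_best `np x 2` matrix of the subgroup's personal bests.
#' @param personal_value Their fitness values.
#' @return A list with the updated `position` (length-2) and `value`.
#' @export
update_subgroup_best <- function(subgroup_best, subgroup_value,
                                 personal_best, personal_value) {
  pp <- as_position(personal_best, "personal_best")
  j <- which.max(personal_value)
  if (personal_value[j] >= subgroup_value) {
    list(position = pp[j, ], value = personal_value[j])
  } else {
    list(position = as.numeric(subgroup_best), value = subgroup_value)
  }
}

#' Fitness of a candidate boundary
#'
#' A candidate boundary (`Edge_j`) takes one member per subgroup; its fitness
#' is the plain sum of the members' per-point fitness values.
#'
#' @param edge An `N x 2` matrix of polar positions (or a tibble with `r` and
#'   `theta` columns), one row per subgroup in order.
#' @param area The `exploration_area`.
#' @return The summed fitness (a scalar).
#' @export
edge_fitness <- function(edge, area) {
  e <- as_position(edge, "edge")
  sum(area_fitness(area, e[, 1], e[, 2]))
}

#' Run the subgroup-partitioned particle swarm
#'
#' The main loop: per iteration an inertia weight is drawn from the schedule,
#' every particle's velocity and position are updated (with sector
#' confinement), then personal and subgroup bests.  After the final iteration
#' the candidate boundary with the highest summed personal-best fitness is
#' selected (ties to the lowest label), finished with [fit_boundary()] and
#' rasterized to a binary mask.
#'
#' @param area An [build_exploration_area()] result.
#' @param config A [sepso_config()]; `config$seed`, when set, seeds all
#'   randomness of the run.
#' @return An object of class `sepso_result`: `edge` (tibble of the winning
#'   boundary members: `subgroup`, `r`, `theta`, `x`, `y`, `fitness`),
#'   `edge_fitness`, `boundary` (dense closed polyline, `n x 2` x/y), `mask`
#'   (binary matrix), `trace` (tibble `iteration`, `best_edge_fitness`), and
#'   the resolved `config`.
#' @export
run_sepso <- function(area, config = sepso_config()) {
  stopifnot(inherits(area, "exploration_area"), inherits(config, "sepso_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subgroups
  np <- config$n_particles
  g <- area$grid
  swarm <- initialize_swarm(area, config)
  sector <- rep(seq_len(n), np)
  v_max <- c(
    config$velocity_clamp * (g$r_max - g$r_min),
    config$velocity_clamp * 2 * pi / n
  )
  shift_up <- c(2:n, 1L) # subgroup i+1, wrapping
  shift_dn <- c(n, 1:(n - 1L)) # subgroup i-1, wrapping
  z <- NULL
  trace <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    iw <- inertia_weight(
      config$omega_strategy, t, config$iterations,
      omega = config$omega, omega_max = config$omega_max,
      omega_min = config$omega_min, z = z
    )
    z <- iw$z
    x <- cbind(as.vector(swarm$r), as.vector(swarm$theta))
    v <- cbind(as.vector(swarm$vr), as.vector(swarm$vtheta))
    pp <- cbind(as.vector(swarm$pp_r), as.vector(swarm$pp_theta))
    gp <- cbind(rep(swarm$gp_r, np), rep(swarm$gp_theta, np))
    nx <- cbind(
      as.vector(swarm$r[shift_up, , drop = FALSE]),
      as.vector(swarm$theta[shift_up, , drop = FALSE])
    )
    pv <- cbind(
      as.vector(swarm$r[shift_dn, , drop = FALSE]),
      as.vector(swarm$theta[shift_dn, , drop = FALSE])
    )
    v <- velocity_update(
      v, x, pp, gp, nx, pv, iw$omega,
      c_personal = config$c_personal, c_global = config$c_global,
      c_adjacent = config$c_adjacent, v_max = v_max
    )
    if (config$radius_only) v[, 2] <- 0
    upd <- position_update(x, v, area, sector)
    x <- upd$position
    v <- upd$velocity
    swarm$r <- matrix(x[, 1], n, np)
    swarm$theta <- matrix(x[, 2], n, np)
    swarm$vr <- matrix(v[, 1], n, np)
    swarm$vtheta <- matrix(v[, 2], n, np)
    val <- area_fitness(area, x[, 1], x[, 2])
    pb <- update_personal_best(pp, as.vector(swarm$pp_val), x, val)
    swarm$pp_r <- matrix(pb$position[, 1], n, np)
    swarm$pp_theta <- matrix(pb$position[, 2], n, np)
    swarm$pp_val <- matrix(pb$value, n, np)
    improved <- max.col(swarm$pp_val, ties.method = "first")
    idx <- cbind(seq_len(n), improved)
    better <- swarm$pp_val[idx] >= swarm$gp_val
    swarm$gp_r[better] <- swarm$pp_r[idx][better]
    swarm$gp_theta[better] <- swarm$pp_theta[idx][better]
    swarm$gp_val[better] <- swarm$pp_val[idx][better]
    trace[t] <- max(colSums(swarm$pp_val))
  }
  edge_sums <- colSums(swarm$pp_val)
  j_star <- which.max(edge_sums)
  edge <- tibble::tibble(
    subgroup = seq_len(n),
    r = swarm$pp_r[, j_star],
    theta = swarm$pp_theta[, j_star],
    x = area$center[1] + swarm$pp_r[, j_star] * cos(swarm$pp_theta[, j_star]),
    y = area$center[2] + swarm$pp_r[, j_star] * sin(swarm$pp_theta[, j_star]),
    fitness = swarm$pp_val[, j_star]
  )
  # A strong distractor (e.g. a vessel) can leave one member far off the
  # ridge, and an interpolating spline through such an outlier may loop.
  # Fall back to the raw member polygon, then to an ellipse fit, rather
  # than fail the whole run; the strictness lives in rasterize_mask().
  finish <- function(pts, method) {
    boundary <- fit_boundary(pts, method = method)
    list(boundary = boundary, mask = rasterize_mask(boundary, area$image_dim))
  }
  pts <- cbind(edge$x, edge$y)
  fin <- tryCatch(finish(pts, config$fit_method), error = function(e) NULL)
  if (is.null(fin)) {
    fin <- tryCatch(
      list(boundary = pts, mask = rasterize_mask(pts, area$image_dim)),
      error = function(e) NULL
    )
  }
  if (is.null(fin)) fin <- finish(pts, "ellipse")
  boundary <- fin$boundary
  mask <- fin$mask
  structure(
    list(
      edge = edge,
      edge_fitness = edge_sums[j_star],
      boundary = boundary,
      mask = mask,
      trace = tibble::tibble(
        iteration = seq_len(config$iterations),
        best_edge_fitness = trace
      ),
      config = config,
      area_center = area$center,
      swarm = swarm
    ),
    class = "sepso_result"
  )
}
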