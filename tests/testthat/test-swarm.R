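test_that("initialization gives every candidate boundary one shared radius", {
  area <- clean_area(10)
  cfg <- sepso_config(n_subgroups = 10, n_particles = 8, iterations = 5)
  set.seed(1)
  sw <- initialize_swarm(area, cfg)
  # all members of label j start at the same radius
  expect_equal(apply(sw$r, 2, function(x) max(x) - min(x)), rep(0, 8))
  expect_true(all(sw$r >= area$grid$r_min & sw$r <= area$grid$r_max))
  expect_true(all(sw$vr == 0) && all(sw$vtheta == 0))
  # angles start at sector midpoints
  mid <- (area$sector_bounds$theta_lo + area$sector_bounds$theta_hi) / 2
  expect_equal(sw$theta, matrix(mid, 10, 8))
  # personal bests are the initial positions; subgroup best dominates them
  expect_equal(sw$pp_r, sw$r)
  expect_true(all(sw$gp_val >= apply(sw$pp_val, 1, max) - 1e-12))
  # same seed, bit-identical swarm
  set.seed(1)
  expect_identical(initialize_swarm(area, cfg), sw)
})

test_that("inertia schedules follow their formulas", {
  expect_equal(inertia_weight("constant", 10, 100, omega = 0.8)$omega, 0.8)
  expect_equal(inertia_weight("linear", 0, 100, omega_max = 0.9, omega_min = 0.4)$omega, 0.9)
  expect_equal(inertia_weight("linear", 100, 100, omega_max = 0.9, omega_min = 0.4)$omega, 0.4)
  expect_equal(inertia_weight("linear", 50, 100, omega_max = 0.9, omega_min = 0.4)$omega, 0.65)
  set.seed(2)
  rw <- replicate(500, inertia_weight("random", 1, 10)$omega)
  expect_true(all(rw >= 0.5 & rw <= 1))
  set.seed(3)
  z <- NULL
  for (i in 1:50) {
    iw <- inertia_weight("chaotic", i, 50, z = z)
    z <- iw$z
    expect_true(z > 0 && z < 1)
    expect_true(iw$omega > 0 && iw$omega < 1)
  }
  expect_error(inertia_weight("cosine", 1, 10), "constant, linear, random, chaotic")
  expect_error(inertia_weight("linear", 11, 10), "k <= iter_max")
})

test_that("the chaotic logistic map stays inside (0, 1)", {
  z <- logistic_map(0.3141, 1e5)
  expect_true(all(z > 0 & z < 1))
})

test_that("velocity update reproduces hand-computed and degenerate cases", {
  ones <- function(n) rep(1, n)
  # identity: omega = 1, all accelerations zero
  v <- velocity_update(c(2, 0.1), c(50, 1), c(55, 1), c(60, 1), c(52, 1), c(54, 1),
    omega = 1, c_personal = 0, c_global = 0, c_adjacent = 0, rand = ones
  )
  expect_equal(v, matrix(c(2, 0.1), 1, 2))
  # converged fixed point: all positions coincide, zero velocity
  v <- velocity_update(c(0, 0), c(50, 1), c(50, 1), c(50, 1), c(50, 1), c(50, 1),
    omega = 0.8, rand = ones
  )
  expect_equal(v, matrix(0, 1, 2))
  # hand evaluation of the five-term rule on the radial component
  v <- velocity_update(c(0, 0), c(50, 0), c(55, 0), c(60, 0), c(52, 0), c(54, 0),
    omega = 0.8, c_personal = 1.7, c_global = 1.7, c_adjacent = 0.3, rand = ones
  )
  expect_equal(v[1, 1], 1.7 * 5 + 1.7 * 10 + 0.3 * 2 + 0.3 * 4) # 27.3
  # component-wise clamping
  v <- velocity_update(c(0, 0), c(50, 0), c(55, 0), c(60, 0), c(52, 0), c(54, 0),
    omega = 0.8, rand = ones, v_max = c(5, 0.1)
  )
  expect_equal(v[1, 1], 5)
})

test_that("with ca = 0 the update reduces bit-for-bit to standard PSO", {
  # independent two-term implementation sharing one RNG stream
  pso_reference <- function(v, x, pp, gp, omega, cp, cg) {
    n <- nrow(x)
    r1 <- matrix(stats::runif(2 * n), n, 2)
    r2 <- matrix(stats::runif(2 * n), n, 2)
    wrap <- function(d) ((d + pi) %% (2 * pi)) - pi
    dp <- cbind(pp[, 1] - x[, 1], wrap(pp[, 2] - x[, 2]))
    dg <- cbind(gp[, 1] - x[, 1], wrap(gp[, 2] - x[, 2]))
    omega * v + cp * r1 * dp + cg * r2 * dg
  }
  set.seed(99)
  n <- 1000
  v <- cbind(rnorm(n), rnorm(n, sd = 0.1))
  x <- cbind(runif(n, 40, 90), runif(n, 0, 2 * pi))
  pp <- cbind(runif(n, 40, 90), runif(n, 0, 2 * pi))
  gp <- cbind(runif(n, 40, 90), runif(n, 0, 2 * pi))
  nb1 <- cbind(runif(n, 40, 90), runif(n, 0, 2 * pi))
  nb2 <- cbind(runif(n, 40, 90), runif(n, 0, 2 * pi))
  set.seed(1234)
  got <- velocity_update(v, x, pp, gp, nb1, nb2,
    omega = 0.8, c_personal = 1.7, c_global = 1.7, c_adjacent = 0
  )
  set.seed(1234)
  want <- pso_reference(v, x, pp, gp, 0.8, 1.7, 1.7)
  expect_identical(got, want)
})

test_that("position update clamps to the annulus and sector, zeroing velocity", {
  area <- clean_area(4)
  g <- area$grid
  # zero velocity leaves the position unchanged
  p0 <- c(60, 0.5)
  out <- position_update(p0, c(0, 0), area, 1L)
  expect_equal(out$position, matrix(p0, 1, 2))
  # radial overshoot pins at r_max and zeroes v_r
  out <- position_update(c(g$r_max - 1, 0.5), c(5, 0), area, 1L)
  expect_equal(out$position[1, 1], g$r_max)
  expect_equal(out$velocity[1, 1], 0)
  # angular overshoot pins one grid step inside the half-open sector bound
  hi <- area$sector_bounds$theta_hi[1]
  out <- position_update(c(60, hi - 0.01), c(0, 0.5), area, 1L)
  expect_equal(out$position[1, 2], hi - g$delta_theta)
  expect_equal(out$velocity[1, 2], 0)
  out <- position_update(c(60, 0.05), c(0, -0.5), area, 1L)
  expect_equal(out$position[1, 2], area$sector_bounds$theta_lo[1])
})

test_that("personal bests move on ties and never regress", {
  pb <- update_personal_best(c(50, 1), 0.4, c(52, 1.1), 0.4)
  expect_equal(pb$position, matrix(c(52, 1.1), 1, 2)) # tie goes to the new position
  pb <- update_personal_best(c(50, 1), 0.4, c(52, 1.1), 0.39)
  expect_equal(pb$position, matrix(c(50, 1), 1, 2))
  expect_equal(pb$value, 0.4)
})

test_that("subgroup best takes the dominating personal best, ties to lowest label", {
  pp <- rbind(c(50, 1), c(55, 1.2), c(60, 1.4))
  up <- update_subgroup_best(c(52, 1.1), 0.9, pp, c(0.1, 0.2, 0.3))
  expect_equal(up$value, 0.9) # all personal bests worse: unchanged
  expect_equal(up$position, c(52, 1.1))
  up <- update_subgroup_best(c(52, 1.1), 0.25, pp, c(0.1, 0.95, 0.95))
  expect_equal(up$position, c(55, 1.2)) # tie between labels 2 and 3 -> label 2
  expect_equal(up$value, 0.95)
  # value is always the max of old and new bests
  for (s in 1:20) {
    set.seed(s)
    vals <- runif(5)
    old <- runif(1)
    up <- update_subgroup_best(c(0, 0), old, matrix(runif(10), 5, 2), vals)
    expect_equal(up$value, max(old, vals))
  }
})

test_that("edge fitness is the sum of member lookups", {
  area <- clean_area(4)
  g <- area$grid
  edge <- cbind(runif(4, g$r_min, g$r_max), c(0.5, 2.0, 3.5, 5.0))
  expect_equal(
    edge_fitness(edge, area),
    sum(vapply(1:4, function(i) area_fitness(area, edge[i, 1], edge[i, 2]), numeric(1)))
  )
  # members outside the annulus contribute exactly zero
  outside <- cbind(rep(g$r_max + 5, 4), c(0.5, 2.0, 3.5, 5.0))
  expect_equal(edge_fitness(outside, area), 0)
  mixed <- rbind(edge[1:2, ], outside[3:4, ])
  expect_equal(edge_fitness(mixed, area), edge_fitness(edge[1:2, ], area))
  # linear in members: summing three known lookups
  vals <- area_fitness(area, edge[, 1], edge[, 2])
  expect_equal(edge_fitness(edge, area), sum(vals))
})

test_that("the swarm recovers a clean circular boundary", {
  sf <- clean_disc()
  area <- clean_area(10)
  cfg <- sepso_config(n_subgroups = 10, n_particles = 10, iterations = 60, seed = 5)
  res <- run_sepso(area, cfg)
  expect_true(all(abs(res$edge$r - sf$spec$a) <= 2 * area$grid$delta_r))
  # summed fitness reaches the brute-force per-sector maximum within 1%
  expect_gte(res$edge_fitness, 0.99 * sum(sector_maxima(area)))
  expect_false(is.unsorted(res$trace$best_edge_fitness))
})

test_that("a zero fitness field degenerates gracefully", {
  area <- clean_area(4)
  area$fitness[] <- 0
  cfg <- sepso_config(n_subgroups = 4, n_particles = 5, iterations = 10, seed = 1)
  res <- run_sepso(area, cfg)
  expect_equal(res$trace$best_edge_fitness, rep(0, 10))
  expect_equal(res$edge_fitness, 0)
})

test_that("runs are deterministic under a fixed seed", {
  area <- clean_area(4)
  cfg <- sepso_config(n_subgroups = 4, n_particles = 6, iterations = 15, seed = 77)
  r1 <- run_sepso(area, cfg)
  r2 <- run_sepso(area, cfg)
  expect_identical(r1$edge, r2$edge)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  # different seeds explore differently but keep invariants
  r3 <- run_sepso(area, update_config(cfg, seed = 78))
  expect_false(identical(r1$edge, r3$edge))
  expect_true(all(r3$edge$r >= area$grid$r_min & r3$edge$r <= area$grid$r_max))
})

test_that("particles stay confined to their sectors throughout a run", {
  area <- clean_area(6)
  cfg <- sepso_config(n_subgroups = 6, n_particles = 8, iterations = 40, seed = 9)
  res <- run_sepso(area, cfg)
  sw <- res$swarm
  lo <- area$sector_bounds$theta_lo
  hi <- area$sector_bounds$theta_hi
  for (i in 1:6) {
    expect_true(all(sw$theta[i, ] >= lo[i] & sw$theta[i, ] < hi[i]))
    expect_true(all(sw$pp_theta[i, ] >= lo[i] & sw$pp_theta[i, ] < hi[i]))
  }
  expect_true(all(sw$r >= area$grid$r_min & sw$r <= area$grid$r_max))
})

test_that("radius-only mode keeps angles at the sector midpoints", {
  area <- clean_area(6)
  cfg <- sepso_config(
    n_subgroups = 6, n_particles = 6, iterations = 20,
    seed = 3, radius_only = TRUE
  )
  res <- run_sepso(area, cfg)
  mid <- (area$sector_bounds$theta_lo + area$sector_bounds$theta_hi) / 2
  expect_equal(res$edge$theta, mid)
})
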