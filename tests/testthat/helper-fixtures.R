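# fixtures are generated in code; the heavier ones are cached for the session
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a clean centred circular disc: no vessels, no noise, no illumination
clean_disc <- function() {
  cached("clean_disc", generate_fundus(fundus_spec(
    a = 60, b = 60, seed = 101,
    vessel_count = 0, noise_sd = 0, illumination = 0
  )))
}

# exploration area over the clean disc with a given sector count
clean_area <- function(n_sectors = 4) {
  cached(paste0("clean_area_", n_sectors), {
    sf <- clean_disc()
    build_exploration_area(sf$image, center = sf$spec$center, n_sectors = n_sectors)
  })
}

# brute-force per-sector grid maxima of an exploration area
sector_maxima <- function(area) {
  m <- area$grid$n_angular / area$n_sectors
  vapply(seq_len(area$n_sectors), function(i) {
    max(area$fitness[, ((i - 1) * m + 1):(i * m)])
  }, numeric(1))
}

# random blob mask for property tests: a disc at a random position
random_mask <- function(size = 64, r_range = c(6, 18)) {
  r_range[2] <- min(r_range[2], size / 2 - 4)
  r <- stats::runif(1, r_range[1], r_range[2])
  cx <- stats::runif(1, r + 1, size - r - 2)
  cy <- stats::runif(1, r + 1, size - r - 2)
  xs <- matrix(0:(size - 1), size, size, byrow = TRUE)
  ys <- matrix(0:(size - 1), size, size)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1L
}
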