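# fixtures and independent oracles shared across test files

default_geom <- maze_geometry()

# straight constructed path: holding -> decision zone -> a destination arm,
# sampled densely enough that every zone is visited
make_straight_track <- function(geom = default_geom, arm = "ARM_LEFT",
                                n = 200, overshoot = 15) {
  start <- geom$holding_axis * (geom$zone_radius + geom$holding_length / 2)
  end <- arm_entrance_point(arm, geom) * (1 + overshoot / geom$zone_radius)
  s <- seq(0, 1, length.out = n)
  data.frame(
    t = s * 10,
    x = start[1] + s * (end[1] - start[1]),
    y = start[2] + s * (end[2] - start[2])
  )
}

# brute-force oracle for the first decision->arm transition
scan_first_crossing <- function(track, geom) {
  z <- classify_zone(track$x, track$y, geom)
  for (i in seq_len(nrow(track) - 1)) {
    if (z[i] == "DECISION" && z[i + 1] %in% c("ARM_LEFT", "ARM_RIGHT")) {
      return(list(arm = z[i + 1], frame = i + 1L))
    }
  }
  NULL
}

# brute-force 3-point running median with endpoint pass-through
median3_oracle <- function(v) {
  out <- v
  for (i in 2:(length(v) - 1)) out[i] <- median(v[(i - 1):(i + 1)])
  out
}

# full-enumeration two-sided binomial p-value (small-likelihood rule)
binom_p_oracle <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Rayleigh test p-value (first-order approximation) for circular uniformity
rayleigh_p <- function(angles) {
  n <- length(angles)
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# random zig-zag trajectory through the maze for property tests
make_random_path <- function(geom = default_geom, n = 120) {
  data.frame(
    t = seq_len(n) / 10,
    x = cumsum(rnorm(n, 0, 6)),
    y = cumsum(rnorm(n, 1, 6)) - geom$zone_radius - 5
  )
}
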