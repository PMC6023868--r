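#' Stimulus simulator configuration
#'
#' Parameters of the virtual-shoal projection: how many silhouettes are
#' rendered, what fraction are directional "leaders" (coherency C), how much
#' faster leaders move than the baseline (relative speed, delta-v), and the
#' rendering geometry. Defaults are the solitary-assay settings: 60
#' silhouettes refreshed at 60 frames per second, baseline speed 3.5 cm/s
#' (1 body length per second for a 3.5 cm fish), and wrapped-Cauchy
#' distractor turning with 30 degrees circular standard deviation.
#'
#' The leader count is `round(coherency * n_silhouettes)`, so the design
#' labels C = 0.66 and C = 0.67 both give 40 leaders of 60 and are treated
#' as the same cell.
#'
#' @param n_silhouettes Number of silhouettes projected (60 in the solitary
#'   assay; the group assay reduces the count, 20 by convention here, since
#'   the count was shown to have no discernible effect).
#' @param coherency Fraction of silhouettes that are leaders, in `[0, 1]`.
#' @param delta_v Leader speed as a multiple of baseline speed (1 or 10 in
#'   the assay).
#' @param baseline_speed Baseline silhouette speed, cm/s.
#' @param body_length Silhouette body length, cm.
#' @param fps Projection refresh rate, frames/s.
#' @param turn_sd_deg Circular standard deviation of the distractor turning
#'   distribution, degrees.
#' @param target_arm Arm the leaders aim at, `"ARM_LEFT"` or `"ARM_RIGHT"`.
#' @param null_fast At coherency 0 there are no leaders; if `TRUE`, all
#'   silhouettes move at `delta_v * baseline_speed` so that the null cell of
#'   a fast treatment contains fast (but directionless) motion.
#' @param leader_boundary_extension Convenience override of the geometry's
#'   leader boundary extension, cm; `NULL` to use the geometry's value.
#' @param fade_time_s Time for a baseline-speed silhouette outside the zone
#'   to fade to invisibility, s. Fade rate is proportional to speed, so a
#'   10x-speed leader fades ten times faster.
#' @param seed Optional RNG seed for reproducible streams.
#' @return An object of class `stimulus_config`.
#' @examples
#' cfg <- stimulus_config(coherency = 0.33, delta_v = 10)
#' n_leaders(cfg) # 20 of 60
#' @export
stimulus_config <- function(n_silhouettes = 60,
                            coherency = 1,
                            delta_v = 1,
                            baseline_speed = 3.5,
                            body_length = 3.5,
                            fps = 60,
                            turn_sd_deg = 30,
                            target_arm = "ARM_LEFT",
                            null_fast = FALSE,
                            leader_boundary_extension = NULL,
                            fade_time_s = 1,
                            seed = NULL) {
  stopifnot(
    n_silhouettes >= 0, coherency >= 0, coherency <= 1, delta_v >= 1,
    baseline_speed > 0, body_length > 0, fps > 0, turn_sd_deg > 0,
    fade_time_s > 0, target_arm %in% c("ARM_LEFT", "ARM_RIGHT")
  )
  structure(
    list(
      n_silhouettes = as.integer(n_silhouettes),
      coherency = coherency,
      delta_v = delta_v,
      baseline_speed = baseline_speed,
      body_length = body_length,
      fps = fps,
      turn_sd_deg = turn_sd_deg,
      target_arm = target_arm,
      null_fast = null_fast,
      leader_boundary_extension = leader_boundary_extension,
      fade_time_s = fade_time_s,
      seed = seed
    ),
    class = "stimulus_config"
  )
}

#' Leader and distractor counts under the coherency rule
#'
#' @param cfg A [stimulus_config()].
#' @return `n_leaders()`: integer count `round(C * n)`; `n_distractors()`:
#'   the remainder.
#' @export
n_leaders <- function(cfg) {
  as.integer(round(cfg$coherency * cfg$n_silhouettes))
}

#' @rdname n_leaders
#' @export
n_distractors <- function(cfg) {
  cfg$n_silhouettes - n_leaders(cfg)
}

#' Wrapped-Cauchy turn angles
#'
#' Draws turn angles from a wrapped Cauchy distribution centred on zero with
#' mean resultant length `rho`, by the inverse-CDF transform
#' `2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 1/2)))`. The wrapped
#' Cauchy has no linear moments; a stated circular standard deviation
#' `sigma` maps to concentration via `rho = exp(-sigma^2 / 2)` (the circular
#' SD / mean-resultant-length relation), so 30 degrees gives
#' `rho = exp(-(pi/6)^2/2)`, about 0.8719.
#'
#' @param n Number of draws.
#' @param rho Concentration (mean resultant length), in `[0, 1]`. `rho = 0`
#'   is the circular uniform; `rho = 1` is a point mass at zero.
#' @return Angles in `(-pi, pi]`, radians.
#' @export
rwrapped_cauchy <- function(n, rho) {
  stopifnot(rho >= 0, rho <= 1)
  if (rho >= 1) return(rep(0, n))
  u <- stats::runif(n)
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
}

#' @rdname rwrapped_cauchy
#' @param sigma_deg Circular standard deviation, degrees.
#' @export
wrapped_cauchy_rho <- function(sigma_deg) {
  exp(-(sigma_deg * pi / 180)^2 / 2)
}

.sil_speed <- function(role, cfg) {
  fast <- cfg$delta_v * cfg$baseline_speed
  if (cfg$coherency == 0 && cfg$null_fast) {
    rep(fast, length(role))
  } else {
    ifelse(role == "LEADER", fast, cfg$baseline_speed)
  }
}

.uniform_in_zone <- function(n, geom) {
  r <- geom$zone_radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

.aim_at <- function(x, y, target) {
  atan2(target[2] - y, target[1] - x)
}

# vector-state core shared by the exported tibble operations and the frame
# loop; state is a list of parallel vectors (role, x, y, heading, speed,
# opacity)

.state_step <- function(st, cfg, geom, dt, rho, target) {
  d <- st$role == "DISTRACTOR"
  if (any(d)) st$heading[d] <- st$heading[d] + rwrapped_cauchy(sum(d), rho)
  l <- !d
  if (any(l)) st$heading[l] <- .aim_at(st$x[l], st$y[l], target)
  st$x <- st$x + st$speed * dt * cos(st$heading)
  st$y <- st$y + st$speed * dt * sin(st$heading)
  st
}

.state_boundary <- function(st, cfg, geom, target) {
  ext <- cfg$leader_boundary_extension
  if (is.null(ext)) ext <- geom$leader_boundary_extension
  r2 <- geom$zone_radius^2
  inside <- st$x^2 + st$y^2 <= r2
  if (ext > 0) {
    shift <- geom$holding_axis * ext
    inside_ext <- (st$x - shift[1])^2 + (st$y - shift[2])^2 <= r2
    inside <- inside | (st$role == "LEADER" & inside_ext)
  }
  fade_step <- (st$speed / cfg$baseline_speed) / (cfg$fade_time_s * cfg$fps)
  st$opacity <- ifelse(inside, st$opacity, st$opacity - fade_step)
  gone <- st$opacity <= 1e-9 # tolerance absorbs accumulated rounding
  if (any(gone)) {
    pos <- .uniform_in_zone(sum(gone), geom)
    st$x[gone] <- pos[, 1]
    st$y[gone] <- pos[, 2]
    st$opacity[gone] <- 1
    relead <- gone & st$role == "LEADER"
    if (any(relead)) {
      st$heading[relead] <- .aim_at(st$x[relead], st$y[relead], target)
    }
  }
  st
}

.as_state <- function(sils) {
  list(role = sils$role, x = sils$x, y = sils$y,
       heading = sils$heading, speed = sils$speed, opacity = sils$opacity)
}

.from_state <- function(sils, st) {
  sils$x <- st$x
  sils$y <- st$y
  sils$heading <- st$heading
  sils$opacity <- st$opacity
  sils
}

#' Initialise the silhouette field
#'
#' Places `n_silhouettes` silhouettes uniformly at random inside the
#' decision zone; `round(C * n)` of them are leaders headed at the target
#' arm entrance, the rest distractors with uniform random headings. All
#' start at full opacity.
#'
#' @param cfg A [stimulus_config()].
#' @param geom A [maze_geometry()].
#' @return A tibble with one row per silhouette: `id`, `role`, `x`, `y`,
#'   `heading` (radians), `speed` (cm/s), `opacity`.
#' @export
init_silhouettes <- function(cfg, geom) {
  n <- cfg$n_silhouettes
  nl <- n_leaders(cfg)
  role <- rep(c("LEADER", "DISTRACTOR"), c(nl, n - nl))
  pos <- .uniform_in_zone(n, geom)
  target <- arm_entrance_point(cfg$target_arm, geom)
  heading <- stats::runif(n, -pi, pi)
  if (nl > 0) {
    heading[role == "LEADER"] <-
      .aim_at(pos[role == "LEADER", 1], pos[role == "LEADER", 2], target)
  }
  tibble::tibble(
    id = seq_len(n),
    role = role,
    x = pos[, 1],
    y = pos[, 2],
    heading = heading,
    speed = .sil_speed(role, cfg),
    opacity = 1
  )
}

#' Advance distractors by one time step
#'
#' Correlated random walk: each heading is perturbed by a wrapped-Cauchy
#' turn angle centred on the current heading, then the silhouette moves
#' `speed * dt` along the new heading.
#'
#' @param sils Silhouette rows (see [init_silhouettes()]); all must be
#'   distractors.
#' @param cfg A [stimulus_config()].
#' @param dt Time step, s (one frame by default).
#' @return The stepped silhouette rows.
#' @export
step_distractor <- function(sils, cfg, dt = 1 / cfg$fps) {
  stopifnot(all(sils$role == "DISTRACTOR"))
  rho <- wrapped_cauchy_rho(cfg$turn_sd_deg)
  sils$heading <- sils$heading + rwrapped_cauchy(nrow(sils), rho)
  sils$x <- sils$x + sils$speed * dt * cos(sils$heading)
  sils$y <- sils$y + sils$speed * dt * sin(sils$heading)
  sils
}

#' Advance leaders by one time step
#'
#' Ballistic motion: each leader re-aims at the target-arm entrance and
#' moves `delta_v * baseline_speed * dt` towards it.
#'
#' @inheritParams step_distractor
#' @param geom A [maze_geometry()].
#' @return The stepped silhouette rows.
#' @export
step_leader <- function(sils, cfg, geom, dt = 1 / cfg$fps) {
  stopifnot(all(sils$role == "LEADER"))
  target <- arm_entrance_point(cfg$target_arm, geom)
  sils$heading <- .aim_at(sils$x, sils$y, target)
  sils$x <- sils$x + sils$speed * dt * cos(sils$heading)
  sils$y <- sils$y + sils$speed * dt * sin(sils$heading)
  sils
}

#' Apply the periodic fade-and-respawn boundary
#'
#' Silhouettes outside the decision zone fade at a rate proportional to
#' their speed (a baseline-speed silhouette fades in `fade_time_s` seconds);
#' once fully faded they reappear uniformly at random inside the zone at
#' full opacity, with the same role. Respawned distractors keep their last
#' heading; respawned leaders re-aim at the trial's target arm. Both the
#' silhouette count and the leader/distractor ratio are therefore constant.
#' In group mode the leaders' effective zone is extended back towards the
#' holding area by the geometry's `leader_boundary_extension`.
#'
#' @param sils Silhouette tibble (any number of rows).
#' @param cfg A [stimulus_config()].
#' @param geom A [maze_geometry()].
#' @return The updated silhouette tibble.
#' @export
apply_boundary <- function(sils, cfg, geom) {
  target <- arm_entrance_point(cfg$target_arm, geom)
  .from_state(sils, .state_boundary(.as_state(sils), cfg, geom, target))
}

#' Simulate the silhouette projection
#'
#' Runs the full stimulus loop: initialisation, per-frame leader/distractor
#' stepping, and the fade-and-respawn boundary. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [stimulus_config()].
#' @param geom A [maze_geometry()].
#' @param duration Simulated duration, s; the frame count is
#'   `round(duration * fps)`.
#' @param thin Keep every `thin`-th frame in the output (state is still
#'   advanced every frame).
#' @return A tibble of silhouette states with columns `frame`, `id`, `role`,
#'   `x`, `y`, `heading`, `speed`, `opacity`; the configuration is attached
#'   as attribute `"config"`.
#' @export
simulate_stimuli <- function(cfg, geom, duration, thin = 1L) {
  stopifnot(duration > 0, thin >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_frames <- as.integer(round(duration * cfg$fps))
  sils <- init_silhouettes(cfg, geom)
  st <- .as_state(sils)
  dt <- 1 / cfg$fps
  rho <- wrapped_cauchy_rho(cfg$turn_sd_deg)
  target <- arm_entrance_point(cfg$target_arm, geom)
  keep <- seq(1L, n_frames, by = thin)
  n <- cfg$n_silhouettes
  nk <- length(keep)
  xs <- matrix(NA_real_, n, nk)
  ys <- hs <- os <- xs
  k <- 0L
  for (f in seq_len(n_frames)) {
    st <- .state_step(st, cfg, geom, dt, rho, target)
    st <- .state_boundary(st, cfg, geom, target)
    if ((f - 1L) %% thin == 0L) {
      k <- k + 1L
      xs[, k] <- st$x
      ys[, k] <- st$y
      hs[, k] <- st$heading
      os[, k] <- st$opacity
    }
  }
  out <- tibble::tibble(
    frame = rep(keep, each = n),
    id = rep(sils$id, nk),
    role = rep(sils$role, nk),
    x = as.vector(xs),
    y = as.vector(ys),
    heading = as.vector(hs),
    speed = rep(sils$speed, nk),
    opacity = as.vector(os)
  )
  attr(out, "config") <- cfg
  out
}
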