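#' Running-median smoothing of a trajectory
#'
#' Replaces each coordinate by the median of itself and its two neighbours
#' (a 3-step running median), removing single-frame tracking spikes.
#' Endpoints are passed through unchanged, which preserves track length.
#'
#' @param track A data frame with columns `t`, `x`, `y` (and any others,
#'   which are kept).
#' @return The track with smoothed `x`, `y`.
#' @export
smooth_positions <- function(track) {
  stopifnot(all(c("t", "x", "y") %in% names(track)))
  if (nrow(track) < 3) {
    stop("running-median smoothing needs at least 3 frames", call. = FALSE)
  }
  track$x <- as.numeric(stats::runmed(track$x, 3, endrule = "keep"))
  track$y <- as.numeric(stats::runmed(track$y, 3, endrule = "keep"))
  track
}

#' Kinematic series of a trajectory
#'
#' Differentiates a (smoothed) track into the assay's kinematic variables.
#' Velocity vectors are first differences of position scaled by the
#' sampling rate and normalised to body lengths per second (FL/s);
#' acceleration is the first difference of speed (FL/s^2); turning arc is
#' the absolute angle between successive velocity vectors (0 to pi) passed
#' through a sine transform so it ranges 0-1. Turns beyond 90 degrees make
#' the sine non-monotone; they are rare in this assay (<2% of steps) and
#' are counted in `n_sharp_turns` as a diagnostic. Steps with zero
#' displacement have undefined turning and are recorded as `NA`.
#'
#' @param track A data frame with columns `t`, `x`, `y`; positions in the
#'   same length unit as `body_length`.
#' @param body_length Fish body (fork) length in position units.
#' @param sampling_rate Frames per second; inferred from the median time
#'   step when `NULL`.
#' @return A list of class `kinematic_series`: `speed` (length n-1),
#'   `acceleration` (n-2), `turning_arc` (n-2), `cumulative_distance`
#'   (n-1, FL), and `n_sharp_turns`.
#' @examples
#' tr <- data.frame(t = 0:5 / 10, x = seq(0, 1.75, length.out = 6), y = 0)
#' ks <- compute_kinematics(tr, body_length = 3.5)
#' ks$speed # constant 1 FL/s
#' @export
compute_kinematics <- function(track, body_length, sampling_rate = NULL) {
  stopifnot(body_length > 0, nrow(track) >= 3)
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(track$t))
  }
  dx <- diff(track$x)
  dy <- diff(track$y)
  step <- sqrt(dx^2 + dy^2)
  speed <- step * sampling_rate / body_length
  acceleration <- diff(speed) * sampling_rate
  # angle between successive velocity vectors via the atan2 of cross/dot
  v1x <- dx[-length(dx)]; v1y <- dy[-length(dy)]
  v2x <- dx[-1]; v2y <- dy[-1]
  theta <- abs(atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y))
  theta[step[-length(step)] == 0 | step[-1] == 0] <- NA_real_
  structure(
    list(
      speed = speed,
      acceleration = acceleration,
      turning_arc = sin(theta),
      theta = theta,
      cumulative_distance = cumsum(step) / body_length,
      n_sharp_turns = sum(theta > pi / 2, na.rm = TRUE)
    ),
    class = "kinematic_series"
  )
}

#' Extract the per-trial decision record from a track
#'
#' Scores a single choice per trial by the first-crossing rule: the decision
#' time `t_d` runs from the first decision-zone entry to the first crossing
#' from the zone into an arm; the time-to-act `t_a` runs from the moment the
#' holding gate opened to that crossing. Accuracy compares the chosen arm
#' with the trial's target arm. A fish that never crosses into an arm is a
#' non-decider: its record keeps the id but no choice fields.
#'
#' @param track A data frame with columns `t`, `x`, `y` (one fish), sorted
#'   by time.
#' @param geom A [maze_geometry()].
#' @param gate_time Time at which the holding gate opened, s.
#' @param target_arm The trial's designated correct arm.
#' @param fish_id Identifier copied into the record.
#' @return A one-row tibble: `fish_id`, `chosen_arm`, `correct`, `t_a`,
#'   `t_d`, `t_decision`.
#' @export
extract_decision <- function(track, geom, gate_time = 0,
                             target_arm = "ARM_LEFT", fish_id = NA) {
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  if (gate_time > max(track$t)) {
    stop("gate_time is after the end of the track", call. = FALSE)
  }
  none <- tibble::tibble(
    fish_id = fish_id, chosen_arm = NA_character_, correct = NA,
    t_a = NA_real_, t_d = NA_real_, t_decision = NA_real_
  )
  cross <- arm_entrance_crossing(track, geom)
  if (is.null(cross)) return(none)
  zones <- classify_zone(track$x, track$y, geom)
  entry <- which(zones == "DECISION")[1]
  t_cross <- track$t[cross$frame]
  tibble::tibble(
    fish_id = fish_id,
    chosen_arm = cross$arm,
    correct = cross$arm == target_arm,
    t_a = t_cross - gate_time,
    t_d = t_cross - track$t[entry],
    t_decision = t_cross
  )
}

#' Decision records for every fish in a trial's track table
#'
#' Applies [extract_decision()] per fish and ranks the deciders by crossing
#' time (ties broken by fish id) to give the decision order.
#'
#' @param tracks A data frame with columns `fish_id`, `t`, `x`, `y`.
#' @param geom A [maze_geometry()].
#' @inheritParams extract_decision
#' @return A tibble with one row per fish, including `decision_order`.
#' @export
extract_trial_decisions <- function(tracks, geom, gate_time = 0,
                                    target_arm = "ARM_LEFT") {
  recs <- tracks |>
    dplyr::group_by(.data$fish_id) |>
    dplyr::group_map(function(tr, key) {
      extract_decision(tr, geom, gate_time, target_arm,
                       fish_id = key$fish_id[1])
    }) |>
    dplyr::bind_rows()
  recs$decision_order <- rank_decision_times(recs$t_decision, recs$fish_id)
  recs
}
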