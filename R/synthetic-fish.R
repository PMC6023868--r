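#' Behavioural parameters of the generative fish model
#'
#' The assay reports phenomena (follow rates, a speed-accuracy trade-off,
#' power-law latency scaling, logistic social feedback); this record holds
#' the minimal generative structure that reproduces them, with
#' assay-anchored defaults.
#'
#' Departure from the holding area is a social-hazard process: fish `i`
#' leaves with hazard `latency_rate * (1 + social_hazard_boost * d)` where
#' `d` is the number of shoalmates that have already departed. Arm choice
#' mixes a private visual-cue weight (set by the relative speed of the
#' leader silhouettes) with a logistic social-feedback term in the signed
#' leading-companion tally Nc. Decision-zone transit time is drawn
#' conditional on correctness, embedding the speed-accuracy trade-off.
#'
#' @param p_follow_fast Probability a solitary fish follows the target arm
#'   when the leaders move 10x baseline (0.85, the observed solitary follow
#'   rate under the fast cue).
#' @param p_follow_slow Same under equal leader/distractor speed (0.44).
#' @param p_program_match_null Chance level at coherency 0, where "correct"
#'   requires the program and the fish to independently pick the same arm
#'   (0.25 by construction).
#' @param social_a,social_b Logistic social-feedback slope and offset:
#'   `P(social) = 1 / (1 + exp(-a (Nc - b)))`; defaults are the fitted
#'   weak-cue values a = 0.52, b = 0.07.
#' @param latency_rate Per-fish baseline hazard of leaving the holding area,
#'   1/s. The default 1/120 puts the median solitary time-to-act near 85 s.
#' @param social_hazard_boost Multiplicative hazard increase per
#'   already-departed shoalmate. The default 25, with `latency_rate`, makes
#'   median time-to-act decay as a power law of group size with exponent
#'   near -0.9 over shoals of 1-15.
#' @param subject_rate_multiplier Multiplier on the subject's own baseline
#'   hazard (1 = exchangeable with companions; >1 pushes subjects towards
#'   the front of the decision order).
#' @param td_correct_mean,td_correct_sd Mean and SD, s, of decision-zone
#'   transit time for correct deciders (2.6 +/- 2).
#' @param td_incorrect_mean,td_incorrect_sd Same for incorrect deciders
#'   (1.3 +/- 0.8).
#' @param swim_speed_mean Nominal swim speed in body lengths per second used
#'   for the within-zone meander micro-structure.
#' @param turn_sd_deg Turning variability of the meander, degrees.
#' @param trial_duration Trial length, s; fish that have not left the
#'   holding area by then are scored as non-deciders (right-censored).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_follow_fast = 0.85,
                            p_follow_slow = 0.44,
                            p_program_match_null = 0.25,
                            social_a = 0.52,
                            social_b = 0.07,
                            latency_rate = 1 / 120,
                            social_hazard_boost = 25,
                            subject_rate_multiplier = 1,
                            td_correct_mean = 2.6,
                            td_correct_sd = 2,
                            td_incorrect_mean = 1.3,
                            td_incorrect_sd = 0.8,
                            swim_speed_mean = 1,
                            turn_sd_deg = 30,
                            trial_duration = 300) {
  p <- list(
    p_follow_fast = p_follow_fast,
    p_follow_slow = p_follow_slow,
    p_program_match_null = p_program_match_null,
    social_a = social_a,
    social_b = social_b,
    latency_rate = latency_rate,
    social_hazard_boost = social_hazard_boost,
    subject_rate_multiplier = subject_rate_multiplier,
    td_correct_mean = td_correct_mean,
    td_correct_sd = td_correct_sd,
    td_incorrect_mean = td_incorrect_mean,
    td_incorrect_sd = td_incorrect_sd,
    swim_speed_mean = swim_speed_mean,
    turn_sd_deg = turn_sd_deg,
    trial_duration = trial_duration
  )
  probs <- unlist(p[c("p_follow_fast", "p_follow_slow", "p_program_match_null")])
  stopifnot(
    all(probs >= 0 & probs <= 1),
    latency_rate > 0, social_hazard_boost >= 0, subject_rate_multiplier > 0,
    td_correct_mean > 0, td_correct_sd > 0,
    td_incorrect_mean > 0, td_incorrect_sd > 0,
    swim_speed_mean > 0, turn_sd_deg > 0, trial_duration > 0
  )
  structure(p, class = "behavior_params")
}

#' Sample holding-area departure times for a shoal
#'
#' Sequential social-hazard process: while `d` fish have departed, each
#' remaining fish `i` departs with hazard
#' `rate_i * (1 + social_hazard_boost * d)`, where `rate_i` is
#' `latency_rate` (times `subject_rate_multiplier` for the subject, fish 1).
#' Inter-departure gaps are exponential with the summed hazard of the fish
#' still holding, and the departing fish is chosen proportionally to its
#' hazard. With `social_hazard_boost = 0` the times are i.i.d.
#' exponentials; with a large boost the subject's departure is dominated by
#' the first-departure time, which scales as 1/N.
#'
#' @param n_fish Shoal size (subject plus companions), >= 1.
#' @param params A [behavior_params()].
#' @return Numeric vector of departure times, s; element 1 is the subject.
#' @export
sample_action_times <- function(n_fish, params) {
  stopifnot(n_fish >= 1)
  rates <- rep(params$latency_rate, n_fish)
  rates[1] <- rates[1] * params$subject_rate_multiplier
  times <- numeric(n_fish)
  alive <- rep(TRUE, n_fish)
  t <- 0
  d <- 0L
  while (any(alive)) {
    h <- rates * (1 + params$social_hazard_boost * d)
    h[!alive] <- 0
    t <- t + stats::rexp(1, sum(h))
    who <- if (sum(alive) == 1L) which(alive) else
      sample.int(n_fish, 1L, prob = h)
    times[who] <- t
    alive[who] <- FALSE
    d <- d + 1L
  }
  times
}

#' Probability of a correct directional decision
#'
#' The choice model mixes a private cue weight with social feedback:
#' `P(correct) = clip(w + (1 - w) / (1 + exp(-a (Nc - b))), 0, 1)`, where
#' the cue weight `w = max(0, 2 p_follow - 1)` is set from the solitary
#' follow rate of the relevant relative-speed treatment (so that a solitary
#' fish, for whom the social term sits near 1/2, is correct with probability
#' about `p_follow`). At coherency 0 there is no directional cue (`w = 0`)
#' and "correct" means the program's random arm designation and the fish's
#' independent choice coincide on the designated arm, which halves the
#' probability: chance level 1/4.
#'
#' @param coherency Stimulus coherency of the trial.
#' @param delta_v Relative speed of the leader silhouettes (1 or 10).
#' @param n_c Signed leading-companion tally at the decision moment
#'   (companions that chose correctly minus those that did not).
#' @param params A [behavior_params()].
#' @return Probability of a correct decision.
#' @examples
#' p <- behavior_params()
#' choice_probability(0.67, 10, n_c = 0, p) # solitary, fast cue: ~0.85
#' @export
choice_probability <- function(coherency, delta_v, n_c, params) {
  p_follow <- if (delta_v >= 10) params$p_follow_fast else params$p_follow_slow
  w <- if (coherency == 0) 0 else max(0, 2 * p_follow - 1)
  social <- 1 / (1 + exp(-params$social_a * (n_c - params$social_b)))
  p <- pmin(pmax(w + (1 - w) * social, 0), 1)
  if (coherency == 0) p <- p / 2
  p
}

#' Sample an arm choice
#'
#' Draws a correct/incorrect outcome from [choice_probability()] and maps it
#' to an arm label relative to the trial's target arm.
#'
#' @inheritParams choice_probability
#' @param target_arm The trial's designated correct arm.
#' @return A list with `arm` and logical `correct`.
#' @export
sample_choice <- function(coherency, delta_v, n_c, params,
                          target_arm = "ARM_LEFT") {
  other <- setdiff(c("ARM_LEFT", "ARM_RIGHT"), target_arm)
  correct <- stats::runif(1) < choice_probability(coherency, delta_v, n_c, params)
  list(arm = if (correct) target_arm else other, correct = correct)
}

# gamma draw matched to a mean/sd pair
.rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

.sample_td <- function(correct, params) {
  ifelse(correct,
         .rgamma_ms(length(correct), params$td_correct_mean, params$td_correct_sd),
         .rgamma_ms(length(correct), params$td_incorrect_mean, params$td_incorrect_sd))
}

# gamma density matched to a mean/sd pair
.dgamma_ms <- function(x, mean, sd) {
  shape <- (mean / sd)^2
  stats::dgamma(x, shape = shape, rate = shape / mean)
}

# Decision core shared by the full and tracks-free trial simulators.
#
# Chronological event simulation. A fish's choice is expressed when it
# crosses into an arm; the social covariate Nc counts the choices of
# companions that crossed before it (the assay's definition). Because the
# transit-time distribution depends on correctness (the speed-accuracy
# trade-off) while correctness depends on Nc at crossing, the draw is split:
# at zone entry the transit time comes from the predictive two-component
# mixture weighted by the choice probability at entry, and at the crossing
# correctness is drawn from its exact conditional given the transit time and
# Nc at crossing (Bayes on the mixture). When Nc is unchanged between entry
# and crossing this reproduces P(correct | Nc) logistic and the stated
# transit-time distributions exactly; otherwise the crossing-time Nc
# dominates. Ties in decision times are broken by fish id.
.simulate_decisions <- function(design, params) {
  n <- design$n_fish
  t_dep <- sample_action_times(n, params)
  ids <- seq_len(n)
  t_decision <- correct <- td <- rep(NA_real_, n)
  n_c_now <- function(t) {
    done <- !is.na(t_decision) & t_decision < t
    sum(correct[done] == 1) - sum(correct[done] == 0)
  }
  entrants <- ids[t_dep <= params$trial_duration]
  entry_queue <- entrants[order(t_dep[entrants], entrants)]
  pending <- integer(0) # entered, crossing not yet resolved
  q_entry <- rep(NA_real_, n)
  resolve_crossing <- function(i) {
    p_c <- choice_probability(design$coherency, design$delta_v,
                              n_c_now(t_decision[i]), params)
    f1 <- .dgamma_ms(td[i], params$td_correct_mean, params$td_correct_sd)
    f0 <- .dgamma_ms(td[i], params$td_incorrect_mean, params$td_incorrect_sd)
    # transit was drawn from the entry-weighted mixture m_q; dividing by it
    # makes the marginal P(correct | Nc at crossing) equal p_c (up to the
    # cap) while keeping transit | correct close to the stated distribution
    m_q <- q_entry[i] * f1 + (1 - q_entry[i]) * f0
    r <- if (m_q > 0) min(1, p_c * f1 / m_q) else p_c
    if (!is.finite(r)) r <- p_c
    correct[i] <<- as.numeric(stats::runif(1) < r)
  }
  while (length(entry_queue) > 0 || length(pending) > 0) {
    next_entry <- if (length(entry_queue)) t_dep[entry_queue[1]] else Inf
    next_cross <- if (length(pending)) min(t_decision[pending]) else Inf
    if (next_cross <= next_entry) {
      i <- pending[which.min(t_decision[pending])]
      resolve_crossing(i)
      pending <- setdiff(pending, i)
    } else {
      i <- entry_queue[1]
      entry_queue <- entry_queue[-1]
      q <- choice_probability(design$coherency, design$delta_v,
                              n_c_now(t_dep[i]), params)
      q_entry[i] <- q
      td[i] <- .sample_td(stats::runif(1) < q, params)
      t_decision[i] <- t_dep[i] + td[i]
      pending <- c(pending, i)
    }
  }
  decided <- !is.na(t_decision)
  other <- setdiff(c("ARM_LEFT", "ARM_RIGHT"), design$target_arm)
  arm <- rep(NA_character_, n)
  arm[decided] <- ifelse(correct[decided] == 1, design$target_arm, other)
  list(
    fish_id = ids,
    role = c("SUBJECT", rep("COMPANION", n - 1)),
    t_depart = ifelse(decided, t_dep, NA_real_),
    t_a = ifelse(decided, t_decision, NA_real_),
    t_d = td,
    chosen_arm = arm,
    correct = ifelse(decided, correct == 1, NA),
    decision_order = rank_decision_times(t_decision, ids)
  )
}

#' Rank decision times within a trial
#'
#' Rank (1 = first) of each fish's decision time among the deciders of its
#' trial; ties are broken by fish id, non-deciders get `NA`.
#'
#' @param t_decision Decision times (NA for non-deciders).
#' @param fish_id Fish identifiers used for tie-breaking.
#' @return Integer ranks.
#' @export
rank_decision_times <- function(t_decision, fish_id = seq_along(t_decision)) {
  out <- rep(NA_integer_, length(t_decision))
  dec <- !is.na(t_decision)
  out[dec] <- order(order(t_decision[dec], fish_id[dec]))
  out
}

# CRW meander bridge across the decision zone: starts at the holding-side
# gate, ends at the target arm entrance, stays inside the zone. The lateral
# meander rides on the straight chord with a sine envelope so the first
# arm-entrance crossing happens exactly at the end.
.zone_bridge <- function(entry, exit, t_d, rate, params) {
  n_steps <- max(2L, ceiling(t_d * rate))
  s <- seq(0, 1, length.out = n_steps + 1L)
  turn_sd <- params$turn_sd_deg * pi / 180
  ang <- cumsum(stats::rnorm(n_steps + 1L, 0, turn_sd))
  meander <- cumsum(sin(ang))
  meander <- meander - s * meander[length(meander)] # bridge to zero
  amp <- stats::runif(1, 2, 5) / max(abs(meander), 1)
  perp <- c(-(exit - entry)[2], (exit - entry)[1])
  perp <- perp / sqrt(sum(perp^2))
  envelope <- sin(pi * s)
  cbind(
    x = entry[1] + s * (exit - entry)[1] + amp * envelope * meander * perp[1],
    y = entry[2] + s * (exit - entry)[2] + amp * envelope * meander * perp[2]
  )
}

# build one fish's track: sit in holding until departure, cross the zone
# along a meander bridge for t_d seconds, then continue a short way into
# the chosen arm.
.fish_track <- function(fish, design, geom, params, rate) {
  gate <- geom$holding_axis * (geom$zone_radius + 3)
  if (is.na(fish$t_a)) {
    t <- seq(0, params$trial_duration, by = 1 / rate)
    return(tibble::tibble(
      fish_id = fish$fish_id, t = t,
      x = gate[1] + stats::rnorm(length(t), 0, 0.3),
      y = gate[2] + stats::rnorm(length(t), 0, 0.3)
    ))
  }
  entry <- geom$holding_axis * (geom$zone_radius - 1e-6)
  exit <- arm_entrance_point(fish$chosen_arm, geom) * 1.02
  hold_t <- seq(0, fish$t_depart, by = 1 / rate)
  hold_t <- hold_t[hold_t < fish$t_depart - 1e-9]
  bridge <- .zone_bridge(entry, exit, fish$t_d, rate, params)
  cross_t <- fish$t_depart + seq(0, fish$t_d, length.out = nrow(bridge))
  arm_axis <- if (fish$chosen_arm == "ARM_LEFT") geom$arm_axis_left else geom$arm_axis_right
  n_arm <- as.integer(rate) # one further second inside the arm
  arm_t <- fish$t_a + seq_len(n_arm) / rate
  arm_xy <- t(vapply(seq_len(n_arm), function(i) {
    exit + arm_axis * 3.5 * params$swim_speed_mean * i / rate
  }, numeric(2)))
  tibble::tibble(
    fish_id = fish$fish_id,
    t = c(hold_t, cross_t, arm_t),
    x = c(gate[1] + stats::rnorm(length(hold_t), 0, 0.3), bridge[, 1], arm_xy[, 1]),
    y = c(gate[2] + stats::rnorm(length(hold_t), 0, 0.3), bridge[, 2], arm_xy[, 2])
  )
}

#' Simulate one Y-maze trial
#'
#' Composes the generative pieces: departure times from the social-hazard
#' process, arm choices from the cue-plus-social-feedback model (each fish's
#' Nc evaluated from the realised decisions of earlier-deciding fish), and
#' decision-zone transit times drawn conditional on correctness. Optionally
#' realises per-fish tracks (holding area, meander bridge across the
#' decision zone, a short run into the chosen arm) at the analysis sampling
#' rate so the kinematics module has realistic input.
#'
#' @param design A list or one-row data frame with fields `coherency`,
#'   `delta_v`, `n_fish`, `target_arm` (and optionally `trial_id`,
#'   `subject_id`, `experiment`).
#' @param params A [behavior_params()].
#' @param geom A [maze_geometry()] (required when `with_tracks = TRUE`).
#' @param with_tracks Generate positional tracks as well as decisions.
#' @param sampling_rate Track sampling rate, Hz.
#' @param seed Optional RNG seed.
#' @return A list of class `maze_trial` with elements `design`, `decisions`
#'   (one row per fish) and `tracks` (a tibble, or `NULL`).
#' @export
simulate_trial <- function(design, params, geom = maze_geometry(),
                           with_tracks = FALSE, sampling_rate = 10,
                           seed = NULL) {
  design <- as.list(design)
  stopifnot(design$n_fish >= 1,
            design$target_arm %in% c("ARM_LEFT", "ARM_RIGHT"))
  if (design$coherency > 0 && is.null(design$target_arm)) {
    stop("directional stimulus (C > 0) requires a target arm", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  decisions <- tibble::as_tibble(.simulate_decisions(design, params))
  tracks <- NULL
  if (with_tracks) {
    tracks <- dplyr::bind_rows(lapply(seq_len(nrow(decisions)), function(i) {
      .fish_track(decisions[i, ], design, geom, params, sampling_rate)
    }))
    if (!is.null(design$trial_id)) tracks$trial_id <- design$trial_id
  }
  structure(list(design = design, decisions = decisions, tracks = tracks),
            class = "maze_trial")
}

#' Generate a full factorial synthetic dataset
#'
#' Experiment 1 is the solitary assay: each subject runs every coherency
#' (0, 0.33, 0.66, 1) by relative-speed (1, 10) cell once, a repeated-
#' measures full factorial (20 subjects gives 160 trials). Experiment 2 is
#' the group assay: coherency fixed at 0.67, subjects crossed with relative
#' speed (1, 10) and shoal size (1, 5, 10, 15) (24 subjects, one pass gives
#' 192 trials). The target arm is randomised per trial.
#'
#' @param experiment 1 (solitary) or 2 (groups).
#' @param params A [behavior_params()].
#' @param seed RNG seed; each trial derives a sub-seed from it by a counter,
#'   so extending a dataset never perturbs existing trials.
#' @param n_subjects Number of subjects (default 20 for experiment 1, 24
#'   for experiment 2).
#' @param n_passes Number of passes through the design (experiment 2).
#' @param with_tracks Also generate positional tracks (slower; decisions
#'   are identical either way).
#' @param geom A [maze_geometry()]; experiment 2 by default extends the
#'   leader boundary by 13.8 cm.
#' @return A list of class `trial_dataset` with `design` (one row per
#'   trial), `decisions` (one row per fish per trial) and `tracks` (tibble
#'   or `NULL`).
#' @export
generate_dataset <- function(experiment, params = behavior_params(),
                             seed = 1L, n_subjects = NULL, n_passes = 1L,
                             with_tracks = FALSE, geom = NULL) {
  stopifnot(experiment %in% c(1L, 2L))
  if (is.null(n_subjects)) n_subjects <- if (experiment == 1L) 20L else 24L
  if (is.null(geom)) {
    geom <- maze_geometry(
      leader_boundary_extension = if (experiment == 2L) 13.8 else 0
    )
  }
  design <- if (experiment == 1L) {
    tidyr::expand_grid(
      subject_id = seq_len(n_subjects),
      coherency = c(0, 0.33, 0.66, 1),
      delta_v = c(1, 10)
    ) |>
      dplyr::mutate(n_fish = 1L, experiment = 1L)
  } else {
    tidyr::expand_grid(
      pass = seq_len(n_passes),
      subject_id = seq_len(n_subjects),
      delta_v = c(1, 10),
      n_fish = c(1L, 5L, 10L, 15L)
    ) |>
      dplyr::mutate(coherency = 0.67, experiment = 2L) |>
      dplyr::select(-"pass")
  }
  set.seed(seed)
  design$target_arm <- sample(c("ARM_LEFT", "ARM_RIGHT"), nrow(design),
                              replace = TRUE)
  design$trial_id <- seq_len(nrow(design))
  if (with_tracks) {
    trials <- lapply(seq_len(nrow(design)), function(i) {
      simulate_trial(design[i, ], params, geom,
                     with_tracks = TRUE, seed = derive_seed(seed, i))
    })
    per_trial <- lapply(trials, function(tr) unclass(tr$decisions))
    tracks <- dplyr::bind_rows(lapply(trials, `[[`, "tracks"))
  } else {
    # fast path: plain-vector core per trial, one tibble at the end
    per_trial <- lapply(seq_len(nrow(design)), function(i) {
      set.seed(derive_seed(seed, i))
      .simulate_decisions(as.list(design[i, ]), params)
    })
    tracks <- NULL
  }
  n_per <- vapply(per_trial, function(d) length(d$fish_id), integer(1))
  decisions <- tibble::as_tibble(c(
    lapply(stats::setNames(nm = names(per_trial[[1]])), function(col) {
      unlist(lapply(per_trial, `[[`, col), use.names = FALSE)
    }),
    list(trial_id = rep(design$trial_id, n_per),
         subject_id = rep(design$subject_id, n_per),
         coherency = rep(design$coherency, n_per),
         delta_v = rep(design$delta_v, n_per),
         n_fish = rep(design$n_fish, n_per),
         target_arm = rep(design$target_arm, n_per))
  ))
  structure(list(design = design, decisions = decisions, tracks = tracks,
                 params = params, geom = geom, seed = seed),
            class = "trial_dataset")
}

#' Derive a per-trial sub-seed from a master seed
#'
#' Counter-based expansion: trial `i` under master seed `s` always receives
#' the same sub-seed, so adding trials never perturbs existing ones. Values
#' stay below 2^31.
#'
#' @param master Master seed (integer).
#' @param counter Trial counter (integer >= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Synthetic Y-maze dataset: experiment %d, %d trials, %d fish rows%s\n",
              x$design$experiment[1], nrow(x$design), nrow(x$decisions),
              if (is.null(x$tracks)) "" else
                sprintf(", %d track frames", nrow(x$tracks))))
  invisible(x)
}
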