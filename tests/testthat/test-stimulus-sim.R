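test_that("coherency rule sets leader counts", {
  expect_equal(n_leaders(stimulus_config(coherency = 1)), 60L)
  expect_equal(n_leaders(stimulus_config(coherency = 0)), 0L)
  expect_equal(n_leaders(stimulus_config(coherency = 0.33)), 20L)
  expect_equal(n_leaders(stimulus_config(coherency = 0.66)), 40L)
  expect_equal(n_leaders(stimulus_config(coherency = 0.67)), 40L)
  expect_equal(n_distractors(stimulus_config(coherency = 0.33)), 40L)
})

test_that("initial silhouettes respect placement, roles and speeds", {
  set.seed(5)
  geom <- default_geom
  cfg <- stimulus_config(coherency = 0.33, delta_v = 10)
  s <- init_silhouettes(cfg, geom)
  expect_equal(nrow(s), 60)
  expect_true(all(sqrt(s$x^2 + s$y^2) <= geom$zone_radius))
  expect_equal(sum(s$role == "LEADER"), 20)
  expect_true(all(s$opacity == 1))
  expect_equal(unique(s$speed[s$role == "LEADER"]), 35)
  expect_equal(unique(s$speed[s$role == "DISTRACTOR"]), 3.5)
  # leaders aim at the target-arm entrance
  target <- arm_entrance_point(cfg$target_arm, geom)
  lead <- s[s$role == "LEADER", ]
  expect_equal(lead$heading, atan2(target[2] - lead$y, target[1] - lead$x))
})

test_that("wrapped-Cauchy turning has the stated concentration", {
  rho <- wrapped_cauchy_rho(30)
  expect_equal(rho, exp(-(pi / 6)^2 / 2))
  set.seed(1)
  d <- rwrapped_cauchy(1e5, rho)
  mrl <- mean(cos(d))
  se <- sd(cos(d)) / sqrt(length(d))
  expect_lt(abs(mrl - rho), 3 * se)
  # degenerate concentration: no turning at all
  expect_true(all(rwrapped_cauchy(100, 1) == 0))
})

test_that("distractor steps turn by wrapped-Cauchy angles and move speed*dt", {
  set.seed(2)
  geom <- default_geom
  cfg <- stimulus_config(coherency = 0)
  s <- init_silhouettes(cfg, geom)
  s2 <- step_distractor(s, cfg)
  step_len <- sqrt((s2$x - s$x)^2 + (s2$y - s$y)^2)
  expect_equal(step_len, rep(3.5 / 60, nrow(s)), tolerance = 1e-12)
})

test_that("leader steps are ballistic towards the target arm", {
  geom <- default_geom
  cfg <- stimulus_config(coherency = 1, delta_v = 10, target_arm = "ARM_LEFT")
  s <- tibble::tibble(id = 1L, role = "LEADER", x = 0, y = 0,
                      heading = 0, speed = 35, opacity = 1)
  s2 <- step_leader(s, cfg, geom)
  # from the centre the heading is the left-arm axis direction
  expect_equal(s2$heading,
               atan2(geom$arm_axis_left[2], geom$arm_axis_left[1]))
  # displacement per second at delta-v 10 is 35 cm
  expect_equal(sqrt((s2$x - s$x)^2 + (s2$y - s$y)^2) * cfg$fps, 35)
  # delta-v 1: leader and distractor speeds coincide
  cfg1 <- stimulus_config(coherency = 0.5, delta_v = 1)
  s1 <- init_silhouettes(cfg1, geom)
  expect_equal(unique(s1$speed), 3.5)
})

test_that("boundary fade conserves counts and scales with speed", {
  set.seed(3)
  geom <- default_geom
  cfg <- stimulus_config(coherency = 0.5, delta_v = 10)
  s <- init_silhouettes(cfg, geom)
  expect_identical(apply_boundary(s, cfg, geom), s) # strictly inside: no-op

  # one leader (10x speed) and one distractor parked outside the zone
  out <- s[c(1, 60), ]
  out$x <- geom$zone_radius + 5
  out$y <- geom$zone_radius + 5
  frames_to_respawn <- function(row) {
    n <- 0
    repeat {
      n <- n + 1
      row <- apply_boundary(row, cfg, geom)
      if (row$opacity == 1 && sqrt(row$x^2 + row$y^2) <= geom$zone_radius) {
        return(n)
      }
    }
  }
  n_fast <- frames_to_respawn(out[1, ]) # leader at 35 cm/s
  n_slow <- frames_to_respawn(out[2, ]) # distractor at 3.5 cm/s
  expect_equal(n_slow, cfg$fps) # baseline fades in fade_time_s = 1 s
  expect_equal(n_fast, cfg$fps / 10) # ten times faster
  # counts unchanged by boundary events
  s_out <- s
  s_out$x <- s_out$x + 100
  s_after <- apply_boundary(s_out, cfg, geom)
  expect_equal(nrow(s_after), nrow(s))
  expect_equal(table(s_after$role), table(s$role))
})

test_that("simulated streams satisfy frame count, conservation and determinism", {
  geom <- default_geom
  cfg <- stimulus_config(coherency = 0.67, delta_v = 10, seed = 99)
  fr <- simulate_stimuli(cfg, geom, duration = 10)
  expect_equal(length(unique(fr$frame)), 600) # 10 s at 60 fps
  counts <- table(fr$frame)
  expect_true(all(counts == 60))
  leaders <- tapply(fr$role == "LEADER", fr$frame, sum)
  expect_true(all(leaders == 40))
  fr2 <- simulate_stimuli(cfg, geom, duration = 10)
  expect_identical(fr, fr2)
})

test_that("per-frame displacement honours the speed contract", {
  geom <- default_geom
  cfg <- stimulus_config(n_silhouettes = 20, coherency = 0.5, delta_v = 10,
                         seed = 7)
  fr <- simulate_stimuli(cfg, geom, duration = 3)
  fr <- fr[order(fr$id, fr$frame), ]
  for (role in c("LEADER", "DISTRACTOR")) {
    sub <- fr[fr$role == role, ]
    one <- sub[sub$id == sub$id[1], ]
    d <- sqrt(diff(one$x)^2 + diff(one$y)^2)
    expected <- unique(one$speed) / cfg$fps
    # exclude respawn jumps (opacity snaps back to 1 after fading)
    n <- length(d)
    respawn <- one$opacity[-1] == 1 & one$opacity[-(n + 1)] < 1
    moved <- d[!respawn]
    expect_true(all(abs(moved - expected) < 1e-9))
  }
})

test_that("null coherency carries no directional information", {
  geom <- default_geom
  ps <- sapply(1:6, function(seed) {
    cfg <- stimulus_config(n_silhouettes = 40, coherency = 0, seed = seed)
    fr <- simulate_stimuli(cfg, geom, duration = 5)
    # net displacement direction per silhouette over the run
    dirs <- sapply(split(fr, fr$id), function(d) {
      d <- d[order(d$frame), ]
      atan2(d$y[nrow(d)] - d$y[1], d$x[nrow(d)] - d$x[1])
    })
    rayleigh_p(dirs)
  })
  # isotropy: no seed significant at 0.01 with Bonferroni over seeds
  expect_true(all(ps > 0.01 / length(ps)))
})

test_that("null_fast moves every silhouette at the fast speed", {
  cfg <- stimulus_config(coherency = 0, delta_v = 10, null_fast = TRUE)
  s <- init_silhouettes(cfg, default_geom)
  expect_true(all(s$role == "DISTRACTOR"))
  expect_equal(unique(s$speed), 35)
})
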