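# shoalmaze

Simulation and analysis tools for virtual-shoal Y-maze assays of collective
directional decision-making in fish.

In these assays a zebrafish (alone or with live shoalmates) is released from
a holding area into a Y-maze whose circular decision zone is filled with
projected conspecific silhouettes. A fraction *C* of the silhouettes
("coherency") are **leaders** that swim ballistically towards one arm; the
rest are **distractors** performing a correlated random walk with
wrapped-Cauchy turning. Leaders move at Δ*v* times the baseline speed
(1 body length ≈ 3.5 cm·s⁻¹). The questions the analyses answer: when does
the fish follow the motion cue, how do the decisions of shoalmates feed
back on the individual's choice, and what does grouping do to the speed and
accuracy of decisions?

The package provides the full computational chain, with a generative fish
model standing in for live-animal recordings:

* **Maze geometry** — `maze_geometry()`, `classify_zone()`,
  `arm_entrance_crossing()`: the 46 cm decision zone, 46 × 23 cm arms, and
  first-crossing scoring of a single choice per trial.
* **Stimulus simulator** — `stimulus_config()`, `simulate_stimuli()`:
  leader/distractor silhouettes with fade-and-respawn periodic boundaries
  that keep the silhouette count and leader ratio constant.
* **Generative fish model** — `behavior_params()`, `simulate_trial()`,
  `generate_dataset()`: holding-area departures from a social-hazard
  process (hazard `λ(1 + β d)` after `d` shoalmates have left), arm choices
  from a cue-plus-social-feedback mixture, and decision-zone transit times
  conditioned on correctness.
* **Kinematics** — `smooth_positions()` (3-step running median),
  `compute_kinematics()` (speed in FL/s, acceleration, sine-scaled turning
  arcs), `extract_decision()` (decision time *T_D*, time-to-act *T_A*).
* **Decision statistics** — `exact_binomial_test()`, `sat_comparison()`
  (Wilcoxon rank-sum), `build_social_ledger()` and `logistic_social_fit()`
  for the social-feedback model
  `P(correct | N_c) = 1 / (1 + exp(−a (N_c − b)))` where `N_c` is the
  number of companions that chose correctly before the subject minus those
  that chose incorrectly, `powerlaw_fit()` for the scaling of median *T_A*
  with shoal size *N*, and `accuracy_regression()` with within-subject
  permutation p-values.
* **Orchestration** — `run_experiment()` for fully seeded, byte-reproducible
  simulation → analysis bundles; a thin CLI in `inst/scripts/shoalmaze.R`.

## Worked example

Simulate the group experiment (24 subjects × Δv ∈ {1, 10} × N ∈ {1, 5, 10,
15}, coherency fixed at 0.67) and run the headline analyses:

```r
library(shoalmaze)

ds     <- generate_dataset(2, behavior_params(), seed = 1)
ledger <- build_social_ledger(ds)
an     <- analyze_dataset(ds)

an$follow_rate[["10"]]
#> exact binomial: k=84 n=95 p0=0.5 p_hat=0.884 P=4.518e-15

an$powerlaw
#> power law: T ~ N^-0.764 (R^2 = 0.997)

logistic_social_fit(ledger[ledger$delta_v == 1, ])
#> social-feedback logistic fit (n=94): a=0.427 (SE 0.110, t_92=3.87,
#>   P=0.0002), b=-1.308
```

Subjects follow the fast-moving leaders far above chance (88% of deciders);
the median time-to-act collapses as a power law of shoal size (here
exponent −0.76 on a single 192-trial dataset); and under the weak cue
(Δv = 1) the social-feedback slope *a* is positive and significant — fish
follow the majority of their leading companions. Transit times of correct
deciders are about twice those of incorrect ones (medians 2.06 s vs
1.31 s, rank-sum P = 0.0017): the speed–accuracy trade-off survives
grouping even as social recruitment accelerates the overall response.

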