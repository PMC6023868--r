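---
title: "Models and methods behind shoalmaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shoalmaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic-data generator does and does not
emulate.

## The assay

A subject fish is released from a holding area into a Y-maze whose central
decision zone (46 cm diameter; arms 46 × 23 cm) is saturated with projected
conspecific silhouettes. Two stimulus factors are controlled:

* **Coherency** `C` — the fraction of silhouettes that are *leaders*,
  moving ballistically towards a target arm chosen at random per trial;
  the remaining *distractors* perform a correlated random walk. The leader
  count is `round(C * n)`, so the design labels 0.66 and 0.67 both denote
  40 leaders of 60 and are treated as the same cell.
* **Relative speed** `Δv` — leader speed as a multiple of the 3.5 cm/s
  baseline (1 body length per second); levels 1 and 10.

Scored outcomes per trial: the chosen arm and its correctness (did the fish
follow the leaders; under `C = 0` the "correct" arm is the program's random
designation), the decision time `T_D` (decision-zone entry to arm
crossing), and in group trials the time-to-act `T_A` (gate opening to arm
crossing, which includes social recruitment while still in the holding
area).

## Stimulus simulator

**Turning distribution.** Distractor turn angles are wrapped Cauchy,
centred on the current heading, specified by a circular standard deviation
of 30°. The wrapped Cauchy has no linear moments, so "standard deviation"
is read as the circular standard deviation `σ_c`, which fixes the
concentration through the mean-resultant-length relation
`ρ = exp(−σ_c²/2) ≈ 0.8719`. Sampling uses the inverse-CDF transform
`2·atan(((1−ρ)/(1+ρ))·tan(π(u−½)))`. The tests verify the sampled mean
resultant length against `ρ` to within Monte-Carlo error, which is exactly
the property the parameterization pins down.

**Boundary and fade.** Silhouettes are confined to the decision zone by a
periodic fade-and-respawn rule: outside the zone, opacity decays at a rate
proportional to speed, and a fully faded silhouette reappears uniformly at
random inside the zone with the same role (distractors keep their heading,
leaders re-aim at the trial's target arm — the target is constant within a
trial). The proportionality constant is under-determined by
"proportional"; the package fixes it so a baseline-speed silhouette fades
in `fade_time_s = 1` s, making a 10× leader fade in 0.1 s. Count and
leader/distractor ratio are therefore invariants of every frame, which the
test suite checks over long runs.

**Group-assay variants.** In group mode the effective boundary for leaders
is extended 13.8 cm back towards the holding area (implemented as the
union of the zone disc and the disc shifted along the holding axis), which
stops many stimuli from vanishing at an arm entrance in front of the
subject, and the silhouette count is reduced; 20 is the package default,
configurable, since the count was shown to have no discernible effect on
either decision speed or accuracy. At `C = 0` the `null_fast` flag makes
all (directionless) silhouettes move at the fast speed, so a fast
treatment's null cell still contains fast motion.

**Time step.** The simulator advances at `1/fps = 1/60` s per frame;
observers may subsample. Streams are deterministic given the
configuration seed.

## Generative fish model

The assay's publications report phenomena — follow rates, a speed–accuracy
trade-off (SAT), power-law latency scaling, logistic social feedback — not
a generative model of the fish. `behavior_params()` holds the minimal
generative structure that reproduces all of them; it exists to exercise
the analysis chain, not to model zebrafish locomotion faithfully.

**Departure (time-to-act).** Fish leave the holding area by a social-hazard
process: while `d` shoalmates have departed, each remaining fish departs
with hazard `λ(1 + βd)`. With `β = 0` departures are i.i.d. exponentials
and the subject's latency is independent of shoal size; with a large boost
the subject's departure is dominated by the first-departure time, whose
median scales as `1/N`, giving power-law-like decay of median `T_A` with
shoal size. The defaults `λ = 1/120` s⁻¹ and `β = 25` were chosen, once,
by simulating median `T_A` over `N ∈ {1, 5, 10, 15}` and matching the
reported scaling exponent of about −0.9: they put the solitary median near
85 s and give a fitted exponent near −0.85 with R² above 0.99. A
`subject_rate_multiplier` (default 1) allows boosting the subject's own
hazard, which pushes subjects into the front half of the decision order,
as observed in tagged-subject recordings; the property is exercised in the
tests with an explicit boost.

**Choice.** The probability of a correct decision mixes a private cue
weight with logistic social feedback:

`P(correct | N_c) = clip( w + (1 − w) / (1 + exp(−a (N_c − b))) )`,

where `N_c` is the signed tally of leading companions (correct minus
incorrect choices made before the subject's own). The cue weight
`w = max(0, 2·p_follow − 1)` is anchored to the observed solitary follow
rates (`p_follow_fast = 0.85`, `p_follow_slow = 0.44`): for a solitary
fish the social term sits near ½, so accuracy reduces to about `p_follow`.
Defaults `a = 0.52`, `b = 0.07` are the fitted weak-cue values. Two
consequences worth noting: at `Δv = 1` the weight is zero, so the choice
curve is the pure logistic (majority rule); at `Δv = 10` the mixture
compresses the logistic's range, so the *effective* fitted slope is much
smaller — the same qualitative pattern as the reported strong-cue fit.
At `C = 0` there is no cue and "correct" requires the program's random
designation and the fish's independent choice to coincide on the
designated arm, which halves the probability: the chance level is 25%.

**Timing of the choice.** Because transit time depends on correctness
(the SAT) while correctness depends on `N_c` *at the arm crossing*, the
trial simulator is a chronological event simulation. At zone entry a fish
draws its transit time from the two-component mixture weighted by the
choice probability given `N_c` at entry; at the crossing, correctness is
drawn from the exact conditional given the realized transit time and
`N_c` at crossing (an importance ratio against the entry-weighted
mixture, capped at 1). When `N_c` is unchanged between entry and crossing
this reproduces the logistic choice curve and the stated transit
distributions exactly; in general the crossing-time covariate dominates,
which is what makes the ledger-based slope recoverable without
attenuation. Ties in decision times are broken by fish id so `N_c` is
always well defined.

**Transit times.** Gamma draws matched to mean ± SD 2.6 ± 2 s (correct)
and 1.3 ± 0.8 s (incorrect), embedding the SAT. The within-zone meander
(for track-producing runs) is a turning-noise bridge from the holding-side
gate to the chosen arm's entrance, scaled to last exactly the drawn
transit time and to stay inside the zone, so the kinematics module
recovers the analytic `T_A`/`T_D` from the tracks.

**Designs.** Experiment 1 is the solitary full factorial (20 subjects ×
4 coherency × 2 speed = 160 trials); experiment 2 crosses 24 subjects with
speed and shoal size `{1, 5, 10, 15}` at fixed `C = 0.67` (192 trials per
pass). Target arms are randomized per trial. Per-trial sub-seeds derive
from the master seed by a counter (`derive_seed()`), so extending a
dataset never perturbs existing trials. The chance-agreement rule for
`C = 0` is implemented in experiment 2 as well for completeness, although
that design never uses `C = 0`.

## Kinematics

Positions are smoothed with a 3-step running median; endpoint handling is
unspecified in the assay's description and the package passes endpoints
through unchanged to preserve track length. Velocities are first
differences scaled by the sampling rate and normalised to body lengths per
second; acceleration is the first difference of speed; the turning arc is
`sin(θ)` of the absolute angle between successive velocity vectors. The
sine is non-monotone beyond 90°; such turns are rare in this assay (<2% of
steps) and the transform is applied as stated, with a diagnostic counter
(`n_sharp_turns`) so users can check the rarity assumption on their own
data. Zero-length steps leave the turning arc undefined (`NA`).

The sampling rate is a property of the track, never hard-coded: recordings
in this family of assays have used both 10 and 12 frames per second, and
both are honoured by parameterization (synthetic tracks default to 10 Hz).

Decisions are scored by the first-crossing rule: one choice per trial at
the first decision-zone-to-arm transition; later re-entries are ignored.
Non-deciders are right-censored at trial end; by default they are excluded
from median `T_A` (whether published latency boxplots include censored
times is ambiguous, so `analyze_dataset(include_censored = )` supports
both conventions).

## Decision statistics

* **Exact binomial test** — two-sided p by the small-likelihood rule with
  a 1e-7 relative tolerance (the convention of mainstream statistical
  software), which reproduces this assay family's printed p-values from
  their printed counts. The test suite verifies the implementation against
  full enumeration for all `k`, `n ≤ 25`, `p0 ∈ {0.25, 0.5, 0.75}`.
* **SAT comparison** — Wilcoxon rank-sum in the Mann-Whitney convention
  (pairs with the first sample larger, plus half-ties), exact for small
  untied samples, normal approximation with tie correction otherwise.
* **Social ledger** — `N_c` recounts companions deciding strictly before
  the subject; non-deciders contribute nothing; subjects without a
  decision are excluded with a message.
* **Logistic social-feedback fit** — own Newton–Raphson with step-halving
  on the natural parameters (intercept/slope), which is well conditioned
  when the slope is near zero where the `(a, b)` parameterization is not
  (`b` is unidentified at `a = 0`). Step-halving guarantees a monotone
  log-likelihood trace; standard errors come from the observed
  information, `b`'s by the delta method; the slope test is a t on `n − 2`
  degrees of freedom. Complete separation (a perfect cut point in `N_c`)
  is flagged as non-convergence, never silently estimated. Instead of
  removing rank-deficient outliers, singleton `N_c` levels can be merged
  into their nearest level (`merge_singletons`), with the affected row
  count reported. `stats::glm()` serves as an independent cross-check in
  the tests, not as the implementation.
* **Accuracy regression** — fixed-effects logistic regression
  (IRLS via `stats::glm()`). Random-effects mixed models are deliberately
  out of scope; as the robustness substitute for subject random effects
  the focal factor can be permuted *within subject* (preserving the
  repeated-measures structure under the null), giving a permutation
  p-value. Multiplicity adjustment defaults to Holm, configurable through
  `adjust_p()`.
* **Power-law fit** — OLS of log median on log `N`; scale-equivariant by
  construction.

## Numerical and reproducibility choices

* Degenerate inputs fail loudly: empty tracks, unsorted timestamps, gates
  after track end, zero-margin tables, zero-variance correlations,
  nonpositive medians.
* Opacity comparisons in the fade rule use a 1e-9 tolerance so that a
  fade scheduled to finish in exactly `k` frames does so despite binary
  rounding.
* All randomness flows from explicit seeds; `run_experiment()` writes a
  manifest with config echo, seed, version and md5 checksums, and
  identical configurations produce byte-identical bundles.

## Problem sizes in the test suite

The statistical property tests use sizes chosen to keep the default suite
fast while leaving comfortable power margins: 10⁵ draws for the
wrapped-Cauchy concentration check; twenty 10⁴-frame streams for the
conservation invariants; 10⁴ replicate trials (2 500 per shoal size) for
the latency power law; 100 datasets of roughly 2 000 subject decisions for
slope recovery (the fitted slope must fall within ±0.1 of the generative
0.5 in at least 90%); and 100 replicate assays of 120 solitary trials for
the SAT detection rate.

## What the generator does not emulate

Synthetic trials reproduce the *statistical* structure the analyses assume
— follow rates, chance level, hazard-coupled departures, the SAT, logistic
social feedback — not zebrafish biology. There is no hydrodynamics, no
body shape, no learning across trials, no perception model (fish do not
"see" the simulated silhouettes; the cue enters only through the follow
probabilities), and the within-zone meander is a geometric bridge rather
than real locomotion. Passing tests therefore validate the pipeline's
correctness and the analyses' power under the assumed generative
structure; they cannot validate the behavioural claims themselves against
real recordings, for which the CSV ingestion path (`read_tracks_csv()`,
`validate_inputs()`, `extract_trial_decisions()`) exists.

## Known limitations

* The social-feedback recovery guarantees hold at the default hazard
  parameters; very fast recruitment combined with long transits increases
  the entry/crossing `N_c` gap and with it the (small) residual bias of
  the importance-ratio cap.
* The holding area's exact shape and gate position are not part of the
  assay's published geometry; a rectangle abutting the decision zone is
  assumed, and only the gate position affects `T_A`.
* Maze depth is ignored; all analysis is 2D, matching overhead tracking.
* `accuracy_regression()` is a fixed-effects stand-in; where a published
  p-value came from a mixed model, the permutation p-value is the
  comparable quantity, not the Wald p.
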