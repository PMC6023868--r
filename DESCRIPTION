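Package: shoalmaze
Title: Virtual-Shoal Y-Maze Simulation and Collective Decision Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the virtual leader/distractor silhouette stimuli used in
    Y-maze shoaling assays with zebrafish, generates synthetic fish trajectories
    and directional decisions from a hazard-based departure process coupled to a
    cue-plus-social-feedback choice model, extracts trajectory kinematics
    (running-median smoothing, speed, acceleration, sine-scaled turning arcs,
    decision times), and provides the decision statistics used in such assays:
    exact binomial tests, Wilcoxon speed-accuracy comparisons, signed
    leading-companion tallies (Nc), logistic social-feedback model fits,
    power-law scaling of time-to-act with group size, and fixed-effects
    accuracy regressions with subject-level permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
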