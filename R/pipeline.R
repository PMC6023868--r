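#' Run the standard analysis suite on a decision dataset
#'
#' Applies the assay's analyses to a set of per-fish decision records:
#' target-arm balance and subject arm-preference binomial tests, follow-rate
#' binomial tests split by relative speed, the Wilcoxon speed-accuracy
#' comparison of decision times, the signed leading-companion ledger with a
#' logistic social-feedback fit per relative-speed level, the power-law fit
#' of median time-to-act against shoal size, per-group-size decision-time /
#' accuracy correlations, and a fixed-effects accuracy regression.
#' Components that need group structure are skipped for solitary-only data.
#'
#' @param dataset A `trial_dataset` or a decisions data frame (see
#'   [build_social_ledger()] for required columns).
#' @param include_censored Include non-deciders' right-censored times (at
#'   trial end) in the median time-to-act; by default non-deciders are
#'   excluded.
#' @param trial_duration Censoring time used when `include_censored`.
#' @return A list of class `maze_analysis` of the component results.
#' @export
analyze_dataset <- function(dataset, include_censored = FALSE,
                            trial_duration = 300) {
  dec <- if (inherits(dataset, "trial_dataset")) dataset$decisions else dataset
  subj <- dec[dec$role == "SUBJECT", ]
  design <- subj[!duplicated(subj$trial_id), ]
  out <- list()

  out$target_balance <- exact_binomial_test(
    sum(design$target_arm == "ARM_LEFT"), nrow(design)
  )
  chosen <- subj$chosen_arm[!is.na(subj$chosen_arm)]
  if (length(chosen) > 0) {
    out$arm_preference <- exact_binomial_test(
      sum(chosen == "ARM_LEFT"), length(chosen)
    )
  }
  decided <- subj[!is.na(subj$correct), ]
  out$follow_rate <- lapply(split(decided, decided$delta_v), function(d) {
    exact_binomial_test(sum(d$correct), nrow(d))
  })

  cue <- decided[decided$coherency > 0, ]
  if (nrow(cue) > 2 && any(cue$correct) && any(!cue$correct)) {
    out$sat <- sat_comparison(cue$t_d[cue$correct], cue$t_d[!cue$correct])
  }

  if (any(dec$n_fish > 1)) {
    ledger <- build_social_ledger(dec)
    out$ledger <- ledger
    out$social_fit <- lapply(split(ledger, ledger$delta_v), function(d) {
      tryCatch(logistic_social_fit(d), error = function(e) NULL)
    })
    ta <- subj$t_a
    if (include_censored) ta[is.na(ta)] <- trial_duration
    med <- tapply(ta, subj$n_fish, stats::median, na.rm = TRUE)
    sizes <- as.numeric(names(med))
    if (sum(!is.na(med)) >= 3) {
      out$powerlaw <- powerlaw_fit(sizes[!is.na(med)], med[!is.na(med)])
    }
    out$td_accuracy_r <- vapply(split(decided, decided$n_fish), function(d) {
      if (nrow(d) < 3 || stats::sd(d$correct) == 0 || stats::sd(d$t_d) == 0) {
        return(NA_real_)
      }
      pearson_r(d$t_d, as.numeric(d$correct))
    }, numeric(1))
    out$regression <- accuracy_regression(
      dplyr::mutate(ledger, delta_v_fast = as.numeric(.data$delta_v >= 10)),
      factors = c("delta_v_fast", "n_c")
    )
  } else {
    d1 <- dplyr::mutate(decided,
                        delta_v_fast = as.numeric(.data$delta_v >= 10),
                        has_cue = as.numeric(.data$coherency > 0))
    out$regression <- accuracy_regression(
      d1, factors = c("delta_v_fast", "has_cue")
    )
  }
  structure(out, class = "maze_analysis")
}

# flatten an analysis into plain lists for JSON
.analysis_json <- function(an) {
  strip <- function(x) {
    if (inherits(x, "social_logistic_fit")) {
      x <- x[c("a", "b", "se_a", "se_b", "t_a", "df", "p_a", "loglik",
               "n", "converged")]
    }
    if (inherits(x, "accuracy_regression")) {
      x <- list(coefficients = as.data.frame(x$coefficients),
                perm_p = x$perm_p, separation = x$separation, n = x$n)
    }
    if (inherits(x, "maze_analysis")) x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    unclass(x)
  }
  strip(an)[setdiff(names(an), "ledger")]
}

#' Assemble a reproducible run configuration
#'
#' @param experiment 1 (solitary) or 2 (groups).
#' @param seed Master seed; per-trial sub-seeds derive from it via
#'   [derive_seed()].
#' @param params A [behavior_params()] (or a list of overrides).
#' @param stimulus A [stimulus_config()] (or a list of overrides).
#' @param geometry A list of [maze_geometry()] argument overrides.
#' @param n_subjects,n_passes Design size overrides.
#' @param include_censored,trial_duration Analysis flags (see
#'   [analyze_dataset()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = 1, seed = 1, params = list(),
                       stimulus = list(), geometry = list(),
                       n_subjects = NULL, n_passes = 1,
                       include_censored = FALSE, trial_duration = 300) {
  if (!inherits(params, "behavior_params")) {
    params <- do.call(behavior_params, params)
  }
  structure(
    list(experiment = as.integer(experiment), seed = as.integer(seed),
         params = params, stimulus = stimulus, geometry = geometry,
         n_subjects = n_subjects, n_passes = as.integer(n_passes),
         include_censored = include_censored,
         trial_duration = trial_duration),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML may contain any [run_config()] field; `params`, `stimulus` and
#' `geometry` are nested maps of overrides. The configuration round-trips
#' losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$params <- unclass(out$params)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run a full simulated experiment end to end
#'
#' Generates the synthetic dataset for the configured experiment, runs the
#' analysis suite, and writes a results bundle: `decisions.csv`,
#' `analysis.json`, and `manifest.json` (configuration echo, seed, package
#' version, and md5 checksums of the outputs). The run is deterministic:
#' the same configuration always produces byte-identical decision tables
#' and analysis JSON.
#'
#' @param config A [run_config()] (or YAML path).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the dataset, the analysis and the
#'   manifest.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output path is not writable: ", out_dir, call. = FALSE)
  unlink(probe)

  params <- config$params
  params$trial_duration <- config$trial_duration
  dataset <- generate_dataset(
    experiment = config$experiment, params = params, seed = config$seed,
    n_subjects = config$n_subjects, n_passes = config$n_passes,
    geom = if (length(config$geometry)) do.call(maze_geometry, config$geometry)
  )
  analysis <- analyze_dataset(dataset,
                              include_censored = config$include_censored,
                              trial_duration = config$trial_duration)

  dec_path <- file.path(out_dir, "decisions.csv")
  utils::write.csv(dataset$decisions, dec_path, row.names = FALSE)
  an_path <- file.path(out_dir, "analysis.json")
  jsonlite::write_json(.analysis_json(analysis), an_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- list(
    experiment = config$experiment,
    seed = config$seed,
    n_trials = nrow(dataset$design),
    package_version = as.character(utils::packageVersion("shoalmaze")),
    config = list(params = unclass(config$params),
                  geometry = config$geometry,
                  n_subjects = config$n_subjects,
                  n_passes = config$n_passes,
                  include_censored = config$include_censored,
                  trial_duration = config$trial_duration),
    checksums = as.list(tools::md5sum(c(dec_path, an_path)) |>
                          stats::setNames(c("decisions.csv", "analysis.json")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = dataset, analysis = analysis, manifest = manifest))
}

#' Validate a trajectory CSV
#'
#' Checks a trajectory table (columns `trial_id`, `fish_id`, `t`, `x`, `y`;
#' `frame` optional) for the problems that most often corrupt downstream
#' kinematics: missing columns, non-numeric or missing coordinates,
#' duplicated frames, non-monotone timestamps (re-sortable, flagged as a
#' warning rather than fatal), and implausible coordinate magnitudes for a
#' maze measured in cm.
#'
#' @param path CSV file path, or a data frame.
#' @return A tibble of issues (empty when the file is clean) with columns
#'   `severity` (`"error"`/`"warning"`), `check`, `detail`.
#' @export
validate_inputs <- function(path) {
  df <- if (is.data.frame(path)) path else {
    tryCatch(utils::read.csv(path),
             error = function(e) stop("malformed CSV: ", conditionMessage(e),
                                      call. = FALSE))
  }
  issues <- list()
  add <- function(severity, check, detail) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(severity = severity, check = check, detail = detail)
  }
  required <- c("trial_id", "fish_id", "t", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    add("error", "columns", paste("missing:", paste(missing, collapse = ", ")))
    return(dplyr::bind_rows(issues))
  }
  for (col in c("t", "x", "y")) {
    if (!is.numeric(df[[col]])) add("error", "types", paste(col, "not numeric"))
    if (anyNA(df[[col]])) add("error", "missing", paste("NA in", col))
  }
  if (length(issues) == 0) {
    by_fish <- split(df, interaction(df$trial_id, df$fish_id, drop = TRUE))
    for (key in names(by_fish)) {
      tt <- by_fish[[key]]$t
      if (anyDuplicated(tt)) {
        add("error", "duplicate_frames", paste("duplicated t in", key))
      }
      if (is.unsorted(tt)) {
        add("warning", "unsorted", paste("timestamps unsorted in", key,
                                         "(re-sortable)"))
      }
    }
    if (max(abs(df$x), abs(df$y)) > 500) {
      add("warning", "units", "coordinates exceed 5 m; are units cm?")
    }
  }
  dplyr::bind_rows(issues)
}

#' Write and read decision tables
#'
#' @param decisions A decisions data frame.
#' @param path CSV path.
#' @return `read_decisions_csv()` returns a tibble.
#' @export
write_decisions_csv <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decisions_csv
#' @export
read_decisions_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname write_decisions_csv
#' @param tracks A tracks data frame (`trial_id`, `fish_id`, `t`, `x`, `y`).
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decisions_csv
#' @export
read_tracks_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
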