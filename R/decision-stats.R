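#' Exact two-sided binomial test
#'
#' Exact test of `k` successes in `n` Bernoulli trials against null
#' probability `p0`, with the two-sided p-value computed by the
#' small-likelihood rule: the sum of `P(X = j)` over all `j` whose point
#' probability does not exceed `P(X = k)` by more than a relative tolerance
#' of 1e-7 (the convention of mainstream statistical software, via
#' [stats::binom.test()]).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return A list of class `binomial_result`: `k`, `n`, `p0`, `p_hat`,
#'   `p_value`, `conf_int`.
#' @examples
#' exact_binomial_test(16, 40) # arm bias under the null stimulus
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  stopifnot(n > 0, k >= 0, k <= n, p0 > 0, p0 < 1)
  bt <- stats::binom.test(k, n, p = p0)
  structure(
    list(k = k, n = n, p0 = p0, p_hat = k / n,
         p_value = bt$p.value, conf_int = as.numeric(bt$conf.int)),
    class = "binomial_result"
  )
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("exact binomial: k=%d n=%d p0=%.3g p_hat=%.3f P=%.4g\n",
              x$k, x$n, x$p0, x$p_hat, x$p_value))
  invisible(x)
}

#' Speed-accuracy comparison of decision-zone transit times
#'
#' Wilcoxon rank-sum (Mann-Whitney) comparison of the decision times of
#' correct versus incorrect deciders. The statistic W is the number of
#' (correct, incorrect) pairs in which the correct decider was slower, plus
#' half the ties; under a speed-accuracy trade-off correct deciders take
#' longer. Exact p-values are used for small samples without ties,
#' otherwise the normal approximation with tie correction (the behaviour of
#' [stats::wilcox.test()]).
#'
#' @param td_correct Decision times of correct deciders, s.
#' @param td_incorrect Decision times of incorrect deciders, s.
#' @return A list of class `sat_result`: `w`, `p_value`, medians and ns.
#' @export
sat_comparison <- function(td_correct, td_incorrect) {
  stopifnot(length(td_correct) > 0, length(td_incorrect) > 0)
  if (length(unique(c(td_correct, td_incorrect))) == 1L) {
    warning("all decision times identical across groups; p = 1")
    return(structure(
      list(w = length(td_correct) * length(td_incorrect) / 2, p_value = 1,
           median_correct = stats::median(td_correct),
           median_incorrect = stats::median(td_incorrect),
           n_correct = length(td_correct),
           n_incorrect = length(td_incorrect)),
      class = "sat_result"
    ))
  }
  wt <- suppressWarnings(stats::wilcox.test(td_correct, td_incorrect))
  structure(
    list(w = unname(wt$statistic), p_value = wt$p.value,
         median_correct = stats::median(td_correct),
         median_incorrect = stats::median(td_incorrect),
         n_correct = length(td_correct),
         n_incorrect = length(td_incorrect)),
    class = "sat_result"
  )
}

#' Signed leading-companion tally per subject decision
#'
#' For every subject decision, counts the companions in the same trial that
#' decided strictly before the subject and tallies correct minus incorrect:
#' the social-feedback covariate Nc. Non-deciding companions contribute
#' nothing. Subjects with no decision are excluded (with a message).
#'
#' @param dataset A `trial_dataset` (from [generate_dataset()]) or a
#'   decisions data frame with columns `trial_id`, `fish_id`, `role`,
#'   `correct`, `t_decision` or `t_a`, plus design columns `delta_v`,
#'   `n_fish` (and optionally `subject_id`, `coherency`).
#' @return A tibble of class `social_ledger`, one row per subject decision:
#'   `trial_id`, `subject_id`, `n_c`, `correct`, `delta_v`, `n_fish`, `t_d`.
#' @export
build_social_ledger <- function(dataset) {
  dec <- if (inherits(dataset, "trial_dataset")) dataset$decisions else dataset
  if (!"t_decision" %in% names(dec)) dec$t_decision <- dec$t_a
  if (!"subject_id" %in% names(dec)) dec$subject_id <- NA
  subj <- dec[dec$role == "SUBJECT" & !is.na(dec$t_decision), ]
  comp <- dec[dec$role == "COMPANION" & !is.na(dec$t_decision), ]
  # companions deciding strictly before their trial subject, signed tally
  comp$subj_t <- subj$t_decision[match(comp$trial_id, subj$trial_id)]
  lead <- comp[!is.na(comp$subj_t) & comp$t_decision < comp$subj_t, ]
  signed <- tapply(2 * as.numeric(lead$correct) - 1, lead$trial_id, sum)
  n_c <- rep(0, nrow(subj))
  hit <- match(as.numeric(names(signed)), subj$trial_id)
  n_c[hit[!is.na(hit)]] <- signed[!is.na(hit)]
  rows <- tibble::tibble(
    trial_id = subj$trial_id,
    subject_id = subj$subject_id,
    n_c = as.integer(n_c),
    correct = subj$correct,
    delta_v = subj$delta_v,
    n_fish = subj$n_fish,
    t_d = subj$t_d
  )
  n_drop <- length(unique(dec$trial_id)) - nrow(rows)
  if (n_drop > 0) {
    message(n_drop, " trial(s) without a subject decision excluded")
  }
  class(rows) <- c("social_ledger", class(rows))
  rows
}

# negative log-likelihood machinery for the social-feedback logistic model
# in its natural-parameter form eta = b0 + b1 * nc (a = b1, b = -b0/b1)
.logis_ll <- function(beta, x, y) {
  eta <- beta[1] + beta[2] * x
  sum(y * eta - log1p(exp(eta)))
}

#' Fit the logistic social-feedback model
#'
#' Maximum-likelihood fit of `P(correct | Nc) = 1 / (1 + exp(-a (Nc - b)))`
#' by Newton-Raphson with step-halving on the natural parameters
#' (intercept and slope of the linear predictor), which keeps the problem
#' well conditioned when the slope is near zero; `a` is the slope and
#' `b = -intercept/slope`. Standard errors come from the observed
#' information (delta method for `b`); the slope test is reported as a
#' t-statistic on `n - 2` degrees of freedom. The log-likelihood trace is
#' retained; step-halving guarantees it never decreases. Complete
#' separation or a singular information matrix is flagged as
#' non-convergence rather than returning silent estimates.
#'
#' Levels of Nc observed only once can optionally be merged into their
#' nearest neighbouring level before fitting (a guard against rank-deficient
#' extreme tallies); the number of affected rows is reported.
#'
#' @param n_c Signed leading-companion tallies (or a `social_ledger`, in
#'   which case `correct` is taken from it).
#' @param correct Logical/0-1 outcomes.
#' @param merge_singletons Merge single-observation Nc levels into their
#'   nearest level before fitting.
#' @param max_iter,tol Newton iteration controls.
#' @return A list of class `social_logistic_fit`: `a`, `b`, `se_a`, `se_b`,
#'   `t_a`, `df`, `p_a`, `loglik`, `ll_trace`, `n`, `n_merged`,
#'   `converged`.
#' @export
logistic_social_fit <- function(n_c, correct = NULL, merge_singletons = FALSE,
                                max_iter = 50L, tol = 1e-10) {
  if (inherits(n_c, "social_ledger") || is.data.frame(n_c)) {
    correct <- n_c$correct
    n_c <- n_c$n_c
  }
  keep <- !is.na(n_c) & !is.na(correct)
  x <- as.numeric(n_c[keep])
  y <- as.numeric(correct[keep])
  n_merged <- 0L
  if (merge_singletons) {
    tab <- table(x)
    singles <- as.numeric(names(tab)[tab == 1L])
    levels_keep <- as.numeric(names(tab)[tab > 1L])
    if (length(singles) > 0 && length(levels_keep) > 0) {
      for (s in singles) {
        x[x == s] <- levels_keep[which.min(abs(levels_keep - s))]
      }
      n_merged <- length(singles)
    }
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("need >= 2 distinct Nc values with both outcomes represented",
         call. = FALSE)
  }
  beta <- c(stats::qlogis(pmin(pmax(mean(y), 0.05), 0.95)), 0)
  ll <- .logis_ll(beta, x, y)
  trace <- ll
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(beta[1] + beta[2] * x)
    grad <- c(sum(y - p), sum((y - p) * x))
    w <- p * (1 - p)
    info <- rbind(c(sum(w), sum(w * x)), c(sum(w * x), sum(w * x^2)))
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # step-halving: never accept a decrease in log-likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- .logis_ll(cand, x, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    beta <- beta + lambda * step
    ll_new <- .logis_ll(beta, x, y)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  # complete separation: a cut point in Nc splits the outcomes perfectly,
  # so the MLE sits at infinity; flag rather than report silent estimates
  separated <- (max(x[y == 1]) < min(x[y == 0])) ||
    (max(x[y == 0]) < min(x[y == 1]))
  if (separated || abs(beta[2]) > 50 || is.null(info) ||
      rcond(info) < 1e-12) {
    converged <- FALSE
  }
  vc <- tryCatch(solve(info), error = function(e) matrix(NA, 2, 2))
  a <- beta[2]
  b <- -beta[1] / beta[2]
  # delta method: b = -b0/b1
  gb <- c(-1 / beta[2], beta[1] / beta[2]^2)
  se_a <- sqrt(vc[2, 2])
  se_b <- sqrt(drop(t(gb) %*% vc %*% gb))
  df <- length(y) - 2L
  t_a <- a / se_a
  structure(
    list(a = a, b = b, se_a = se_a, se_b = se_b,
         t_a = t_a, df = df,
         p_a = 2 * stats::pt(-abs(t_a), df),
         loglik = ll, ll_trace = trace, n = length(y),
         n_merged = n_merged, converged = converged),
    class = "social_logistic_fit"
  )
}

#' @export
print.social_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "social-feedback logistic fit (n=%d%s): a=%.3f (SE %.3f, t_%d=%.2f, P=%.3g), b=%.3f\n",
    x$n, if (x$converged) "" else ", NOT CONVERGED", x$a, x$se_a, x$df,
    x$t_a, x$p_a, x$b))
  invisible(x)
}

#' Predicted accuracy from the social-feedback logistic model
#'
#' @param a,b Model parameters.
#' @param n_c Signed leading-companion tally.
#' @return `1 / (1 + exp(-a (n_c - b)))`.
#' @export
social_logistic <- function(a, b, n_c) {
  1 / (1 + exp(-a * (n_c - b)))
}

#' Power-law fit of median time-to-act against group size
#'
#' Ordinary least squares of `log(median)` on `log(N)`: the slope is the
#' power-law exponent and R-squared comes from the log-log regression. The
#' fit is scale-equivariant: rescaling all medians changes only the
#' intercept.
#'
#' @param group_sizes Group sizes (>= 3 distinct values).
#' @param medians Median times per group size, all positive.
#' @return A list of class `powerlaw_fit`: `exponent`, `intercept` (log
#'   scale), `r_squared`, plus the inputs.
#' @examples
#' powerlaw_fit(c(1, 5, 10, 15), 30 * c(1, 5, 10, 15)^-1) # exponent -1
#' @export
powerlaw_fit <- function(group_sizes, medians) {
  stopifnot(length(group_sizes) == length(medians),
            length(unique(group_sizes)) >= 3)
  if (any(medians <= 0)) stop("medians must be positive", call. = FALSE)
  fit <- stats::lm(log(medians) ~ log(group_sizes))
  structure(
    list(exponent = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         group_sizes = group_sizes, medians = medians),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power law: T ~ N^%.3f (R^2 = %.3f)\n",
              x$exponent, x$r_squared))
  invisible(x)
}

#' Fixed-effects logistic regression of decision accuracy
#'
#' Logistic regression (fitted by iteratively reweighted least squares via
#' [stats::glm()]) of subject correctness on design factors, with Wald z
#' statistics. As a robustness substitute for subject random effects,
#' within-subject permutation p-values can be requested: the focal factor's
#' values are permuted within each subject's own trials, preserving the
#' repeated-measures structure under the null of no factor effect.
#'
#' @param data A data frame with a logical/0-1 `correct` column, the factor
#'   columns, and `subject_id` when permutation p-values are requested.
#' @param factors Character vector of predictor column names (subset of
#'   the design variables, e.g. `c("delta_v", "coherency", "n_fish",
#'   "n_c", "t_d")`).
#' @param n_perm Number of within-subject permutations for the focal
#'   factor's p-value; 0 disables.
#' @param perm_factor Factor to permute (default: the first).
#' @return A list of class `accuracy_regression`: `coefficients` (tibble
#'   with estimate, SE, z, p), `perm_p`, `separation` flag, and the glm
#'   object.
#' @export
accuracy_regression <- function(data, factors, n_perm = 0,
                                perm_factor = factors[1]) {
  stopifnot(length(factors) >= 1, all(factors %in% names(data)),
            "correct" %in% names(data))
  data <- data[stats::complete.cases(data[, c("correct", factors)]), ]
  form <- stats::as.formula(
    paste("correct ~", paste(factors, collapse = " + "))
  )
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = data))
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 50)
  cf <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]),
    std_error = unname(cf[, 2]),
    z = unname(cf[, 3]),
    p_value = unname(cf[, 4])
  )
  perm_p <- NULL
  if (n_perm > 0) {
    stopifnot("subject_id" %in% names(data))
    obs_z <- abs(coefs$z[coefs$term == perm_factor])
    perm_z <- vapply(seq_len(n_perm), function(i) {
      d <- data
      d[[perm_factor]] <- stats::ave(d[[perm_factor]], d$subject_id,
                                     FUN = sample)
      pf <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = d))
      abs(summary(pf)$coefficients[perm_factor, 3])
    }, numeric(1))
    perm_p <- (1 + sum(perm_z >= obs_z)) / (n_perm + 1)
  }
  structure(
    list(coefficients = coefs, perm_p = perm_p, perm_factor = perm_factor,
         separation = separation, fit = fit, n = nrow(data)),
    class = "accuracy_regression"
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table A 2x2 matrix of nonnegative counts.
#' @param correct Apply Yates continuity correction (off by default).
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Adjust a set of p-values for multiple comparisons
#'
#' Post-hoc adjustment with Holm's method by default (configurable to any
#' method of [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values.
#' @param method Adjustment method.
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p, method = "holm") {
  stats::p.adjust(p, method = method)
}
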