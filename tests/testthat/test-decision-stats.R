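test_that("exact binomial test equals full enumeration", {
  # tiny case by hand: all-successes of 3 at p0 = 0.5 sums the two tails
  expect_equal(exact_binomial_test(3, 3)$p_value, 0.25)
  for (n in c(5, 12, 25)) {
    for (p0 in c(0.25, 0.5, 0.75)) {
      for (k in 0:n) {
        expect_equal(exact_binomial_test(k, n, p0)$p_value,
                     binom_p_oracle(k, n, p0), tolerance = 1e-12,
                     info = sprintf("k=%d n=%d p0=%.2f", k, n, p0))
      }
    }
  }
  expect_error(exact_binomial_test(1, 0))
  expect_error(exact_binomial_test(5, 4))
})

test_that("rank-sum comparison matches enumeration on small samples", {
  res <- sat_comparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$w, 0) # every pair has the second sample larger
  expect_equal(res$p_value, 0.1) # 2/20 orderings as or more extreme
  expect_warning(res2 <- sat_comparison(c(2, 2), c(2, 2)), "identical")
  expect_equal(res2$p_value, 1)
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_gt(sat_comparison(x, x)$p_value, 0.6) # exchangeable: large p
})

test_that("rank-sum test has power against a one-sd shift", {
  set.seed(15)
  ps <- replicate(40, {
    sat_comparison(rnorm(200, 1), rnorm(200, 0))$p_value
  })
  expect_gte(mean(ps < 0.001), 0.99)
})

test_that("social ledger tallies leading companions correctly", {
  mk <- function(t_dec, correct, trial = 1) {
    n <- length(t_dec)
    tibble::tibble(
      trial_id = trial, fish_id = seq_len(n),
      role = c("SUBJECT", rep("COMPANION", n - 1)),
      subject_id = 1, correct = correct, t_decision = t_dec,
      t_a = t_dec, t_d = 1, delta_v = 1, n_fish = n,
      coherency = 0.67, target_arm = "ARM_LEFT"
    )
  }
  # subject decides first: no leading companions
  led <- build_social_ledger(mk(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(led$n_c, 0L)
  # three companions ahead, two correct and one incorrect: Nc = 1
  led2 <- build_social_ledger(mk(c(9, 1, 2, 3, 20),
                                 c(TRUE, TRUE, TRUE, FALSE, TRUE)))
  expect_equal(led2$n_c, 1L)
  # non-deciding companions contribute nothing
  led3 <- build_social_ledger(mk(c(5, 1, NA, NA), c(TRUE, FALSE, NA, NA)))
  expect_equal(led3$n_c, -1L)
  # subject without a decision is excluded
  expect_message(
    led4 <- build_social_ledger(mk(c(NA, 1, 2), c(NA, TRUE, TRUE))),
    "excluded")
  expect_equal(nrow(led4), 0)
})

test_that("ledger agrees with a brute-force recount on random trials", {
  set.seed(16)
  for (rep in 1:10) {
    n_trials <- 8
    dec <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
      n <- sample(c(5, 10, 15), 1)
      t_dec <- ifelse(runif(n) < 0.15, NA, runif(n, 0, 60))
      tibble::tibble(
        trial_id = tr, fish_id = seq_len(n),
        role = c("SUBJECT", rep("COMPANION", n - 1)),
        subject_id = tr, correct = ifelse(is.na(t_dec), NA, runif(n) < 0.6),
        t_decision = t_dec, t_a = t_dec, t_d = 1,
        delta_v = 1, n_fish = n, coherency = 0.67, target_arm = "ARM_LEFT"
      )
    }))
    led <- suppressMessages(build_social_ledger(dec))
    for (i in seq_len(nrow(led))) {
      tr <- dec[dec$trial_id == led$trial_id[i], ]
      subj_t <- tr$t_decision[tr$role == "SUBJECT"]
      ahead <- tr$role == "COMPANION" & !is.na(tr$t_decision) &
        tr$t_decision < subj_t
      expect_equal(led$n_c[i],
                   as.integer(sum(tr$correct[ahead]) - sum(!tr$correct[ahead])))
    }
    # permutation equivariance: relabelling companion ids changes nothing
    dec_perm <- dec |>
      dplyr::group_by(trial_id) |>
      dplyr::mutate(fish_id = c(fish_id[1], sample(fish_id[-1]))) |>
      dplyr::ungroup()
    led_perm <- suppressMessages(build_social_ledger(dec_perm))
    expect_equal(led$n_c, led_perm$n_c)
  }
})

test_that("logistic social fit recovers parameters and matches glm", {
  set.seed(17)
  n_c <- sample(-5:9, 2000, replace = TRUE)
  p <- 1 / (1 + exp(-0.5 * (n_c - 0)))
  correct <- runif(2000) < p
  fit <- logistic_social_fit(n_c, correct)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 0.5), 0.1)
  # independent route: glm in the natural parameterization
  g <- glm(correct ~ n_c, family = binomial())
  expect_equal(fit$a, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(fit$b, unname(-coef(g)[1] / coef(g)[2]), tolerance = 1e-4)
  expect_equal(fit$se_a, sqrt(vcov(g)[2, 2]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  # likelihood is monotone over iterations and stationary at the optimum
  expect_true(all(diff(fit$ll_trace) >= -1e-10))
  phat <- plogis(fit$a * (n_c - fit$b))
  grad <- c(sum(correct - phat), sum((correct - phat) * n_c))
  expect_lt(sqrt(sum(grad^2)), 1e-6)
})

test_that("logistic fit evaluates the reported curve and flags separation", {
  expect_equal(social_logistic(0.52, 0.07, 0), 0.490901, tolerance = 1e-6)
  expect_equal(social_logistic(0.52, 0.07, 5), 0.9284819, tolerance = 1e-6)
  # complete separation must be flagged, not silently estimated
  n_c <- c(-3, -2, -1, 1, 2, 3)
  sep <- logistic_social_fit(n_c, n_c > 0)
  expect_false(sep$converged)
  expect_error(logistic_social_fit(c(1, 1, 1), c(TRUE, FALSE, TRUE)),
               "distinct")
})

test_that("null social feedback is rejected at the nominal rate", {
  set.seed(18)
  rejections <- replicate(60, {
    n_c <- sample(-4:6, 400, replace = TRUE)
    correct <- runif(400) < 0.6 # flat in n_c: true a = 0
    logistic_social_fit(n_c, correct)$p_a < 0.05
  })
  expect_lt(mean(rejections), 0.15) # near the nominal 5% type-I rate
})

test_that("singleton Nc levels can be merged into their neighbours", {
  set.seed(19)
  n_c <- c(rep(0, 50), rep(1, 50), rep(2, 50), 9)
  correct <- c(runif(150) < 0.6, TRUE)
  fit <- logistic_social_fit(n_c, correct, merge_singletons = TRUE)
  expect_equal(fit$n_merged, 1L)
})

test_that("power-law fit is exact on power-law input and scale-equivariant", {
  sizes <- c(1, 5, 10, 15)
  fit <- powerlaw_fit(sizes, 30 * sizes^-1)
  expect_equal(fit$exponent, -1)
  expect_equal(fit$r_squared, 1)
  flat <- powerlaw_fit(sizes, rep(4, 4))
  expect_equal(flat$exponent, 0)
  f1 <- powerlaw_fit(sizes, c(40, 9, 5, 3.4))
  f2 <- powerlaw_fit(sizes, 10 * c(40, 9, 5, 3.4))
  expect_equal(f1$exponent, f2$exponent)
  expect_equal(f2$intercept - f1$intercept, log(10))
  expect_equal(f1$r_squared, f2$r_squared)
  expect_error(powerlaw_fit(c(1, 5), c(2, 1)))
  expect_error(powerlaw_fit(sizes, c(1, 2, -1, 3)), "positive")
})

test_that("chi-square on 2x2 tables matches hand computation", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_2x2(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  skew <- matrix(c(20, 10, 10, 20), 2)
  res2 <- chi_square_2x2(skew)
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-9) # sum (O-E)^2/E
  expect_equal(res2$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("pearson correlation behaves at its boundary cases", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x), 1)
  set.seed(20)
  a <- rnorm(100)
  b <- residuals(lm(rnorm(100) ~ a)) # orthogonal to a by construction
  expect_lt(abs(pearson_r(a, b)), 1e-12)
  z <- cbind(rnorm(1e5), rnorm(1e5))
  y <- 0.3 * z[, 1] + sqrt(1 - 0.09) * z[, 2]
  expect_equal(pearson_r(z[, 1], y), 0.3, tolerance = 0.012)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("accuracy regression detects injected effects and respects the null", {
  set.seed(21)
  n <- 600
  d_null <- tibble::tibble(
    subject_id = rep(1:20, each = 30),
    delta_v = sample(c(1, 10), n, replace = TRUE),
    correct = runif(n) < 0.6
  )
  r0 <- accuracy_regression(d_null, "delta_v", n_perm = 200)
  expect_false(r0$separation)
  expect_gt(r0$perm_p, 0.01)

  d_eff <- d_null
  d_eff$correct <- runif(n) < ifelse(d_eff$delta_v == 10, 0.85, 0.45)
  r1 <- accuracy_regression(d_eff, "delta_v", n_perm = 200)
  z1 <- r1$coefficients[r1$coefficients$term == "delta_v", ]
  expect_gt(z1$estimate, 0)
  expect_lt(z1$p_value, 0.001)
  expect_lt(r1$perm_p, 0.02)

  # single balanced binary factor: coefficient is the log-odds difference
  d_bal <- tibble::tibble(
    subject_id = 1,
    fast = rep(c(0, 1), each = 200),
    correct = c(runif(200) < 0.5, runif(200) < 0.8)
  )
  r2 <- accuracy_regression(d_bal, "fast")
  p0 <- mean(d_bal$correct[d_bal$fast == 0])
  p1 <- mean(d_bal$correct[d_bal$fast == 1])
  est <- r2$coefficients$estimate[r2$coefficients$term == "fast"]
  expect_equal(est, qlogis(p1) - qlogis(p0), tolerance = 1e-6)
})

test_that("holm adjustment is applied by default", {
  p <- c(0.01, 0.04, 0.03)
  expect_equal(adjust_p(p), p.adjust(p, "holm"))
  expect_equal(adjust_p(p, "bonferroni"), p.adjust(p, "bonferroni"))
})
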