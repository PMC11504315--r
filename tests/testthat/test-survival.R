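test_that("the product-limit estimator matches hand computations", {
  # no events: survival stays at 1
  none <- km_estimate(data.frame(time = c(5, 10, 15), event = FALSE))
  expect_true(all(none$table$survival == 1))

  # one event among four: S drops to 3/4
  one <- km_estimate(data.frame(time = c(5, 6, 7, 8),
                                event = c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(one$table$survival[one$table$time == 5], 0.75)

  # times {2, 4+, 6, 8+, 10}: S = 0.8, 0.8*(2/3), then 0
  km <- km_estimate(data.frame(time = c(2, 4, 6, 8, 10),
                               event = c(TRUE, FALSE, TRUE, FALSE, TRUE)))
  s <- km$table$survival[km$table$n_event > 0]
  expect_equal(s, c(0.8, 0.8 * 2 / 3, 0), tolerance = 1e-9)
  expect_true(all(diff(km$table$survival) <= 0))
  expect_error(km_estimate(data.frame(time = numeric(), event = logical())),
               "no observations")
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(501)
  t <- sample(1:40, 25, replace = TRUE)
  km <- km_estimate(data.frame(time = t, event = TRUE))
  for (i in seq_len(nrow(km$table))) {
    expect_equal(km$table$survival[i], mean(t > km$table$time[i]))
  }
})

test_that("the log-rank test matches a manual risk-set tabulation", {
  # identical groups: no signal
  base <- data.frame(time = c(3, 5, 8, 12), event = c(TRUE, TRUE, FALSE, TRUE))
  both <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  same <- log_rank_test(both)
  expect_lt(same$chi_square, 1e-10)
  expect_gt(same$p_value, 0.999)

  # 6-subject worked example, tie-free: manual O-E / V accumulation
  obs <- data.frame(time = c(1, 3, 5, 2, 4, 6),
                    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                    group = rep(c("a", "b"), each = 3))
  got <- log_rank_test(obs)
  manual <- manual_log_rank(obs$time, obs$event, obs$group == "a")
  expect_equal(got$chi_square, manual, tolerance = 1e-6)
  expect_equal(got$p_value, pchisq(manual, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  # invariant under swapping the group labels
  swapped <- obs
  swapped$group <- ifelse(obs$group == "a", "b", "a")
  expect_equal(log_rank_test(swapped)$chi_square, got$chi_square)

  expect_error(log_rank_test(data.frame(time = 1:3, event = TRUE,
                                        group = "a")), "two groups")
  expect_error(log_rank_test(data.frame(time = 1:4, event = FALSE,
                                        group = rep(c("a", "b"), 2))),
               "zero events")
})

test_that("the Cox fit agrees with direct partial-likelihood maximization", {
  # tie-free toy data; Breslow ties so the log partial likelihood is simple
  obs <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                    x = c(1, 0, 1, 1, 0, 0))
  log_pl <- function(beta) {
    ll <- 0
    for (i in which(obs$event)) {
      risk <- obs$time >= obs$time[i]
      ll <- ll + beta * obs$x[i] - log(sum(exp(beta * obs$x[risk])))
    }
    ll
  }
  beta_hat <- optimize(log_pl, c(-10, 10), maximum = TRUE)$maximum
  fit <- cox_fit(obs, "x", ties = "breslow")
  expect_equal(fit$coefficients$coef[1], beta_hat, tolerance = 1e-4)
  expect_equal(fit$coefficients$hazard_ratio[1], exp(beta_hat), tolerance = 1e-4)
  expect_true(fit$coefficients$ci_low[1] <= fit$coefficients$hazard_ratio[1])
  expect_true(fit$coefficients$ci_high[1] >= fit$coefficients$hazard_ratio[1])
})

test_that("the Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(503)
  t <- sort(sample(seq(1, 500), 40))   # distinct times, no ties
  obs <- data.frame(time = t,
                    event = runif(40) < 0.7,
                    group = sample(c("a", "b"), 40, replace = TRUE))
  obs$x <- as.integer(obs$group == "b")
  fit <- cox_fit(obs, "x")
  score_chi <- summary(fit$fit)$sctest[["test"]]
  expect_equal(score_chi, log_rank_test(obs)$chi_square, tolerance = 1e-6)
})

test_that("the Cox fit recovers a known two-group hazard ratio", {
  set.seed(504)
  n <- 1000
  x <- rep(0:1, each = n / 2)
  t_event <- rexp(n, rate = 0.05 * 2^x)      # true HR = 2
  cens <- rexp(n, rate = 0.0125)             # ~20% censoring
  obs <- data.frame(time = pmin(t_event, cens), event = t_event <= cens, x = x)
  fit <- cox_fit(obs, "x")
  expect_gt(fit$coefficients$hazard_ratio[1], 1.8)
  expect_lt(fit$coefficients$hazard_ratio[1], 2.2)
  expect_error(cox_fit(data.frame(time = 1:4, event = c(TRUE, TRUE, FALSE, FALSE),
                                  x = 1), "x"), "constant covariate")
})

test_that("monotone likelihood is surfaced as a diagnostic, not an error", {
  obs <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    x = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(obs, "x")
  expect_true(length(fit$diagnostics) > 0)
})

test_that("UVA p-value filtering is strict at the threshold", {
  p <- c(eNOS = 0.001, PSA = 0.561, x = 0.10, itgb4 = 0.097)
  expect_equal(uva_filter(p), c("eNOS", "itgb4"))
  expect_equal(uva_filter(c(a = 0.5)), character(0))
})

test_that("PFS assembly requires follow-up times for censored patients", {
  cohort <- table1_cohort()
  expect_error(pfs_observations(cohort), "follow_up_time")
  cohort$follow_up_time <- ifelse(cohort$recurrence, NA, 48)
  obs <- pfs_observations(cohort)
  expect_equal(nrow(obs), 30L)
  expect_equal(sum(obs$event), 8L)
  expect_equal(obs$time[obs$event], c(4, 6, 12, 36, 4, 7, 7, 8))
  expect_true(all(obs$time[!obs$event] == 48))
})
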