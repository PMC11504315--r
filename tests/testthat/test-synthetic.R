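test_that("configuration validation rejects infeasible settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(event_fraction_target = 0), "event_fraction_target")
  expect_error(sim_config(follow_up_window = c(72, 36)), "follow_up_window")
  expect_error(sim_config(hazard_ratio_per_flag = 0), "hazard_ratio_per_flag")
  expect_error(sim_config(latent_loading = 1), "latent_loading")
  expect_error(sim_config(prevalence = c(enos = 0.4)), "all five markers")
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(sim_config(seed = 99))
  b <- generate_cohort(sim_config(seed = 99))
  expect_identical(a, b)
  c <- generate_cohort(sim_config(seed = 100))
  expect_false(identical(a$markers, c$markers))
})

test_that("generated data satisfy the panel and cohort invariants", {
  sim <- generate_cohort(sim_config(n_patients = 200, seed = 5))
  attainable <- sort(unique(as.vector(outer(0:3, 0:4))))
  for (col in c("enos_ihc", "hif2a_ihc", "itgb4_ihc")) {
    expect_true(all(sim$markers[[col]] %in% attainable))
  }
  expect_true(all(is.finite(sim$markers$h19_norm) & sim$markers$h19_norm >= 0))
  expect_true(all(is.finite(sim$markers$cdh1_norm) & sim$markers$cdh1_norm >= 0))
  expect_true(all(sim$cohort$psa >= 1.79 & sim$cohort$psa <= 18.5))
  expect_true(all(sim$cohort$gleason_total %in% c(6, 7, 9)))
  # observed times: events carry recurrence times, censored carry follow-up
  expect_true(all(sim$cohort$time_to_recurrence[sim$cohort$recurrence] > 0))
  expect_true(all(is.na(sim$cohort$follow_up_time[sim$cohort$recurrence])))
  expect_true(all(sim$cohort$follow_up_time[!sim$cohort$recurrence] <= 72))
  # marker values land on the flag's side of each published cut-off
  rules <- default_bioscore_rules()
  flags_from_values <- sapply(names(rules), function(nm) {
    apply_rule(rules[[nm]], sim$markers[[rules[[nm]]$marker]])
  })
  expect_equal(unname(flags_from_values), unname(sim$flags))
})

test_that("flag prevalence matches the configured rates in large cohorts", {
  cfg <- sim_config(n_patients = 3000, seed = 17)
  sim <- generate_cohort(cfg)
  se3 <- 3 * sqrt(0.4 * 0.6 / 3000)
  for (m in colnames(sim$flags)) {
    expect_lt(abs(mean(sim$flags[, m]) - 0.4), se3)
  }
  # the shared latent variable induces positive flag correlation
  expect_gt(mean(cor(sim$flags)[lower.tri(diag(5))]), 0.1)
})

test_that("a null panel carries no prognostic signal", {
  cfg <- sim_config(hazard_ratio_per_flag = 1, n_patients = 30)
  aucs <- vapply(1:200, function(r) {
    sim <- generate_cohort(cfg, seed = 6000 + r)
    if (sum(sim$cohort$recurrence) %in% c(0, nrow(sim$cohort))) return(NA_real_)
    scores <- compute_bioscore(sim$markers)
    empirical_auc(scores$score, sim$cohort$recurrence)
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.02)
})

test_that("stronger per-flag hazards raise the score among progressors", {
  mean_event_score <- function(hr) {
    cfg <- sim_config(hazard_ratio_per_flag = hr)
    s <- 0; n <- 0
    for (r in 1:150) {
      sim <- generate_cohort(cfg, seed = 7000 + r)
      ev <- sim$cohort$recurrence
      if (!any(ev)) next
      s <- s + sum(compute_bioscore(sim$markers)$score[ev])
      n <- n + sum(ev)
    }
    s / n
  }
  expect_gt(mean_event_score(4), mean_event_score(1) + 0.3)
})

test_that("simulated cohorts round-trip through the CSV schemas", {
  sim <- generate_cohort(sim_config(seed = 3))
  fc <- tempfile(fileext = ".csv"); fm <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, fc)
  write_markers(sim$markers, fm)
  cohort2 <- read_cohort(fc)
  markers2 <- read_markers(fm)
  expect_equal(cohort2$psa, sim$cohort$psa)
  expect_equal(cohort2$recurrence, sim$cohort$recurrence)
  expect_equal(cohort2$follow_up_time, sim$cohort$follow_up_time)
  expect_equal(cohort2$gleason_primary, sim$cohort$gleason_primary)
  expect_equal(markers2$enos_ihc, sim$markers$enos_ihc)
  expect_equal(markers2$h19_norm, sim$markers$h19_norm)
})

test_that("YAML configs map onto the generator settings", {
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yml")
  writeLines(c("n_patients: 12", "seed: 4", "hazard_ratio_per_flag: 2.0",
               "prevalence:", "  enos: 0.3", "  hif2a: 0.3", "  itgb4: 0.3",
               "  h19: 0.3", "  cdh1: 0.3"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$n_patients, 12L)
  expect_equal(cfg$hazard_ratio_per_flag, 2)
  expect_equal(unname(cfg$prevalence), rep(0.3, 5))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("the recovery experiment is reproducible and robust to failures", {
  cfg <- sim_config(n_patients = 24)
  one <- recovery_experiment(cfg, replicates = 1, seed = 42)
  two <- recovery_experiment(cfg, replicates = 1, seed = 42)
  expect_identical(one, two)
  expect_equal(nrow(one), 1L)
  res <- recovery_experiment(cfg, replicates = 5, seed = 10)
  expect_equal(nrow(res), 5L)
  expect_true(all(is.na(res$error) | nzchar(res$error)))
  expect_true(is.data.frame(attr(res, "summary")))
})
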