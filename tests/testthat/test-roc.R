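test_that("empirical AUC matches the all-pairs definition on anchor cases", {
  expect_equal(empirical_auc(c(1, 2, 3, 7, 8, 9),
                             c(rep(FALSE, 3), rep(TRUE, 3))), 1)
  expect_equal(empirical_auc(rep(2, 10), c(rep(TRUE, 4), rep(FALSE, 6))), 0.5)
  cohort <- table1_cohort()
  # brute-force pair count over the printed table: 70 wins out of 8 x 22 pairs
  expect_equal(empirical_auc(cohort$psa, cohort$recurrence), 70 / 176)
  expect_error(empirical_auc(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("empirical AUC equals rank-based and brute-force oracles", {
  set.seed(301)
  for (i in 1:200) {
    inst <- random_roc_instance()
    auc <- empirical_auc(inst$values, inst$labels)
    expect_equal(auc, brute_force_auc(inst$values, inst$labels))
    # Mann-Whitney U oracle: wilcox.test's W counts event > non-event pairs
    w <- suppressWarnings(wilcox.test(inst$values[inst$labels],
                                      inst$values[!inst$labels]))$statistic
    expect_equal(auc, unname(w) / (sum(inst$labels) * sum(!inst$labels)))
    # complement identity
    expect_equal(auc + empirical_auc(-inst$values, inst$labels), 1)
  }
})

test_that("dichotomized AUC reproduces the printed clinical rows exactly", {
  cohort <- table1_cohort()
  psa <- binary_auc_at_cutoff(cohort$psa, cohort$recurrence,
                              cutoff_rule("PSA", 6.3, "at_or_above"))
  expect_equal(round(psa$auc, 3), 0.568)
  expect_true(psa$flipped)            # low PSA tracks progression in this cohort
  expect_equal(psa$rule$direction, "below")
  expect_equal(psa$auc, (psa$sensitivity + psa$specificity) / 2)

  pgs_pos <- vapply(cohort$pathologic_gleason, gleason_at_least_4_3, logical(1))
  pgs <- binary_auc_at_cutoff(as.numeric(pgs_pos), cohort$recurrence,
                              cutoff_rule("pGS", 1, "at_or_above"))
  expect_equal(round(pgs$auc, 3), 0.716)
  expect_false(pgs$flipped)
  expect_equal(pgs$sensitivity, 6 / 8)
  expect_equal(pgs$specificity, 15 / 22)
})

test_that("dichotomized AUC auto-flip and degenerate rules behave", {
  set.seed(302)
  for (i in 1:50) {
    inst <- random_roc_instance()
    thr <- sample(inst$values, 1)
    res <- binary_auc_at_cutoff(inst$values, inst$labels,
                                cutoff_rule("m", thr, "at_or_above"))
    expect_gte(res$auc, 0.5)
    expect_equal(res$auc, (res$sensitivity + res$specificity) / 2)
    # flipped rule applied directly reproduces the reported sens/spec
    pos <- apply_rule(res$rule, inst$values)
    expect_equal(mean(pos[inst$labels]), res$sensitivity)
  }
  # a rule selecting everyone positive is uninformative
  res <- binary_auc_at_cutoff(c(5, 6, 7, 8), c(TRUE, TRUE, FALSE, FALSE),
                              cutoff_rule("m", 0, "at_or_above"))
  expect_equal(res$auc, 0.5)
  expect_equal(res$sensitivity + res$specificity, 1)
})

test_that("Youden-optimal cut-off equals the exhaustive maximizer", {
  # perfect separation: events low, non-events high
  sep <- optimal_cutoff(c(1, 2, 3, 7, 8, 9),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$rule$direction, "at_or_below")
  expect_equal(sep$rule$threshold, 3)

  expect_warning(deg <- optimal_cutoff(rep(4, 8), c(rep(TRUE, 3), rep(FALSE, 5))),
                 "degenerate")
  expect_equal(deg$youden_j, 0)

  set.seed(303)
  for (i in 1:200) {
    inst <- random_roc_instance(20)
    got <- optimal_cutoff(inst$values, inst$labels)
    expect_equal(got$youden_j, brute_force_best_youden(inst$values, inst$labels))
    # the returned rule reproduces its own operating point
    pos <- apply_rule(got$rule, inst$values)
    expect_equal(mean(pos[inst$labels]) + mean(!pos[!inst$labels]) - 1,
                 got$youden_j)
  }
})

test_that("Youden ties break toward higher specificity then smaller threshold", {
  # two rules reach J = 0.5; the one with specificity 1 wins
  got <- optimal_cutoff(c(1, 2, 8, 9), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(got$youden_j, 0.5)
  expect_equal(got$specificity, 1)
  expect_equal(got$rule$threshold, 1)
  expect_equal(got$rule$direction, "at_or_below")

  # equal J and specificity: the smaller threshold is returned
  got2 <- optimal_cutoff(c(1, 1, 2, 2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(got2$youden_j, 0)
  expect_equal(got2$specificity, 0.5)
  expect_equal(got2$rule$threshold, 1)
})

test_that("bootstrap intervals are deterministic and consistent", {
  v <- c(rnorm(15, 2), rnorm(15))
  l <- c(rep(TRUE, 15), rep(FALSE, 15))
  ci1 <- auc_confidence_interval(v, l, B = 500, seed = 9)
  ci2 <- auc_confidence_interval(v, l, B = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= ci1[2])
  expect_error(auc_confidence_interval(v, l, B = 100), "B >= 200")

  # perfectly separated large sample: interval hugs 1
  v2 <- c(seq(10, 11, length.out = 60), seq(1, 2, length.out = 60))
  l2 <- c(rep(TRUE, 60), rep(FALSE, 60))
  ci <- auc_confidence_interval(v2, l2, B = 300, seed = 1)
  expect_equal(unname(ci), c(1, 1))
})

test_that("DeLong intervals agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(304)
  for (i in 1:25) {
    inst <- random_roc_instance(40)
    ci <- auc_confidence_interval(inst$values, inst$labels, method = "delong")
    ref <- suppressMessages(pROC::ci.auc(
      pROC::roc(inst$labels, inst$values, direction = "<", quiet = TRUE),
      method = "delong"))
    expect_equal(ci[1], max(0, ref[1]), tolerance = 1e-8)
    expect_equal(ci[2], min(1, ref[3]), tolerance = 1e-8)
  }
  expect_error(auc_confidence_interval(c(1, 2, 3), c(TRUE, FALSE, FALSE),
                                       method = "delong"), "at least 2")
})

test_that("the AUC p-value tracks the exact Mann-Whitney test", {
  expect_equal(auc_p_value(rep(1, 12), c(rep(TRUE, 5), rep(FALSE, 7))), 1)
  v <- c(11:30, 1:20 / 10)
  l <- c(rep(TRUE, 20), rep(FALSE, 20))
  expect_lt(auc_p_value(v, l), 0.001)

  # within 10% relative of the exact rank enumeration for small tie-free data
  set.seed(305)
  for (i in 1:40) {
    n1 <- sample(4:10, 1); n0 <- sample(4:10, 1)
    v <- sample(seq_len(200), n1 + n0)      # distinct -> exact test available
    l <- c(rep(TRUE, n1), rep(FALSE, n0))
    p_norm <- auc_p_value(v, l)
    p_exact <- wilcox.test(v[l], v[!l], exact = TRUE)$p.value
    if (p_exact > 0.05) expect_lt(abs(p_norm - p_exact) / p_exact, 0.10)
  }
})

test_that("DeLong interval coverage is nominal under a null AUC", {
  # true AUC = 0.5, n1 = n0 = 50: 95% interval should cover in (92%, 98%)
  set.seed(306)
  l <- c(rep(TRUE, 50), rep(FALSE, 50))
  hits <- 0
  for (i in 1:1000) {
    v <- rnorm(100)
    ci <- auc_confidence_interval(v, l, method = "delong")
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / 1000, 0.92)
  expect_lt(hits / 1000, 0.98)
})
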