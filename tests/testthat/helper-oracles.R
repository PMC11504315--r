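# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (pair counting, exhaustive scans, manual
# risk-set tabulation) rather than reusing package internals.

# All-pairs AUC by explicit double loop over (event, non-event) pairs.
brute_force_auc <- function(values, labels) {
  ev <- values[labels]
  ne <- values[!labels]
  total <- 0
  for (a in ev) {
    for (b in ne) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(ev) * length(ne))
}

# Exhaustive Youden maximum over every observed threshold and direction.
brute_force_best_youden <- function(values, labels) {
  best <- -Inf
  for (thr in unique(values)) {
    for (dir in c("ge", "le")) {
      pos <- if (dir == "ge") values >= thr else values <= thr
      j <- mean(pos[labels]) + mean(!pos[!labels]) - 1
      if (j > best) best <- j
    }
  }
  best
}

# Manual one-df log-rank tabulation: observed minus expected events in group 1
# accumulated over distinct event times, with the hypergeometric variance.
manual_log_rank <- function(time, event, group1) {
  u <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group1)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}

# Random two-class marker instance with ties possible.
random_roc_instance <- function(n_max = 50) {
  n1 <- sample(2:(n_max / 2), 1)
  n0 <- sample(2:(n_max / 2), 1)
  pool <- if (runif(1) < 0.5) sample(1:8, n1 + n0, replace = TRUE) else
    round(rnorm(n1 + n0), 1)
  list(values = pool, labels = c(rep(TRUE, n1), rep(FALSE, n0)))
}

table1_cohort <- function() read_cohort(table1_path())

# Simulated cohort CSV/marker CSV paths for IO round trips.
write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
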