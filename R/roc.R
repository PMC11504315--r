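# Run code with a temporary RNG state so seeded helpers do not disturb the
# caller's stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Define a marker dichotomization rule
#'
#' A cut-off rule maps a marker value to "dysregulated = TRUE" via an
#' explicit threshold and inequality direction. The direction is always
#' stated, never inferred when the rule is applied.
#'
#' @param marker Marker name.
#' @param threshold Finite numeric threshold, in the marker's units.
#' @param direction One of \code{"at_or_above"} (\code{>=}), \code{"above"}
#'   (\code{>}), \code{"at_or_below"} (\code{<=}), \code{"below"}
#'   (\code{<}).
#' @return A \code{cutoff_rule} object.
#' @examples
#' cutoff_rule("PSA", 6.3, "at_or_above")
#' @export
cutoff_rule <- function(marker, threshold,
                        direction = c("at_or_above", "above", "at_or_below", "below")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  structure(list(marker = marker, threshold = as.numeric(threshold),
                 direction = direction),
            class = "cutoff_rule")
}

#' @export
format.cutoff_rule <- function(x, ...) {
  op <- c(at_or_above = ">=", above = ">", at_or_below = "<=", below = "<")[x$direction]
  sprintf("%s %s %g", x$marker, op, x$threshold)
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat("Cut-off rule:", format(x), "\n")
  invisible(x)
}

#' Apply a cut-off rule to marker values
#'
#' @param rule A \code{\link{cutoff_rule}}.
#' @param values Numeric marker values.
#' @return Logical vector: TRUE where the value counts as dysregulated.
#' @export
apply_rule <- function(rule, values) {
  stopifnot(inherits(rule, "cutoff_rule"))
  switch(rule$direction,
         at_or_above = values >= rule$threshold,
         above       = values >  rule$threshold,
         at_or_below = values <= rule$threshold,
         below       = values <  rule$threshold)
}

# Logical complement of a rule: !(x >= t) is (x < t), etc.
.flip_rule <- function(rule) {
  flipped <- c(at_or_above = "below", above = "at_or_below",
               at_or_below = "above", below = "at_or_above")[rule$direction]
  cutoff_rule(rule$marker, rule$threshold, flipped)
}

.check_two_classes <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop("values and labels must have equal length", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (any(is.na(values)) || any(is.na(labels))) {
    stop("missing values are not allowed in ROC computations", call. = FALSE)
  }
  if (!any(labels) || all(labels)) {
    stop("AUC undefined: both event and non-event classes must be non-empty",
         call. = FALSE)
  }
  labels
}

#' Empirical (all-pairs) area under the ROC curve
#'
#' Nonparametric AUC by the all-pairs estimator: over every (event,
#' non-event) pair, score 1 when the event value is larger, 0.5 when tied,
#' then divide by the number of pairs. Orientation is fixed:
#' higher values predict the event. This equals the Mann-Whitney U statistic
#' divided by \eqn{n_1 n_0} and the probability that a random event patient
#' outranks a random non-event patient.
#'
#' @param values Numeric marker values, one per patient.
#' @param labels Logical event indicators (TRUE = progression).
#' @return AUC in [0, 1].
#' @examples
#' empirical_auc(c(1, 2, 3, 7, 8, 9), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' @export
empirical_auc <- function(values, labels) {
  labels <- .check_two_classes(values, labels)
  ev <- values[labels]
  ne <- values[!labels]
  cmp <- outer(ev, ne, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp) / (length(ev) * length(ne))
}

#' Dichotomized-test AUC at a fixed cut-off
#'
#' Dichotomizes the marker by a cut-off rule and evaluates it as a binary
#' test against the observed events: sensitivity = P(positive | event),
#' specificity = P(negative | no event), and AUC = (sensitivity +
#' specificity) / 2, the exact area under the single-bend ROC of a binary
#' test. When that AUC falls below 0.5 the rule's direction is reversed and
#' the complementary AUC reported; the returned rule records the effective
#' direction and \code{flipped} marks the reversal.
#'
#' @param values Numeric marker values.
#' @param labels Logical event indicators.
#' @param rule A \code{\link{cutoff_rule}}.
#' @param auto_flip Reverse the rule when AUC < 0.5 (default TRUE).
#' @return An object of class \code{roc_result}: list with \code{auc},
#'   \code{sensitivity}, \code{specificity}, \code{youden_j}, \code{rule}
#'   (effective), \code{flipped}, \code{n_event}, \code{n_nonevent}.
#' @examples
#' cohort <- read_cohort(table1_path())
#' binary_auc_at_cutoff(cohort$psa, cohort$recurrence,
#'                      cutoff_rule("PSA", 6.3, "at_or_above"))
#' @export
binary_auc_at_cutoff <- function(values, labels, rule, auto_flip = TRUE) {
  labels <- .check_two_classes(values, labels)
  pos <- apply_rule(rule, values)
  sens <- mean(pos[labels])
  spec <- mean(!pos[!labels])
  auc <- (sens + spec) / 2
  flipped <- FALSE
  if (auto_flip && auc < 0.5) {
    rule <- .flip_rule(rule)
    sens <- 1 - sens
    spec <- 1 - spec
    auc <- 1 - auc
    flipped <- TRUE
  }
  structure(list(auc = auc, sensitivity = sens, specificity = spec,
                 youden_j = sens + spec - 1, rule = rule, flipped = flipped,
                 n_event = sum(labels), n_nonevent = sum(!labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Binary-test ROC at cut-off [%s]%s\n", format(x$rule),
              if (isTRUE(x$flipped)) " (direction auto-flipped)" else ""))
  cat(sprintf("  AUC %.3f  sensitivity %.3f  specificity %.3f  (J = %.3f)\n",
              x$auc, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Youden-optimal cut-off selection
#'
#' Scans every observed marker value as a candidate threshold in both
#' dichotomization directions (\code{at_or_above} and \code{at_or_below})
#' and returns the rule maximizing the Youden index J = sensitivity +
#' specificity - 1. Ties are broken by higher specificity, then smaller
#' threshold, then direction (\code{at_or_above} first). When every value is
#' identical no cut-off separates the classes; a degenerate rule with J = 0
#' is returned with a warning.
#'
#' @param values Numeric marker values.
#' @param labels Logical event indicators.
#' @param marker Marker name recorded in the returned rule.
#' @return A list with \code{rule} (\code{\link{cutoff_rule}}),
#'   \code{youden_j}, \code{sensitivity}, \code{specificity}.
#' @export
optimal_cutoff <- function(values, labels, marker = "marker") {
  labels <- .check_two_classes(values, labels)
  candidates <- sort(unique(values))
  if (length(candidates) == 1L) {
    warning("all marker values identical; returning degenerate rule with J = 0")
    res <- binary_auc_at_cutoff(values, labels,
                                cutoff_rule(marker, candidates, "at_or_above"),
                                auto_flip = FALSE)
    return(list(rule = res$rule, youden_j = res$youden_j,
                sensitivity = res$sensitivity, specificity = res$specificity))
  }
  best <- NULL
  for (dir in c("at_or_above", "at_or_below")) {
    for (thr in candidates) {
      pos <- if (dir == "at_or_above") values >= thr else values <= thr
      sens <- mean(pos[labels]); spec <- mean(!pos[!labels])
      j <- sens + spec - 1
      better <- is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
           (spec > best$specificity + 1e-12 ||
              (abs(spec - best$specificity) <= 1e-12 && thr < best$rule$threshold)))
      if (better) {
        best <- list(rule = cutoff_rule(marker, thr, dir), youden_j = j,
                     sensitivity = sens, specificity = spec)
      }
    }
  }
  best
}

#' Confidence interval for the empirical AUC
#'
#' Two interval methods: a class-stratified percentile bootstrap (events and
#' non-events resampled with replacement separately, so every resample
#' retains both classes) and the DeLong variance-based normal interval.
#' The bootstrap is deterministic given \code{seed}.
#'
#' @param values Numeric marker values.
#' @param labels Logical event indicators.
#' @param method \code{"bootstrap"} (default) or \code{"delong"}.
#' @param B Bootstrap replicates (>= 200); default 2000.
#' @param seed Integer seed for the bootstrap; default 1.
#' @param conf Confidence level; default 0.95.
#' @return Numeric vector \code{c(low, high)}.
#' @export
auc_confidence_interval <- function(values, labels,
                                    method = c("bootstrap", "delong"),
                                    B = 2000, seed = 1, conf = 0.95) {
  method <- match.arg(method)
  labels <- .check_two_classes(values, labels)
  ev <- values[labels]; ne <- values[!labels]
  alpha <- (1 - conf) / 2
  if (method == "bootstrap") {
    if (B < 200) stop("bootstrap needs B >= 200", call. = FALSE)
    stats_b <- .with_seed(seed, {
      vapply(seq_len(B), function(b) {
        e <- sample(ev, replace = TRUE)
        n <- sample(ne, replace = TRUE)
        empirical_auc(c(e, n), c(rep(TRUE, length(e)), rep(FALSE, length(n))))
      }, numeric(1))
    })
    unname(stats::quantile(stats_b, c(alpha, 1 - alpha), type = 7))
  } else {
    if (length(ev) < 2L || length(ne) < 2L) {
      stop("DeLong interval needs at least 2 patients per class", call. = FALSE)
    }
    auc <- empirical_auc(values, labels)
    # placement values: per-event mean win rate over non-events and vice versa
    psi <- outer(ev, ne, function(a, b) (a > b) + 0.5 * (a == b))
    v10 <- rowMeans(psi)
    v01 <- colMeans(psi)
    se <- sqrt(stats::var(v10) / length(ev) + stats::var(v01) / length(ne))
    z <- stats::qnorm(1 - alpha)
    c(max(0, auc - z * se), min(1, auc + z * se))
  }
}

#' Two-sided p-value for AUC = 0.5
#'
#' Normal-approximation Mann-Whitney test of the null that the marker does
#' not discriminate (AUC = 0.5), with the standard tie correction to the
#' rank variance and a continuity correction (needed for close agreement
#' with the exact rank test at small sample sizes). When all values are
#' tied the variance vanishes and p = 1.
#'
#' @param values Numeric marker values.
#' @param labels Logical event indicators.
#' @return Two-sided p-value.
#' @export
auc_p_value <- function(values, labels) {
  labels <- .check_two_classes(values, labels)
  n1 <- sum(labels); n0 <- sum(!labels); n <- n1 + n0
  u <- empirical_auc(values, labels) * n1 * n0
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n0 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  shift <- u - n1 * n0 / 2
  z <- (shift - sign(shift) * 0.5) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}
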