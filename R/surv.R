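#' Assemble progression-free-survival observations
#'
#' Builds the (time, event) pairs for PFS analysis from a cohort: recurrent
#' patients contribute their time of recurrence as an event; censored
#' patients contribute their follow-up time, which must be supplied (the
#' clinical table prints recurrence times only, so censoring times come from
#' an explicit \code{follow_up_time} column or the synthetic generator).
#'
#' @param cohort A \code{cohort} data frame with \code{recurrence},
#'   \code{time_to_recurrence} and, for censored patients,
#'   \code{follow_up_time}.
#' @return Data frame with \code{patient_id}, \code{time} (months),
#'   \code{event} (logical).
#' @export
pfs_observations <- function(cohort) {
  if (is.null(cohort$follow_up_time) && any(!cohort$recurrence)) {
    stop("censored patients lack follow_up_time; survival analysis needs it",
         call. = FALSE)
  }
  time <- ifelse(cohort$recurrence, cohort$time_to_recurrence,
                 cohort$follow_up_time)
  if (any(is.na(time))) {
    stop("missing follow-up time for censored patient(s): ",
         paste(cohort$patient_id[is.na(time)], collapse = ", "), call. = FALSE)
  }
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  data.frame(patient_id = cohort$patient_id, time = time,
             event = cohort$recurrence, stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator with log-log confidence bands, optionally
#' stratified by group. Fitting is delegated to
#' \code{survival::survfit}; the returned table exposes the step function
#' (time, at-risk count, events, S(t), bands) in plain columns.
#'
#' @param observations Data frame with \code{time}, \code{event} and
#'   optionally \code{group}.
#' @param conf Confidence level; default 0.95.
#' @return A list of class \code{km_curve}: \code{table} (data frame with
#'   \code{group} when stratified, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{survival}, \code{ci_low}, \code{ci_high}) and the
#'   underlying \code{survfit} object as \code{fit}.
#' @examples
#' obs <- data.frame(time = c(2, 4, 6, 8, 10),
#'                   event = c(TRUE, FALSE, TRUE, FALSE, TRUE))
#' km_estimate(obs)$table$survival  # 0.8, 0.5333, 0
#' @export
km_estimate <- function(observations, conf = 0.95) {
  if (!nrow(observations)) stop("no observations", call. = FALSE)
  if (any(observations$time <= 0)) stop("survival times must be positive",
                                        call. = FALSE)
  has_group <- !is.null(observations$group)
  fml <- if (has_group) {
    survival::Surv(time, event) ~ group
  } else {
    survival::Surv(time, event) ~ 1
  }
  fit <- survival::survfit(fml, data = observations, conf.type = "log-log",
                           conf.int = conf)
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    survival = s$surv, ci_low = s$lower, ci_high = s$upper)
  if (has_group) tab <- cbind(group = sub("^group=", "", as.character(s$strata)), tab)
  structure(list(table = tab, fit = fit), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier progression-free survival\n")
  print(utils::head(x$table, 12), row.names = FALSE)
  if (nrow(x$table) > 12) cat("  ...", nrow(x$table) - 12, "more rows\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank comparison of survival between
#' two groups, via \code{survival::survdiff}.
#'
#' @param observations Data frame with \code{time}, \code{event},
#'   \code{group} (exactly two distinct values).
#' @return List with \code{chi_square}, \code{p_value}, \code{df} and the
#'   per-group observed/expected event table \code{table}.
#' @export
log_rank_test <- function(observations, group = observations$group) {
  if (is.null(group)) stop("log-rank test needs a group column", call. = FALSE)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two groups", call. = FALSE)
  if (!any(observations$event)) {
    stop("log-rank test undefined with zero events", call. = FALSE)
  }
  d <- data.frame(time = observations$time, event = observations$event, g = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(chi_square = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L,
       table = data.frame(group = levels(g), n = as.vector(sd$n),
                          observed = sd$obs, expected = sd$exp))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via \code{survival::coxph} (Newton-Raphson; Efron
#' tie handling by default, appropriate for months-resolution times with
#' ties; Breslow available for cross-checking). Reports per-covariate hazard
#' ratios with Wald 95\% confidence intervals and p-values. Monotone
#' likelihood (perfect separation) is surfaced as a convergence warning in
#' \code{diagnostics}.
#'
#' @param observations Data frame with \code{time}, \code{event} and the
#'   covariate columns named in \code{covariates}.
#' @param covariates Character vector of covariate column names.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return A list of class \code{cox_fit}: \code{coefficients} (data frame
#'   with term, coef, hazard_ratio, ci_low, ci_high, se, p), \code{ties},
#'   \code{n}, \code{n_event}, \code{diagnostics}, and the underlying
#'   \code{coxph} fit as \code{fit}.
#' @export
cox_fit <- function(observations, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!any(observations$event)) stop("Cox model needs at least one event",
                                     call. = FALSE)
  for (cv in covariates) {
    v <- observations[[cv]]
    if (is.null(v)) stop("missing covariate column: ", cv, call. = FALSE)
    if (length(unique(v)) < 2L) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  diagnostics <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = observations, ties = ties),
    warning = function(w) {
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hazard_ratio = exp(co[, "coef"]),
                    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    se = co[, "se(coef)"],
                    p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = out, ties = ties, n = sm$n,
                 n_event = sm$nevent, diagnostics = diagnostics, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d patients, %d events\n",
              x$ties, x$n, x$n_event))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (length(x$diagnostics)) cat("diagnostics:", x$diagnostics, sep = "\n  ")
  invisible(x)
}

#' Select variables for multivariate analysis by univariate p-value
#'
#' Retains variables whose univariate p-value is strictly below the
#' threshold (default 0.10), preserving input order.
#'
#' @param p_values Named numeric vector of univariate p-values.
#' @param threshold Strict upper bound; default 0.10.
#' @return Character vector of retained variable names.
#' @examples
#' uva_filter(c(eNOS = 0.001, PSA = 0.561, x = 0.10))  # "eNOS"
#' @export
uva_filter <- function(p_values, threshold = 0.10) {
  names(p_values)[p_values < threshold]
}
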