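# Ordinal encoding of a Gleason score that respects ISUP ordering:
# 6 (3+3) < 7 (3+4) < 7 (4+3) < 8 < 9 ...
.gleason_ordinal <- function(total, primary) total * 10 + primary

# One univariate report row: dichotomize, evaluate as a binary test, attach
# interval/p on the dichotomized indicator and the continuous all-pairs AUC.
.uva_row <- function(variable, values, labels, rule, ci_method, B, seed) {
  res <- binary_auc_at_cutoff(values, labels, rule)
  ind <- as.numeric(apply_rule(res$rule, values))
  ci <- auc_confidence_interval(ind, labels, method = ci_method, B = B, seed = seed)
  data.frame(variable = variable,
             cutoff = res$rule$threshold,
             direction = res$rule$direction,
             flipped = res$flipped,
             auc = res$auc,
             ci_low = ci[1], ci_high = ci[2],
             p = auc_p_value(ind, labels),
             sensitivity = res$sensitivity,
             specificity = res$specificity,
             auc_continuous = empirical_auc(values, labels),
             stringsAsFactors = FALSE)
}

#' Univariate prognostic report (ROC cut-off analysis)
#'
#' Evaluates each available variable as a dichotomized prognostic test for
#' progression: the clinical variables (PSA at 6.3 ng/mL, bioptic and
#' pathologic Gleason at >= 4+3, when present) and the five biomarkers at
#' their published cut-offs when a marker table is supplied. Each row
#' reports the effective cut-off rule (after orientation auto-flip), the
#' binary-test AUC = (sensitivity + specificity)/2, a confidence interval
#' and Mann-Whitney p on the dichotomized indicator, and the continuous
#' all-pairs AUC of the raw variable as a supplementary column. Variables
#' that cannot be evaluated (all values missing, or only one outcome class)
#' are skipped with a warning. Raw p-values are reported; an optional
#' Benjamini-Hochberg column can be switched on.
#'
#' @param cohort A \code{cohort} data frame.
#' @param markers Optional \code{marker_panel} aligned to the cohort by
#'   \code{patient_id}.
#' @param rules Marker dichotomization rules; default
#'   \code{\link{default_bioscore_rules}}.
#' @param psa_cutoff PSA cut-off in ng/mL; default 6.3.
#' @param ci_method,B,seed Interval settings passed to
#'   \code{\link{auc_confidence_interval}}.
#' @param adjust_p Add a Benjamini-Hochberg adjusted p column; default FALSE.
#' @return Data frame with one row per evaluated variable; skipped variables
#'   are listed in the \code{skipped} attribute.
#' @examples
#' run_uva(read_cohort(table1_path()))
#' @export
run_uva <- function(cohort, markers = NULL, rules = default_bioscore_rules(),
                    psa_cutoff = 6.3, ci_method = c("bootstrap", "delong"),
                    B = 2000, seed = 1, adjust_p = FALSE) {
  ci_method <- match.arg(ci_method)
  labels <- cohort$recurrence
  if (!any(labels) || all(labels)) {
    stop("univariate report needs both progression and non-progression patients",
         call. = FALSE)
  }
  rows <- list(); skipped <- character()
  add <- function(variable, values, rule) {
    if (all(is.na(values))) {
      skipped <<- c(skipped, variable)
      warning("skipping ", variable, ": no values available", call. = FALSE)
      return(invisible())
    }
    keep <- !is.na(values)
    lab <- labels[keep]
    if (!any(lab) || all(lab) || length(unique(values[keep])) < 2L) {
      skipped <<- c(skipped, variable)
      warning("skipping ", variable, ": single class or constant values",
              call. = FALSE)
      return(invisible())
    }
    rows[[length(rows) + 1L]] <<- .uva_row(variable, values[keep], lab, rule,
                                           ci_method, B, seed)
  }
  add("PSA", cohort$psa, cutoff_rule("psa", psa_cutoff, "at_or_above"))
  if (!is.null(cohort$bioptic_gleason)) {
    bgs <- vapply(cohort$bioptic_gleason, function(g) {
      if (is.null(g)) NA_real_ else .gleason_ordinal(g$total, g$primary)
    }, numeric(1))
    add("bGS", bgs, cutoff_rule("bGS", .gleason_ordinal(7, 4), "at_or_above"))
  } else {
    skipped <- c(skipped, "bGS")
    warning("skipping bGS: bioptic Gleason not recorded in this cohort",
            call. = FALSE)
  }
  add("pGS", .gleason_ordinal(cohort$gleason_total, cohort$gleason_primary),
      cutoff_rule("pGS", .gleason_ordinal(7, 4), "at_or_above"))
  if (!is.null(markers)) {
    m <- markers[match(cohort$patient_id, markers$patient_id), , drop = FALSE]
    for (nm in names(rules)) {
      add(nm, m[[rules[[nm]]$marker]], rules[[nm]])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), cutoff = numeric(), direction = character(),
               flipped = logical(), auc = numeric(), ci_low = numeric(),
               ci_high = numeric(), p = numeric(), sensitivity = numeric(),
               specificity = numeric(), auc_continuous = numeric(),
               stringsAsFactors = FALSE)
  if (adjust_p && nrow(out)) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Run the full BioScore analysis pipeline
#'
#' End-to-end evaluation on a cohort with marker panels: the univariate
#' report, per-patient BioScore with high/low classification at >= 3,
#' the composite score's binary ROC performance (AUC, sensitivity,
#' specificity, CI, p), and — when follow-up times allow — Kaplan-Meier
#' curves by risk class, the log-rank test and a Cox hazard ratio. The Cox
#' model codes the high-risk class as reference, so the reported hazard
#' ratio is for low- versus high-risk patients (a protective HR < 1 when
#' the score is prognostic); the coding is echoed in the output. In
#' \code{mva_mode = "flags"} the five marker indicators enter the Cox model
#' jointly instead of the single risk class. Survival stages are skipped
#' with a notice when censored patients lack follow-up times; ROC stages
#' still run.
#'
#' @param cohort A \code{cohort} data frame.
#' @param markers A \code{marker_panel} for the same patients.
#' @param rules Marker rules; default \code{\link{default_bioscore_rules}}.
#' @param high_threshold BioScore high-risk threshold; default 3.
#' @param mva_mode \code{"bioscore"} (single risk-class covariate, default)
#'   or \code{"flags"} (five marker indicators).
#' @param ci_method,B,seed Interval settings.
#' @return A list of class \code{bioscore_report}: \code{uva},
#'   \code{bioscore} (per-patient table), \code{excluded_patients},
#'   \code{score_roc} (list: auc, sensitivity, specificity, ci, p,
#'   threshold), \code{km} (\code{km_curve} or NULL), \code{log_rank},
#'   \code{cox}, \code{notes}, and \code{config} echoing rules, seed,
#'   threshold and coding so a run is fully reproducible.
#' @export
run_full <- function(cohort, markers, rules = default_bioscore_rules(),
                     high_threshold = 3, mva_mode = c("bioscore", "flags"),
                     ci_method = c("bootstrap", "delong"), B = 2000, seed = 1) {
  mva_mode <- match.arg(mva_mode)
  ci_method <- match.arg(ci_method)
  uva <- suppressWarnings(run_uva(cohort, markers, rules, ci_method = ci_method,
                                  B = B, seed = seed))
  scored <- bioscore_with_exclusions(markers, rules, high_threshold)
  scores <- scored$scores
  idx <- match(scores$patient_id, cohort$patient_id)
  if (any(is.na(idx))) {
    stop("marker table contains patient ids absent from the cohort", call. = FALSE)
  }
  labels <- cohort$recurrence[idx]
  res <- binary_auc_at_cutoff(scores$score, labels,
                              cutoff_rule("bioscore", high_threshold, "at_or_above"),
                              auto_flip = FALSE)
  ind <- as.numeric(apply_rule(res$rule, scores$score))
  score_roc <- list(auc = res$auc, sensitivity = res$sensitivity,
                    specificity = res$specificity,
                    ci = auc_confidence_interval(ind, labels, method = ci_method,
                                                 B = B, seed = seed),
                    p = auc_p_value(ind, labels),
                    threshold = high_threshold)
  notes <- character()
  km <- NULL; lr <- NULL; cx <- NULL
  sub <- cohort[idx, , drop = FALSE]
  obs <- tryCatch(pfs_observations(sub), error = function(e) {
    notes <<- c(notes, paste("survival stages skipped:", conditionMessage(e)))
    NULL
  })
  if (!is.null(obs)) {
    obs$group <- factor(scores$risk_class, levels = c("high", "low"))
    if (nlevels(droplevels(obs$group)) == 2L && any(obs$event)) {
      km <- km_estimate(obs)
      lr <- log_rank_test(obs)
      cx <- if (mva_mode == "bioscore") {
        obs$low_risk <- as.integer(obs$group == "low")
        cox_fit(obs, "low_risk")
      } else {
        cov_cols <- paste0(names(rules), "_flag")
        for (cc in cov_cols) obs[[cc]] <- as.integer(scores[[cc]])
        cox_fit(obs, cov_cols)
      }
    } else {
      notes <- c(notes, "survival comparison skipped: need two risk classes and >= 1 event")
    }
  }
  structure(list(uva = uva, bioscore = scores,
                 excluded_patients = scored$excluded,
                 score_roc = score_roc, km = km, log_rank = lr, cox = cx,
                 notes = notes,
                 config = list(rules = rules, seed = seed,
                               high_threshold = high_threshold,
                               mva_mode = mva_mode, ci_method = ci_method, B = B,
                               hr_coding = "low vs high (high = reference)")),
            class = "bioscore_report")
}

#' @export
print.bioscore_report <- function(x, ...) {
  cat("BioScore analysis report\n")
  cat("\nUnivariate cut-off analysis:\n")
  print(x$uva[, c("variable", "cutoff", "direction", "auc", "ci_low", "ci_high", "p")],
        row.names = FALSE, digits = 3)
  cat(sprintf("\nBioScore (>= %d = high risk): %d high / %d low; %d excluded\n",
              x$score_roc$threshold, sum(x$bioscore$risk_class == "high"),
              sum(x$bioscore$risk_class == "low"), length(x$excluded_patients)))
  cat(sprintf("  binary AUC %.3f (%.3f-%.3f), sens %.1f%%, spec %.1f%%, p = %.4g\n",
              x$score_roc$auc, x$score_roc$ci[1], x$score_roc$ci[2],
              100 * x$score_roc$sensitivity, 100 * x$score_roc$specificity,
              x$score_roc$p))
  if (!is.null(x$log_rank)) {
    cat(sprintf("  log-rank chi-square %.3f, p = %.4g\n",
                x$log_rank$chi_square, x$log_rank$p_value))
  }
  if (!is.null(x$cox)) {
    hr <- x$cox$coefficients
    cat(sprintf("  Cox HR [%s] %.3f (%.3f-%.3f), p = %.4g\n",
                x$config$hr_coding, hr$hazard_ratio[1], hr$ci_low[1],
                hr$ci_high[1], hr$p[1]))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Tables go to CSV, summaries and the config echo (rules, seed, coding) to
#' JSON, so a run is fully reproducible and machine-checkable.
#'
#' @param report A \code{bioscore_report} from \code{\link{run_full}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bioscore_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$uva, file.path(dir, "uva_report.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$bioscore),
                   file.path(dir, "bioscore_table.csv"), row.names = FALSE)
  if (!is.null(report$km)) {
    utils::write.csv(report$km$table, file.path(dir, "km_curves.csv"),
                     row.names = FALSE)
  }
  summary_json <- list(
    score_roc = report$score_roc,
    log_rank = if (!is.null(report$log_rank)) {
      report$log_rank[c("chi_square", "p_value")]
    },
    cox = if (!is.null(report$cox)) report$cox$coefficients,
    excluded_patients = report$excluded_patients,
    notes = report$notes,
    config = list(
      seed = report$config$seed,
      high_threshold = report$config$high_threshold,
      mva_mode = report$config$mva_mode,
      ci_method = report$config$ci_method,
      bootstrap_reps = report$config$B,
      hr_coding = report$config$hr_coding,
      rules = lapply(report$config$rules, function(r) {
        list(marker = r$marker, threshold = r$threshold, direction = r$direction)
      })))
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
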