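#' The five default BioScore dichotomization rules
#'
#' The composite score counts dysregulated markers by the published
#' cut-offs: eNOS IHC score strictly > 1, HIF-2alpha IHC score strictly > 0,
#' beta4 integrin IHC score strictly > 4, H19 normalized level <= 1.1392
#' (low H19 counts as dysregulated), and CDH1 normalized level >= 0.0051.
#' The mixed strict/non-strict inequalities follow the published rules
#' exactly.
#'
#' @return A named list of five \code{\link{cutoff_rule}} objects:
#'   \code{enos}, \code{hif2a}, \code{itgb4}, \code{h19}, \code{cdh1}.
#' @examples
#' default_bioscore_rules()
#' @export
default_bioscore_rules <- function() {
  list(
    enos  = cutoff_rule("enos_ihc",  1,      "above"),
    hif2a = cutoff_rule("hif2a_ihc", 0,      "above"),
    itgb4 = cutoff_rule("itgb4_ihc", 4,      "above"),
    h19   = cutoff_rule("h19_norm",  1.1392, "at_or_below"),
    cdh1  = cutoff_rule("cdh1_norm", 0.0051, "at_or_above")
  )
}

#' Compute the composite BioScore per patient
#'
#' Each of the five marker rules contributes 1 to the score when satisfied
#' (an indicator sum, not a sum of raw values), giving an integer score 0-5;
#' patients with score >= \code{high_threshold} (default 3) are classed as
#' high risk. Patients with any missing marker value cannot be scored and
#' raise an error (the table-level wrapper excludes and logs them instead of
#' imputing).
#'
#' @param markers A \code{marker_panel} data frame (see
#'   \code{\link{read_markers}}) or any data frame with columns
#'   \code{patient_id}, \code{enos_ihc}, \code{hif2a_ihc}, \code{itgb4_ihc},
#'   \code{h19_norm}, \code{cdh1_norm}.
#' @param rules Named list of five rules as from
#'   \code{\link{default_bioscore_rules}}; each rule's \code{marker} names
#'   the column it applies to.
#' @param high_threshold Score at or above which a patient is high risk;
#'   default 3.
#' @return A data frame of class \code{bioscore_table}: \code{patient_id},
#'   one logical flag column per rule (\code{<name>_flag}), \code{score}
#'   (integer 0-5) and \code{risk_class} (\code{"high"}/\code{"low"}).
#' @examples
#' panel <- data.frame(patient_id = "p1", enos_ihc = 6, hif2a_ihc = 2,
#'                     itgb4_ihc = 8, h19_norm = 0.5, cdh1_norm = 0.01)
#' compute_bioscore(panel)
#' @export
compute_bioscore <- function(markers, rules = default_bioscore_rules(),
                             high_threshold = 3) {
  stopifnot(is.data.frame(markers), length(rules) >= 1)
  cols <- vapply(rules, `[[`, character(1), "marker")
  missing_cols <- setdiff(cols, names(markers))
  if (length(missing_cols)) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- rowSums(is.na(markers[, cols, drop = FALSE])) > 0
  if (any(incomplete)) {
    stop(sprintf("incomplete marker panel for %d patient(s): %s",
                 sum(incomplete),
                 paste(markers$patient_id[incomplete], collapse = ", ")),
         call. = FALSE)
  }
  flags <- vapply(rules, function(r) apply_rule(r, markers[[r$marker]]),
                  logical(nrow(markers)))
  flags <- matrix(flags, nrow = nrow(markers),
                  dimnames = list(NULL, paste0(names(rules), "_flag")))
  score <- as.integer(rowSums(flags))
  out <- data.frame(patient_id = markers$patient_id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  out$score <- score
  out$risk_class <- ifelse(score >= high_threshold, "high", "low")
  class(out) <- c("bioscore_table", "data.frame")
  out
}

#' Score a marker table, excluding incomplete panels
#'
#' Convenience wrapper around \code{\link{compute_bioscore}} that drops
#' patients with missing marker values instead of failing, and reports them.
#'
#' @inheritParams compute_bioscore
#' @return A list with \code{scores} (the \code{bioscore_table} for complete
#'   panels) and \code{excluded} (character vector of patient ids dropped
#'   for missing markers).
#' @export
bioscore_with_exclusions <- function(markers, rules = default_bioscore_rules(),
                                     high_threshold = 3) {
  cols <- vapply(rules, `[[`, character(1), "marker")
  missing_cols <- setdiff(cols, names(markers))
  if (length(missing_cols)) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- rowSums(is.na(markers[, cols, drop = FALSE])) > 0
  excluded <- as.character(markers$patient_id[incomplete])
  kept <- markers[!incomplete, , drop = FALSE]
  if (!nrow(kept)) stop("no patient has a complete marker panel", call. = FALSE)
  list(scores = compute_bioscore(kept, rules, high_threshold),
       excluded = excluded)
}
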