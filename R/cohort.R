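#' Parse a formatted Gleason score string
#'
#' Gleason scores are reported as \code{"T (P + S)"}, e.g. \code{"7 (4 + 3)"},
#' where \code{P} and \code{S} are the primary and secondary growth patterns
#' and \code{T} their sum. The printed total must equal \code{P + S}.
#'
#' @param text Character scalar such as \code{"7 (4 + 3)"}. Whitespace around
#'   the numbers is tolerated.
#' @return An object of class \code{gleason_score}: a list with integer fields
#'   \code{primary}, \code{secondary} and \code{total}.
#' @examples
#' parse_gleason("7 (4 + 3)")
#' @export
parse_gleason <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("gleason score must be a single character string", call. = FALSE)
  }
  m <- regmatches(text, regexec(
    "^\\s*(\\d+)\\s*\\(\\s*(\\d+)\\s*\\+\\s*(\\d+)\\s*\\)\\s*$", text))[[1L]]
  if (length(m) != 4L) {
    stop(sprintf("malformed Gleason score string: '%s' (expected 'T (P + S)')",
                 text), call. = FALSE)
  }
  total <- as.integer(m[2L]); primary <- as.integer(m[3L]); secondary <- as.integer(m[4L])
  if (total != primary + secondary) {
    stop(sprintf("inconsistent Gleason score '%s': total %d != %d + %d",
                 text, total, primary, secondary), call. = FALSE)
  }
  gleason_score(primary, secondary)
}

#' Construct a Gleason score from its patterns
#'
#' @param primary,secondary Integer growth patterns, each in 3..5.
#' @return A \code{gleason_score} object.
#' @export
gleason_score <- function(primary, secondary) {
  primary <- as.integer(primary); secondary <- as.integer(secondary)
  if (is.na(primary) || is.na(secondary) ||
      primary < 3L || primary > 5L || secondary < 3L || secondary > 5L) {
    stop("Gleason patterns must be integers in 3..5", call. = FALSE)
  }
  structure(list(primary = primary, secondary = secondary,
                 total = primary + secondary),
            class = "gleason_score")
}

#' @export
format.gleason_score <- function(x, ...) {
  sprintf("%d (%d + %d)", x$total, x$primary, x$secondary)
}

#' @export
print.gleason_score <- function(x, ...) {
  cat("Gleason score", format(x), "\n")
  invisible(x)
}

#' Is a Gleason score at or above 4+3?
#'
#' Implements the ISUP ordering in which 7 (3+4) ranks below 7 (4+3): a score
#' qualifies when its total exceeds 7, or equals 7 with primary pattern 4.
#' This is the dichotomization used for the pathologic Gleason cut-off in the
#' univariate prognostic analysis.
#'
#' @param gs A \code{gleason_score}, or a character string parseable by
#'   \code{\link{parse_gleason}}.
#' @return Logical scalar.
#' @examples
#' gleason_at_least_4_3(parse_gleason("7 (3 + 4)")) # FALSE
#' gleason_at_least_4_3("7 (4 + 3)")                # TRUE
#' @export
gleason_at_least_4_3 <- function(gs) {
  if (is.character(gs)) gs <- parse_gleason(gs)
  stopifnot(inherits(gs, "gleason_score"))
  gs$total > 7L || (gs$total == 7L && gs$primary >= 4L)
}

# Literal recurrence cells: "-" or blank = censored, "yes" = progression.
.parse_recurrence <- function(x) {
  x <- trimws(tolower(as.character(x)))
  if (x %in% c("", "-", "no", "false", "0") || is.na(x)) return(FALSE)
  if (x %in% c("yes", "true", "1")) return(TRUE)
  stop(sprintf("unrecognized recurrence cell '%s'", x), call. = FALSE)
}

#' Read a patient-level clinical cohort table
#'
#' Parses a CSV modeled on the study's clinical table: one row per patient
#' with identifier, age, serum PSA (ng/mL), pathologic Gleason score string,
#' TNM stage string, recurrence flag and (for recurrent patients) time of
#' recurrence in months. A blank or \code{"-"} recurrence cell means no
#' recurrence. Optional columns \code{bioptic_gleason} and
#' \code{follow_up_time} are carried when present: censoring times are not
#' part of the core schema, so survival analyses require an explicit
#' \code{follow_up_time} for censored patients while ROC analyses do not.
#'
#' @param path Path to a CSV file with a header row. Required columns:
#'   \code{patient_id}, \code{age}, \code{psa}, \code{pathologic_gleason},
#'   \code{stage}, \code{recurrence}, \code{time_to_recurrence}.
#' @return A data frame of class \code{cohort} with one row per patient, in
#'   file order: \code{patient_id}, \code{age}, \code{psa},
#'   \code{pathologic_gleason} (list of \code{gleason_score}),
#'   \code{gleason_primary}, \code{gleason_secondary}, \code{gleason_total},
#'   \code{stage}, \code{recurrence} (logical), \code{time_to_recurrence},
#'   and optionally \code{bioptic_gleason} (list column) and
#'   \code{follow_up_time}.
#' @examples
#' path <- system.file("extdata", "table1_cohort.csv", package = "bioscore")
#' cohort <- read_cohort(path)
#' nrow(cohort)          # 30
#' sum(cohort$recurrence) # 8
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  required <- c("patient_id", "age", "psa", "pathologic_gleason", "stage",
                "recurrence", "time_to_recurrence")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  out <- data.frame(patient_id = character(n), age = numeric(n),
                    psa = numeric(n), stringsAsFactors = FALSE)
  if (n == 0L) {
    cohort <- data.frame(patient_id = character(), age = numeric(),
                         psa = numeric(), gleason_primary = integer(),
                         gleason_secondary = integer(), gleason_total = integer(),
                         stage = character(), recurrence = logical(),
                         time_to_recurrence = numeric(),
                         stringsAsFactors = FALSE)
    cohort$pathologic_gleason <- list()
    class(cohort) <- c("cohort", "data.frame")
    return(cohort)
  }
  num_field <- function(x, row, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop(sprintf("row %d: non-numeric %s '%s'", row, what, x),
                       call. = FALSE)
    v
  }
  gs <- vector("list", n)
  rec <- logical(n); ttr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    out$patient_id[i] <- raw$patient_id[i]
    out$age[i] <- num_field(raw$age[i], i, "age")
    out$psa[i] <- num_field(raw$psa[i], i, "PSA")
    if (out$age[i] <= 0) stop(sprintf("row %d: age must be positive", i), call. = FALSE)
    if (out$psa[i] <= 0) stop(sprintf("row %d: PSA must be positive", i), call. = FALSE)
    gs[[i]] <- parse_gleason(raw$pathologic_gleason[i])
    rec[i] <- .parse_recurrence(raw$recurrence[i])
    cell <- trimws(raw$time_to_recurrence[i])
    if (rec[i]) {
      ttr[i] <- num_field(cell, i, "time of recurrence")
      if (ttr[i] <= 0) stop(sprintf("row %d: time of recurrence must be positive", i),
                            call. = FALSE)
    } else if (nzchar(cell) && cell != "-") {
      ttr[i] <- num_field(cell, i, "time of recurrence")
    }
  }
  out$gleason_primary <- vapply(gs, `[[`, integer(1), "primary")
  out$gleason_secondary <- vapply(gs, `[[`, integer(1), "secondary")
  out$gleason_total <- vapply(gs, `[[`, integer(1), "total")
  out$stage <- raw$stage
  out$recurrence <- rec
  out$time_to_recurrence <- ttr
  out$pathologic_gleason <- gs
  if ("bioptic_gleason" %in% names(raw)) {
    out$bioptic_gleason <- lapply(raw$bioptic_gleason, function(s) {
      if (is.na(s) || !nzchar(trimws(s)) || trimws(s) == "-") NULL else parse_gleason(s)
    })
  }
  if ("follow_up_time" %in% names(raw)) {
    out$follow_up_time <- vapply(raw$follow_up_time, function(s) {
      s <- trimws(s)
      if (is.na(s) || !nzchar(s) || s == "-") NA_real_
      else suppressWarnings(as.numeric(s))
    }, numeric(1), USE.NAMES = FALSE)
  }
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort table back to CSV
#'
#' Serializes a \code{cohort} in the same schema \code{\link{read_cohort}}
#' reads, so that \code{read_cohort(write_cohort(x, f))} reproduces \code{x}
#' field for field.
#'
#' @param cohort A \code{cohort} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- data.frame(
    patient_id = cohort$patient_id,
    age = cohort$age,
    psa = cohort$psa,
    pathologic_gleason = vapply(cohort$pathologic_gleason, format, character(1)),
    stage = cohort$stage,
    recurrence = ifelse(cohort$recurrence, "yes", "-"),
    time_to_recurrence = ifelse(is.na(cohort$time_to_recurrence), "",
                                as.character(cohort$time_to_recurrence)),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(cohort$bioptic_gleason)) {
    out$bioptic_gleason <- vapply(cohort$bioptic_gleason, function(g) {
      if (is.null(g)) "" else format(g)
    }, character(1))
  }
  if (!is.null(cohort$follow_up_time)) {
    out$follow_up_time <- ifelse(is.na(cohort$follow_up_time), "",
                                 as.character(cohort$follow_up_time))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Path to the packaged 30-patient cohort fixture
#'
#' The package ships the study's printed clinical table (30 patients, 8 with
#' recurrence) as a plain-text CSV for worked examples and exact checks.
#'
#' @return File path to the fixture CSV.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_cohort.csv", package = "bioscore",
              mustWork = TRUE)
}

#' Read a per-patient marker panel table
#'
#' The marker table carries the five biomarker values per patient: IHC
#' Intensity x Quantity scores (0-12) for eNOS, HIF-2alpha and beta4 integrin
#' and housekeeping-normalized transcript ratios for H19 and CDH1. Scores may
#' be given directly (\code{enos_ihc}, \code{hif2a_ihc}, \code{itgb4_ihc}) or
#' as intensity/quantity column pairs (\code{enos_intensity},
#' \code{enos_quantity}, ...), in which case the product is computed. When
#' both are present the explicit score wins and a warning is raised if they
#' disagree.
#'
#' @param path Path to a CSV with header; required: \code{patient_id}, the
#'   three IHC scores (directly or as pairs) and \code{h19_norm},
#'   \code{cdh1_norm}.
#' @return A data frame of class \code{marker_panel} with columns
#'   \code{patient_id}, \code{enos_ihc}, \code{hif2a_ihc}, \code{itgb4_ihc},
#'   \code{h19_norm}, \code{cdh1_norm}.
#' @export
read_markers <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!"patient_id" %in% names(raw)) {
    stop("marker table is missing required column patient_id", call. = FALSE)
  }
  ihc_col <- function(marker) {
    score_col <- paste0(marker, "_ihc")
    int_col <- paste0(marker, "_intensity")
    qty_col <- paste0(marker, "_quantity")
    has_pair <- all(c(int_col, qty_col) %in% names(raw))
    has_score <- score_col %in% names(raw)
    if (!has_pair && !has_score) {
      stop(sprintf("marker table must provide %s or (%s, %s)",
                   score_col, int_col, qty_col), call. = FALSE)
    }
    prod_score <- if (has_pair) {
      mapply(ihc_score, raw[[int_col]], raw[[qty_col]])
    } else NULL
    if (has_score) {
      sc <- as.numeric(raw[[score_col]])
      ok <- !is.na(sc) & sc == as.integer(sc) & sc %in% .attainable_ihc_scores()
      if (any(!ok)) stop(sprintf("invalid %s score(s): must be attainable IxQ products",
                                 score_col), call. = FALSE)
      if (has_pair && any(sc != prod_score)) {
        warning(sprintf("%s disagrees with %s x %s for %d patient(s); explicit score used",
                        score_col, int_col, qty_col, sum(sc != prod_score)))
      }
      as.integer(sc)
    } else as.integer(prod_score)
  }
  ratio_col <- function(col) {
    if (!col %in% names(raw)) stop("marker table is missing column ", col, call. = FALSE)
    v <- as.numeric(raw[[col]])
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      stop(col, " must be finite and non-negative", call. = FALSE)
    }
    v
  }
  out <- data.frame(patient_id = as.character(raw$patient_id),
                    enos_ihc = ihc_col("enos"),
                    hif2a_ihc = ihc_col("hif2a"),
                    itgb4_ihc = ihc_col("itgb4"),
                    h19_norm = ratio_col("h19_norm"),
                    cdh1_norm = ratio_col("cdh1_norm"),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Write a marker panel table to CSV
#'
#' @param markers A \code{marker_panel} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(as.data.frame(markers)[, c("patient_id", "enos_ihc", "hif2a_ihc",
                                              "itgb4_ihc", "h19_norm", "cdh1_norm")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
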