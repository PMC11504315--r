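#' Droplet digital PCR concentration by Poisson inversion
#'
#' In ddPCR the sample is partitioned into ~20,000 droplets and target copies
#' distribute across them as Poisson. The mean copies per droplet is
#' recovered from the fraction of positive droplets as
#' \eqn{\lambda = -\ln(1 - k/n)} and the concentration in copies/uL is
#' \eqn{\lambda / v} with \eqn{v} the droplet volume. A fully positive well
#' is saturated and the concentration is not estimable.
#'
#' @param positive_droplets Number of positive droplets (k).
#' @param total_droplets Total accepted droplets (n), > 0.
#' @param droplet_volume Droplet volume in microliters; default 0.00085
#'   (0.85 nL, the QX200 partition volume).
#' @return Concentration in copies per microliter.
#' @examples
#' ddpcr_concentration(5000, 15000)  # 477.018 copies/uL
#' @export
ddpcr_concentration <- function(positive_droplets, total_droplets,
                                droplet_volume = 0.00085) {
  if (any(total_droplets <= 0)) stop("total_droplets must be positive", call. = FALSE)
  if (any(droplet_volume <= 0)) stop("droplet_volume must be positive", call. = FALSE)
  if (any(positive_droplets < 0 | positive_droplets > total_droplets)) {
    stop("positive_droplets must be in [0, total_droplets]", call. = FALSE)
  }
  if (any(positive_droplets == total_droplets)) {
    stop("well saturated: all droplets positive, concentration not estimable",
         call. = FALSE)
  }
  lambda <- -log1p(-positive_droplets / total_droplets)
  lambda / droplet_volume
}

#' Droplet-count quality control
#'
#' A well passes QC only when strictly more than 12,000 accepted droplets
#' were read; wells at or below the bound are rejected.
#'
#' @param total_droplets Total accepted droplets. Vectorized.
#' @param min_droplets QC bound (strict); default 12000.
#' @return Logical pass/fail.
#' @examples
#' ddpcr_qc(c(12001, 12000, 8000))  # TRUE FALSE FALSE
#' @export
ddpcr_qc <- function(total_droplets, min_droplets = 12000) {
  total_droplets > min_droplets
}

#' Normalize a target concentration to the housekeeping gene
#'
#' @param target_conc Target concentration, copies/uL.
#' @param housekeeping_conc Housekeeping-gene concentration, copies/uL; must
#'   be positive.
#' @return Dimensionless ratio target/housekeeping.
#' @export
normalize_to_housekeeping <- function(target_conc, housekeeping_conc) {
  if (any(housekeeping_conc <= 0)) {
    stop("housekeeping concentration must be positive; sample should be excluded",
         call. = FALSE)
  }
  if (any(target_conc < 0)) stop("target concentration must be non-negative",
                                 call. = FALSE)
  target_conc / housekeeping_conc
}

#' Process a droplet-count table into normalized transcript levels
#'
#' Takes raw per-well droplet counts (long format: patient, target, positive
#' and total droplets), sums replicate wells per patient/target, applies the
#' droplet-count QC rule, converts to copies/uL by Poisson inversion and
#' normalizes each target to the housekeeping gene. Patients whose
#' housekeeping well fails QC, is saturated, or has zero signal are excluded
#' and listed in the QC log, as are individual failing target wells.
#'
#' @param wells Data frame with columns \code{patient_id}, \code{target}
#'   (values among the \code{targets} and \code{housekeeping} names),
#'   \code{positive_droplets}, \code{total_droplets}.
#' @param targets Character vector of target transcript names; default
#'   \code{c("H19", "CDH1")}.
#' @param housekeeping Housekeeping gene name; default \code{"GAPDH"}.
#' @param droplet_volume Droplet volume in uL; default 0.00085.
#' @param min_droplets QC bound on summed droplets; default 12000.
#' @return A list with \code{levels} (data frame: patient_id, target, value)
#'   and \code{qc_log} (data frame of exclusions with reasons).
#' @export
ddpcr_normalize_table <- function(wells, targets = c("H19", "CDH1"),
                                  housekeeping = "GAPDH",
                                  droplet_volume = 0.00085,
                                  min_droplets = 12000) {
  needed <- c("patient_id", "target", "positive_droplets", "total_droplets")
  if (!all(needed %in% names(wells))) {
    stop("droplet table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  # replicate wells are merged by summing droplets, then estimating once
  agg <- stats::aggregate(cbind(positive_droplets, total_droplets) ~ patient_id + target,
                          data = wells, FUN = sum)
  qc_log <- data.frame(patient_id = character(), target = character(),
                       reason = character(), stringsAsFactors = FALSE)
  log_fail <- function(pid, tgt, why) {
    qc_log <<- rbind(qc_log, data.frame(patient_id = pid, target = tgt,
                                        reason = why, stringsAsFactors = FALSE))
  }
  conc_or_na <- function(row) {
    if (!ddpcr_qc(row$total_droplets, min_droplets)) {
      log_fail(row$patient_id, row$target,
               sprintf("droplet count %d <= %d", row$total_droplets, min_droplets))
      return(NA_real_)
    }
    if (row$positive_droplets == row$total_droplets) {
      log_fail(row$patient_id, row$target, "saturated well")
      return(NA_real_)
    }
    ddpcr_concentration(row$positive_droplets, row$total_droplets, droplet_volume)
  }
  out <- data.frame(patient_id = character(), target = character(),
                    value = numeric(), stringsAsFactors = FALSE)
  for (pid in unique(agg$patient_id)) {
    sub <- agg[agg$patient_id == pid, , drop = FALSE]
    hk <- sub[sub$target == housekeeping, , drop = FALSE]
    if (nrow(hk) != 1L) {
      log_fail(pid, housekeeping, "missing housekeeping well")
      next
    }
    hk_conc <- conc_or_na(hk[1L, ])
    if (is.na(hk_conc) || hk_conc == 0) {
      if (!is.na(hk_conc)) log_fail(pid, housekeeping, "zero housekeeping signal")
      next
    }
    for (tgt in targets) {
      tw <- sub[sub$target == tgt, , drop = FALSE]
      if (nrow(tw) != 1L) {
        log_fail(pid, tgt, "missing target well")
        next
      }
      tc <- conc_or_na(tw[1L, ])
      if (is.na(tc)) next
      out <- rbind(out, data.frame(patient_id = pid, target = tgt,
                                   value = normalize_to_housekeeping(tc, hk_conc),
                                   stringsAsFactors = FALSE))
    }
  }
  list(levels = out, qc_log = qc_log)
}
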