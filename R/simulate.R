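#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the structure of the study cohort: 30 patients, a
#' target progression fraction of 8/30, censoring drawn uniformly over a
#' 36-72 month (3-6 year) follow-up window, five correlated marker
#' dysregulation indicators, and an exponential progression hazard that
#' multiplies by \code{hazard_ratio_per_flag} for every dysregulated marker.
#' When \code{baseline_hazard} is \code{NULL} it is calibrated numerically
#' so the expected observed-event fraction equals
#' \code{event_fraction_target} (see
#' \code{\link{calibrate_baseline_hazard}}).
#'
#' @param n_patients Cohort size; default 30.
#' @param event_fraction_target Expected fraction of patients whose
#'   progression is observed before censoring; default 8/30.
#' @param follow_up_window Censoring window in months, \code{c(low, high)};
#'   default \code{c(36, 72)}.
#' @param prevalence Named per-marker dysregulation prevalences in [0,1];
#'   default 0.4 each for \code{enos}, \code{hif2a}, \code{itgb4},
#'   \code{h19}, \code{cdh1}.
#' @param hazard_ratio_per_flag Multiplicative hazard factor per
#'   dysregulated marker; default 2.5 (a strongly prognostic panel).
#' @param baseline_hazard Events/month for a patient with zero flags, or
#'   \code{NULL} to calibrate.
#' @param latent_loading Correlation loading of the shared latent
#'   aggressiveness variable on each marker's dysregulation propensity, in
#'   [0, 1); default 0.5.
#' @param seed Integer seed; default 1.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 30,
                       event_fraction_target = 8 / 30,
                       follow_up_window = c(36, 72),
                       prevalence = c(enos = 0.4, hif2a = 0.4, itgb4 = 0.4,
                                      h19 = 0.4, cdh1 = 0.4),
                       hazard_ratio_per_flag = 2.5,
                       baseline_hazard = NULL,
                       latent_loading = 0.5,
                       seed = 1) {
  markers <- c("enos", "hif2a", "itgb4", "h19", "cdh1")
  if (!all(markers %in% names(prevalence))) {
    stop("prevalence must name all five markers: ",
         paste(markers, collapse = ", "), call. = FALSE)
  }
  prevalence <- prevalence[markers]
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must be in [0, 1]", call. = FALSE)
  }
  if (length(follow_up_window) != 2L || follow_up_window[1] >= follow_up_window[2] ||
      follow_up_window[1] <= 0) {
    stop("follow_up_window must be c(low, high) with 0 < low < high", call. = FALSE)
  }
  if (event_fraction_target <= 0 || event_fraction_target >= 1) {
    stop("event_fraction_target must be in (0, 1)", call. = FALSE)
  }
  if (hazard_ratio_per_flag <= 0) stop("hazard_ratio_per_flag must be positive",
                                       call. = FALSE)
  if (!is.null(baseline_hazard) && baseline_hazard <= 0) {
    stop("baseline_hazard must be positive", call. = FALSE)
  }
  if (latent_loading < 0 || latent_loading >= 1) {
    stop("latent_loading must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 event_fraction_target = event_fraction_target,
                 follow_up_window = follow_up_window,
                 prevalence = prevalence,
                 hazard_ratio_per_flag = hazard_ratio_per_flag,
                 baseline_hazard = baseline_hazard,
                 latent_loading = latent_loading,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose top-level keys are \code{\link{sim_config}}
#'   arguments (\code{prevalence} as a named map).
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$prevalence)) raw$prevalence <- unlist(raw$prevalence)
  if (!is.null(raw$follow_up_window)) raw$follow_up_window <- as.numeric(raw$follow_up_window)
  do.call(sim_config, raw)
}

# Distribution of the number of dysregulated markers under the shared-latent
# probit model, by numerical integration over the latent variable.
.flag_count_distribution <- function(prevalence, loading, grid_n = 801) {
  z <- seq(-8, 8, length.out = grid_n)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  qs <- stats::qnorm(1 - prevalence)
  denom <- sqrt(1 - loading^2)
  pmf <- numeric(length(prevalence) + 1L)
  for (i in seq_along(z)) {
    p_flag <- stats::pnorm((loading * z[i] - qs) / denom)
    # Poisson-binomial pmf by convolution across markers
    f <- 1
    for (p in p_flag) f <- c(f * (1 - p), 0) + c(0, f * p)
    pmf <- pmf + w[i] * f
  }
  pmf
}

#' Calibrate the baseline progression hazard to an event-fraction target
#'
#' Solves for the exponential baseline hazard at which the expected fraction
#' of patients with an observed progression (event before uniform censoring
#' over the follow-up window) equals the target, averaging over the
#' flag-count distribution implied by the configured prevalences and latent
#' loading. Deterministic: the flag-count distribution is obtained by
#' numerical integration, and the root is found to a tolerance of 1e-6.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Baseline hazard in events/month.
#' @export
calibrate_baseline_hazard <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pmf <- .flag_count_distribution(config$prevalence, config$latent_loading)
  a <- config$follow_up_window[1]; b <- config$follow_up_window[2]
  hr <- config$hazard_ratio_per_flag
  expected_fraction <- function(base) {
    lam <- base * hr^(seq_along(pmf) - 1L)
    p_obs <- 1 - (exp(-lam * a) - exp(-lam * b)) / (lam * (b - a))
    sum(pmf * p_obs)
  }
  stats::uniroot(function(base) expected_fraction(base) - config$event_fraction_target,
                 interval = c(1e-9, 1), tol = 1e-9, extendInt = "upX")$root
}

# Inverse-CDF draw from a lognormal restricted to one side of a cut-off.
.rlnorm_side <- function(n, meanlog, sdlog, cutoff, side = c("at_or_below", "above")) {
  side <- match.arg(side)
  f_cut <- stats::plnorm(cutoff, meanlog, sdlog)
  u <- if (side == "at_or_below") stats::runif(n, 0, f_cut)
       else stats::runif(n, f_cut, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

.sample_pair <- function(pairs, probs) {
  k <- sample.int(nrow(pairs), 1L, prob = probs)
  pairs[k, ]
}

# Draw one (intensity, quantity) pair conditioned on the marker's
# dysregulation flag; products always satisfy the marker's cut-off side.
.draw_ihc <- function(marker, flag) {
  if (marker == "enos") {
    if (flag) { # score > 1
      i <- sample(2:3, 1L)
      q <- sample(1:4, 1L, prob = c(0.15, 0.25, 0.3, 0.3))
    } else {    # score <= 1
      if (stats::runif(1) < 0.6) { i <- 0L; q <- 0L } else { i <- 1L; q <- 1L }
    }
  } else if (marker == "hif2a") {
    if (flag) { # score > 0
      i <- sample(1:3, 1L, prob = c(0.4, 0.4, 0.2))
      q <- sample(1:4, 1L, prob = c(0.3, 0.3, 0.25, 0.15))
    } else { i <- 0L; q <- 0L }
  } else if (marker == "itgb4") {
    if (flag) { # score > 4
      pq <- .sample_pair(cbind(c(2, 2, 3, 3, 3), c(3, 4, 2, 3, 4)),
                         c(0.25, 0.2, 0.2, 0.2, 0.15))
    } else {    # score <= 4
      pq <- .sample_pair(cbind(c(0, 1, 1, 1, 1, 2, 2), c(0, 1, 2, 3, 4, 1, 2)),
                         c(0.1, 0.1, 0.2, 0.2, 0.1, 0.15, 0.15))
    }
    i <- pq[1]; q <- pq[2]
  } else stop("unknown IHC marker: ", marker)
  c(intensity = as.integer(i), quantity = as.integer(q))
}

#' Generate a synthetic biopsy cohort with marker panels
#'
#' Emulates the study design end to end so every pipeline stage can be
#' exercised without patient data. Per patient: a shared latent
#' aggressiveness variable induces correlated dysregulation indicators for
#' the five markers (probit model); IHC intensity and quantity grades are
#' drawn from flag-conditional categorical distributions and multiplied (so
#' scores are always attainable I x Q products on the flag's side of the
#' published cut-off); transcript ratios are drawn from lognormals
#' restricted to the flag's side of the cut-off; the progression time is
#' exponential with hazard \code{baseline * hazard_ratio_per_flag^n_flags};
#' censoring is uniform over the follow-up window; the observed time is the
#' minimum, rounded up to whole months. PSA (1.79-18.5 ng/mL), age and
#' Gleason/stage categories match the ranges of the clinical table. Output
#' is byte-identical for a given seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return A list with \code{cohort} (a \code{cohort} data frame including
#'   \code{follow_up_time} for censored patients), \code{markers} (a
#'   \code{marker_panel}), \code{flags} (logical matrix of the true
#'   dysregulation indicators) and \code{baseline_hazard} (the value used).
#' @examples
#' sim <- generate_cohort(sim_config(n_patients = 20, seed = 42))
#' table(sim$cohort$recurrence)
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  base <- if (is.null(config$baseline_hazard)) calibrate_baseline_hazard(config)
          else config$baseline_hazard
  markers <- names(config$prevalence)
  rules <- default_bioscore_rules()
  .with_seed(seed, {
    n <- config$n_patients
    l <- config$latent_loading
    z <- stats::rnorm(n)
    flags <- sapply(markers, function(m) {
      eps <- stats::rnorm(n)
      l * z + sqrt(1 - l^2) * eps > stats::qnorm(1 - config$prevalence[[m]])
    })
    flags <- matrix(flags, nrow = n, dimnames = list(NULL, markers))
    ihc <- array(0L, dim = c(n, 3L, 2L),
                 dimnames = list(NULL, c("enos", "hif2a", "itgb4"),
                                 c("intensity", "quantity")))
    for (i in seq_len(n)) {
      for (m in c("enos", "hif2a", "itgb4")) {
        ihc[i, m, ] <- .draw_ihc(m, flags[i, m])
      }
    }
    h19 <- numeric(n); cdh1 <- numeric(n)
    for (i in seq_len(n)) {
      h19[i] <- if (flags[i, "h19"]) {
        .rlnorm_side(1, log(0.4), 0.8, rules$h19$threshold, "at_or_below")
      } else {
        .rlnorm_side(1, log(3), 0.8, rules$h19$threshold, "above")
      }
      cdh1[i] <- if (flags[i, "cdh1"]) {
        .rlnorm_side(1, log(0.05), 1, rules$cdh1$threshold, "above")
      } else {
        # ratio strictly below the CDH1 cut-off counts as not dysregulated
        .rlnorm_side(1, log(0.001), 1, rules$cdh1$threshold, "at_or_below")
      }
      if (cdh1[i] == rules$cdh1$threshold) cdh1[i] <- cdh1[i] * 0.999
    }
    n_flags <- rowSums(flags)
    lambda <- base * config$hazard_ratio_per_flag^n_flags
    t_event <- stats::rexp(n, rate = lambda)
    t_cens <- stats::runif(n, config$follow_up_window[1], config$follow_up_window[2])
    event <- t_event <= t_cens
    obs_time <- pmax(1, ceiling(pmin(t_event, t_cens)))
    psa <- {
      lo <- stats::plnorm(1.79, log(8), 0.45); hi <- stats::plnorm(18.5, log(8), 0.45)
      round(stats::qlnorm(stats::runif(n, lo, hi), log(8), 0.45), 2)
    }
    gs_levels <- c("6 (3 + 3)", "7 (3 + 4)", "7 (4 + 3)", "9 (4 + 5)")
    gs_text <- sample(gs_levels, n, replace = TRUE,
                      prob = c(2, 15, 12, 1) / 30)
    stages <- sample(c("pT2c pNx pMx", "pT2c pN0 pMx", "pT3a pN0 pMx", "pT3b pN0 pMx"),
                     n, replace = TRUE, prob = c(0.40, 0.33, 0.17, 0.10))
    gs <- lapply(gs_text, parse_gleason)
    cohort <- data.frame(
      patient_id = sprintf("SIM#%d", seq_len(n)),
      age = sample(50:78, n, replace = TRUE),
      psa = psa,
      gleason_primary = vapply(gs, `[[`, integer(1), "primary"),
      gleason_secondary = vapply(gs, `[[`, integer(1), "secondary"),
      gleason_total = vapply(gs, `[[`, integer(1), "total"),
      stage = stages,
      recurrence = event,
      time_to_recurrence = ifelse(event, obs_time, NA_real_),
      follow_up_time = ifelse(event, NA_real_, obs_time),
      stringsAsFactors = FALSE)
    cohort$pathologic_gleason <- gs
    class(cohort) <- c("cohort", "data.frame")
    panel <- data.frame(
      patient_id = cohort$patient_id,
      enos_ihc = as.integer(ihc[, "enos", "intensity"] * ihc[, "enos", "quantity"]),
      hif2a_ihc = as.integer(ihc[, "hif2a", "intensity"] * ihc[, "hif2a", "quantity"]),
      itgb4_ihc = as.integer(ihc[, "itgb4", "intensity"] * ihc[, "itgb4", "quantity"]),
      h19_norm = h19,
      cdh1_norm = cdh1,
      stringsAsFactors = FALSE)
    class(panel) <- c("marker_panel", "data.frame")
    list(cohort = cohort, markers = panel, flags = flags, baseline_hazard = base)
  })
}

#' Parameter-recovery experiment over simulated cohorts
#'
#' Repeatedly generates cohorts, runs the full scoring pipeline with the
#' default rules, and records the BioScore binary AUC, sensitivity,
#' specificity and the Cox hazard ratio for low- versus high-risk class.
#' Replicate failures (e.g. a cohort with no events) are recorded, not
#' fatal.
#'
#' @param config A \code{\link{sim_config}}.
#' @param replicates Number of simulated cohorts; >= 1.
#' @param seed Integer master seed; replicate r uses \code{seed + r}.
#' @return A data frame with one row per replicate (\code{replicate},
#'   \code{auc}, \code{sensitivity}, \code{specificity},
#'   \code{hazard_ratio}, \code{hr_ci_low}, \code{hr_ci_high},
#'   \code{n_events}, \code{error}), with a \code{summary} attribute giving
#'   means over successful replicates.
#' @export
recovery_experiment <- function(config = sim_config(), replicates = 100, seed = 1) {
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rows[[r]] <- tryCatch({
      sim <- generate_cohort(config, seed = seed + r)
      scores <- compute_bioscore(sim$markers)
      res <- binary_auc_at_cutoff(scores$score, sim$cohort$recurrence,
                                  cutoff_rule("score", 3, "at_or_above"),
                                  auto_flip = FALSE)
      obs <- pfs_observations(sim$cohort)
      obs$low_risk <- as.integer(scores$risk_class == "low")
      cx <- cox_fit(obs, "low_risk")
      data.frame(replicate = r, auc = res$auc, sensitivity = res$sensitivity,
                 specificity = res$specificity,
                 hazard_ratio = cx$coefficients$hazard_ratio[1],
                 hr_ci_low = cx$coefficients$ci_low[1],
                 hr_ci_high = cx$coefficients$ci_high[1],
                 n_events = sum(sim$cohort$recurrence),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(replicate = r, auc = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, hazard_ratio = NA_real_,
                 hr_ci_low = NA_real_, hr_ci_high = NA_real_,
                 n_events = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  ok <- is.na(out$error)
  attr(out, "summary") <- data.frame(
    replicates = replicates, failed = sum(!ok),
    mean_auc = mean(out$auc[ok]), mean_sensitivity = mean(out$sensitivity[ok]),
    mean_specificity = mean(out$specificity[ok]),
    mean_event_fraction = mean(out$n_events[ok]) / config$n_patients,
    mean_log_hr = mean(log(out$hazard_ratio[ok])))
  out
}
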