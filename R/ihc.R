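#' Bin a percentage of positive cells into the ordinal Quantity grade
#'
#' Semiquantitative IHC reading uses a 0-4 Quantity grade: 0 when no cells
#' stain, 1 for 1-9\% positive cells, 2 for 10-39\%, 3 for 40-69\% and 4 for
#' 70-100\%. Bins are defined on integer percentages; fractional input is
#' rounded to the nearest integer percent before binning.
#'
#' @param percent_positive Percentage of positive cells, 0-100. Vectorized.
#' @return Integer grade(s) in 0..4.
#' @examples
#' quantity_bin(c(0, 5, 25, 50, 70))
#' @export
quantity_bin <- function(percent_positive) {
  if (any(is.na(percent_positive)) ||
      any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent_positive must be in [0, 100]", call. = FALSE)
  }
  p <- round(percent_positive)
  as.integer(ifelse(p == 0, 0L,
             ifelse(p <= 9, 1L,
             ifelse(p <= 39, 2L,
             ifelse(p <= 69, 3L, 4L)))))
}

#' Semiquantitative IHC score: Intensity x Quantity
#'
#' Staining Intensity is graded 0 (negative) to 3 (high) and positive-cell
#' Quantity 0 to 4 (see \code{\link{quantity_bin}}); the slide score is their
#' product, 0-12, assessed separately on normal and tumoral areas.
#'
#' @param intensity Integer 0-3. Vectorized.
#' @param quantity Integer 0-4. Vectorized.
#' @return Integer score(s) in 0..12.
#' @examples
#' ihc_score(2, 3)  # 6
#' @export
ihc_score <- function(intensity, quantity) {
  bad_i <- is.na(intensity) | intensity != as.integer(intensity) |
    intensity < 0 | intensity > 3
  bad_q <- is.na(quantity) | quantity != as.integer(quantity) |
    quantity < 0 | quantity > 4
  if (any(bad_i)) stop("intensity must be an integer in 0..3", call. = FALSE)
  if (any(bad_q)) stop("quantity must be an integer in 0..4", call. = FALSE)
  as.integer(intensity) * as.integer(quantity)
}

# Products attainable as I*Q with I in 0..3, Q in 0..4.
.attainable_ihc_scores <- function() {
  sort(unique(as.vector(outer(0:3, 0:4))))
}

#' Paired tumor-versus-normal comparison of IHC scores
#'
#' Classical paired Student t-test on per-patient (tumor - normal) score
#' differences, the test used to compare marker staining between tumoral and
#' contralateral normal areas. Two degenerate cases are resolved by
#' convention before delegating to the t distribution: when every difference
#' is zero the test is null (t = 0, p = 1); when the differences have zero
#' spread but a nonzero common value the shift is certain at any level and p
#' is reported as 0 with an infinite t.
#'
#' @param tumor_scores,normal_scores Numeric vectors of equal length >= 2,
#'   matched by patient.
#' @return A list with \code{statistic} (t), \code{p_value} (two-sided),
#'   \code{df}, \code{mean_difference} and \code{n}.
#' @examples
#' paired_tumor_normal_test(c(6, 8, 9, 8), c(5, 6, 6, 6))
#' @export
paired_tumor_normal_test <- function(tumor_scores, normal_scores) {
  if (length(tumor_scores) != length(normal_scores)) {
    stop("tumor and normal score vectors must have equal length (matched pairs)",
         call. = FALSE)
  }
  n <- length(tumor_scores)
  if (n < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  d <- as.numeric(tumor_scores) - as.numeric(normal_scores)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = 0, p_value = 1, df = n - 1L,
                  mean_difference = 0, n = n))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0, df = n - 1L,
                mean_difference = mean(d), n = n))
  }
  tt <- stats::t.test(tumor_scores, normal_scores, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate), n = n)
}

#' Aggregate multiple cores per patient to one IHC score
#'
#' When several cores or areas are scored for the same patient, the
#' per-patient value is the maximum tumor-area score by default (worst-region
#' grading); the mean is available as an alternative.
#'
#' @param scores Numeric vector of per-core scores for one patient/marker.
#' @param method \code{"max"} (default) or \code{"mean"}.
#' @return A single numeric score.
#' @export
aggregate_cores <- function(scores, method = c("max", "mean")) {
  method <- match.arg(method)
  if (!length(scores)) stop("no scores to aggregate", call. = FALSE)
  switch(method, max = max(scores), mean = mean(scores))
}
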