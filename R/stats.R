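#' Percent of positive events
#'
#' `100 * count(values >= cutoff) / n`; a tie at the cutoff counts as
#' positive.
#'
#' @param values Intensity vector (at least one value).
#' @param cutoff Positivity cutoff (a.u.).
#' @return Percent in [0, 100].
#' @export
pct_positive <- function(values, cutoff) {
  if (length(values) < 1L)
    stop("insufficient-data error: pct_positive needs >= 1 value",
         call. = FALSE)
  100 * sum(values >= cutoff) / length(values)
}

#' Mean fluorescence intensity
#'
#' Arithmetic mean intensity on the 0--10,000 linear scale, either over
#' all events or over positively stained events only (as used for
#' antigens whose published MFI refers to positive cells).
#'
#' @param values Intensity vector (at least one value).
#' @param mode `"all_events"` or `"positives_only"`.
#' @param cutoff Positivity cutoff; required for `positives_only`.
#' @return MFI in a.u.; `NA` (an undefined statistic, not zero) when
#'   `positives_only` finds no positive event.
#' @export
mfi <- function(values, mode = c("all_events", "positives_only"),
                cutoff = NULL) {
  mode <- match.arg(mode)
  if (length(values) < 1L)
    stop("insufficient-data error: mfi needs >= 1 value", call. = FALSE)
  if (mode == "all_events") return(mean(values))
  if (is.null(cutoff))
    stop("parameter error: positives_only requires a cutoff", call. = FALSE)
  pos <- values[values >= cutoff]
  if (!length(pos)) return(NA_real_)
  mean(pos)
}

#' Coefficient of variation of fluorescence
#'
#' `100 * sample SD / mean` (n - 1 denominator), expressed as percent.
#'
#' @param values Intensity vector, at least two values with positive
#'   mean.
#' @return CV in percent.
#' @export
cv_of <- function(values) {
  if (length(values) < 2L)
    stop("insufficient-data error: cv_of needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0)
    stop("undefined statistic: cv_of requires mean > 0", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Subset fractions among gated NK events
#'
#' @param labels A `gate_result` (or a factor of subset labels).
#' @return Named numeric: percent of NK events per NK subset present in
#'   the gating method (sums to 100).
#' @export
subset_fractions <- function(labels) {
  if (inherits(labels, "gate_result")) labels <- labels$labels
  nk_levels <- intersect(c("NK_low", "NK_int", "NK_high"), levels(labels))
  nk <- labels[labels %in% nk_levels]
  if (!length(nk))
    stop("insufficient-data error: no NK events", call. = FALSE)
  counts <- table(factor(nk, levels = nk_levels))
  stats::setNames(100 * as.numeric(counts) / length(nk), nk_levels)
}

#' Cohort summary of a per-subject statistic
#'
#' Mean, sample SD, median (midpoint convention for even n), minimum and
#' maximum across subjects -- the cells of a cohort reference table.
#'
#' @param per_subject_values Numeric vector, one value per subject
#'   (n >= 2); `NA`s (undefined per-subject statistics) are dropped.
#' @param statistic Optional statistic id carried into the result.
#' @return A one-row data frame of class `cohort_summary` with columns
#'   `statistic`, `mean`, `sd`, `median`, `min`, `max`, `n_subjects`.
#' @export
summarize_cohort <- function(per_subject_values, statistic = NA_character_) {
  x <- per_subject_values[!is.na(per_subject_values)]
  if (length(x) < 2L)
    stop("insufficient-data error: summarize_cohort needs >= 2 subjects",
         call. = FALSE)
  out <- data.frame(statistic = statistic, mean = mean(x),
                    sd = stats::sd(x), median = stats::median(x),
                    min = min(x), max = max(x), n_subjects = length(x))
  class(out) <- c("cohort_summary", class(out))
  out
}
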