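#' Calibrate positivity thresholds from an isotype-control tube
#'
#' The cutoff of each stained channel is an upper quantile of the
#' isotype control's intensity distribution on that channel (default the
#' 99.5th percentile), computed as the order statistic at
#' `ceiling(quantile * n)` so it is monotone in the quantile and matches
#' a direct sort.
#'
#' @param isotype_sample A [sample_events] object from the isotype tube
#'   (at least 1000 events).
#' @param quantile Upper quantile in (0.5, 1); default 0.995. May be a
#'   named vector to set per-channel quantiles.
#' @param channels Channels to calibrate; default all non-scatter
#'   channels.
#' @return An object of class `threshold_set`: list with `cutoffs`
#'   (named by channel id), `quantile`, and `isotype_tube` provenance.
#' @export
calibrate_thresholds <- function(isotype_sample, quantile = 0.995,
                                 channels = NULL) {
  stopifnot(inherits(isotype_sample, "sample_events"))
  n <- nrow(isotype_sample$events)
  if (n < 1000L)
    stop("insufficient-data error: isotype tube has ", n,
         " events (>= 1000 required)", call. = FALSE)
  if (any(quantile <= 0.5) || any(quantile >= 1))
    stop("parameter error: quantile must lie in (0.5, 1)", call. = FALSE)
  if (is.null(channels)) {
    channels <- isotype_sample$channels$channel_id[
      !isotype_sample$channels$channel_id %in% c("FSC", "SSC")]
  }
  q_for <- function(ch) {
    if (length(quantile) > 1L && !is.null(names(quantile)) &&
        ch %in% names(quantile)) quantile[[ch]] else quantile[[1]]
  }
  cutoffs <- vapply(channels, function(ch) {
    x <- sort(isotype_sample$events[, ch])
    x[ceiling(q_for(ch) * n)]
  }, numeric(1))
  structure(list(cutoffs = cutoffs, quantile = quantile,
                 isotype_tube = isotype_sample$tube_id,
                 subject_id = isotype_sample$subject_id),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> isotype tube", x$isotype_tube, "(quantile",
      paste(x$quantile, collapse = "/"), ")\n")
  print(round(x$cutoffs, 2))
  invisible(x)
}

#' Export a threshold set to YAML
#'
#' @param thresholds A `threshold_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  yaml::write_yaml(list(quantile = unname(thresholds$quantile),
                        isotype_tube = thresholds$isotype_tube,
                        cutoffs = as.list(thresholds$cutoffs)), path)
  invisible(path)
}

# cutoff for the channel carrying `marker` in `sample`
cutoff_for <- function(thresholds, sample, marker) {
  ch <- sample$channels$channel_id[channel_for_marker(sample, marker)]
  co <- thresholds$cutoffs[[ch]]
  if (is.null(co))
    stop("panel error: no calibrated cutoff for channel '", ch, "'",
         call. = FALSE)
  co
}

#' Gate CD3-/CD56+ NK-cells
#'
#' Events with CD3 below its cutoff and CD56 at or above its cutoff are
#' NK-cells; CD3-positive events are T-cells; the remainder are labelled
#' `B_or_other`. A tie at a cutoff counts as positive.
#'
#' @param sample A [sample_events] object whose tube carries CD3 and
#'   CD56.
#' @param thresholds A `threshold_set` from [calibrate_thresholds()].
#' @return List with `labels` (factor `T`/`B_or_other`/`NK` per event)
#'   and `nk_mask` (logical).
#' @export
gate_nk <- function(sample, thresholds) {
  cd3 <- marker_values(sample, "CD3")
  cd56 <- marker_values(sample, "CD56")
  co3 <- cutoff_for(thresholds, sample, "CD3")
  co56 <- cutoff_for(thresholds, sample, "CD56")
  t_mask <- cd3 >= co3
  nk_mask <- !t_mask & cd56 >= co56
  labels <- factor(ifelse(t_mask, "T", ifelse(nk_mask, "NK", "B_or_other")),
                   levels = c("T", "B_or_other", "NK"))
  list(labels = labels, nk_mask = nk_mask)
}

subset_levels <- c("T", "B_or_other", "NK_low", "NK_int", "NK_high")

new_gate_result <- function(labels, boundary, fit, sample, method, log) {
  structure(list(labels = factor(labels, levels = subset_levels),
                 cd56_boundary = boundary, fit = fit,
                 tube_id = sample$tube_id, subject_id = sample$subject_id,
                 method = method, log = log),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result>", x$method, "gating of tube", x$tube_id,
      "(subject", paste0(x$subject_id, ")"), "\n")
  print(table(x$labels))
  if (is.finite(x$cd56_boundary))
    cat("  CD56 low/high boundary:", round(x$cd56_boundary, 1), "a.u.\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Conventional two-subset split of gated NK-cells
#'
#' Reproduces the conventional analysis: NK-cells are split into
#' CD56+low and CD56+high using the deterministic CD56 mixture boundary
#' together with differential CD16 positivity (CD56+high cells sit above
#' the CD56 boundary and are CD16-negative/low; everything else is
#' CD56+low). A consistency check warns when the CD56+low gate is less
#' than 95% CD16-positive or the CD56+high gate is majority
#' CD16-positive.
#'
#' @param sample A [sample_events] object (tube must carry CD16).
#' @param thresholds A `threshold_set`.
#' @param nk_mask Logical NK event mask; computed via [gate_nk()] when
#'   omitted.
#' @param boundary Optional CD56 boundary override (a.u.); fitted from
#'   the data by default.
#' @return A `gate_result` with per-event labels in
#'   `{T, B_or_other, NK_low, NK_high}`.
#' @export
split_conventional <- function(sample, thresholds, nk_mask = NULL,
                               boundary = NULL) {
  nk0 <- gate_nk(sample, thresholds)
  if (is.null(nk_mask)) nk_mask <- nk0$nk_mask
  labels <- as.character(nk0$labels)
  log <- character(0)
  fit <- NULL
  if (!any(nk_mask)) {
    return(new_gate_result(labels, NA_real_, NULL, sample, "conventional",
                           "no NK events; split not attempted"))
  }
  cd56 <- marker_values(sample, "CD56")
  cd16 <- marker_values(sample, "CD16")
  co16 <- cutoff_for(thresholds, sample, "CD16")
  if (is.null(boundary)) {
    fit <- fit_cd56_mixture(cd56[nk_mask])
    boundary <- fit$boundary
    if (fit$no_high_component) {
      log <- c(log, "no high CD56 component; all NK events labelled NK_low")
      warning("CD56 distribution looks unimodal in tube '", sample$tube_id,
              "'; single NK class returned", call. = FALSE)
    }
  }
  high <- nk_mask & cd56 >= boundary & cd16 < co16
  if (!is.null(fit) && fit$no_high_component)
    high <- rep(FALSE, length(high))  # no detectable high component
  labels[nk_mask] <- "NK_low"
  labels[high] <- "NK_high"
  # consistency: CD56+low should be CD16+, CD56+high CD16-/low
  low_mask <- labels == "NK_low"
  if (any(low_mask)) {
    p16 <- 100 * mean(cd16[low_mask] >= co16)
    if (p16 < 95) {
      log <- c(log, sprintf("consistency: NK_low only %.1f%% CD16+", p16))
      warning(sprintf("NK_low gate only %.1f%% CD16+ in tube '%s'", p16,
                      sample$tube_id), call. = FALSE)
    }
  }
  new_gate_result(labels, boundary, fit, sample, "conventional", log)
}

#' Three-way split via the pooled CXCR3/CCR5 channel
#'
#' The defining split for the transitional subset: NK events negative on
#' the pooled PE channel are CD56+low; pooled-positive events are
#' CD56+int or CD56+high according to the CD56 boundary, which is fitted
#' on the pooled-positive NK events only. Labels partition the NK gate.
#'
#' @inheritParams split_conventional
#' @return A `gate_result` with per-event labels in
#'   `{T, B_or_other, NK_low, NK_int, NK_high}`.
#' @export
split_three_way <- function(sample, thresholds, nk_mask = NULL,
                            boundary = NULL) {
  nk0 <- gate_nk(sample, thresholds)
  if (is.null(nk_mask)) nk_mask <- nk0$nk_mask
  labels <- as.character(nk0$labels)
  if (!any(nk_mask))
    return(new_gate_result(labels, NA_real_, NULL, sample, "three_way",
                           "no NK events; split not attempted"))
  cd56 <- marker_values(sample, "CD56")
  pe <- marker_values(sample, "CXCR3+CCR5")
  cope <- cutoff_for(thresholds, sample, "CXCR3+CCR5")
  pe_pos <- pe >= cope
  if (!any(nk_mask & pe_pos))
    stop("degenerate-split error: no pooled CXCR3/CCR5-positive NK events ",
         "in tube '", sample$tube_id, "'", call. = FALSE)
  fit <- NULL
  log <- character(0)
  if (is.null(boundary)) {
    # the boundary is fitted on pooled-positive NK events; when those are
    # too few for a stable fit, fall back to all NK events (the high
    # component sits above the low+int bulk there too)
    if (sum(nk_mask & pe_pos) >= 100L) {
      fit <- fit_cd56_mixture(cd56[nk_mask & pe_pos])
    } else {
      fit <- fit_cd56_mixture(cd56[nk_mask])
      log <- c(log, sprintf(
        "only %d pooled-positive NK events; CD56 boundary fitted on all %d NK events",
        sum(nk_mask & pe_pos), sum(nk_mask)))
    }
    boundary <- fit$boundary
    if (fit$no_high_component)
      log <- c(log, "no high CD56 component among pooled-positive NK events")
  }
  labels[nk_mask] <- "NK_low"
  if (!is.null(fit) && fit$no_high_component) {
    # int and high are not separable on CD56: one pooled-positive class
    labels[nk_mask & pe_pos] <- "NK_int"
  } else {
    labels[nk_mask & pe_pos] <- ifelse(cd56[nk_mask & pe_pos] >= boundary,
                                       "NK_high", "NK_int")
  }
  new_gate_result(labels, boundary, fit, sample, "three_way", log)
}
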