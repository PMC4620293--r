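new_test_result <- function(statistic, value, p, n_a, n_b, method) {
  structure(list(statistic = statistic, value = unname(value),
                 p_value = unname(p), n_a = n_a, n_b = n_b,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s = %.4g, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$value, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups, the test
#' used for all group contrasts in the reference analysis. The p-value
#' is exact (full enumeration of rank assignments, doubled one-sided
#' tail) when `max(n_a, n_b) <= 8` and there are no ties, otherwise a
#' normal approximation with continuity and tie correction is used. The
#' reported U is `min(U_a, U_b)`.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param alpha Significance level recorded alongside the result.
#' @return A `test_result` with the U statistic, p-value, sample sizes
#'   and method note (`"exact"` or `"approximate"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2L || n_b < 2L)
    stop("insufficient-data error: mann_whitney needs >= 2 values per group",
         call. = FALSE)
  x <- c(a, b)
  r <- rank(x)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)
  ties <- anyDuplicated(x) > 0L

  if (!ties && max(n_a, n_b) <= 8L) {
    combos <- utils::combn(n_a + n_b, n_a)
    rs <- colSums(matrix(r[combos], nrow = n_a))
    u_all <- rs - n_a * (n_a + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_a), mean(u_all >= u_a)))
    method <- "exact"
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    tie_tab <- table(x)
    s2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                              (n * (n - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(s2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "approximate"
  }
  res <- new_test_result("U", u, p, n_a, n_b, method)
  res$alpha <- alpha
  res$significant <- p < alpha
  res
}

#' Subject-level correlation
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value
#' (t distribution for Pearson; large-sample approximation for
#' Spearman).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `test_result` carrying r and its p-value.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("insufficient-data error: correlate needs >= 3 paired values",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant input vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = method,
    exact = if (method == "spearman") FALSE else NULL))
  new_test_result("r", ct$estimate, ct$p.value, length(x), length(x),
                  method)
}

#' Intermediacy verdict for a transitional subset
#'
#' Formalizes "intermediate expression": the CD56+int group is called
#' intermediate for a marker statistic only if its mean lies strictly
#' between the CD56+low and CD56+high means (in either direction) and
#' both pairwise Mann-Whitney tests (low vs int, int vs high) are
#' significant at `alpha`.
#'
#' @param low,int,high Per-subject values for the three subsets (each
#'   n >= 2).
#' @param alpha Significance level (default 0.05).
#' @param marker,statistic Optional labels carried into the verdict.
#' @return An object of class `intermediacy_verdict`.
#' @export
intermediacy <- function(low, int, high, alpha = 0.05,
                         marker = NA_character_,
                         statistic = NA_character_) {
  m <- c(low = mean(low, na.rm = TRUE), int = mean(int, na.rm = TRUE),
         high = mean(high, na.rm = TRUE))
  strict_between <- (m["low"] < m["int"] & m["int"] < m["high"]) ||
    (m["high"] < m["int"] & m["int"] < m["low"])
  t_li <- mann_whitney(low, int, alpha)
  t_ih <- mann_whitney(int, high, alpha)
  structure(list(marker = marker, statistic = statistic, means = m,
                 is_intermediate = unname(strict_between) &&
                   t_li$p_value < alpha && t_ih$p_value < alpha,
                 low_vs_int = t_li, int_vs_high = t_ih, alpha = alpha),
            class = "intermediacy_verdict")
}

#' @export
print.intermediacy_verdict <- function(x, ...) {
  cat("<intermediacy_verdict>",
      if (is.na(x$marker)) "" else paste0(x$marker, " "),
      if (is.na(x$statistic)) "" else paste0("(", x$statistic, ") "),
      if (x$is_intermediate) "INTERMEDIATE" else "not intermediate", "\n",
      sep = "")
  cat(sprintf("  means low/int/high: %.4g / %.4g / %.4g\n",
              x$means["low"], x$means["int"], x$means["high"]))
  cat(sprintf("  p(low vs int) = %.4g, p(int vs high) = %.4g (alpha %.3g)\n",
              x$low_vs_int$p_value, x$int_vs_high$p_value, x$alpha))
  invisible(x)
}

#' Screening flag for CD56+int expansion
#'
#' A pragmatic screening rule (not part of the reference study's
#' analysis) for the expanded transitional compartment seen in chronic
#' NK-cell lymphoproliferative disorders: a subject is flagged when
#' their CD56+int share exceeds the reference mean by more than `k`
#' reference SDs (strict inequality).
#'
#' @param subject_fraction Subject's CD56+int percent of NK events.
#' @param reference_mean,reference_sd Reference cohort mean and SD
#'   (percent); `reference_sd` must be > 0.
#' @param k Number of SDs (default 3).
#' @return Logical flag.
#' @export
flag_expansion <- function(subject_fraction, reference_mean, reference_sd,
                           k = 3) {
  if (any(reference_sd <= 0))
    stop("parameter error: reference_sd must be > 0", call. = FALSE)
  subject_fraction > reference_mean + k * reference_sd
}

#' Benjamini-Hochberg adjustment helper
#'
#' Optional multiple-testing adjustment for a set of comparison
#' p-values (the reference analysis reports raw p-values; this is off
#' by default in the pipeline).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
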