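infer_protocol <- function(sample) {
  markers <- sample$channels$marker
  if (all(markers %in% c("none", "isotype"))) return("isotype")
  if ("CXCR3+CCR5" %in% markers) return("three_way")
  "conventional"
}

stat_row <- function(subject_id, tube_id, protocol, subset, marker, values,
                     cutoff) {
  pos <- values[values >= cutoff]
  data.frame(
    subject_id = subject_id, tube_id = tube_id, protocol = protocol,
    subset = subset, marker = marker, n_events = length(values),
    pct = pct_positive(values, cutoff),
    mfi_all = mfi(values, "all_events"),
    mfi_pos = mfi(values, "positives_only", cutoff),
    cv_all = if (length(values) >= 2 && mean(values) > 0) cv_of(values)
             else NA_real_,
    cv_pos = if (length(pos) >= 2 && mean(pos) > 0) cv_of(pos)
             else NA_real_,
    stringsAsFactors = FALSE)
}

process_tube <- function(sample, thresholds, logf) {
  protocol <- infer_protocol(sample)
  gr <- if (protocol == "three_way") split_three_way(sample, thresholds)
        else split_conventional(sample, thresholds)
  lab <- gr$labels
  nk_n <- sum(lab %in% c("NK_low", "NK_int", "NK_high"))
  logf(sprintf("subject %s tube %s [%s]: %d events, NK %d (%.1f%%), %s",
               sample$subject_id, sample$tube_id, protocol,
               nrow(sample$events), nk_n,
               100 * nk_n / nrow(sample$events),
               paste(sprintf("%s=%d", levels(lab), tabulate(lab, 5)),
                     collapse = " ")))
  subsets <- if (protocol == "three_way") c("NK_low", "NK_int", "NK_high")
             else c("NK_low", "NK_high")
  markers <- setdiff(unique(sample$channels$marker),
                     c("none", "isotype", "CD3"))
  rows <- list()
  for (m in markers) {
    vals <- marker_values(sample, m)
    co <- cutoff_for(thresholds, sample, m)
    for (s in subsets) {
      sel <- lab == s
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <-
        stat_row(sample$subject_id, sample$tube_id, protocol, s, m,
                 vals[sel], co)
    }
  }
  shares <- NULL
  scatter <- NULL
  if (nk_n > 0) {
    fr <- subset_fractions(gr)
    shares <- data.frame(subject_id = sample$subject_id,
                         tube_id = sample$tube_id, protocol = protocol,
                         subset = names(fr), share = as.numeric(fr),
                         stringsAsFactors = FALSE)
    fsc <- sample$events[, "FSC"]
    ssc <- sample$events[, "SSC"]
    scatter <- do.call(rbind, lapply(subsets, function(s) {
      sel <- lab == s
      if (!any(sel)) return(NULL)
      data.frame(subject_id = sample$subject_id, tube_id = sample$tube_id,
                 subset = s, fsc = mean(fsc[sel]), ssc = mean(ssc[sel]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(stats = do.call(rbind, rows), shares = shares, scatter = scatter,
       gate_log = gr$log, boundary = gr$cd56_boundary)
}

#' Run the full simulate-gate-stats-compare pipeline
#'
#' Orchestrates the whole analysis: simulate (or load) each subject's
#' tubes, calibrate per-subject thresholds from that subject's isotype
#' tube, gate every stained tube (conventional split for single-receptor
#' tubes, three-way split for pooled-channel tubes), compute per-subset
#' statistics, and aggregate cohort tables, group comparisons, the
#' CXCR3--CCR5 subject-level correlation, intermediacy verdicts and
#' expansion flags. Deterministic given `config$seed`.
#'
#' @param config A [nk_cohort_config()] (simulate mode).
#' @param samples Optional pre-loaded data (load mode): nested list
#'   `samples[[subject]][[tube]]` of [sample_events], each subject
#'   including one isotype tube. When given, `config` is not required.
#' @param quantile Isotype quantile for threshold calibration.
#' @param alpha Significance level for comparisons.
#' @param expansion_k SD multiplier for the expansion screening flag.
#' @param out_dir Optional directory; when given, [write_report()] is
#'   called on the result.
#' @param verbose Print per-tube progress lines.
#' @return An object of class `nk_report`; see Details.
#' @details The report bundles: `per_subject` (one row per subject x
#'   tube x subset x marker with percent positive, MFI over all events
#'   and over positives, and both CVs), `shares` and `scatter`,
#'   `cohort_tables` (mean/SD/median/range across subjects for every
#'   statistic), `comparisons` (pairwise Mann-Whitney per marker and
#'   statistic), `correlations` (Pearson and Spearman CXCR3-CCR5),
#'   `intermediacy` (verdicts for CD56, CD16, CD62L, CD94, CD122, CD57,
#'   CD158a), `expansion` (per-subject flags) and `log`.
#' @export
run_pipeline <- function(config = NULL, samples = NULL, quantile = 0.995,
                         alpha = 0.05, expansion_k = 3, out_dir = NULL,
                         verbose = FALSE) {
  log_lines <- character(0)
  logf <- function(msg) {
    log_lines[[length(log_lines) + 1L]] <<- msg
    if (verbose) message(msg)
  }

  if (is.null(samples)) {
    if (is.null(config))
      stop("config error: either a cohort_config or samples are required",
           call. = FALSE)
    subjects <- draw_subject_params(config)
    subject_ids <- vapply(subjects, `[[`, "", "subject_id")
  } else {
    subject_ids <- names(samples)
  }

  all_stats <- list(); all_shares <- list(); all_scatter <- list()
  all_thresh <- list()
  for (i in seq_along(subject_ids)) {
    sid <- subject_ids[i]
    if (is.null(samples)) {
      tubes <- config$tubes
      iso_j <- which(vapply(tubes, function(t) t$protocol == "isotype",
                            logical(1)))[1]
      iso <- simulate_tube(subjects[[i]], tubes[[iso_j]],
                           config$isotype_events,
                           seed = tube_seed(config$seed, i, iso_j))
      thresholds <- calibrate_thresholds(iso, quantile = quantile)
      stained_j <- setdiff(seq_along(tubes), iso_j)
      get_sample <- function(j) simulate_tube(
        subjects[[i]], tubes[[j]], config$n_events_per_tube,
        seed = tube_seed(config$seed, i, j))
    } else {
      subj_samples <- samples[[sid]]
      proto <- vapply(subj_samples, infer_protocol, "")
      if (!any(proto == "isotype"))
        stop("stage error [calibrate, subject ", sid, "]: no isotype tube",
             call. = FALSE)
      iso <- subj_samples[[which(proto == "isotype")[1]]]
      thresholds <- calibrate_thresholds(iso, quantile = quantile)
      stained_j <- which(proto != "isotype")
      get_sample <- function(j) subj_samples[[j]]
    }
    all_thresh[[sid]] <- data.frame(
      subject_id = sid, channel = names(thresholds$cutoffs),
      cutoff = as.numeric(thresholds$cutoffs), stringsAsFactors = FALSE)
    for (j in stained_j) {
      s <- get_sample(j)
      res <- tryCatch(process_tube(s, thresholds, logf),
                      error = function(e)
                        stop("stage error [gate, subject ", sid, ", tube ",
                             s$tube_id, "]: ", conditionMessage(e),
                             call. = FALSE))
      all_stats[[length(all_stats) + 1L]] <- res$stats
      all_shares[[length(all_shares) + 1L]] <- res$shares
      all_scatter[[length(all_scatter) + 1L]] <- res$scatter
    }
  }
  per_subject <- do.call(rbind, all_stats)
  shares <- do.call(rbind, all_shares)
  scatter <- do.call(rbind, all_scatter)
  thresholds_df <- do.call(rbind, all_thresh)
  rownames(per_subject) <- rownames(shares) <- rownames(thresholds_df) <- NULL

  n_subj <- length(subject_ids)
  report <- structure(
    list(per_subject = per_subject, shares = shares, scatter = scatter,
         thresholds = thresholds_df, n_subjects = n_subj, alpha = alpha,
         log = log_lines),
    class = "nk_report")
  report$cohort_tables <- build_cohort_tables(report)
  report$comparisons <- build_comparisons(report, alpha)
  report$correlations <- build_correlations(report)
  report$intermediacy <- build_intermediacy(report, alpha)
  report$expansion <- build_expansion(report, expansion_k)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# reference tube for subset shares / CD56 stats: first three-way tube
reference_tube <- function(report) {
  tw <- unique(report$per_subject$tube_id[
    report$per_subject$protocol == "three_way"])
  if (length(tw)) tw[1] else NA_character_
}

# per-subject vector of one statistic
subject_stat <- function(report, tube, subset, marker, stat) {
  d <- report$per_subject
  sel <- d$tube_id == tube & d$subset == subset & d$marker == marker
  stats::setNames(d[[stat]][sel], d$subject_id[sel])
}

build_cohort_tables <- function(report) {
  d <- report$per_subject
  keys <- unique(d[, c("tube_id", "protocol", "subset", "marker")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    for (stat in c("pct", "mfi_all", "mfi_pos", "cv_all", "cv_pos")) {
      v <- subject_stat(report, keys$tube_id[k], keys$subset[k],
                        keys$marker[k], stat)
      if (sum(!is.na(v)) < 2) next
      s <- summarize_cohort(v, statistic = stat)
      rows[[length(rows) + 1L]] <- cbind(keys[k, ], s, row.names = NULL)
    }
  }
  ref <- reference_tube(report)
  if (!is.na(ref)) {
    sh <- report$shares[report$shares$tube_id == ref, ]
    for (s in unique(sh$subset)) {
      v <- sh$share[sh$subset == s]
      if (length(v) >= 2) {
        srow <- summarize_cohort(v, statistic = "share")
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(tube_id = ref, protocol = "three_way", subset = s,
                     marker = "(subset share)"), srow, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_comparisons <- function(report, alpha) {
  d <- report$per_subject
  rows <- list()
  contrasts <- list(c("NK_low", "NK_int"), c("NK_int", "NK_high"),
                    c("NK_low", "NK_high"))
  keys <- unique(d[, c("tube_id", "protocol", "marker")])
  for (k in seq_len(nrow(keys))) {
    stats_used <- if (keys$protocol[k] == "three_way")
      c("pct", "mfi_all", "mfi_pos") else c("pct", "mfi_all")
    for (stat in stats_used) {
      for (ct in contrasts) {
        va <- subject_stat(report, keys$tube_id[k], ct[1], keys$marker[k],
                           stat)
        vb <- subject_stat(report, keys$tube_id[k], ct[2], keys$marker[k],
                           stat)
        if (sum(!is.na(va)) < 2 || sum(!is.na(vb)) < 2) next
        mw <- mann_whitney(va, vb, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          tube_id = keys$tube_id[k], marker = keys$marker[k],
          statistic = stat, group_a = ct[1], group_b = ct[2],
          U = mw$value, p_value = mw$p_value, method = mw$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_correlations <- function(report) {
  d <- report$per_subject
  t3 <- unique(d$tube_id[d$marker == "CXCR3" & d$protocol == "conventional"])
  t5 <- unique(d$tube_id[d$marker == "CCR5" & d$protocol == "conventional"])
  if (!length(t3) || !length(t5)) return(NULL)
  x <- subject_stat(report, t3[1], "NK_low", "CXCR3", "pct")
  y <- subject_stat(report, t5[1], "NK_low", "CCR5", "pct")
  common <- intersect(names(x), names(y))
  if (length(common) < 3) return(NULL)
  out <- lapply(c("pearson", "spearman"), function(m) {
    ct <- correlate(x[common], y[common], method = m)
    data.frame(pair = "pct CXCR3+ vs pct CCR5+ in CD56+low", method = m,
               r = ct$value, p_value = ct$p_value, n = length(common),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

build_intermediacy <- function(report, alpha) {
  d <- report$per_subject
  plan <- list(CD56 = "mfi_all", CD16 = "mfi_all", CD62L = "mfi_pos",
               CD94 = "mfi_pos", CD122 = "mfi_pos", CD57 = "mfi_pos",
               CD158a = "mfi_pos")
  rows <- list()
  for (m in names(plan)) {
    stat <- plan[[m]]
    tube <- unique(d$tube_id[d$marker == m & d$protocol == "three_way"])
    if (!length(tube)) next
    v <- lapply(c("NK_low", "NK_int", "NK_high"), function(s)
      subject_stat(report, tube[1], s, m, stat))
    if (any(vapply(v, function(x) sum(!is.na(x)) < 2, logical(1)))) next
    verdict <- intermediacy(v[[1]], v[[2]], v[[3]], alpha = alpha,
                            marker = m, statistic = stat)
    rows[[length(rows) + 1L]] <- data.frame(
      marker = m, statistic = stat,
      mean_low = verdict$means[["low"]], mean_int = verdict$means[["int"]],
      mean_high = verdict$means[["high"]],
      p_low_int = verdict$low_vs_int$p_value,
      p_int_high = verdict$int_vs_high$p_value,
      is_intermediate = verdict$is_intermediate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_expansion <- function(report, k) {
  ref <- reference_tube(report)
  if (is.na(ref)) return(NULL)
  sh <- report$shares[report$shares$tube_id == ref &
                        report$shares$subset == "NK_int", ]
  if (nrow(sh) < 2) return(NULL)
  m <- mean(sh$share); s <- stats::sd(sh$share)
  data.frame(subject_id = sh$subject_id, int_share = sh$share,
             reference_mean = m, reference_sd = s, k = k,
             flagged = flag_expansion(sh$share, m, s, k),
             stringsAsFactors = FALSE)
}

#' @export
print.nk_report <- function(x, ...) {
  cat("<nk_report>", x$n_subjects, "subjects;",
      length(unique(x$per_subject$tube_id)), "stained tubes;",
      nrow(x$per_subject), "subject x subset x marker records\n")
  ref <- reference_tube(x)
  if (!is.na(ref)) {
    sh <- x$cohort_tables
    sh <- sh[sh$marker == "(subset share)", ]
    if (nrow(sh))
      cat("  NK subset shares (% of CD56+ NK, cohort mean):",
          paste(sprintf("%s %.1f", sub("NK_", "", sh$subset), sh$mean),
                collapse = ", "), "\n")
  }
  if (!is.null(x$correlations))
    cat(sprintf("  CXCR3-CCR5 correlation: r = %.3f (Pearson) / %.3f (Spearman)\n",
                x$correlations$r[1], x$correlations$r[2]))
  if (!is.null(x$intermediacy))
    cat("  intermediate markers:",
        paste(x$intermediacy$marker[x$intermediacy$is_intermediate],
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.nk_report <- function(object, ...) {
  print(object)
  ct <- object$cohort_tables
  cat("\nCohort tables (mean ± SD, percent to one decimal, MFI as",
      "integers):\n")
  fmt <- function(r) {
    if (r$statistic %in% c("pct", "share"))
      sprintf("%.1f ± %.1f", r$mean, r$sd)
    else sprintf("%.0f ± %.0f", r$mean, r$sd)
  }
  show <- ct[ct$statistic %in% c("share", "pct", "mfi_all", "mfi_pos"), ]
  for (tube in unique(show$tube_id)) {
    cat("\n", tube, "\n", sep = "")
    tt <- show[show$tube_id == tube, ]
    for (i in seq_len(nrow(tt)))
      cat(sprintf("  %-8s %-16s %-8s %s\n", tt$marker[i], tt$subset[i],
                  tt$statistic[i], fmt(tt[i, ])))
  }
  invisible(object)
}

#' Recover the CXCR3--CCR5 subject-level correlation by simulation
#'
#' Repeatedly simulates small cohorts (CXCR3 and CCR5 single-receptor
#' tubes plus an isotype tube), gates each subject with the conventional
#' split, computes the percent of CXCR3+ and of CCR5+ cells within the
#' CD56+low gate, and correlates the two percentages across subjects
#' within each replicate cohort. The mean recovered coefficient
#' estimates how well the generator's configured subject-level
#' correlation survives gating and measurement.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param n_subjects Subjects per cohort.
#' @param n_events,isotype_events Events per stained/isotype tube
#'   (reduced sizes are adequate: the within-subject measurement error
#'   is small against the between-subject spread).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param method Correlation method.
#' @param profile Optional profile sheet (default packaged).
#' @return Numeric vector of per-replicate correlation coefficients.
#' @export
recover_ckr_correlation <- function(n_replicates = 500, n_subjects = 15,
                                    n_events = 2000, isotype_events = 1000,
                                    seed = 1, method = "pearson",
                                    profile = NULL) {
  if (is.null(profile)) profile <- read_profile_sheet()
  vapply(seq_len(n_replicates), function(k) {
    cfg <- nk_cohort_config(profile = profile, n_subjects = n_subjects,
                            n_events_per_tube = n_events,
                            isotype_events = isotype_events,
                            tubes = c("P1_CXCR3", "P1_CCR5"),
                            seed = (seed + 7919 * k) %% 2147483647)
    subs <- draw_subject_params(cfg)
    x <- y <- numeric(n_subjects)
    iso_j <- match("ISO", names(cfg$tubes))
    for (i in seq_len(n_subjects)) {
      iso <- simulate_tube(subs[[i]], cfg$tubes$ISO, cfg$isotype_events,
                           seed = tube_seed(cfg$seed, i, iso_j))
      th <- calibrate_thresholds(iso)
      for (m in c("CXCR3", "CCR5")) {
        tb <- paste0("P1_", m)
        s <- simulate_tube(subs[[i]], cfg$tubes[[tb]], cfg$n_events_per_tube,
                           seed = tube_seed(cfg$seed, i,
                                            match(tb, names(cfg$tubes))))
        gr <- suppressWarnings(split_conventional(s, th))
        p <- pct_positive(marker_values(s, m)[gr$labels == "NK_low"],
                          cutoff_for(th, s, m))
        if (m == "CXCR3") x[i] <- p else y[i] <- p
      }
    }
    correlate(x, y, method = method)$value
  }, numeric(1))
}

#' Write a report bundle to disk
#'
#' Writes tidy CSVs (full precision) and the run log: per-subject
#' statistics, subset shares, scatter summaries, thresholds, cohort
#' tables, comparisons, correlations, intermediacy verdicts and
#' expansion flags.
#'
#' @param report An `nk_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(report$per_subject, "per_subject_stats.csv")
  w(report$shares, "subset_shares.csv")
  w(report$scatter, "scatter_summaries.csv")
  w(report$thresholds, "thresholds.csv")
  w(report$cohort_tables, "cohort_tables.csv")
  w(report$comparisons, "comparisons.csv")
  w(report$correlations, "correlations.csv")
  w(report$intermediacy, "intermediacy.csv")
  w(report$expansion, "expansion_flags.csv")
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
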