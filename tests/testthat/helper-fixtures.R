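# Shared fixture builders (all data generated in code).

# minimal hand-built subject: populations with fully specified expression
make_subject <- function(frequencies, expression, subject_id = "SX") {
  pops <- names(frequencies)
  scatter <- list(event_sd = c(fsc = 20, ssc = 12))
  for (p in pops) scatter[[p]] <- c(fsc = 300, ssc = 150)
  structure(list(subject_id = subject_id, cells = numeric(0),
                 frequencies = frequencies, scatter = scatter,
                 expression = expression),
            class = "subject_params")
}

mk_spec <- function(frac, mp, cvp, mn = 3, cvn = 1) {
  c(frac = frac, mfi_pos = mp, cv_pos = cvp, mfi_neg = mn, cv_neg = cvn)
}

# four-population subject with widely separated, bright markers: latent
# labels should be recoverable almost perfectly by gating
separated_subject <- function() {
  pops <- c("T", "B", "NK_low", "NK_int", "NK_high")
  freq <- c(T = 60, B = 14, NK_low = 18, NK_int = 5, NK_high = 3)
  expr <- lapply(pops, function(p) list(
    CD3 = if (p == "T") mk_spec(100, 2000, 0.3) else mk_spec(0, 2000, 0.3),
    CD56 = switch(p,
                  NK_low = mk_spec(100, 400, 0.25),
                  NK_int = mk_spec(100, 700, 0.25),
                  NK_high = mk_spec(100, 5000, 0.25),
                  mk_spec(0, 400, 0.3)),
    CD16 = switch(p,
                  NK_low = mk_spec(100, 300, 0.3),
                  NK_int = mk_spec(50, 300, 0.3),
                  mk_spec(0, 300, 0.3)),
    `CXCR3+CCR5` = switch(p,
                          NK_int = mk_spec(100, 500, 0.3),
                          NK_high = mk_spec(100, 500, 0.3),
                          mk_spec(0, 500, 0.3)),
    CXCR3 = switch(p,
                   NK_int = mk_spec(100, 500, 0.3),
                   NK_high = mk_spec(100, 500, 0.3),
                   mk_spec(0, 500, 0.3)),
    isotype = mk_spec(0, 30, 0.6)))
  names(expr) <- pops
  make_subject(freq, expr, "SEP")
}

tube_threeway <- list(tube_id = "TW", protocol = "three_way",
                      markers = c(FL1 = "CD16", FL2 = "CXCR3+CCR5",
                                  FL3 = "CD56", FL4 = "CD3"))
tube_conventional <- list(tube_id = "CONV", protocol = "conventional",
                          markers = c(FL1 = "CD16", FL2 = "CXCR3",
                                      FL3 = "CD56", FL4 = "CD3"))
tube_iso <- list(tube_id = "ISO", protocol = "isotype",
                 markers = c(FL1 = "isotype", FL2 = "isotype",
                             FL3 = "isotype", FL4 = "isotype"))

# simple sample_events from a matrix
mk_sample <- function(m, markers = NULL, tube_id = "t1") {
  ch <- data.frame(channel_id = colnames(m),
                   fluorochrome = ifelse(colnames(m) %in% c("FSC", "SSC"),
                                         "none", "PE"),
                   marker = markers %||% rep("none", ncol(m)),
                   stringsAsFactors = FALSE)
  sample_events(m, ch, subject_id = "s", tube_id = tube_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
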