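iso_sample <- function(n = 5000, seed = 1, const = NULL) {
  set.seed(seed)
  subj <- separated_subject()
  s <- simulate_tube(subj, tube_iso, n, seed = seed)
  if (!is.null(const)) s$events[, "FL1"] <- const
  s
}

test_that("isotype threshold calibration matches a direct sort", {
  s <- iso_sample(5000, const = 3.0)
  th <- calibrate_thresholds(s)
  expect_equal(unname(th$cutoffs[["FL1"]]), 3.0)

  s2 <- iso_sample(20000, seed = 2)
  th2 <- calibrate_thresholds(s2, quantile = 0.995)
  for (ch in c("FL1", "FL2", "FL3", "FL4")) {
    x <- sort(s2$events[, ch])
    expect_equal(unname(th2$cutoffs[[ch]]), x[ceiling(0.995 * 20000)])
  }
  # monotone in the quantile
  th_lo <- calibrate_thresholds(s2, quantile = 0.95)
  th_hi <- calibrate_thresholds(s2, quantile = 0.999)
  expect_true(all(th_hi$cutoffs >= th_lo$cutoffs))

  expect_error(calibrate_thresholds(s2, quantile = 0.4), "parameter error")
  expect_error(calibrate_thresholds(s2, quantile = 1), "parameter error")
  tiny <- mk_sample(matrix(runif(20, 0, 10), 10, 2,
                           dimnames = list(NULL, c("FL1", "FL2"))))
  expect_error(calibrate_thresholds(tiny), "insufficient-data")
})

test_that("the CD3-/CD56+ NK gate recovers latent populations", {
  subj <- separated_subject()
  th <- calibrate_thresholds(iso_sample(20000, seed = 3))
  s <- simulate_tube(subj, tube_threeway, 50000, seed = 4)
  g <- gate_nk(s, th)
  truth <- s$latent %in% c("NK_low", "NK_int", "NK_high")
  recall <- sum(g$nk_mask & truth) / sum(truth)
  precision <- sum(g$nk_mask & truth) / sum(g$nk_mask)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
  expect_equal(100 * mean(g$nk_mask), 26, tolerance = 0.05)  # 18+5+3 %

  # all-CD3+ input: empty NK gate
  s$events[, "FL4"] <- 5000
  g2 <- gate_nk(s, th)
  expect_equal(sum(g2$nk_mask), 0)
  expect_true(all(g2$labels == "T"))

  no_cd3 <- mk_sample(matrix(runif(40, 0, 100), 10, 4,
                             dimnames = list(NULL, c("FSC", "SSC", "FL3",
                                                     "FL4"))),
                      markers = c("none", "none", "CD56", "CD19"))
  expect_error(gate_nk(no_cd3, th), "panel error")
})

test_that("the CD56 mixture boundary separates published component locations", {
  set.seed(7)
  lo <- nkckr:::rlnorm_moments(9000, 615, 0.4)
  hi <- nkckr:::rlnorm_moments(1000, 2926, 0.37)
  fit <- fit_cd56_mixture(c(lo, hi))
  expect_false(fit$no_high_component)
  expect_gt(fit$boundary, 615)
  expect_lt(fit$boundary, 2926)
  expect_true(fit$converged)

  # predict() classifies against the boundary
  cls <- predict(fit, c(100, 9000))
  expect_equal(as.character(cls), c("low", "high"))

  # unimodal input: no high component, boundary above the 99th percentile
  set.seed(8)
  uni <- nkckr:::rlnorm_moments(5000, 500, 0.4)
  fit_u <- fit_cd56_mixture(uni)
  expect_true(fit_u$no_high_component)
  expect_gte(fit_u$boundary, quantile(uni, 0.99))

  expect_error(fit_cd56_mixture(runif(50, 1, 10)), "insufficient-data")
})

test_that("the boundary is scale-equivariant and deterministic", {
  set.seed(9)
  x <- c(nkckr:::rlnorm_moments(5000, 466, 0.5),
         nkckr:::rlnorm_moments(500, 2926, 0.37))
  b1 <- cd56_boundary(x)
  b2 <- cd56_boundary(x)          # no random initialisation
  expect_identical(b1, b2)
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(cd56_boundary(x * k), k * b1, tolerance = 1e-8)
  }
})

test_that("conventional split separates CD16-bright low from high NK-cells", {
  subj <- separated_subject()
  th <- calibrate_thresholds(iso_sample(20000, seed = 10))
  s <- simulate_tube(subj, tube_conventional, 50000, seed = 11)
  gr <- suppressWarnings(split_conventional(s, th))
  expect_s3_class(gr, "gate_result")
  # partition of all events
  expect_equal(sum(table(gr$labels)), 50000)

  # latent-label oracle: well-separated profiles misclassify <= 1 %
  lat <- as.character(s$latent)
  lat[lat == "NK_int"] <- "NK_low"  # int folds into conventional low
  nk <- lat %in% c("NK_low", "NK_high")
  agree <- mean(as.character(gr$labels)[nk] == lat[nk])
  expect_gte(agree, 0.99)

  cd16 <- marker_values(s, "CD16")
  expect_gt(mean(cd16[gr$labels == "NK_low"]),
            3 * mean(cd16[gr$labels == "NK_high"]))

  # degenerate: identical CD56 on all NK events -> single class + warning
  s2 <- s
  s2$events[, "FL3"] <- ifelse(gate_nk(s2, th)$nk_mask, 400,
                               s2$events[, "FL3"])
  expect_warning(
    expect_warning(gr2 <- split_conventional(s2, th), "unimodal|single NK"),
    "CD16")   # the all-low gate also trips the CD16 consistency check
  expect_equal(sum(gr2$labels == "NK_high"), 0)
})

test_that("three-way split partitions NK events and matches latent labels", {
  subj <- separated_subject()
  th <- calibrate_thresholds(iso_sample(20000, seed = 12))
  s <- simulate_tube(subj, tube_threeway, 50000, seed = 13)
  gr <- split_three_way(s, th)
  tab <- table(gr$labels)
  expect_equal(sum(tab), 50000)
  expect_equal(sum(tab[c("NK_low", "NK_int", "NK_high")]),
               sum(gate_nk(s, th)$nk_mask))

  nk <- s$latent %in% c("NK_low", "NK_int", "NK_high")
  acc <- mean(as.character(gr$labels)[nk] == as.character(s$latent)[nk])
  expect_gte(acc, 0.98)

  # monotonicity: raising the boundary never moves an event int -> low
  b <- gr$cd56_boundary
  gr_hi <- split_three_way(s, th, boundary = b * 2)
  was_int <- gr$labels == "NK_int"
  expect_false(any(gr_hi$labels[was_int] == "NK_low"))
  # and events only flow high -> int, never the reverse
  was_high <- gr$labels == "NK_high"
  expect_true(all(gr_hi$labels[was_high] %in% c("NK_high", "NK_int")))

  # degenerate: no pooled-positive NK events
  s3 <- s
  s3$events[, "FL2"] <- 1
  expect_error(split_three_way(s3, th), "degenerate-split")
})

test_that("raising the isotype quantile never raises downstream percent positive", {
  subj <- separated_subject()
  iso <- iso_sample(20000, seed = 14)
  s <- simulate_tube(subj, tube_threeway, 20000, seed = 15)
  cd16 <- marker_values(s, "CD16")
  prev <- Inf
  for (q in c(0.95, 0.99, 0.995, 0.999)) {
    th <- calibrate_thresholds(iso, quantile = q)
    p <- pct_positive(cd16, nkckr:::cutoff_for(th, s, "CD16"))
    expect_lte(p, prev)
    prev <- p
  }
})

test_that("thresholds export to YAML", {
  th <- calibrate_thresholds(iso_sample(5000, seed = 16))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(th, f)
  back <- yaml::read_yaml(f)
  expect_equal(back$cutoffs$FL1, unname(th$cutoffs[["FL1"]]))
  expect_equal(back$isotype_tube, "ISO")
})
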