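test_that("lognormal moment matching reproduces mean and CV", {
  # degenerate case: cv = 0 is a point mass
  p0 <- lognormal_from_moments(250, 0)
  expect_equal(unname(p0["log_scale"]), 0)
  expect_equal(exp(unname(p0["log_location"])), 250)

  # Monte-Carlo moment oracle at n = 1e6, 1% tolerance
  set.seed(101)
  for (case in list(c(100, 0.5), c(2926, 0.37), c(3, 1))) {
    p <- lognormal_from_moments(case[1], case[2])
    x <- rlnorm(1e6, p["log_location"], p["log_scale"])
    expect_equal(mean(x), case[1], tolerance = 0.01)
    expect_equal(sd(x) / mean(x), case[2], tolerance = 0.01)
  }
  expect_error(lognormal_from_moments(0, 0.5), "mean must be > 0")
  expect_error(lognormal_from_moments(-3, 0.5), "mean must be > 0")
})

test_that("zero-SD cells make every subject identical to the mean profile", {
  cfg <- nk_cohort_config(n_subjects = 4, n_events_per_tube = 1000,
                          tubes = "P2_CD16", seed = 1)
  cfg$cells$sd <- 0
  cfg$cells$location <- cfg$cells$mean
  subs <- draw_subject_params(cfg)
  for (i in 2:4) expect_equal(subs[[i]]$cells, subs[[1]]$cells)
  expect_equal(unname(subs[[1]]$cells["share.NK_low"]), 90.3)
})

test_that("truncated-normal subject draws recover the published cell means", {
  cfg <- nk_cohort_config(n_subjects = 10000, n_events_per_tube = 1000,
                          tubes = "P2_CD16", seed = 7)
  subs <- draw_subject_params(cfg)
  low <- vapply(subs, function(s) s$cells[["share.NK_low"]], numeric(1))
  expect_equal(mean(low), 90.3, tolerance = 0.2 / 90.3)
  expect_true(all(low >= 83.4 & low <= 98.0))
  # independent rejection-sampling oracle for the same cell
  set.seed(1)
  oracle <- rnorm(5e5, nkckr:::truncnorm_location(90.3, 3.9, 83.4, 98.0),
                  3.9)
  oracle <- oracle[oracle >= 83.4 & oracle <= 98.0]
  expect_equal(mean(low), mean(oracle), tolerance = 0.002)
})

test_that("the Gaussian copula realizes the configured subject-level correlation", {
  cfg <- nk_cohort_config(n_subjects = 10000, n_events_per_tube = 1000,
                          tubes = "P1_CXCR3", seed = 11)
  subs <- draw_subject_params(cfg)
  a <- vapply(subs, function(s) s$cells[["p1.CXCR3.lowtrue.pct"]],
              numeric(1))
  b <- vapply(subs, function(s) s$cells[["p1.CCR5.lowtrue.pct"]],
              numeric(1))
  expect_equal(cor(a, b), 0.656, tolerance = 0.05 / 0.656)
  expect_true(all(a >= 0 & a <= 100))
})

test_that("simulated tubes honour expression specs and latent labels", {
  # single population, one marker at 100%: everything above background
  subj <- make_subject(
    c(NK_high = 100),
    list(NK_high = list(CD3 = mk_spec(0, 800, 0.4),
                        CD56 = mk_spec(100, 2926, 0.37),
                        CD16 = mk_spec(100, 500, 0.2),
                        `CXCR3+CCR5` = mk_spec(100, 500, 0.3),
                        isotype = mk_spec(0, 30, 0.6))))
  s <- simulate_tube(subj, tube_threeway, 5000, seed = 3)
  expect_true(all(marker_values(s, "CD16") > 3))
  expect_equal(levels(s$latent), "NK_high")

  # two-population 50/50 mixture: binomial latent counts within 3 SD
  subj2 <- make_subject(
    c(T = 50, B = 50),
    list(T = list(CD3 = mk_spec(100, 800, 0.4), CD56 = mk_spec(0, 400, 0.3),
                  CD16 = mk_spec(0, 300, 0.3),
                  `CXCR3+CCR5` = mk_spec(0, 500, 0.3),
                  isotype = mk_spec(0, 30, 0.6)),
         B = list(CD3 = mk_spec(0, 800, 0.4), CD56 = mk_spec(0, 400, 0.3),
                  CD16 = mk_spec(0, 300, 0.3),
                  `CXCR3+CCR5` = mk_spec(0, 500, 0.3),
                  isotype = mk_spec(0, 30, 0.6))))
  n <- 40000
  s2 <- simulate_tube(subj2, tube_threeway, n, seed = 4)
  p_hat <- mean(s2$latent == "T")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))

  expect_error(
    simulate_tube(make_subject(c(T = 100), list(T = list())),
                  tube_threeway, 100, seed = 1),
    "no expression spec")
})

test_that("default NK_high profile reproduces the published CD16 positive fraction", {
  cfg <- nk_cohort_config(n_subjects = 2, n_events_per_tube = 1e5,
                          tubes = "P2_CD16", seed = 21)
  cfg$cells$sd <- 0
  cfg$cells$location <- cfg$cells$mean
  subs <- draw_subject_params(cfg)
  s <- simulate_tube(subs[[1]], cfg$tubes$P2_CD16, 1e5, seed = 21)
  iso <- simulate_tube(subs[[1]], cfg$tubes$ISO, 5e4, seed = 22)
  th <- calibrate_thresholds(iso)
  # the generator is calibrated so that the GATED subset reproduces the
  # published fraction (gate exchange included)
  gr <- split_three_way(s, th)
  hi <- gr$labels == "NK_high"
  pct <- pct_positive(marker_values(s, "CD16")[hi],
                      nkckr:::cutoff_for(th, s, "CD16"))
  expect_equal(pct, 28.7, tolerance = 4 / 28.7)
})

test_that("cohort simulation is fully reproducible from its seed", {
  cfg <- nk_cohort_config(n_subjects = 3, n_events_per_tube = 2000,
                          isotype_events = 1500, tubes = "P2_CD16",
                          seed = 33)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$samples$S01$P2_CD16$events,
                   c2$samples$S01$P2_CD16$events)
  expect_identical(c1$samples$S03$ISO$events, c2$samples$S03$ISO$events)
  expect_identical(c1$samples$S02$P2_CD16$latent,
                   c2$samples$S02$P2_CD16$latent)
})

test_that("CD56 median ordering and population frequencies are preserved", {
  cfg <- nk_cohort_config(n_subjects = 2, n_events_per_tube = 5e4,
                          tubes = "P2_CD16", seed = 12)
  subs <- draw_subject_params(cfg)
  s <- simulate_tube(subs[[1]], cfg$tubes$P2_CD16, 5e4, seed = 13)
  cd56 <- marker_values(s, "CD56")
  med <- vapply(c("NK_low", "NK_int", "NK_high"),
                function(p) median(cd56[s$latent == p]), numeric(1))
  expect_true(med["NK_low"] < med["NK_int"])
  expect_true(med["NK_int"] < med["NK_high"])

  emp <- 100 * table(s$latent) / length(s$latent)
  for (p in names(subs[[1]]$frequencies)) {
    f <- subs[[1]]$frequencies[[p]]
    expect_lt(abs(emp[[p]] - f), 3.5 * sqrt(f * (100 - f) / 5e4) + 0.05)
  }
})

test_that("profile sheets round-trip through YAML", {
  prof <- read_profile_sheet()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_profile_sheet(prof, f)
  prof2 <- read_profile_sheet(f)
  expect_equal(prof2$threeway$CD56$NK_high$mfi$mean, 2926)
  expect_equal(prof2$shares$NK_low$mean, 90.3)
  cfg <- nk_cohort_config(profile = f, n_subjects = 2,
                          n_events_per_tube = 1000)
  expect_s3_class(cfg, "cohort_config")
})

test_that("infeasible configuration is rejected", {
  prof <- read_profile_sheet()
  prof$shares$NK_low$min <- 99
  prof$shares$NK_low$max <- 98   # min > max
  expect_error(nk_cohort_config(profile = prof), "infeasible range")
  expect_error(nk_cohort_config(n_subjects = 1), "n_subjects")
  prof2 <- read_profile_sheet()
  prof2$correlated_pairs[[1]]$r <- 1.2
  expect_error(nk_cohort_config(profile = prof2), "correlation")
})
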