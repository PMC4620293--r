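test_that("sample_events enforces its invariants", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("FL1", "FL2")))
  ch <- data.frame(channel_id = c("FL1", "FL2"), fluorochrome = "PE",
                   marker = c("a", "b"))
  expect_s3_class(sample_events(m, ch), "sample_events")
  expect_error(sample_events(m * 1e6, ch), "\\[0, 10000\\]")
  expect_error(sample_events(m[, 1, drop = FALSE], ch), "channel count")
  ch2 <- ch; ch2$channel_id <- c("FL1", "FL1")
  expect_error(sample_events(m, ch2), "duplicate")
  expect_error(sample_events(m[0, , drop = FALSE], ch), "one event")
})

test_that("CSV round-trip preserves the event matrix and layout", {
  set.seed(1)
  m <- matrix(runif(30, 0, 9000), 5, 6,
              dimnames = list(NULL, c("FSC", "SSC", "FL1", "FL2", "FL3",
                                      "FL4")))
  s <- mk_sample(m, markers = c("none", "none", "CD16", "CXCR3", "CD56",
                                "CD3"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(s, f, "csv")
  s2 <- read_events(f)
  expect_equal(nrow(s2$events), 5)
  expect_equal(nrow(s2$channels), 6)
  expect_equal(s2$channels$channel_id, colnames(m))
  expect_equal(unname(s2$events), unname(m), tolerance = 1e-8)

  # one header row plus one row per event
  s3 <- mk_sample(m[1:3, ])
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_events(s3, f3, "csv")
  expect_length(readLines(f3), 4L)
})

test_that("FCS round-trip preserves counts, channel order and intensities", {
  set.seed(2)
  m <- matrix(runif(6 * 500, 0, 10000), 500, 6,
              dimnames = list(NULL, c("FSC", "SSC", "FL1", "FL2", "FL3",
                                      "FL4")))
  s <- mk_sample(m, markers = c("none", "none", "CD16", "CXCR3+CCR5",
                                "CD56", "CD3"))
  f <- withr::local_tempfile(fileext = ".fcs")
  write_events(s, f, "fcs")
  s2 <- read_events(f)
  expect_equal(s2$channels$channel_id, s$channels$channel_id)
  expect_equal(s2$channels$marker, s$channels$marker)
  expect_equal(nrow(s2$events), 500)
  # float32 storage: relative error well below 1e-4
  expect_lt(max(abs(s2$events - s$events) / pmax(s$events, 1)), 1e-4)

  # event-count keyword equals matrix rows (independent parse of TEXT)
  raw <- readBin(f, "raw", file.info(f)$size)
  header <- rawToChar(raw[1:58])
  toff <- as.numeric(substring(header, c(11, 19), c(18, 26)))
  txt <- rawToChar(raw[(toff[1] + 1):(toff[2] + 1)])
  expect_match(txt, "\\$TOT\\|500\\|")
})

test_that("reader output is independent of the file format", {
  set.seed(3)
  m <- matrix(runif(40, 0, 10000), 10, 4,
              dimnames = list(NULL, c("FSC", "SSC", "FL1", "FL2")))
  s <- mk_sample(m, markers = c("none", "none", "CD16", "CD56"))
  fc <- withr::local_tempfile(fileext = ".fcs")
  fv <- withr::local_tempfile(fileext = ".csv")
  write_events(s, fc, "fcs")
  write_events(s, fv, "csv")
  a <- read_events(fc)
  b <- read_events(fv)
  expect_lt(max(abs(a$events - b$events) / pmax(b$events, 1)), 1e-4)
})

test_that("scatter-only samples and generated tubes survive a round-trip", {
  m <- matrix(runif(20, 0, 1000), 10, 2,
              dimnames = list(NULL, c("FSC", "SSC")))
  s <- mk_sample(m)
  f <- withr::local_tempfile(fileext = ".fcs")
  write_events(s, f, "fcs")
  s2 <- read_events(f)
  expect_equal(nrow(s2$events), 10)

  subj <- separated_subject()
  tube <- simulate_tube(subj, tube_threeway, 2000, seed = 5)
  f2 <- withr::local_tempfile(fileext = ".fcs")
  write_events(tube, f2, "fcs")
  back <- read_events(f2)
  expect_equal(colMeans(back$events), colMeans(tube$events),
               tolerance = 1e-5)
})

test_that("unreadable files and unknown panel channels raise clear errors", {
  f <- withr::local_tempfile(fileext = ".fcs")
  m <- matrix(runif(40, 0, 100), 10, 4,
              dimnames = list(NULL, c("FSC", "SSC", "FL1", "FL2")))
  write_events(mk_sample(m), f, "fcs")
  raw <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw[1:(length(raw) - 50)], f)  # truncate DATA
  expect_error(read_events(f), "truncated.*offset|offset.*truncated")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_events(mk_sample(m), f2, "csv")
  expect_error(
    read_events(f2, panel = list(t1 = list(FL9 = "CD16")), tube_id = "t1"),
    "metadata error")
  expect_error(read_events("no/such/file.fcs"), "does not exist")
})

test_that("acquisition validation reports count, range and duplicates", {
  m <- matrix(runif(4e5, 0, 100), 2e5, 2,
              dimnames = list(NULL, c("FSC", "SSC")))
  expect_true(validate_acquisition(mk_sample(m))$pass)

  small <- mk_sample(m[1:10, ])
  rep <- validate_acquisition(small)
  expect_false(rep$pass)
  expect_equal(rep$count_deficit, 199990)

  bad <- mk_sample(m[1:2000, ])
  bad$events[5, 1] <- 10001
  rep2 <- validate_acquisition(bad, min_events = 100)
  expect_false(rep2$pass)
  expect_equal(rep2$range_violations, 1)
})
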