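test_that("Mann-Whitney exact path matches hand enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$value, 0)            # U = min(Ua, Ub)
  expect_equal(r$p_value, 0.1)        # 2/20 assignments as extreme
  expect_equal(r$method, "exact")

  # symmetry: swapping groups leaves U and p unchanged
  r2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$value, r$value)
  expect_equal(r2$p_value, r$p_value)

  # identical groups (ties force the approximation): p ~ 1
  r3 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r3$method, "approximate")
  expect_gt(r3$p_value, 0.9)

  expect_error(mann_whitney(1, c(1, 2)), "insufficient-data")
})

test_that("exact p equals the full-enumeration oracle for all n <= 6 rank patterns", {
  # p depends only on ranks: enumerate every assignment of na ranks out
  # of na+nb, for all tie-free group sizes up to 6, and compare with the
  # independent exact implementation in wilcox.test
  for (na in 2:6) {
    for (nb in c(na, max(2, na - 1))) {
      n <- na + nb
      combos <- combn(n, na)
      for (j in seq_len(ncol(combos))) {
        a <- combos[, j]
        b <- setdiff(seq_len(n), a)
        ours <- mann_whitney(a, b)
        oracle <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
        expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-12)
        expect_equal(ours$method, "exact")
      }
    }
  }
})

test_that("approximate p agrees with the tie-corrected normal reference", {
  set.seed(30)
  for (i in 1:50) {
    a <- round(rnorm(13, 50, 10), 1)
    b <- round(rnorm(15, 55, 10), 1)
    ours <- mann_whitney(a, b)
    oracle <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE))
    expect_equal(ours$method, "approximate")
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-9)
  }
})

test_that("correlation handles perfect, inverse and degenerate inputs", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(correlate(x, x)$value, 1)
  expect_equal(correlate(x, -x)$value, -1)
  expect_error(correlate(x, rep(2, 5)), "undefined-correlation")
  expect_error(correlate(x[1:2], x[1:2]), "insufficient-data")

  set.seed(31)
  a <- rnorm(20); b <- a + rnorm(20)
  expect_equal(correlate(a, b)$value, unname(cor(a, b)), tolerance = 1e-12)
  expect_equal(correlate(a, b, "spearman")$value,
               unname(cor(a, b, method = "spearman")), tolerance = 1e-12)
})

test_that("intermediacy requires strict ordering plus significant contrasts", {
  set.seed(32)
  low <- rnorm(15, 466, 50)
  int <- rnorm(15, 615, 60)
  high <- rnorm(15, 2926, 200)
  v <- intermediacy(low, int, high, marker = "CD56", statistic = "mfi")
  expect_true(v$is_intermediate)
  expect_lt(v$low_vs_int$p_value, 0.05)

  # direction agnostic: relabelling low <-> high gives the same verdict
  v2 <- intermediacy(high, int, low)
  expect_true(v2$is_intermediate)

  # three identical groups: no strict ordering
  same <- rnorm(10, 100, 5)
  expect_false(intermediacy(same, same, same)$is_intermediate)

  # int outside the [low, high] interval: false regardless of p-values
  v3 <- intermediacy(rnorm(15, 100, 1), rnorm(15, 500, 1),
                     rnorm(15, 300, 1))
  expect_false(v3$is_intermediate)
  expect_lt(v3$low_vs_int$p_value, 0.05)
})

test_that("the expansion screening flag applies a strict k-SD rule", {
  expect_false(flag_expansion(6.1, 6.1, 4.0, k = 3))
  expect_true(flag_expansion(50, 6.1, 4.0, k = 3))   # 50 > 6.1 + 12
  expect_false(flag_expansion(6.1, 6.1, 4.0, k = 0)) # strict inequality
  expect_true(flag_expansion(6.2, 6.1, 4.0, k = 0))
  expect_error(flag_expansion(10, 6.1, 0), "reference_sd")
})
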