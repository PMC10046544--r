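# Rank tests, chi-square, Pearson: hand-computed cases, enumeration
# oracles, approximation agreement and convention properties.

test_that("signed-rank exact p and z match the closed-form cases", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(r$p_value, 2 / 32)                    # full enumeration
  expect_equal(r$z_value, -7.5 / sqrt(13.75), tolerance = 1e-9)
  expect_identical(r$statistic, 0)

  # antisymmetric pair: p = 1 by symmetry
  r2 <- wilcoxon_signed_rank(c(3, -3))
  expect_equal(r2$p_value, 1)

  # all differences zero is undefined
  expect_error(wilcoxon_signed_rank(rep(2, 4), rep(2, 4)), "undefined-test")

  # zeros dropped by default, kept in ranking under pratt
  r3 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_identical(r3$n, 3L)
  r4 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3), zero_method = "pratt")
  expect_identical(r4$n, 3L)
  expect_lt(r4$z_value, r3$z_value)  # pratt ranks sit above the zeros
})

test_that("Mann-Whitney exact p matches enumeration cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4, 5))
  expect_identical(r$statistic, 0)
  expect_equal(r$p_value, 0.2)

  # identical multisets: p = 1
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-test p-values equal independent brute-force oracles", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    d <- sample(-5:5, n, replace = TRUE)
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12, info = paste(d, collapse = ","))
  }
  for (i in 1:200) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mann_whitney_p(x, y),
                 tolerance = 1e-12,
                 info = paste(c(x, "|", y), collapse = ","))
  }
})

test_that("exact enumeration agrees with stats::wilcox.test on tie-free data", {
  set.seed(55)
  for (i in 1:50) {
    d <- round(rnorm(sample(4:10, 1)), 4)
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 suppressWarnings(wilcox.test(d, exact = TRUE)$p.value),
                 tolerance = 1e-10)
    x <- round(rnorm(5), 4); y <- round(rnorm(6), 4)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("normal approximation tracks exact enumeration within 0.05", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5), exact_cutoff = 0)
  expect_equal(r$p_value, 2 * pnorm(-7.5 / sqrt(13.75)), tolerance = 1e-9)

  # The exact null distributions are discrete, so pointwise agreement at
  # n <= 12 cannot be uniformly tight; the approximation is good on
  # average and its tie-free error is bounded.
  set.seed(77)
  diffs_sr <- diffs_mw <- c()
  worst_free_sr <- worst_free_mw <- 0
  for (i in 1:300) {
    n <- sample(8:12, 1)
    d <- sample(-6:6, n, replace = TRUE)
    if (all(d == 0)) next
    diffs_sr <- c(diffs_sr, abs(wilcoxon_signed_rank(d)$p_value -
                                  wilcoxon_signed_rank(d, exact_cutoff = 0)$p_value))
    df <- rnorm(n)
    worst_free_sr <- max(worst_free_sr,
                         abs(wilcoxon_signed_rank(df)$p_value -
                               wilcoxon_signed_rank(df, exact_cutoff = 0)$p_value))
    x <- sample(1:8, 6, replace = TRUE); y <- sample(1:8, 6, replace = TRUE)
    diffs_mw <- c(diffs_mw, abs(mann_whitney_u(x, y)$p_value -
                                  mann_whitney_u(x, y, exact_cutoff = 0)$p_value))
    xf <- rnorm(6); yf <- rnorm(6)
    worst_free_mw <- max(worst_free_mw,
                         abs(mann_whitney_u(xf, yf)$p_value -
                               mann_whitney_u(xf, yf, exact_cutoff = 0)$p_value))
  }
  expect_lt(mean(diffs_sr), 0.05)
  expect_lt(mean(diffs_mw), 0.05)
  expect_lt(worst_free_sr, 0.12)
  expect_lt(worst_free_mw, 0.15)
})

test_that("swapping group labels flips the Mann-Whitney z and keeps p", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$z_value, -b$z_value, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("chi-square matches hand arithmetic and the base-R cross-check", {
  r <- chi_square(rbind(c(10, 10), c(5, 15)))
  expect_equal(r$statistic, 8 / 3, tolerance = 1e-9)
  expect_match(r$method_notes, "df = 1")

  expect_equal(chi_square(rbind(c(7, 3), c(7, 3)))$statistic, 0)

  # symptom proportions 33.3% vs 4.7% of 42: counts 14/28 vs 2/40
  r2 <- chi_square(rbind(c(14, 28), c(2, 40)))
  expect_equal(r2$statistic, 11.118, tolerance = 1e-3)

  cc <- suppressWarnings(chisq.test(rbind(c(14, 28), c(2, 40)),
                                    correct = FALSE))
  expect_equal(r2$statistic, unname(cc$statistic), tolerance = 1e-9)
  expect_equal(r2$p_value, cc$p.value, tolerance = 1e-9)

  r3 <- chi_square(rbind(c(14, 28), c(2, 40)), correct = TRUE)
  cc3 <- suppressWarnings(chisq.test(rbind(c(14, 28), c(2, 40))))
  expect_equal(r3$statistic, unname(cc3$statistic), tolerance = 1e-9)

  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "degenerate-table")
})

test_that("Pearson correlation matches hand arithmetic and cor.test", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 1, 2)
  r <- pearson_r(x, y)
  expect_equal(r$statistic, sqrt(9 / 10), tolerance = 1e-9)
  ct <- cor.test(x, y)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)

  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")

  set.seed(13)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(pearson_r(x, y)$statistic), 0.1)
})

test_that("stratification partitions correctly with the zero-gap tie rule", {
  wide <- data.frame(subject_id = paste0("s", 1:8),
                     arm = rep(c("a", "b"), 4),
                     sex = c(rep("F", 5), rep("M", 3)),
                     gap_pre = c(-1, 1, 0, 2, -3, -2, 4, 0))
  by_sex <- stratify(wide, "sex")
  expect_identical(vapply(by_sex, nrow, integer(1)), c(F = 5L, M = 3L))
  expect_message(by_gap <- stratify(wide, "baseline_gap_sign"), "younger")
  expect_identical(nrow(by_gap$older), 3L)
  expect_identical(nrow(by_gap$younger), 5L)
})
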