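# Reference values for the bias summaries are the printed inter-reader
# study rows (mean, SD, n = 144, z = 1.96) and their published 95% CIs.

table3 <- tibble::tibble(
  parameter = c("LVESV", "LVEDV", "RVEDV", "RVSV", "PAPMU_ES"),
  mean = c(-3.1, 2.1, -3.8, -4.2, -0.2),
  sd = c(6.6, 7.0, 9.8, 10.3, 2.5),
  ci_low = c(-4.2, 1.0, -5.4, -5.9, -0.6),
  ci_high = c(-2.0, 3.2, -2.2, -2.5, 0.2))

# construct n paired differences with exactly the given mean and SD
diffs_with <- function(mean, sd, n = 144) {
  x <- scale(seq_len(n))[, 1]
  mean + sd * x / stats::sd(x)
}

test_that("bias CIs reproduce the published bounds at one decimal", {
  for (i in seq_len(nrow(table3))) {
    b <- summarize_bias(diffs_with(table3$mean[i], table3$sd[i]),
                        parameter = table3$parameter[i])
    expect_equal(round(b$ci_low, 1), table3$ci_low[i],
                 info = table3$parameter[i])
    expect_equal(round(b$ci_high, 1), table3$ci_high[i],
                 info = table3$parameter[i])
    expect_equal(b$n, 144)
  }
  # the stroke-volume row: upper bound rounds to the printed 7.9
  b <- summarize_bias(diffs_with(6.5, 8.3))
  expect_equal(round(b$ci_high, 1), 7.9)
})

test_that("acceptability is CI containment in the tolerance range", {
  b_sv <- summarize_bias(diffs_with(6.5, 8.3), tolerance = 4.5)
  expect_false(b_sv$acceptable)
  expect_gt(b_sv$ci_low, 4.5)
  b_esv <- summarize_bias(diffs_with(-3.1, 6.6), tolerance = 7.3)
  expect_true(b_esv$acceptable)
  b_edv <- summarize_bias(diffs_with(2.1, 7.0), tolerance = 10.8)
  expect_true(b_edv$acceptable)
  z <- summarize_bias(rep(0, 10), tolerance = 0.5)
  expect_equal(z$mean_diff, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  expect_true(z$acceptable)
  expect_error(summarize_bias(1), "insufficient-data")
  # monotone: enlarging the half-width never flips acceptable -> not
  d <- diffs_with(2, 4, 50)
  verdicts <- vapply(seq(0.5, 10, by = 0.5), function(hw)
    summarize_bias(d, tolerance = hw)$acceptable, logical(1))
  expect_true(all(diff(verdicts) >= 0))
})

test_that("tolerance ranges derive from intrareader variability", {
  expect_warning(t0 <- derive_tolerance_range(rep(c(0, 0), 5)), "fewer than 30")
  expect_equal(t0$half_width, 0)
  set.seed(101)
  x <- stats::rnorm(10000)
  t1 <- suppressWarnings(derive_tolerance_range(x))
  expect_equal(t1$half_width, 1.96, tolerance = 0.03 / 1.96)
  t2 <- suppressWarnings(derive_tolerance_range(2 * x))
  expect_equal(t2$half_width, 2 * t1$half_width)
  expect_equal(t2$method, "z95")
  # the k-factor method widens the interval for small n and approaches
  # z95 for large n
  y <- stats::rnorm(40)
  k_small <- derive_tolerance_range(y, method = "ki-factor")
  expect_gt(k_small$half_width, derive_tolerance_range(y)$half_width)
  k_large <- derive_tolerance_range(x, method = "ki-factor")
  expect_equal(k_large$half_width, t1$half_width, tolerance = 0.03)
  expect_error(derive_tolerance_range(numeric(0)), "insufficient-data")
})

test_that("outlier detection is the brute-force tolerance filter", {
  d <- c(a = 1, b = -2, c = 8)
  out <- detect_outliers(d, 4.5)
  expect_equal(out$case_id, "c")
  expect_equal(out$half_width, 4.5)
  expect_equal(nrow(detect_outliers(d, 10)), 0)
  out0 <- detect_outliers(d, 0)
  expect_setequal(out0$case_id, c("a", "b", "c"))
  # sorted by |diff| descending, equals a direct filter
  set.seed(7)
  dd <- stats::rnorm(50); names(dd) <- sprintf("k%02d", 1:50)
  hw <- 0.8
  out2 <- detect_outliers(dd, hw)
  expect_setequal(out2$case_id, names(dd)[abs(dd) > hw])
  expect_equal(out2$diff, out2$diff[order(-abs(out2$diff))])
  # outlier count non-increasing in the half-width
  counts <- vapply(seq(0, 3, by = 0.25), function(h)
    nrow(detect_outliers(dd, h)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("bland-altman bias and limits of agreement", {
  ident <- tibble::tibble(v1 = c(1, 2, 3), v2 = c(1, 2, 3))
  ba0 <- bland_altman(ident)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  d <- diffs_with(6.5, 8.3)
  ba <- bland_altman(tibble::tibble(v1 = 100 + d, v2 = 100))
  expect_equal(ba$bias, 6.5)
  expect_equal(ba$loa_low, 6.5 - 1.96 * 8.3, tolerance = 1e-9)
  expect_equal(ba$loa_high, 22.768, tolerance = 1e-3)
  expect_equal(nrow(ba$points), 144)
  expect_error(bland_altman(ident[1, ]), "insufficient-data")
})

test_that("plot data keeps case labels and sound quantiles", {
  pairs <- tibble::tibble(case_id = c("x", "y", "z"),
                          v1 = c(10, 12, 9), v2 = c(11, 10, 9))
  pd <- plot_data(pairs)
  expect_setequal(pd$paired$case_id, pairs$case_id)
  expect_equal(pd$paired$diff, pairs$v1 - pairs$v2)
  expect_setequal(pd$qq$case_id, pairs$case_id)
  expect_equal(pd$qq$sample, sort(pairs$v1 - pairs$v2))
  single <- plot_data(pairs[1, ])
  expect_equal(nrow(single$paired), 1)
  expect_equal(nrow(single$qq), 1)
  # normal synthetic differences lie near the standardised identity line
  set.seed(31)
  d <- stats::rnorm(2000)
  qq <- plot_data(tibble::tibble(v1 = d, v2 = 0))$qq
  fit <- stats::lm(sample ~ theoretical, data = qq)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(unname(stats::coef(fit)[1]), 0, tolerance = 0.05)
})

test_that("tolerance and intrareader CSV round-trips work", {
  tol <- tibble::tibble(parameter = c("LVSV", "LVEDV"),
                        half_width = c(4.5, 10.8),
                        method = "published", n_intra = NA_integer_)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tol, f)
  back <- read_tolerance_csv(f)
  expect_equal(back$half_width, tol$half_width)
  intra <- tibble::tibble(case_id = rep(sprintf("c%d", 1:40), 2),
                          parameter = rep(c("LVSV", "LVEDV"), each = 40),
                          diff = c(stats::rnorm(40, 0, 2), stats::rnorm(40, 0, 5)))
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(intra, f2)
  tt <- tolerance_table(read_intra_diffs_csv(f2))
  expect_equal(nrow(tt), 2)
  expect_equal(tt$half_width[tt$parameter == "LVSV"],
               1.96 * stats::sd(intra$diff[intra$parameter == "LVSV"]))
})
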