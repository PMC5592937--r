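test_that("per-record allele proportions and mixedness follow the read counts", {
  rec <- toy_records(n = 3, ref = "A", alt = "G",
                     pool_ad = c("3,7", "0,12", "9,0"))
  expect_equal(casper_allele_proportion(rec, "G"), c(0.7, 1.0, 0.0))
  expect_equal(is_mixed(rec), c(TRUE, FALSE, FALSE))

  zero <- toy_records(n = 1, pool_ad = "0,0")
  expect_true(is.na(casper_allele_proportion(zero, "G")))
  expect_true(is.na(is_mixed(zero)))

  one_read <- toy_records(n = 1, pool_ad = "5,1")
  expect_true(is_mixed(one_read))
  expect_false(is_mixed(one_read, min_support = 2))
  expect_error(casper_allele_proportion(rec, "T"), "not an allele")
})

test_that("window enumeration matches the closed form", {
  expect_equal(nrow(make_windows(50, 50, 5)), 1)
  w <- make_windows(60, 50, 5)
  expect_equal(w$start, c(0L, 5L, 10L))
  w <- make_windows(12, 5, 2)
  expect_equal(w$start, c(0L, 2L, 4L, 6L))
  expect_warning(w0 <- make_windows(10, 50, 5), "no windows")
  expect_equal(nrow(w0), 0)
  expect_error(make_windows(100, 10, 11), "step")

  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:400, 1)
    W <- sample(1:60, 1)
    s <- sample(1:W, 1)
    w <- suppressWarnings(make_windows(n, W, s))
    expect_equal(nrow(w), if (n < W) 0L else floor((n - W) / s) + 1L)
    if (nrow(w) > 0) {
      expect_true(all(w$end - w$start == W))
      expect_lte(max(w$end), n)
    }
  }
})

test_that("scan statistics are window means of the per-variant tracks", {
  # all records fixed for the target allele: every window (1.0, 0.0)
  fixed <- toy_records(n = 60, pool_ad = "0,12", cm_gt = "1")
  s <- scan_bsa(fixed, window_size = 50, step = 5)
  expect_equal(s$windows$casper_proportion, rep(1, 3))
  expect_equal(s$windows$mixed_proportion, rep(0, 3))

  # 5 mixed variants in a 50-variant window: mixed proportion 0.1
  mixed <- toy_records(n = 50, pool_ad = c(rep("1,11", 5), rep("0,12", 45)))
  s <- scan_bsa(mixed, window_size = 50, step = 5)
  expect_equal(s$windows$mixed_proportion, 0.1)

  # pooled-reads alternative statistic
  two <- toy_records(n = 50, pool_ad = c(rep("5,5", 25), rep("0,20", 25)))
  s_mean <- scan_bsa(two, window_size = 50, step = 50)
  s_pool <- scan_bsa(two, window_size = 50, step = 50, pooled_reads = TRUE)
  expect_equal(s_mean$windows$casper_proportion, 0.75)
  expect_equal(s_pool$windows$casper_proportion, (25 * 5 + 25 * 20) / (25 * 10 + 25 * 20))

  expect_error(scan_bsa(toy_records(pos = c(200L, 100L))), "sorted")
})

test_that("records without a usable target call or pool depth are skipped", {
  recs <- toy_records(n = 60, cm_gt = c(rep("1", 56), "0/1", ".", "1", "1"),
                      pool_ad = c(rep("0,12", 59), "0,0"))
  expect_message(s <- scan_bsa(recs), "Skipping 3")
  expect_equal(nrow(s$variants), 57)
  expect_equal(s$n_skipped, 3)
})

test_that("peak calling maximizes the target proportion with stated tie-breaks", {
  w <- tibble::tibble(
    window = 1:3, start_index = c(0L, 5L, 10L),
    casper_proportion = c(0.5, 0.8, 0.8),
    mixed_proportion = c(0.0, 0.3, 0.1)
  )
  expect_equal(locate_peak(w)$window, 3) # tie on proportion, lower mixed wins
  w$mixed_proportion <- c(0, 0.2, 0.2)
  expect_equal(locate_peak(w)$window, 2) # then smallest start index

  ramp <- toy_records(n = 60, pool_ad = paste0(60:1, ",", 1:60))
  s <- scan_bsa(ramp, window_size = 50, step = 5)
  expect_equal(s$peak, 3) # monotone ramp peaks in the last window
  expect_error(locate_peak(suppressWarnings(scan_bsa(ramp, 50, 5)$windows[0, ])),
               "no windows")
})

test_that("scanning is invariant to shuffling then re-sorting the input", {
  design <- small_design(seed = 13)
  records <- simulate_experiment(design)
  s1 <- scan_bsa(records)
  set.seed(1)
  shuffled <- records[sample.int(nrow(records)), ]
  s2 <- scan_bsa(dplyr::arrange(shuffled, pos))
  expect_identical(tidy(s1), tidy(s2))
})

test_that("tidy, glance and autoplot expose the scan", {
  s <- scan_bsa(toy_records(n = 55, pool_ad = "0,12"), window_size = 50, step = 5)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_true(all(td$casper_proportion >= 0 & td$casper_proportion <= 1))
  g <- glance(s)
  expect_equal(g$n_windows, 2)
  expect_equal(g$peak_casper_proportion, 1)
  expect_s3_class(autoplot(s), "ggplot")
})
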