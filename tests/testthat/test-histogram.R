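test_that("histogram retains values, applies windows, and counts pixels", {
  h <- lifetime_histogram(0.642, bin_width = 0.01)
  expect_equal(h$n_pixels, 1)
  expect_equal(sum(h$counts), 1)
  centers <- h$bin_edges[-1] - 0.005
  expect_equal(centers[which(h$counts == 1)], 0.645)
  # window semantics: values outside are dropped
  hw <- lifetime_histogram(c(0.6, 1.0, 2.4), bin_width = 0.01,
                           time_window = c(0, 1.5))
  expect_equal(hw$n_pixels, 2)
  expect_equal(sort(hw$values), c(0.6, 1.0))
  expect_warning(lifetime_histogram(numeric(0)), "empty")
})

test_that("cutoff at zero percent is the identity", {
  h <- lifetime_histogram(c(0.5, 0.6, 0.7, 5), bin_width = 0.05)
  h0 <- apply_cutoff(h, 0)
  expect_equal(h0$counts, h$counts)
  expect_equal(h0$values, h$values)
  expect_equal(h0$cutoff_percent, 0)
})

test_that("one-percent cutoff trims exactly the extreme values", {
  h <- lifetime_histogram(as.numeric(1:100), bin_width = 1)
  hc <- apply_cutoff(h, 1)
  expect_equal(hc$n_pixels, 98)
  expect_equal(range(hc$values), c(2, 99))
  expect_error(apply_cutoff(h, 50))
  expect_error(apply_cutoff(h, -1))
})

test_that("cutoff is monotone and preserves symmetric means", {
  set.seed(5)
  v <- c(seq(0.5, 1.5, by = 0.01))       # exactly symmetric about 1
  h <- lifetime_histogram(v, bin_width = 0.01)
  ns <- vapply(c(0, 1, 5, 10, 25), function(p)
    apply_cutoff(h, p)$n_pixels, numeric(1))
  expect_true(all(diff(ns) <= 0))
  for (p in c(1, 5, 25))
    expect_equal(mean(apply_cutoff(h, p)$values), 1, tolerance = 1e-12)
})

test_that("single-component extraction is the histogram mean", {
  expect_equal(extract_single_lifetime(
    lifetime_histogram(rep(0.65, 10))), 0.65)
  expect_equal(extract_single_lifetime(
    lifetime_histogram(c(0.6, 0.7))), 0.65)
  expect_error(extract_single_lifetime(
    suppressWarnings(lifetime_histogram(numeric(0)))), "empty")
})

test_that("two narrow components are located to within a bin", {
  set.seed(6)
  v <- c(rnorm(600, 0.65, 0.02), rnorm(400, 1.00, 0.02))
  h <- lifetime_histogram(v, bin_width = 0.01)
  pk <- extract_two_lifetimes(h)
  expect_false(attr(pk, "single_peak"))
  expect_lt(abs(pk[1] - 0.65), 0.011)
  expect_lt(abs(pk[2] - 1.00), 0.011)
  # mixture-model alternative agrees
  pg <- extract_two_lifetimes(h, method = "gmm")
  expect_lt(abs(pg[1] - 0.65), 0.02)
  expect_lt(abs(pg[2] - 1.00), 0.02)
})

test_that("a unimodal histogram is flagged as a single peak", {
  set.seed(7)
  h <- lifetime_histogram(rnorm(500, 0.8, 0.03), bin_width = 0.01)
  pk <- extract_two_lifetimes(h)
  expect_true(attr(pk, "single_peak"))
  expect_lt(abs(pk[1] - 0.8), 0.03)
  expect_true(is.na(pk[2]))
  expect_error(extract_two_lifetimes(
    suppressWarnings(lifetime_histogram(numeric(0)))), "empty")
})

test_that("peak ranking respects prominence, not just height", {
  # a tall narrow spike flanked by zeros and a broad lower mound: both are
  # genuine peaks; two tall bins on the same mound are not two peaks
  v <- c(rep(0.3, 50), rep(1, 20), rep(1.01, 18), rep(1.02, 15),
         rep(0.99, 15))
  h <- lifetime_histogram(v, bin_width = 0.01)
  pk <- extract_two_lifetimes(h, min_separation = 0.1)
  expect_lt(abs(pk[1] - 0.3), 0.011)
  expect_lt(abs(pk[2] - 1.0), 0.03)
})
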