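test_that("mean intensity is total counts over total pixels", {
  expect_equal(mean_intensity(matrix(1, 512, 512)), 1)
  expect_equal(mean_intensity(matrix(0, 16, 16)), 0)
  img <- matrix(0, 8, 8); img[3, 4] <- 32
  expect_equal(mean_intensity(img), 0.5)
})

test_that("spot center is the intensity-weighted centroid", {
  expect_equal(spot_center(rep(0.1, 5), rep(-0.2, 5)),
               c(x = 0.1, y = -0.2))
  expect_equal(spot_center(c(-0.4, 0.4), c(0, 0)), c(x = 0, y = 0))
  expect_equal(spot_center(c(0, 1), c(0, 0), weights = c(3, 1)),
               c(x = 0.25, y = 0))
  expect_error(spot_center(numeric(0), numeric(0)))
})

test_that("mean radius matches the uniform-disk closed form", {
  set.seed(8)
  n <- 1e5; R0 <- 0.7
  r <- R0 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  mr <- mean_radius(r * cos(th), r * sin(th), center = c(0, 0))
  se <- stats::sd(r) / sqrt(n)
  expect_lt(abs(mr - 2 * R0 / 3), 3 * se)
  expect_equal(mean_radius(rep(0.2, 9), rep(0.1, 9)), 0)
})

test_that("spot summary agrees between exit records and binned pixels", {
  st <- simulate_gate_stack(
    fluorophore(1, 0.013, 1e6, source_position(z = 0.1)),
    tissue_optics(), tiny_detector(n = 64, width = 2), tiny_gates(),
    seed = 14, keep_records = TRUE)
  with_rec <- spot_summary(st, center = c(0, 0))
  st$records <- NULL
  binned <- spot_summary(st, center = c(0, 0))
  expect_lt(abs(with_rec$mean_radius - binned$mean_radius),
            st$detector$pitch_x)
  expect_equal(with_rec$mean_intensity, binned$mean_intensity)
  expect_equal(with_rec$depth, 0.1)
})

test_that("centroid of a centered source is unbiased", {
  st <- simulate_gate_stack(
    fluorophore(1, 0.013, 2e6, source_position(x = 0.2, y = -0.1, z = 0.05)),
    tissue_optics(), tiny_detector(n = 32, width = 4), tiny_gates(),
    seed = 15, keep_records = TRUE)
  ctr <- spot_center(st$records$x, st$records$y)
  n <- nrow(st$records)
  se <- stats::sd(st$records$x) / sqrt(n)
  expect_lt(abs(ctr["x"] - 0.2), 3 * se)
  expect_lt(abs(ctr["y"] + 0.1), 3 * se)
})

test_that("intensity declines and radius grows with tissue depth", {
  res <- spot_depth_series(depths = c(0.1, 0.2, 0.3), scale = 0.02,
                           seed = 16)
  expect_true(all(diff(res$mean_intensity) < 0))
  expect_true(all(diff(res$mean_radius) > 0))
})

test_that("mean radius is invariant to the photon budget", {
  opt <- tissue_optics()
  mk <- function(a, seed) {
    st <- simulate_gate_stack(
      fluorophore(1, 0.013, a, source_position(z = 0.1)), opt,
      tiny_detector(n = 32, width = 4), tiny_gates(), seed = seed,
      keep_records = TRUE)
    r <- sqrt(st$records$x^2 + st$records$y^2)
    c(m = mean(r), se = stats::sd(r) / sqrt(length(r)))
  }
  a1 <- mk(1e6, 17); a2 <- mk(2e6, 18)
  expect_lt(abs(a1["m"] - a2["m"]),
            3 * sqrt(a1["se"]^2 + a2["se"]^2))
})
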