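test_that("scene presets carry the standard study parameters", {
  icg <- paper_scene("icg_single", z = 0.3)
  f <- icg$fluorophores[[1]]
  expect_equal(c(f$tau, f$qy, f$a), c(0.65, 0.009, 5e6))
  expect_equal(f$position$z, 0.3)
  expect_equal(icg$optics$mu_s, 300)
  expect_equal(icg$gates$n_gates, 117L)
  expect_equal(icg$detector$pe, 0.13)

  ird <- paper_scene("irdye800_single")
  expect_equal(ird$fluorophores[[1]]$tau, 1)
  expect_equal(ird$fluorophores[[1]]$a, 7.6e7)

  hq <- paper_scene("highqy_1.1ns")
  expect_equal(c(hq$fluorophores[[1]]$tau, hq$fluorophores[[1]]$qy),
               c(1.1, 0.28))

  two <- paper_scene("two_dye_sep", dx = 2, z = 0.1)
  xs <- vapply(two$fluorophores, function(f) f$position$x, numeric(1))
  zs <- vapply(two$fluorophores, function(f) f$position$z, numeric(1))
  expect_equal(sort(xs), c(-1, 1))
  expect_equal(zs, c(0.1, 0.1))
  expect_equal(paper_scene("two_dye_depth", z = 0.3)$fluorophores[[2]]$position$z,
               0.3)
  expect_error(paper_scene("nope"), "icg_single")
})

test_that("run configurations round-trip bit-exactly through files", {
  cfg <- list(scene = list(name = "two_dye_depth", z = 0.3, dx = 2,
                           a = 7.6e7),
              seed = 7L, scale = 0.1,
              analysis = list(ref = "simulated", ref_tau = 0.65,
                              cutoff = 1, bin_width = 0.01))
  for (ext in c(".json", ".yaml")) {
    p <- tempfile(fileext = ext)
    write_run_config(cfg, p)
    back <- read_run_config(p)
    expect_equal(back, cfg)
  }
})

test_that("analytic stacks follow the exact decay and Poisson statistics", {
  g <- tiny_gates()
  st <- analytic_stack(0.65, 1e5, gates = g,
                       detector = detector_config(n_px_x = 8, n_px_y = 8))
  tot <- apply(st$counts, 3, sum)
  expected <- exp(-g$gate_times_ns / 0.65)
  expect_equal(tot / tot[1], expected / expected[1], tolerance = 1e-12)
  expect_equal(sum(st$counts), 1e5, tolerance = 1e-9)

  lam <- 1e4
  sums <- vapply(1:10, function(i)
    sum(analytic_stack(0.65, lam, gates = g,
                       detector = detector_config(n_px_x = 8, n_px_y = 8),
                       mode = "poisson", seed = i)$counts), numeric(1))
  expect_lt(abs(mean(sums) - lam), 3 * sqrt(lam / 10))
})

test_that("background injection adds the expected Poisson counts", {
  g <- gate_config()
  det <- detector_config(n_px_x = 32, n_px_y = 32)
  st <- gate_stack(array(0L, c(32, 32, g$n_gates)), g, det)
  expect_identical(inject_background(st, 0)$counts, st$counts)
  bg <- inject_background(st, 2, seed = 31)
  expect_equal(sum(st$counts), 0)          # input untouched
  lam <- 2 * 32 * 32 * g$n_gates
  expect_lt(abs(sum(bg$counts) - lam), 3 * sqrt(lam))
})

test_that("cutoff and window recover two dyes swamped by background", {
  # two analytic spots (0.65 / 1.0 ns) plus strong uniform background:
  # the raw histogram mean is far off; windowing to the expected range
  # with a 5% cutoff restores both component estimates
  g <- gate_config()
  det <- detector_config(width = 2, height = 2, n_px_x = 48, n_px_y = 48)
  s1 <- analytic_stack(0.65, 4e4, gates = g, detector = det,
                       spot_sigma = 0.08, mode = "poisson",
                       center = c(-0.5, 0), seed = 41)
  s2 <- analytic_stack(1.00, 4e4, gates = g, detector = det,
                       spot_sigma = 0.08, mode = "poisson",
                       center = c(0.5, 0), seed = 42)
  both <- s1; both$counts <- s1$counts + s2$counts
  noisy <- inject_background(both, 0.05, seed = 43)

  cal <- calibrate(compute_phasor(noisy), "analytic", 0.65)
  h_raw <- lifetime_histogram(cal, min_count = 1)
  expect_gt(abs(extract_single_lifetime(h_raw) - 0.825), 0.2)  # swamped

  mx <- multiplex_lifetimes(noisy, ref = "analytic", ref_tau = 0.65,
                            centers = rbind(c(-0.5, 0), c(0.5, 0)),
                            cutoff = 5, time_window = c(0, 1.5),
                            region_radius = 0.25)
  expect_lt(abs(mx$f1 - 0.65), 0.1)
  expect_lt(abs(mx$f2 - 1.00), 0.1)
})

test_that("fixture generation is bit-reproducible", {
  g <- tiny_gates()
  a1 <- analytic_stack(1, 5e3, gates = g, mode = "poisson", seed = 77)
  a2 <- analytic_stack(1, 5e3, gates = g, mode = "poisson", seed = 77)
  expect_identical(a1$counts, a2$counts)
})
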