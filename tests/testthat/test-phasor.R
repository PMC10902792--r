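make_stack <- function(counts_by_gate, gates, det = NULL) {
  # uniform spatial layout: every pixel shares the same per-gate trace
  det <- det %||% detector_config(n_px_x = 2, n_px_y = 2, pe = 0.5)
  G <- gates$n_gates
  arr <- array(rep(counts_by_gate, each = 4), c(2, 2, G))
  gate_stack(arr, gates, det)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("phasor of a delta decay at t = 0 is (1, 0)", {
  g <- tiny_gates()
  tr <- c(100, rep(0, g$n_gates - 1))
  ph <- compute_phasor(make_stack(tr, g))
  expect_equal(unname(ph$g[1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(ph$s[1, 1]), 0, tolerance = 1e-12)
})

test_that("uniform counts over gates tiling a full period give (0, 0)", {
  g <- gate_config(n_gates = 100, gate_step = 500, rep_rate_mhz = 20)
  ph <- compute_phasor(make_stack(rep(7, 100), g))
  expect_lt(abs(ph$g[1, 1]), 1e-10)
  expect_lt(abs(ph$s[1, 1]), 1e-10)
})

test_that("zero-count pixels are flagged invalid", {
  g <- tiny_gates()
  arr <- array(0, c(2, 2, g$n_gates))
  arr[1, 1, 1] <- 5
  st <- gate_stack(arr, g, detector_config(n_px_x = 2, n_px_y = 2))
  ph <- compute_phasor(st)
  expect_false(is.na(ph$g[1, 1]))
  expect_true(all(is.na(ph$g[-1])))
  expect_warning(compute_phasor(gate_stack(array(0, c(2, 2, g$n_gates)), g,
                                           detector_config(n_px_x = 2,
                                                           n_px_y = 2))),
                 "invalid")
})

test_that("discrete exponential phasor matches the direct-summation oracle", {
  g <- gate_config()            # 117 gates at 428 ps, 20 MHz
  tau <- 1
  tk <- g$gate_times_ns
  trace <- exp(-tk / tau)
  ph <- compute_phasor(make_stack(trace, g))
  w <- 2 * pi * 20e-3
  # brute-force oracle: plain accumulation loop
  num_g <- num_s <- den <- 0
  for (k in seq_along(tk)) {
    num_g <- num_g + trace[k] * cos(w * tk[k])
    num_s <- num_s + trace[k] * sin(w * tk[k])
    den <- den + trace[k]
  }
  expect_equal(unname(ph$g[1, 1]), num_g / den, tolerance = 1e-12)
  expect_equal(unname(ph$s[1, 1]), num_s / den, tolerance = 1e-12)
  # and the geometric closed form agrees
  pd <- phasor_discrete(tau, g)
  expect_equal(Re(pd), num_g / den, tolerance = 1e-12)
  expect_equal(Im(pd), num_s / den, tolerance = 1e-12)
})

test_that("calibration with an exact reference is the identity", {
  g <- tiny_gates()
  st <- analytic_stack(0.8, 1e5, gates = g,
                       detector = detector_config(n_px_x = 4, n_px_y = 4))
  raw <- compute_phasor(st)
  cal <- calibrate(raw, phasor_discrete(0.8, g), 0.8)
  # measured reference equals the stack's own phasor -> pixels mapped to
  # the theoretical point; re-calibrating with the theoretical reference
  # is then the identity
  cal2 <- calibrate(cal, phasor_theoretical(0.8, g$rep_rate_mhz), 0.8)
  expect_equal(cal2$g, cal$g, tolerance = 1e-12)
  expect_equal(cal2$s, cal$s, tolerance = 1e-12)
})

test_that("calibration undoes a known rotation and scale distortion", {
  g <- tiny_gates()
  st <- analytic_stack(1.0, 1e5, gates = g,
                       detector = detector_config(n_px_x = 4, n_px_y = 4))
  truth <- calibrate(compute_phasor(st), "self", 1.0)
  distort <- 0.83 * exp(1i * 0.37)
  bent <- truth
  z <- complex(real = truth$g, imaginary = truth$s) * distort
  bent$g <- matrix(Re(z), 4); bent$s <- matrix(Im(z), 4)
  bent$calibrated <- FALSE
  ref_bent <- phasor_theoretical(1.0, g$rep_rate_mhz) * distort
  fixed <- calibrate(bent, ref_bent, 1.0)
  expect_equal(fixed$g, truth$g, tolerance = 1e-10)
  expect_equal(fixed$s, truth$s, tolerance = 1e-10)
})

test_that("degenerate references are rejected", {
  g <- tiny_gates()
  st <- analytic_stack(1, 1e4, gates = g,
                       detector = detector_config(n_px_x = 2, n_px_y = 2))
  expect_error(calibrate(compute_phasor(st), complex(real = 0), 1),
               "origin")
})

test_that("phase and modulation follow the two-argument arctangent", {
  f <- structure(list(g = matrix(c(1, 0.5, 0, NA)),
                      s = matrix(c(0, 0.5, 0, NA)),
                      total = matrix(c(1, 1, 1, 0)), f_mhz = 20,
                      calibrated = TRUE),
                 class = "phasor_field")
  pm <- phase_and_modulation(f)
  expect_equal(pm$phi[1], 0)
  expect_equal(pm$phi[2], pi / 4)
  expect_equal(pm$m[2], sqrt(0.5))
  expect_equal(pm$phi[3], 0)         # atan2(0, 0) = 0: origin pixel
  expect_true(is.na(pm$phi[4]))      # invalid pixel propagates
})

test_that("phase lifetime inverts the phasor angle", {
  expect_equal(phase_lifetime(0, 20), 0, ignore_attr = TRUE)
  expect_equal(phase_lifetime(atan(2 * pi * 0.02 * 1), 20), 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  tau <- phase_lifetime(c(-0.1, 0.3, pi / 2, 2), 20)
  expect_equal(attr(tau, "physical"), c(FALSE, TRUE, FALSE, FALSE))
  expect_true(is.infinite(tau[3]))
})

test_that("self-calibrated noiseless stacks close the pipeline exactly", {
  # full pipeline: analytic stack -> phasor -> calibrate -> tau_phi
  st <- analytic_stack(0.65, 1e6,
                       detector = detector_config(n_px_x = 8, n_px_y = 8))
  fit <- phasor_flim(st, ref_tau = 0.65, ref = "self")
  expect_lt(abs(fit$mean_lifetime - 0.65), 1e-9)
  expect_lt(abs(aggregate_lifetime(fit$field) - 0.65), 1e-9)
})

test_that("calibrated mono-exponential phasors sit on the universal semicircle", {
  for (tau in c(0.3, 0.65, 0.8, 1.0, 1.1, 2.0)) {
    st <- analytic_stack(tau, 1e5,
                         detector = detector_config(n_px_x = 4, n_px_y = 4))
    cal <- calibrate(compute_phasor(st), "analytic", tau)
    resid <- abs((cal$g - 0.5)^2 + cal$s^2 - 0.25)
    expect_lt(max(resid), 1e-9)
  }
})

test_that("shorter lifetimes lie closer to the (1, 0) phasor corner", {
  taus <- c(0.3, 0.65, 1.0, 2.0)
  gs <- vapply(taus, function(tau) {
    st <- analytic_stack(tau, 1e5,
                         detector = detector_config(n_px_x = 2, n_px_y = 2))
    Re(pooled_phasor(calibrate(compute_phasor(st), "analytic", tau)))
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
})

test_that("simulated single dyes are recovered within 3 percent", {
  # end-to-end: simulate -> phasor -> calibrate against a simulated
  # reference -> aggregate lifetime, at two depths
  opt <- tissue_optics(fresnel = FALSE)
  det <- detector_config(width = 2, height = 2, n_px_x = 64, n_px_y = 64,
                         pe = 0.13)
  g <- gate_config()
  set.seed(21)
  for (z in c(0.1, 0.3)) {
    st <- simulate_gate_stack(fluorophore(1, 0.013, 2e7,
                                          source_position(z = z)),
                              opt, det, g)
    ref <- simulate_gate_stack(fluorophore(0.65, 0.009, 2e7,
                                           source_position(z = z)),
                               opt, det, g)
    cal <- calibrate(compute_phasor(st), ref, 0.65)
    expect_lt(abs(aggregate_lifetime(cal) - 1), 0.03)
  }
})
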