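test_that("emission counts follow the rounded exponential decay", {
  fl <- fluorophore(tau = 0.65, qy = 0.009, a = 5e6)
  n <- emission_counts(fl, gate_config())
  expect_equal(n[1], 45000L)            # A = round(a * QY) at t = 0
  expect_equal(n[2], 23294L)            # round(45000 * exp(-0.428/0.65))
  expect_true(all(diff(n) <= 0))
  # flat-decay limit: infinite lifetime keeps every gate at A
  flat <- emission_counts(fluorophore(1e9, 0.5, 1000), gate_config())
  expect_equal(flat, rep(500L, 117))
  # zero budget
  expect_equal(sum(emission_counts(fluorophore(1, 0.5, 0), gate_config())), 0)
})

test_that("zero-budget scene yields an all-zero stack", {
  st <- simulate_gate_stack(fluorophore(1, 0.5, 0), tissue_optics(),
                            tiny_detector(), tiny_gates(), seed = 1)
  expect_equal(sum(st$counts), 0)
  expect_error(simulate_gate_stack(list(), tissue_optics(),
                                   tiny_detector(), tiny_gates()),
               "empty scene")
})

test_that("detected counts never exceed emitted and binning is exhaustive", {
  fl <- fluorophore(1, 0.013, 5e5, source_position(z = 0.05))
  st <- simulate_gate_stack(fl, tissue_optics(), tiny_detector(),
                            tiny_gates(), seed = 3, keep_records = TRUE)
  expect_lte(sum(st$counts), sum(st$n_emitted))
  # every kept photon lands in exactly one pixel of one gate page
  expect_equal(sum(st$counts), sum(st$n_detected))
  expect_equal(nrow(st$records), sum(st$n_detected))
  expect_true(all(st$counts >= 0))
  expect_equal(dim(st$counts), c(32L, 32L, 30L))
})

test_that("photon-efficiency thinning keeps the expected fraction", {
  fl <- fluorophore(1, 0.013, 1e6, source_position(z = 0.05))
  opt <- tissue_optics()
  det1 <- tiny_detector()                     # pe = 1
  det13 <- det1; det13$pe <- 0.13
  st1 <- simulate_gate_stack(fl, opt, det1, tiny_gates(), seed = 7)
  st13 <- simulate_gate_stack(fl, opt, det13, tiny_gates(), seed = 7)
  n1 <- sum(st1$counts); n13 <- sum(st13$counts)
  se <- sqrt(0.13 * 0.87 * n1)
  expect_lt(abs(n13 - 0.13 * n1), 3 * se)
})

test_that("doubling the photon budget doubles expected detected counts", {
  opt <- tissue_optics()
  st_a <- simulate_gate_stack(fluorophore(1, 0.013, 1e6,
                                          source_position(z = 0.05)),
                              opt, tiny_detector(), tiny_gates(), seed = 8)
  st_b <- simulate_gate_stack(fluorophore(1, 0.013, 2e6,
                                          source_position(z = 0.05)),
                              opt, tiny_detector(), tiny_gates(), seed = 9)
  n_a <- sum(st_a$counts); n_b <- sum(st_b$counts)
  expect_lt(abs(n_b - 2 * n_a), 3 * sqrt(n_b + 4 * n_a))
})

test_that("per-gate detected counts decay with the source lifetime", {
  # detection probability is gate-independent, so a log-linear fit of the
  # per-gate totals recovers -1/tau
  fl <- fluorophore(1, 0.1, 2e6, source_position(z = 0.05))
  st <- simulate_gate_stack(fl, tissue_optics(),
                            tiny_detector(width = 4), gate_config(),
                            seed = 10)
  tot <- apply(st$counts, 3, sum)
  tk <- st$gates$gate_times_ns
  sel <- 1:8                                  # high-count gates
  slope <- stats::coef(stats::lm(log(tot[sel]) ~ tk[sel]))[2]
  expect_lt(abs(slope - (-1)) / 1, 0.05)
})

test_that("total intensity image conserves and localizes counts", {
  st <- simulate_gate_stack(fluorophore(1, 0.5, 0), tissue_optics(),
                            tiny_detector(), tiny_gates(), seed = 1)
  expect_equal(total_intensity_image(st), matrix(0, 32, 32))
  # one photon placed manually in gate 3
  st$counts[10, 10, 3] <- 1L
  img <- total_intensity_image(st)
  expect_equal(sum(img), 1)
  expect_equal(img[10, 10], 1)
  expect_equal(sum(img), sum(st$counts))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  fl <- fluorophore(0.65, 0.009, 2e5, source_position(z = 0.05))
  s1 <- simulate_gate_stack(fl, tissue_optics(), tiny_detector(),
                            tiny_gates(), seed = 99)
  s2 <- simulate_gate_stack(fl, tissue_optics(), tiny_detector(),
                            tiny_gates(), seed = 99)
  expect_identical(s1$counts, s2$counts)
})
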