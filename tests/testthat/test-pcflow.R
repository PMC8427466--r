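test_that("velocity decoding is linear in phase with aliasing detection", {
  expect_equal(as.numeric(decode_velocity(matrix(pi / 2), 66)), 33)
  expect_equal(as.numeric(decode_velocity(matrix(0), 66)), 0)
  expect_equal(as.numeric(decode_velocity(matrix(-pi / 4), 33)), -8.25)
  expect_false(attr(decode_velocity(matrix(0.9 * pi), 33), "aliasing"))
  expect_true(attr(decode_velocity(matrix(0.96 * pi), 33), "aliasing"))
  expect_error(decode_velocity(matrix(0), -1), "venc")
})

test_that("frame flow sums voxel-area-weighted velocities in ml/min", {
  v <- matrix(0, 10, 10)
  roi <- matrix(TRUE, 10, 10)
  expect_equal(frame_flow(v, roi, 0.043264), 0)

  v <- matrix(10, 10, 10)   # 100 voxels at 10 cm/s
  expect_equal(frame_flow(v, roi, 0.208^2), 25.9584, tolerance = 1e-10)

  # doubling velocities doubles flow (linearity)
  set.seed(3)
  v <- matrix(runif(100, -5, 30), 10, 10)
  expect_equal(frame_flow(2 * v, roi, 0.04), 2 * frame_flow(v, roi, 0.04))

  expect_error(frame_flow(v, matrix(FALSE, 10, 10), 0.04), "empty")
})

test_that("discretised parabolic flow approaches the closed form", {
  closed_form <- function(R_mm, vmax) pi * (R_mm / 10)^2 * vmax / 2 * 60
  disc_flow <- function(px_mm, R_mm, vmax, n) {
    centre <- c(n / 2 + 1, n / 2 + 1)
    r <- px_mm * sqrt(outer((seq_len(n) - centre[1])^2,
                            (seq_len(n) - centre[2])^2, "+"))
    v <- vmax * pmax(0, 1 - (r / R_mm)^2)
    frame_flow(v, r <= R_mm, px_mm^2)
  }
  truth <- closed_form(1.75, 20)
  expect_equal(truth, 57.727, tolerance = 1e-4)
  # at the acquisition's 0.208 mm voxels: within 5%
  err208 <- abs(disc_flow(0.208, 1.75, 20, 96) - truth) / truth
  expect_lt(err208, 0.05)
  # refining the grid shrinks the error
  err104 <- abs(disc_flow(0.104, 1.75, 20, 192) - truth) / truth
  err052 <- abs(disc_flow(0.052, 1.75, 20, 384) - truth) / truth
  expect_lt(err104, err208)
  expect_lt(err052, err104)
})

test_that("cycle averaging integrates periodically and is period-invariant", {
  t12 <- (0:11) * (60000 / 350) / 12
  const <- flow_curve(rep(42, 12), t12, "infra_IVC", 350)
  expect_equal(cycle_mean_flow(const), 42)

  # single harmonic sampled uniformly: periodic trapezoid is exact
  period <- 60000 / 350
  f <- 50 + 10 * sin(2 * pi * t12 / period)
  expect_equal(cycle_mean_flow(flow_curve(f, t12, "x", 350)), 50,
               tolerance = 1e-12)

  # identical curves at different heart rates share the time-average
  t300 <- (0:11) * (60000 / 300) / 12
  t400 <- (0:11) * (60000 / 400) / 12
  f2 <- 30 + 5 * cos(2 * pi * (0:11) / 12)
  expect_equal(cycle_mean_flow(flow_curve(f2, t300, "x", 300)),
               cycle_mean_flow(flow_curve(f2, t400, "x", 400)))

  expect_error(cycle_mean_flow(flow_curve(f2[1:2], t300[1:2], "x", 300)),
               "3 frames")
  bad <- flow_curve(f2, rev(t300), "x", 300)
  expect_error(cycle_mean_flow(bad), "increasing")
})

test_that("caval subtraction normalises flow difference to liver weight", {
  expect_equal(caval_subtraction_tlbf(70, 30, 20), 200)
  expect_equal(caval_subtraction_tlbf(50, 50, 20), 0)
  expect_equal(caval_subtraction_tlbf(60.9, 14.0, 14), 335)
  expect_warning(neg <- caval_subtraction_tlbf(30, 40, 20), "negative")
  expect_equal(neg, -50)
  expect_error(caval_subtraction_tlbf(70, 30, 0), "positive")
})

test_that("partial-volume rule compares voxel width to a third of the diameter", {
  expect_true(partial_volume_check(3.5, 0.208))
  expect_false(partial_volume_check(0.6, 0.208))
  expect_true(partial_volume_check(3.0, 1.0))   # boundary inclusive
})

test_that("simulated cines recover the configured TLBF by caval subtraction", {
  ph <- tiny_phantom(seed = 5, tlbf_true = 335, pulsatility_fraction = 0.2)
  supra <- simulate_pc_cine(ph, "supra_IVC", n_phases = 13)
  infra <- simulate_pc_cine(ph, "infra_IVC", n_phases = 13)
  fr <- flow_result(supra, infra, ph$liver_weight_g)
  expect_true(fr$partial_volume_ok)
  expect_false(any(fr$aliasing))
  expect_rel_equal(fr$tlbf, 335, 0.05)
})
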