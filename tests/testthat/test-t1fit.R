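test_that("gaussian smoothing preserves mass and matches kernel arithmetic", {
  # constant image is unchanged (unit-sum kernel, reflect padding)
  const <- matrix(7.3, 20, 20)
  expect_equal(gaussian_smooth(const), const, tolerance = 1e-12)

  # unit impulse: centre value equals the central kernel weight
  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  sm <- gaussian_smooth(imp, sigma = 1.6)
  expect_equal(sm[21, 21], 1 / (2 * pi * 1.6^2), tolerance = 1e-3)
  expect_equal(sum(sm), 1, tolerance = 1e-12)   # mass conserved

  # interior mean preserved on a random image
  set.seed(1)
  img <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
  sm <- gaussian_smooth(img)
  interior <- 20:108
  expect_lt(abs(mean(sm[interior, interior]) - mean(img[interior, interior])) /
              mean(img[interior, interior]), 1e-3)

  expect_error(gaussian_smooth(img, sigma = 0), "positive")
})

test_that("Look-Locker correction follows T1 = T1* (alpha - 1)", {
  expect_equal(looklocker_correct(600, 2.0), 600)
  expect_equal(looklocker_correct(600, 1.9), 540)
  expect_true(is.na(looklocker_correct(600, 1.0)))
  expect_equal(looklocker_correct(c(600, 700), c(1.9, 2.0)), c(540, 700))
  expect_error(looklocker_correct(-5, 1.9), "positive")
})

test_that("recovery fitting is exact on noiseless curves and robust to noise", {
  tis <- 110 * (1:50)
  y <- ir_curve(1000, 1.9, 700, tis)
  f <- fit_recovery(y, tis)
  expect_true(f$valid)
  expect_rel_equal(f$m0, 1000, 1e-6)
  expect_rel_equal(f$alpha, 1.9, 1e-6)
  expect_rel_equal(f$t1_star, 700, 1e-6)
  expect_rel_equal(f$t1, 630, 1e-6)

  # magnitude input: polarity restored before fitting
  fm <- fit_recovery(abs(y), tis)
  expect_true(fm$valid)
  expect_rel_equal(fm$t1, 630, 1e-6)

  # Monte-Carlo bias at SNR 100: median relative T1 error under 2%
  set.seed(7)
  errs <- replicate(500, {
    fit_recovery(y + rnorm(50, 0, 10), tis)$t1
  })
  expect_lt(median(abs(errs - 630)) / 630, 0.02)

  # degenerate inputs yield invalid results, not errors
  expect_false(fit_recovery(rep(0, 50), tis)$valid)
  expect_false(fit_recovery(c(1, 2, NA, NA), 110 * (1:4))$valid)
  expect_false(fit_recovery(y[1:3], tis[1:3])$valid)
})

test_that("profiled fit matches a brute-force grid minimiser of the objective", {
  tis <- 110 * (1:50)
  set.seed(42)
  for (rep in 1:20) {
    m0 <- runif(1, 500, 2000)
    alpha <- runif(1, 1.5, 2.1)
    t1s <- runif(1, 300, 2500)
    y <- ir_curve(m0, alpha, t1s, tis) + rnorm(50, 0, 15)
    f <- fit_recovery(y, tis)

    # dense 3-D grid over (M0, alpha, T1*) around the generative values
    m0g <- seq(0.7 * m0, 1.3 * m0, length.out = 31)
    alg <- seq(1.3, 2.2, length.out = 31)
    tsg <- seq(0.6 * t1s, 1.6 * t1s, length.out = 61)
    best <- Inf
    for (ts in tsg) {
      e <- exp(-tis / ts)
      for (a in alg) {
        # residual sum over the m0 grid, vectorised
        basis <- 1 - a * e
        bb <- sum(basis^2)
        by <- sum(basis * y)
        rss <- sum(y^2) - 2 * m0g * by + m0g^2 * bb
        best <- min(best, min(rss))
      }
    }
    expect_lte(f$rss, best + 1e-8)
  }
})

test_that("fitted T1* increases with the true T1*", {
  tis <- 110 * (1:50)
  fits <- vapply(seq(400, 2400, by = 400), function(ts) {
    fit_recovery(ir_curve(1000, 1.9, ts, tis), tis)$t1_star
  }, numeric(1))
  expect_false(is.unsorted(fits, strictly = TRUE))
})

test_that("map fitting recovers phantom ground truth pixel-wise", {
  ph <- tiny_phantom(seed = 2)
  ser <- simulate_fair_series(ph, "global")
  maps <- fit_t1_map(ser, smooth = FALSE)
  truth <- phantom_truth_maps(ph)
  tissue <- ph$region > 0L
  expect_true(all(maps$valid[tissue]))
  expect_rel_equal(maps$t1[tissue], truth$t1[tissue], 1e-4)
  # background is invalid, never fitted to nonsense
  expect_false(any(maps$valid[!tissue]))

  # a single all-zero pixel becomes exactly that invalid pixel
  ser2 <- ser
  ser2$images[10, 12, ] <- 0
  maps2 <- fit_t1_map(ser2, smooth = FALSE)
  expect_false(maps2$valid[10, 12])
  expect_true(maps2$valid[10, 13])

  # smoothing a spatially uniform series changes nothing
  proto <- tiny_protocol(matrix_size = 16L, n_readouts = 50L)
  tis <- protocol_tis(proto)
  imgs <- array(rep(ir_curve(1000, 1.9, 700, tis), each = 256), c(16, 16, 50))
  useries <- ir_series(imgs, tis, "global", proto)
  m_raw <- fit_t1_map(useries, smooth = FALSE)
  m_sm <- fit_t1_map(useries, smooth = TRUE)
  expect_equal(m_sm$t1, m_raw$t1, tolerance = 1e-9)
})
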