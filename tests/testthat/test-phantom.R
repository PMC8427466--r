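test_that("cohort generation honours the configured distributions", {
  # zero-variance draws reproduce the group means exactly
  cc <- cohort_config(n_sham = 4L, n_bdl = 3L,
                      sham_perfusion = c(316, 0), bdl_perfusion = c(199, 0),
                      sham_t1 = c(1256, 0), bdl_t1 = c(1533, 0),
                      sham_weight = c(14, 0), bdl_weight = c(30, 0),
                      sham_tlbf_offset = c(144, 0),
                      bdl_tlbf_offset = c(-54, 0),
                      sham_lps_perfusion = c(78, 0),
                      bdl_lps_perfusion = c(-49, 0),
                      sham_lps_t1 = c(0.2, 0), bdl_lps_t1 = c(14, 0),
                      attrition_probability_bdl = 0)
  cohort <- build_cohort(cc, seed = 5, grid_shape = c(8L, 8L))
  tt <- cohort_truth_table(cohort)
  expect_equal(nrow(tt), 7L)
  expect_equal(tt$perfusion[tt$cohort == "sham"], rep(316, 4))
  expect_equal(tt$perfusion[tt$cohort == "BDL"], rep(199, 3))
  expect_equal(tt$tlbf[tt$cohort == "sham"], rep(316 + 144, 4))
  expect_false(any(tt$lost_post_lps))

  # identical cohort under a fixed seed
  c1 <- cohort_truth_table(build_cohort(cohort_config(), seed = 11,
                                        grid_shape = c(8L, 8L)))
  c2 <- cohort_truth_table(build_cohort(cohort_config(), seed = 11,
                                        grid_shape = c(8L, 8L)))
  expect_identical(c1, c2)

  expect_error(cohort_config(n_sham = 0L), "at least 1")
})

test_that("large simulated cohorts recover the generator means", {
  cc <- cohort_config(n_sham = 2000L, n_bdl = 2000L)
  tt <- cohort_truth_table(build_cohort(cc, seed = 42, grid_shape = c(8L, 8L)))
  for (g in c("sham", "BDL")) {
    cfg <- if (g == "sham") cc$sham_perfusion else cc$bdl_perfusion
    v <- tt$perfusion[tt$cohort == g]
    sem <- cfg[2] / sqrt(length(v))
    expect_lt(abs(mean(v) - cfg[1]), 3 * sem)
    cfg_t1 <- if (g == "sham") cc$sham_t1 else cc$bdl_t1
    t1v <- tt$t1[tt$cohort == g]
    expect_lt(abs(mean(t1v) - cfg_t1[1]), 3 * cfg_t1[2] / sqrt(length(t1v)))
  }
  # BDL attrition close to its configured probability
  expect_lt(abs(mean(tt$lost_post_lps[tt$cohort == "BDL"]) - 2 / 9), 0.03)
})

test_that("slice-selective T1 reflects the perfusion shortening", {
  expect_equal(t1_slice_selective_from_perfusion(1256, 0), 1256)
  expect_equal(t1_slice_selective_from_perfusion(1256, 140), 1200)
  expect_equal(t1_slice_selective_from_perfusion(1256, 316), 1256 / (1 + 316 / 3000))
  expect_equal(round(t1_slice_selective_from_perfusion(1256, 316), 1), 1136.3)
  expect_error(t1_slice_selective_from_perfusion(-5, 100), "positive")
})

test_that("FAIR forward model nulls at T1* log(alpha) and is invertible", {
  # with alpha = 2, T1* = T1 and the null crossing sits at T1 ln 2
  ph <- tiny_phantom(t1_liver_ms = 540, alpha_true = 2, perfusion_liver = 0)
  proto <- fair_protocol(matrix_size = 32L, n_readouts = 50L,
                         ti_spacing_ms = 540 * log(2) / 10, fov_mm = 60)
  ser <- simulate_fair_series(ph, "global", protocol = proto)
  liver <- ph$region == 1L
  null_img <- ser$images[, , 10]         # TI = 540 ln 2 exactly
  expect_lt(max(abs(null_img[liver])), 1e-9)

  # zero perfusion makes the slice-selective series equal the global one
  sg <- simulate_fair_series(ph, "global", noise_sd = 3, seed = 9)
  ss <- simulate_fair_series(ph, "slice_selective", noise_sd = 3, seed = 9)
  expect_identical(sg$images, ss$images)

  # determinism under a fixed seed
  a <- simulate_fair_series(tiny_phantom(), "global", noise_sd = 5, seed = 4)
  b <- simulate_fair_series(tiny_phantom(), "global", noise_sd = 5, seed = 4)
  expect_identical(a$images, b$images)
})

test_that("phase-contrast cine follows the encoding arithmetic", {
  ph <- tiny_phantom(pulsatility_fraction = 0)
  cine <- simulate_pc_cine(ph, "infra_IVC", n_phases = 12, matrix_size = 64L)
  for (k in 2:12) {
    expect_identical(cine$phases[, , k], cine$phases[, , 1])
  }

  # peak 20 cm/s at venc 33 -> max phase 20 pi / 33, no wrap
  cine <- simulate_pc_cine(tiny_phantom(pulsatility_fraction = 0),
                           "infra_IVC", venc = 33, n_phases = 13,
                           matrix_size = 96L)
  expect_equal(max(cine$phases), 20 * pi / 33, tolerance = 1e-3)
  v <- decode_velocity(cine$phases[, , 1], 33)
  expect_false(attr(v, "aliasing"))

  # peak 40 cm/s exceeds venc 33: wrapped phases, aliasing flagged (the
  # near-pi band is resolved at the acquisition's 0.208 mm pixels)
  ph40 <- tiny_phantom(infra_peak_velocity = 40, pulsatility_fraction = 0)
  cine40 <- simulate_pc_cine(ph40, "infra_IVC", venc = 33, n_phases = 13,
                             matrix_size = 192L)
  expect_true(all(cine40$phases <= pi & cine40$phases > -pi))
  expect_true(any(cine40$phases < -0.5))   # wrapped negative values present
  v40 <- decode_velocity(cine40$phases[, , 1], 33)
  expect_true(attr(v40, "aliasing"))

  expect_error(simulate_pc_cine(ph, "infra_IVC", venc = -1), "venc")
})

test_that("respiratory schedule covers k-space and respects quiescence", {
  ph <- tiny_phantom(seed = 3)
  proto <- tiny_protocol()
  rt <- simulate_respiration_and_timetable(ph, proto, seed = 8)
  tab <- rt$timetable
  expect_equal(nrow(tab), proto$matrix_size * proto$n_readouts)
  expect_equal(sort(unique(tab$kspace_row)), seq_len(proto$matrix_size))
  expect_equal(sort(unique(tab$ti_index)), seq_len(proto$n_readouts))
  # four lines per segment, times strictly increasing within a segment
  for (s in unique(tab$segment)[1:3]) {
    seg <- tab[tab$segment == s, ]
    expect_equal(nrow(seg), proto$n_readouts * proto$lines_per_segment)
    expect_false(is.unsorted(seg$time_s, strictly = TRUE))
  }
  # quiescent windows non-overlapping and increasing
  w <- rt$resp$windows
  expect_true(all(diff(w$start) > 0))
  expect_true(all(w$end > w$start))
  expect_true(all(w$start[-1] >= w$end[-nrow(w)] - 1e-12))

  # fully quiescent breathing leaves nothing to discard
  rt1 <- simulate_respiration_and_timetable(ph, proto, seed = 8,
                                            quiescent_fraction = 1)
  expect_true(all(flag_lines(rt1$timetable, rt1$resp)$keep))

  # a readout train longer than the quiescent window must flag lines
  rt2 <- simulate_respiration_and_timetable(ph, proto, seed = 8,
                                            quiescent_fraction = 0.4)
  expect_gt(sum(!flag_lines(rt2$timetable, rt2$resp)$keep), 0)

  # determinism
  rt3 <- simulate_respiration_and_timetable(ph, proto, seed = 8)
  expect_identical(rt3$timetable, rt$timetable)
})
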