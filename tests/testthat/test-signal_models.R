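test_that("T2-prepared signal follows the mono-exponential preparation model", {
  expect_identical(t2prep_signal(0.83, 47, 0), 0.83)
  expect_equal(t2prep_signal(1, 55, 55), exp(-1), tolerance = 1e-12)
  s <- t2prep_signal(1, 52, c(0, 24, 55))
  expect_equal(s[2] / s[1], exp(-24 / 52), tolerance = 1e-14)
  expect_equal(s[3] / s[1], exp(-55 / 52), tolerance = 1e-14)
  expect_error(t2prep_signal(1, 0, 10), "positive")
  expect_error(t2prep_signal(1, -5, 10), "positive")
  expect_error(t2prep_signal(1, 50, -1), "non-negative")
})

test_that("prepared signal is monotone in prep time and in T2", {
  preps <- seq(0, 120, by = 10)
  for (t2 in c(30, 50, 80, 200)) {
    s <- t2prep_signal(1, t2, preps)
    expect_true(all(diff(s) < 0))
  }
  for (tp in c(10, 24, 55, 90)) {
    s <- vapply(c(30, 50, 80, 200), function(t2) t2prep_signal(1, t2, tp),
                numeric(1))
    expect_true(all(diff(s) > 0))
  }
})

test_that("acquisition protocol enforces its own consistency", {
  p <- acquisition_protocol(readout = "flash_centric")
  expect_equal(p$trajectory_center_index, 1L)
  # 150 ms window at TR 2.8 ms leaves at most 53 readout lines
  expect_lte(p$n_readout_lines, 53L)
  expect_equal(p$n_readout_lines, 53L)
  p2 <- acquisition_protocol(readout = "ssfp_linear")
  expect_equal(p2$trajectory_center_index, as.integer(ceiling(53 / 2)))
  expect_error(acquisition_protocol(prep_times_ms = c(0, 0, 55)), "distinct")
  expect_error(acquisition_protocol(prep_times_ms = 24), "two")
  expect_error(acquisition_protocol(flip_angle_deg = 190), "flip")
  expect_error(acquisition_protocol(readout = "flash_centric",
                                    trajectory_center_index = 5), "centric")
  expect_error(acquisition_protocol(n_readout_lines = 100,
                                    readout_tr_ms = 2.8), "window")
})

test_that("degenerate single-line centric shot records the prepared magnetization", {
  p <- acquisition_protocol(readout = "flash_centric", flip_angle_deg = 90,
                            n_readout_lines = 1)
  tis <- tissue_properties()[1, ]
  for (m in c(0.2, 0.63, 1)) {
    expect_equal(readout_effective_signal(m, tis, p), m, tolerance = 1e-12)
  }
  # ideal readout passes any magnetization through unchanged
  pi0 <- acquisition_protocol(readout = "ideal")
  expect_identical(readout_effective_signal(0.4, tis, pi0), 0.4)
})

test_that("proton density scales signals linearly and leaves fitted T2 unchanged", {
  p <- acquisition_protocol(readout = "ssfp_linear")
  base <- tissue_properties(list(myocardium = list(proton_density = 0.5)))
  scaled <- tissue_properties(list(myocardium = list(proton_density = 1.0)))
  s1 <- effective_prep_signals(base[1, ], p)
  s2 <- effective_prep_signals(scaled[1, ], p)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_equal(oracle_loglin_t2(s1), oracle_loglin_t2(s2), tolerance = 1e-10)
})

test_that("readout families order apparent T2: spoiled-centric below ideal below bSSFP-linear", {
  for (t2 in c(40, 50, 62, 80)) {
    for (t1 in unique(c(4 * t2, 1000, 1400))) {
      if (t1 < 4 * t2) next
      tis <- list(class_name = "x", t1_ms = t1, t2_ms = t2,
                  proton_density = 1)
      fits <- vapply(c("flash_centric", "ideal", "ssfp_linear"),
                     function(ro) {
        p <- acquisition_protocol(readout = ro)
        oracle_loglin_t2(effective_prep_signals(tis, p))
      }, numeric(1))
      expect_lte(fits["flash_centric"], fits["ideal"] + 1e-9)
      expect_lte(fits["ideal"], fits["ssfp_linear"] + 1e-9)
      # the ideal readout is exact
      expect_equal(unname(fits["ideal"]), t2, tolerance = 1e-9)
    }
  }
})
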