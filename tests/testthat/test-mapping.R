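test_that("noiseless 3-point signals invert exactly", {
  s <- 100 * exp(-c(0, 24, 55) / 50)
  map <- fit_t2_map(series_from_signals(s))
  expect_equal(map$t2_ms[1, 1], 50, tolerance = 1e-9)
  expect_equal(map$amplitude[1, 1], 100, tolerance = 1e-7)
  expect_true(map$valid_mask[1, 1])
  expect_false(map$clamped[1, 1])
})

test_that("degenerate signals clamp at the ceiling or invalidate, never error", {
  flat <- fit_t2_map(series_from_signals(c(5, 5, 5)))
  expect_equal(flat$t2_ms[1, 1], 300)
  expect_true(flat$clamped[1, 1])
  rising <- fit_t2_map(series_from_signals(c(1, 2, 3)))
  expect_true(rising$clamped[1, 1])
  nonpos <- fit_t2_map(series_from_signals(c(5, 0, 1)))
  expect_false(nonpos$valid_mask[1, 1])
  expect_true(is.na(nonpos$t2_ms[1, 1]))
})

test_that("fitted T2 is invariant to a positive scaling of the whole series", {
  s <- 7 * exp(-c(0, 24, 55) / 63)
  for (k in c(0.01, 1, 250)) {
    map <- fit_t2_map(series_from_signals(k * s))
    expect_equal(map$t2_ms[1, 1], 63, tolerance = 1e-9)
  }
})

test_that("log-linear and nonlinear fits agree on noiseless data", {
  spec <- small_spec(noise_sigma = 0)
  fr <- render_phantom(spec)
  ser <- simulate_prepared_series(fr, noise = "none")
  m1 <- fit_t2_map(ser, method = "loglin")
  m2 <- fit_t2_map(ser, method = "nls")
  # mono-exponential (pure-tissue) pixels; mixed voxels are legitimately
  # fit differently by the two objectives
  pure <- fr[, , "myocardium"] == 1 | fr[, , "blood"] == 1
  ok <- pure & m1$valid_mask & !m1$clamped & m2$valid_mask & !m2$clamped
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(m1$t2_ms[ok] - m2$t2_ms[ok])), 0.1)
})

test_that("a 50/50 myocardium-blood voxel fits near 91 ms, as the closed-form oracle predicts", {
  s <- oracle_mixed_signal(0.5)
  map <- fit_t2_map(series_from_signals(s))
  expect_equal(map$t2_ms[1, 1], oracle_loglin_t2(s), tolerance = 1e-9)
  expect_equal(map$t2_ms[1, 1], 91.204, tolerance = 0.001)
})

test_that("multi-echo three-parameter fit recovers noiseless parameters exactly", {
  s <- simulate_multiecho_series(62, amplitude = 1000, offset = 10)
  f <- fit_t2_multiecho(s)
  expect_equal(f$t2_ms, 62, tolerance = 1e-6 * 62)
  expect_equal(f$amplitude, 1000, tolerance = 1e-6 * 1000)
  expect_equal(f$offset, 10, tolerance = 1e-4)
  # offset-free data yields a negligible offset estimate
  f0 <- fit_t2_multiecho(simulate_multiecho_series(45, amplitude = 800))
  expect_lt(abs(f0$offset), 1e-6 * 800)
  # S3 surface
  expect_named(coef(f), c("amplitude", "t2_ms", "offset"))
  expect_equal(predict(f), f$fitted, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(residuals(f))), 1e-6)
  expect_error(fit_t2_multiecho(c(3, 2, 1), c(1, 2, 3)), ">= 4 echoes")
})

test_that("multi-echo estimator precision under Rician noise is sub-millisecond", {
  te <- seq(7, 224, length.out = 32)
  clean <- 1000 * exp(-te / 62)
  set.seed(20260901)
  est <- replicate(500, {
    y <- sqrt((clean + rnorm(32, 0, 5))^2 + rnorm(32, 0, 5)^2)
    fit_t2_multiecho(y, te)$t2_ms
  })
  expect_lt(sd(est), 1)
  expect_lt(abs(mean(est) - 62), 1)
})

test_that("registration is the identity on a motion-free series", {
  spec <- small_spec(noise_sigma = 0)
  ser <- simulate_prepared_series(render_phantom(spec), noise = "none")
  reg <- motion_correct(ser)
  expect_true(all(reg$registration$converged))
  shifts <- sqrt(reg$registration$shift_rows_px^2 +
                   reg$registration$shift_cols_px^2)
  expect_lt(max(shifts), 1e-3)
})

test_that("known rigid translations are recovered within half a pixel", {
  spec <- phantom_spec(grid_shape = c(64, 64), motion_amplitude_mm = 4.2,
                       motion_direction_deg = 30, noise_sigma = 0.01)
  ser <- simulate_prepared_series(render_phantom(spec), seed = 5)
  reg <- motion_correct(ser)
  truth <- ser$truth$displacements_mm
  for (i in 2:3) {
    err_x <- abs(reg$registration$shift_x_mm[i] - truth[i, "dx_mm"]) /
      spec$pixel_size_mm[2]
    err_y <- abs(reg$registration$shift_y_mm[i] - truth[i, "dy_mm"]) /
      spec$pixel_size_mm[1]
    expect_lt(err_x, 0.5)
    expect_lt(err_y, 0.5)
  }
})

test_that("motion correction lowers the map error against ground truth", {
  spec <- phantom_spec(grid_shape = c(64, 64), motion_amplitude_mm = 4.2,
                       motion_direction_deg = 30, noise_sigma = 0.01)
  fr <- render_phantom(spec)
  ser <- simulate_prepared_series(fr, seed = 5)
  myo <- fr[, , "myocardium"] > 0.95
  err <- function(map) {
    ok <- myo & map$valid_mask
    mean(abs(map$t2_ms[ok] - 50))
  }
  e_raw <- err(fit_t2_map(ser))
  e_cor <- err(fit_t2_map(motion_correct(ser)))
  expect_lt(e_cor, e_raw)
})

test_that("fitting a perfectly re-registered translated series matches the static fit", {
  spec <- small_spec(noise_sigma = 0)
  fr <- render_phantom(spec)
  static <- fit_t2_map(simulate_prepared_series(fr, noise = "none"))
  # translate image 3 by exactly one pixel and undo it exactly
  ser <- simulate_prepared_series(fr, noise = "none")
  shifted <- ser
  shifted$images[, , 3] <- cmrT2map:::shift_image(ser$images[, , 3], 1, 0)
  shifted$images[, , 3] <- cmrT2map:::shift_image(shifted$images[, , 3],
                                                  -1, 0)
  remap <- fit_t2_map(shifted)
  interior <- fr[, , "background"] == 0
  interior[c(1:2, 47:48), ] <- FALSE
  ok <- interior & static$valid_mask & remap$valid_mask
  rel <- abs(remap$t2_ms[ok] - static$t2_ms[ok]) / static$t2_ms[ok]
  expect_lt(max(rel), 1e-3)
})
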