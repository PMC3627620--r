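test_that("tissue fractions form a partition of unity, lesions included", {
  spec <- small_spec(
    thin_thickness_mm = 3, thin_angle_deg = 0,
    lesion_specs = list(
      list(center_angle_deg = 200, extent_deg = 70, class = "edema"),
      list(center_angle_deg = 200, extent_deg = 25, transmurality = 0.5,
           class = "mvo_core")),
    fat_arc = list(center_angle_deg = 90, extent_deg = 60, thickness_mm = 3))
  fr <- render_phantom(spec)
  tot <- apply(fr, c(1, 2), sum)
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(fr >= 0))
  # all named classes got some area
  for (cl in c("myocardium", "blood", "edema", "mvo_core", "fat",
               "background")) {
    expect_gt(sum(fr[, , cl]), 0)
  }
})

test_that("subgrid factor 1 disables partial-volume mixing", {
  fr <- render_phantom(small_spec(subgrid_factor = 1))
  expect_true(all(fr %in% c(0, 1)))
})

test_that("a pixel straddling the endocardial border mixes blood and myocardium", {
  spec <- phantom_spec(grid_shape = c(48, 48), pixel_size_mm = c(1, 1),
                       endo_radius_mm = 10.5, epi_radius_mm = 20,
                       subgrid_factor = 8)
  fr <- render_phantom(spec)
  # walk along +x from the center: the pixel containing r = 10.5 straddles
  cx <- spec$lv_center
  col <- round(cx[2] + 10.5)
  b <- unname(fr[round(cx[1]), col, "blood"])
  m <- unname(fr[round(cx[1]), col, "myocardium"])
  expect_gt(b, 0); expect_lt(b, 1)
  expect_gt(m, 0); expect_lt(m, 1)
  expect_equal(b + m, 1, tolerance = 1e-9)
})

test_that("rendered class areas match a dense analytic rasterization oracle", {
  n <- 48
  spec <- phantom_spec(grid_shape = c(n, n), pixel_size_mm = c(1, 1),
                       endo_radius_mm = 20, epi_radius_mm = 28 - 1e-9,
                       subgrid_factor = 8)
  fr <- render_phantom(spec)
  orc <- oracle_annulus_fractions(n, 20, 28 - 1e-9)
  # per-pixel fractions agree within the 8x subpixel band, areas within 1%
  expect_lt(max(abs(fr[, , "myocardium"] - orc$myocardium)), 1 / 8)
  expect_lt(max(abs(fr[, , "blood"] - orc$blood)), 1 / 8)
  expect_lt(abs(sum(fr[, , "myocardium"]) - sum(orc$myocardium)),
            0.01 * sum(orc$myocardium))
  # majority-class pixel counts agree to within a one-subpixel boundary band
  expect_lt(sum((fr[, , "blood"] > 0.5) != (orc$blood > 0.5)), 0.02 * n * n)
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_spec(endo_radius_mm = 20, epi_radius_mm = 18),
               "epi_radius_mm")
  expect_error(phantom_spec(thin_thickness_mm = 12), "thin_thickness_mm")
  expect_error(phantom_spec(lesion_specs = list(
    list(center_angle_deg = 0, extent_deg = 30, class = "mvo_core"))),
    "edema")
  expect_error(phantom_spec(lesion_specs = list(
    list(center_angle_deg = 0, extent_deg = 30, class = "bone"))),
    "unknown")
})

test_that("noiseless motion-free ideal-readout series is exactly exponential", {
  # a phantom whose annulus is pure myocardium over a wide band
  spec <- small_spec(noise_sigma = 0)
  fr <- render_phantom(spec)
  ser <- simulate_prepared_series(fr, noise = "none")
  pure <- fr[, , "myocardium"] == 1
  expect_gt(sum(pure), 50)
  pd <- tissue_properties()$proton_density[1]
  for (i in 1:3) {
    expected <- pd * exp(-c(0, 24, 55)[i] / 50)
    expect_equal(ser$images[, , i][pure],
                 rep(expected, sum(pure)), tolerance = 1e-12)
  }
  # mixed pixels are the fraction-weighted sum of pure signals
  mix <- fr[, , "myocardium"] > 0 & fr[, , "blood"] > 0
  i <- which(mix)[1]
  s_expected <- fr[, , "myocardium"][i] * pd * exp(-c(0, 24, 55) / 50) +
    fr[, , "blood"][i] * 1.0 * exp(-c(0, 24, 55) / 200)
  expect_equal(as.numeric(ser$images[, , ][cbind(
    rep(arrayInd(i, dim(fr)[1:2])[1], 3),
    rep(arrayInd(i, dim(fr)[1:2])[2], 3), 1:3)]),
    s_expected, tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed, noiseless part seed-free", {
  spec <- small_spec(noise_sigma = 0.02, motion_amplitude_mm = 2)
  fr <- render_phantom(spec)
  a <- simulate_prepared_series(fr, seed = 42)
  b <- simulate_prepared_series(fr, seed = 42)
  expect_identical(a$images, b$images)
  c1 <- simulate_prepared_series(fr, seed = 1, noise = "none")
  c2 <- simulate_prepared_series(fr, seed = 99, noise = "none")
  expect_identical(c1$images, c2$images)
  # different noise seeds differ
  d <- simulate_prepared_series(fr, seed = 43)
  expect_false(identical(a$images, d$images))
})

test_that("simulation does not disturb the session RNG", {
  spec <- small_spec(noise_sigma = 0.02)
  fr <- render_phantom(spec)
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_prepared_series(fr, seed = 3))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("blood fraction monotonically raises the fitted T2 of a mixed voxel", {
  fits <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(fb) {
    oracle_loglin_t2(oracle_mixed_signal(fb))
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
  expect_equal(fits[1], 50, tolerance = 1e-9)
  expect_equal(fits[5], 200, tolerance = 1e-9)
  expect_equal(fits[3], 91.204, tolerance = 0.001)
})

test_that("multi-echo simulation matches its closed form and default grid", {
  s <- simulate_multiecho_series(62, amplitude = 5, offset = 0,
                                 echo_times_ms = 62)
  expect_equal(as.numeric(s), 5 * exp(-1), tolerance = 1e-12)
  s0 <- simulate_multiecho_series(50, amplitude = 0, offset = 3.3)
  expect_true(all(s0 == 3.3))
  g <- attr(simulate_multiecho_series(62), "echo_times_ms")
  expect_length(g, 32)
  expect_equal(g[1], 7)
  expect_equal(g[32], 224)
  expect_equal(diff(g), rep((224 - 7) / 31, 31), tolerance = 1e-12)
  expect_error(simulate_multiecho_series(-5), "positive")
  expect_error(simulate_multiecho_series(50, echo_times_ms = c(10, 5)),
               "increasing")
})

test_that("cine stacks sample one cardiac cycle and respect the motion spec", {
  spec <- phantom_spec(grid_shape = c(48, 48), pixel_size_mm = c(1.8, 1.8),
                       rr_interval_ms = 1000)
  cin <- make_cine(spec, n_frames = 10, contraction_mm = 0)
  expect_equal(cin$times_ms, seq(0, 900, by = 100))
  expect_true(all(cin$times_ms >= 0 & cin$times_ms < 1000))
  # zero motion and zero contraction: all frames identical
  for (i in 2:10) expect_equal(cin$frames[, , i], cin$frames[, , 1])
  # with drift, the truth translations ramp to the spec amplitude
  spec2 <- phantom_spec(grid_shape = c(48, 48), pixel_size_mm = c(1.8, 1.8),
                        motion_amplitude_mm = 2.8)
  cin2 <- make_cine(spec2, n_frames = 40, contraction_mm = 0)
  expect_equal(max(cin2$truth$translations_mm[, "dx_mm"]), 2.8,
               tolerance = 1e-9)
  expect_error(make_cine(spec, n_frames = 1), "n_frames")
})
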