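test_that("a circular annulus divides into six near-equal sectors", {
  spec <- phantom_spec(grid_shape = c(128, 128), pixel_size_mm = c(1, 1),
                       endo_radius_mm = 20, epi_radius_mm = 28)
  ct <- annulus_contours(spec)
  lab <- segment_myocardium(ct, c(128, 128), c(1, 1))
  counts <- tabulate(lab[lab > 0], 6)
  expect_true(all(counts > 0))
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.02)
  expect_identical(attr(lab, "segment_labels")[2], "anteroseptal")
})

test_that("rotating the RV-insertion reference by 60 degrees permutes labels cyclically", {
  spec <- phantom_spec(grid_shape = c(96, 96), pixel_size_mm = c(1, 1))
  ct1 <- annulus_contours(spec)
  ct2 <- ct1
  ct2$rv_insertion_angle_deg <- ct1$rv_insertion_angle_deg + 60
  l1 <- segment_myocardium(ct1, c(96, 96), c(1, 1))
  l2 <- segment_myocardium(ct2, c(96, 96), c(1, 1))
  expect_identical(l1 > 0, l2 > 0)          # same myocardial pixel set
  # label k under the rotated reference equals label k+1 under the original
  expected <- ifelse(l1 > 0, (l1 %% 6) + 1L, 0L)
  agree <- mean(l2[l1 > 0] == expected[l1 > 0])
  expect_gt(agree, 0.999)
})

test_that("segment pixel counts match the dense rasterization oracle", {
  n <- 48
  spec <- phantom_spec(grid_shape = c(n, n), pixel_size_mm = c(1, 1),
                       endo_radius_mm = 20, epi_radius_mm = 28 - 1e-9)
  ct <- annulus_contours(spec)
  lab <- segment_myocardium(ct, c(n, n), c(1, 1))
  orc <- oracle_annulus_fractions(n, 20, 28 - 1e-9)
  # pixel-center-in-annulus: oracle pixels whose center radius is in band
  center <- (n + 1) / 2
  x <- matrix(seq_len(n) - center, n, n, byrow = TRUE)  # varies along cols
  y <- matrix(center - seq_len(n), n, n)                # varies along rows
  r <- sqrt(x^2 + y^2)
  in_band <- r <= 28 - 1e-9 & r > 20    # oracle membership at pixel centers
  expect_lt(sum(in_band != (lab > 0)), 0.015 * sum(in_band))
})

test_that("contour geometry errors are detected", {
  theta <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- function(r, c0 = 24) cbind(c0 + r * sin(theta), c0 + r * cos(theta))
  expect_error(contour_set(circ(12), circ(10)), "cross")
  bow <- cbind(c(10, 30, 10, 30), c(10, 30, 30, 10))
  expect_error(contour_set(bow, circ(22)), "self-intersects")
  ok <- contour_set(circ(10), circ(20))
  expect_s3_class(ok, "contour_set")
})

test_that("four-chamber territories partition the wall by axis and side", {
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- function(r) cbind(32 + r * sin(theta), 32 + r * cos(theta))
  ct <- contour_set(circ(12), circ(20), view = "4CV", apex_angle_deg = 270)
  lab <- segment_myocardium(ct, c(64, 64), c(1, 1))
  expect_setequal(sort(unique(lab[lab > 0])), 1:6)
  expect_identical(attr(lab, "view"), "4CV")
  # apical territories (3, 4) sit at the apex end (large row, apex at 270)
  rows_apical <- row(lab)[lab %in% c(3, 4)]
  rows_basal <- row(lab)[lab %in% c(1, 6)]
  expect_gt(min(rows_apical), max(rows_basal) - 64 / 3)
  expect_gt(mean(rows_apical), mean(rows_basal))
  # septal (1-3) and lateral (4-6) are on opposite sides of the axis
  cols_septal <- col(lab)[lab %in% 1:3]
  cols_lateral <- col(lab)[lab %in% 4:6]
  expect_lt(abs(mean(cols_septal) + mean(cols_lateral) - 65), 2)
  expect_gt(abs(mean(cols_septal) - mean(cols_lateral)), 10)
})

test_that("segment statistics honour validity, the global rule and the flag boundary", {
  lab <- matrix(0L, 20, 20)
  lab[2:19, 2:19] <- rep(1:6, length.out = 18 * 18)
  t2 <- matrix(55, 20, 20)
  map <- fake_t2map(t2)
  rs <- roi_stats(map, lab)
  expect_equal(rs$mean_t2_ms[rs$id > 0], rep(55, 6))
  expect_equal(rs$abs_dev_from_global_ms[rs$id > 0], rep(0, 6))
  expect_equal(sum(rs$n_pixels[rs$id > 0]), sum(lab > 0))
  expect_false(any(rs$flagged))
  # one hot segment at exactly the 70 ms boundary flags (and only it)
  t2[lab == 3] <- 70.0
  rs2 <- roi_stats(fake_t2map(t2), lab)
  expect_identical(rs2$flagged[rs2$id > 0], c(FALSE, FALSE, TRUE, FALSE,
                                              FALSE, FALSE))
  expect_lt(rs2$mean_t2_ms[rs2$id == 3] - 70, 1e-12)
  # global mean lies within the segment means
  seg_means <- rs2$mean_t2_ms[rs2$id > 0]
  g <- rs2$mean_t2_ms[rs2$id == 0]
  expect_gte(g, min(seg_means)); expect_lte(g, max(seg_means))
  # invalid pixels are excluded from every statistic
  valid <- matrix(TRUE, 20, 20); valid[lab == 5] <- FALSE
  rs3 <- roi_stats(fake_t2map(t2, valid = valid), lab)
  expect_equal(rs3$n_pixels[rs3$id == 5], 0L)
  expect_true(is.na(rs3$mean_t2_ms[rs3$id == 5]))
})

test_that("roi_stats ignores pixels outside the labels and any relabeling order", {
  t2 <- matrix(runif(400, 40, 60), 20, 20)
  lab <- matrix(0L, 20, 20); lab[5:15, 5:15] <- rep(1:6, length.out = 121)
  rs <- roi_stats(fake_t2map(t2), lab)
  # swapping two label ids swaps their rows, nothing else
  lab2 <- lab; lab2[lab == 1] <- 2L; lab2[lab == 2] <- 1L
  rs2 <- roi_stats(fake_t2map(t2), lab2)
  expect_equal(rs$mean_t2_ms[rs$id == 1], rs2$mean_t2_ms[rs2$id == 2])
  expect_equal(rs$mean_t2_ms[rs$id == 0], rs2$mean_t2_ms[rs2$id == 0])
  # changing unlabeled pixels changes nothing
  t2b <- t2; t2b[lab == 0] <- 999
  rs3 <- roi_stats(fake_t2map(t2b), lab)
  expect_equal(rs3$mean_t2_ms, rs$mean_t2_ms)
})

test_that("edema-remote comparison recovers truth and honours MVO exclusion", {
  t2 <- matrix(51, 30, 30)
  edema <- matrix(FALSE, 30, 30); edema[5:12, 5:12] <- TRUE
  remote <- matrix(FALSE, 30, 30); remote[20:28, 20:28] <- TRUE
  mvo <- matrix(FALSE, 30, 30); mvo[8:10, 8:10] <- TRUE
  t2[edema] <- 73; t2[mvo] <- 60
  cmp <- edema_vs_remote(fake_t2map(t2), edema, remote, mvo)
  expect_equal(cmp$difference_ms, 22.0, tolerance = 1e-12)
  expect_equal(cmp$edema_mean_ms, 73)
  # with the core removed the edema mean equals the core-free lesion's
  t2_nocore <- t2; t2_nocore[mvo] <- 73
  cmp2 <- edema_vs_remote(fake_t2map(t2_nocore), edema, remote, mvo)
  expect_equal(cmp$edema_mean_ms, cmp2$edema_mean_ms)
  expect_error(edema_vs_remote(fake_t2map(t2), edema, edema), "overlap")
  expect_error(edema_vs_remote(fake_t2map(t2), mvo, remote, mvo), "empty")
})

test_that("noisy edema-remote differences are centred on the true contrast", {
  spec <- small_spec(
    noise_sigma = 0.02,
    lesion_specs = list(list(center_angle_deg = 200, extent_deg = 80,
                             class = "edema")))
  fr <- render_phantom(spec)
  edema <- fr[, , "edema"] > 0.9
  remote <- fr[, , "myocardium"] > 0.95
  diffs <- vapply(1:100, function(s) {
    ser <- simulate_prepared_series(fr, seed = s, noise = "rician")
    edema_vs_remote(fit_t2_map(ser), edema, remote)$difference_ms
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 23), 1)   # truth: 73 - 50 ms
})
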