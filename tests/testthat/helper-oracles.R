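# Shared fixtures and independent oracles, built in code at test time.

# log-linear 3-point fit of a signal vector (independent of the package's
# vectorized implementation): least-squares line on log-signal vs prep time
oracle_loglin_t2 <- function(signals, t = c(0, 24, 55)) {
  f <- stats::lm(log(signals) ~ t)
  -1 / unname(stats::coef(f)[2])
}

# closed-form mixed-voxel signal: fraction-weighted sum of pure exponentials
oracle_mixed_signal <- function(frac_blood, t = c(0, 24, 55),
                                t2_myo = 50, t2_blood = 200) {
  (1 - frac_blood) * exp(-t / t2_myo) + frac_blood * exp(-t / t2_blood)
}

# dense analytic rasterization oracle: per-pixel class fractions of an
# annulus (endo/epi radii in mm, isotropic pixels) sampled at `over`-fold
# oversampling, classified directly from the disc geometry
oracle_annulus_fractions <- function(n, endo_mm, epi_mm, pixel_mm = 1,
                                     over = 64) {
  center <- (n + 1) / 2
  sub <- rep(seq_len(n), each = over) - 0.5 + (seq_len(over) - 0.5) / over
  x <- matrix((sub - center) * pixel_mm, n * over, n * over, byrow = TRUE)
  y <- matrix((center - sub) * pixel_mm, n * over, n * over)
  r <- sqrt(x^2 + y^2)
  cls <- matrix(0L, n * over, n * over)        # 0 bg, 1 myo, 2 blood
  cls[r <= epi_mm] <- 1L
  cls[r < endo_mm] <- 2L
  shrink <- function(m) {
    mm <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      mm[i, j] <- mean(m[(i - 1) * over + seq_len(over),
                         (j - 1) * over + seq_len(over)])
    }
    mm
  }
  list(myocardium = shrink(cls == 1L), blood = shrink(cls == 2L))
}

# minimal hand-built t2map object for ROI statistics tests
fake_t2map <- function(t2, valid = NULL, pixel_size_mm = c(1, 1)) {
  if (is.null(valid)) valid <- !is.na(t2)
  structure(list(
    t2_ms = t2, amplitude = t2 * 0 + 1, fit_error = t2 * 0,
    valid_mask = valid, clamped = t2 * 0 > 1, clamp_ceiling_ms = 300,
    method = "loglin", prep_times_ms = c(0, 24, 55),
    pixel_size_mm = pixel_size_mm, truth = NULL
  ), class = "t2map")
}

# single-tissue prepared series built directly from given per-prep signals
series_from_signals <- function(signals, prep_times = c(0, 24, 55),
                                shape = c(1, 1)) {
  img <- array(rep(signals, each = prod(shape)),
               dim = c(shape, length(signals)))
  structure(list(
    images = img, prep_times_ms = prep_times,
    protocol = acquisition_protocol(prep_times_ms = prep_times),
    pixel_size_mm = c(1, 1), spec = NULL, truth = NULL
  ), class = "prepared_series")
}

small_spec <- function(...) phantom_spec(grid_shape = c(48, 48), ...)
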