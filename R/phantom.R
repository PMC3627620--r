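#' Tissue relaxation properties
#'
#' Default per-class relaxation times and relative proton densities used by
#' the digital cardiac phantom at 1.5 T. Myocardial T2 is set to 50 ms;
#' blood has a T2 of about 200 ms and pericardial fat about 80 ms, which is
#' why partial-volume inclusion of either neighbour inflates an apparent
#' myocardial T2. The background class represents air (zero proton density;
#' its relaxation times are placeholders).
#'
#' @param overrides optional named list of single-row replacements, e.g.
#'   \code{list(myocardium = list(t2_ms = 45))}.
#' @return data.frame with columns \code{class_name}, \code{t1_ms},
#'   \code{t2_ms}, \code{proton_density}.
#' @examples
#' tissue_properties()
#' @export
tissue_properties <- function(overrides = NULL) {
  tp <- data.frame(
    class_name = c("myocardium", "blood", "fat", "edema", "mvo_core",
                   "background"),
    t1_ms = c(1000, 1600, 260, 1200, 1100, 1),
    t2_ms = c(50, 200, 80, 73, 60, 1),
    proton_density = c(0.7, 1.0, 0.9, 0.75, 0.45, 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, tp$class_name)
      if (is.na(i)) stop("unknown tissue class: ", nm)
      for (f in names(overrides[[nm]])) tp[i, f] <- overrides[[nm]][[f]]
    }
  }
  validate_tissues(tp)
  tp
}

validate_tissues <- function(tp) {
  stopifnot(is.data.frame(tp),
            all(c("class_name", "t1_ms", "t2_ms", "proton_density") %in%
                  names(tp)))
  if (any(tp$t1_ms <= 0) || any(tp$t2_ms <= 0))
    stop("relaxation times must be positive")
  if (any(tp$t1_ms < tp$t2_ms)) stop("t1_ms must be >= t2_ms")
  if (any(tp$proton_density < 0)) stop("proton_density must be >= 0")
  invisible(tp)
}

#' Specification of a 2D cardiac phantom slice
#'
#' Geometry, motion and noise parameters of a short-axis left-ventricular
#' phantom: a myocardial annulus (endocardial radius \code{endo_radius_mm},
#' epicardial radius \code{epi_radius_mm}) around a blood pool, optionally
#' with an angularly thin wall sector, sector-shaped lesions (edema with or
#' without a microvascular-obstruction core), a pericardial fat arc, rigid
#' in-plane motion, and Rician noise. Wall thickness may vary with angle: if
#' \code{thin_thickness_mm} is given, the thickness is modulated
#' cosinusoidally from \code{thin_thickness_mm} at \code{thin_angle_deg} up to
#' \code{epi_radius_mm - endo_radius_mm} at the opposite side, emulating thin
#' anteroseptal/apical walls (the normal range is roughly 2-8 mm).
#'
#' Angles are mathematical image angles in degrees (0 = +x/right,
#' counterclockwise positive with y pointing up); segment angles downstream
#' are measured clockwise starting from \code{rv_insertion_angle_deg}.
#'
#' @param grid_shape image size in pixels, \code{c(rows, cols)}.
#' @param pixel_size_mm in-plane resolution \code{c(row_mm, col_mm)}; the
#'   mapping protocol default is 2.7 x 2.1 mm per pixel.
#' @param slice_thickness_mm slice thickness (informational).
#' @param lv_center LV center in 1-based pixel coordinates \code{c(row, col)};
#'   defaults to the grid center.
#' @param endo_radius_mm,epi_radius_mm endocardial/epicardial radii, mm.
#' @param thin_thickness_mm minimum wall thickness of the thin sector (mm), or
#'   \code{NULL} for a uniform wall.
#' @param thin_angle_deg angular location of the thin sector.
#' @param rv_insertion_angle_deg anterior RV insertion reference angle.
#' @param lesion_specs list of sector lesions, each a list with
#'   \code{center_angle_deg}, \code{extent_deg}, \code{class} (a tissue class
#'   name), and optional \code{transmurality} in (0, 1] (fraction of the wall,
#'   from the endocardium; default 1). Later entries override earlier ones, so
#'   an \code{mvo_core} sector placed inside an \code{edema} sector carves the
#'   core out of the lesion.
#' @param fat_arc optional pericardial fat rim: list with
#'   \code{center_angle_deg}, \code{extent_deg}, \code{thickness_mm}.
#' @param motion_amplitude_mm peak residual in-plane displacement between the
#'   single-shot images (and the diastolic drift of cine frames).
#' @param motion_direction_deg direction of the displacement.
#' @param motion_profile optional function of absolute scan time (ms)
#'   returning the scalar displacement in mm; default is a linear drift from 0
#'   to \code{motion_amplitude_mm} across the k-space-center times of the
#'   shots.
#' @param noise_sigma noise scale relative to a proton density of 1.
#' @param rr_interval_ms simulated cardiac period; default 1000 ms.
#' @param subgrid_factor subpixel oversampling for partial-volume rendering
#'   (1 disables mixing).
#' @return object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(grid_shape = c(64, 64),
                         pixel_size_mm = c(2.7, 2.1),
                         slice_thickness_mm = 8,
                         lv_center = NULL,
                         endo_radius_mm = 20,
                         epi_radius_mm = 28,
                         thin_thickness_mm = NULL,
                         thin_angle_deg = 0,
                         rv_insertion_angle_deg = 90,
                         lesion_specs = list(),
                         fat_arc = NULL,
                         motion_amplitude_mm = 0,
                         motion_direction_deg = 0,
                         motion_profile = NULL,
                         noise_sigma = 0,
                         rr_interval_ms = 1000,
                         subgrid_factor = 8) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4L),
            length(pixel_size_mm) == 2L, all(pixel_size_mm > 0))
  if (is.null(lv_center)) lv_center <- (grid_shape + 1) / 2
  if (endo_radius_mm <= 0 || epi_radius_mm <= endo_radius_mm)
    stop("need epi_radius_mm > endo_radius_mm > 0")
  if (!is.null(thin_thickness_mm)) {
    if (thin_thickness_mm <= 0 ||
        thin_thickness_mm > epi_radius_mm - endo_radius_mm)
      stop("thin_thickness_mm must be in (0, epi - endo]")
  }
  if (subgrid_factor < 1) stop("subgrid_factor must be >= 1")
  if (motion_amplitude_mm < 0) stop("motion_amplitude_mm must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  known <- tissue_properties()$class_name
  for (ls in lesion_specs) {
    if (!is.list(ls) || is.null(ls$center_angle_deg) || is.null(ls$extent_deg)
        || is.null(ls$class))
      stop("each lesion spec needs center_angle_deg, extent_deg, class")
    if (!ls$class %in% known) stop("unknown lesion class: ", ls$class)
    tm <- ls$transmurality %||% 1
    if (tm <= 0 || tm > 1) stop("transmurality must be in (0, 1]")
  }
  # an MVO core must lie inside some edema sector
  for (ls in lesion_specs) {
    if (identical(ls$class, "mvo_core")) {
      inside <- any(vapply(lesion_specs, function(e) {
        identical(e$class, "edema") &&
          abs(ang_diff(ls$center_angle_deg, e$center_angle_deg)) +
            ls$extent_deg / 2 <= e$extent_deg / 2 + 1e-9
      }, logical(1)))
      if (!inside) stop("mvo_core sector must lie inside an edema sector")
    }
  }
  structure(list(
    grid_shape = grid_shape, pixel_size_mm = as.numeric(pixel_size_mm),
    slice_thickness_mm = slice_thickness_mm, lv_center = as.numeric(lv_center),
    endo_radius_mm = endo_radius_mm, epi_radius_mm = epi_radius_mm,
    thin_thickness_mm = thin_thickness_mm, thin_angle_deg = thin_angle_deg,
    rv_insertion_angle_deg = rv_insertion_angle_deg,
    lesion_specs = lesion_specs, fat_arc = fat_arc,
    motion_amplitude_mm = motion_amplitude_mm,
    motion_direction_deg = motion_direction_deg,
    motion_profile = motion_profile,
    noise_sigma = noise_sigma, rr_interval_ms = rr_interval_ms,
    subgrid_factor = as.integer(subgrid_factor)
  ), class = "phantom_spec")
}

# signed circular difference a - b in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# wall thickness (mm) as a function of mathematical angle (deg)
wall_thickness_at <- function(spec, phi_deg) {
  tmax <- spec$epi_radius_mm - spec$endo_radius_mm
  if (is.null(spec$thin_thickness_mm)) return(rep(tmax, length(phi_deg)))
  tmin <- spec$thin_thickness_mm
  d <- ang_diff(phi_deg, spec$thin_angle_deg) * pi / 180
  tmin + (tmax - tmin) * (1 - cos(d)) / 2
}

# mm coordinates (x right, y up) of continuous 1-based pixel positions
pix_to_mm <- function(spec, rows, cols) {
  list(x = (cols - spec$lv_center[2]) * spec$pixel_size_mm[2],
       y = (spec$lv_center[1] - rows) * spec$pixel_size_mm[1])
}

#' Render per-pixel tissue fractions of a phantom
#'
#' Rasterizes the phantom geometry on a subpixel grid
#' (\code{subgrid_factor^2} subpixels per pixel), assigns each subpixel a
#' single tissue class, and averages subpixels into per-pixel tissue
#' fractions. Fractions are non-negative and sum to exactly 1 at every pixel;
#' with \code{subgrid_factor = 1} every fraction is 0 or 1 (no
#' partial-volume mixing).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return numeric array \code{rows x cols x classes} with tissue class names
#'   on the third dimension and the spec attached as attribute
#'   \code{"spec"}.
#' @examples
#' fr <- render_phantom(phantom_spec(grid_shape = c(32, 32)))
#' range(apply(fr, c(1, 2), sum))  # partition of unity
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$subgrid_factor
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  # subpixel centers in continuous pixel coordinates
  sub_r <- rep(seq_len(nr), each = f) - 0.5 + (seq_len(f) - 0.5) / f
  sub_c <- rep(seq_len(nc), each = f) - 0.5 + (seq_len(f) - 0.5) / f
  mmr <- (spec$lv_center[1] - sub_r) * spec$pixel_size_mm[1]  # y, length nr*f
  mmc <- (sub_c - spec$lv_center[2]) * spec$pixel_size_mm[2]  # x, length nc*f
  x <- matrix(mmc, nrow = nr * f, ncol = nc * f, byrow = TRUE)
  y <- matrix(mmr, nrow = nr * f, ncol = nc * f)
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x) * 180 / pi
  thick <- matrix(wall_thickness_at(spec, as.vector(phi)), nrow = nr * f)
  epi_r <- spec$endo_radius_mm + thick
  if (any(epi_r <= spec$endo_radius_mm))
    stop("degenerate geometry: epicardium not outside endocardium")
  classes <- tissue_properties()$class_name
  cls <- matrix(match("background", classes), nr * f, nc * f)
  cls[r <= epi_r] <- match("myocardium", classes)
  cls[r < spec$endo_radius_mm] <- match("blood", classes)
  for (ls in spec$lesion_specs) {
    tm <- ls$transmurality %||% 1
    sel <- abs(ang_diff(phi, ls$center_angle_deg)) <= ls$extent_deg / 2 &
      r >= spec$endo_radius_mm & r <= spec$endo_radius_mm + tm * thick &
      r <= epi_r
    cls[sel] <- match(ls$class, classes)
  }
  if (!is.null(spec$fat_arc)) {
    fa <- spec$fat_arc
    sel <- abs(ang_diff(phi, fa$center_angle_deg)) <= fa$extent_deg / 2 &
      r > epi_r & r <= epi_r + fa$thickness_mm
    cls[sel] <- match("fat", classes)
  }
  fr <- array(0, dim = c(nr, nc, length(classes)),
              dimnames = list(NULL, NULL, classes))
  for (k in seq_along(classes)) {
    if (any(cls == k)) fr[, , k] <- block_mean((cls == k) * 1, f)
  }
  # enforce exact partition of unity against floating-point accumulation
  tot <- apply(fr, c(1, 2), sum)
  for (k in seq_along(classes)) fr[, , k] <- fr[, , k] / tot
  attr(fr, "spec") <- spec
  fr
}

# k-space-center acquisition times (absolute scan time, ms) per shot
shot_center_times <- function(protocol) {
  n <- length(protocol$prep_times_ms)
  beats_per_shot <- max(1, protocol$scan_time_beats / n)
  (seq_len(n) - 1) * beats_per_shot * protocol$rr_interval_ms +
    protocol$prep_times_ms +
    (protocol$trajectory_center_index - 1) * protocol$readout_tr_ms
}

# per-image rigid displacement (dx, dy in mm) implied by the spec's motion
# model, sampled at the k-space-center time of each shot
series_displacements <- function(spec, protocol) {
  tt <- shot_center_times(protocol)
  if (spec$motion_amplitude_mm == 0) {
    d <- rep(0, length(tt))
  } else if (!is.null(spec$motion_profile)) {
    d <- vapply(tt, spec$motion_profile, numeric(1))
  } else {
    d <- spec$motion_amplitude_mm * (tt - tt[1]) / (tt[length(tt)] - tt[1])
  }
  th <- spec$motion_direction_deg * pi / 180
  cbind(dx_mm = d * cos(th), dy_mm = d * sin(th))
}

#' Simulate a T2-prepared single-shot image series
#'
#' Builds the noiseless per-pixel signal of every prepared image as the
#' tissue-fraction-weighted sum of per-tissue recorded signals (including the
#' readout transient and inter-shot saturation, see
#' \code{\link{effective_prep_signals}}), applies the per-image rigid in-plane
#' displacement sampled from the motion model at each shot's k-space-center
#' time, and adds noise last. Ground truth (true T2 of the dominant tissue,
#' unshifted tissue fractions, applied displacements) is stored alongside.
#'
#' @param fractions tissue-fraction array from \code{\link{render_phantom}}.
#' @param tissues tissue table, see \code{\link{tissue_properties}}.
#' @param protocol an \code{\link{acquisition_protocol}}.
#' @param seed integer seed for the noise; \code{NULL} uses the session RNG.
#'   The noiseless component is independent of the seed.
#' @param noise noise model: \code{"rician"} (magnitude of a complex Gaussian,
#'   the physical model for magnitude MR images), \code{"gaussian"} (for
#'   analytic checks), or \code{"none"}.
#' @param noise_sigma noise scale; defaults to the spec's value.
#' @return object of class \code{"prepared_series"}: list with \code{images}
#'   (rows x cols x n array), \code{prep_times_ms}, \code{protocol},
#'   \code{pixel_size_mm} and \code{truth}.
#' @export
simulate_prepared_series <- function(fractions,
                                     tissues = tissue_properties(),
                                     protocol = acquisition_protocol(),
                                     seed = NULL,
                                     noise = c("rician", "gaussian", "none"),
                                     noise_sigma = NULL) {
  noise <- match.arg(noise)
  spec <- attr(fractions, "spec")
  if (is.null(spec)) stop("fractions must carry a phantom_spec attribute")
  validate_tissues(tissues)
  classes <- dimnames(fractions)[[3]]
  if (is.null(classes) || !all(classes %in% tissues$class_name))
    stop("unknown tissue class in fractions")
  if (is.null(noise_sigma)) noise_sigma <- spec$noise_sigma
  preps <- protocol$prep_times_ms
  n_img <- length(preps)
  nr <- dim(fractions)[1]; nc <- dim(fractions)[2]

  sig <- sapply(classes, function(cn) {
    effective_prep_signals(tissues[tissues$class_name == cn, ], protocol)
  })                                    # n_img x n_class
  sig <- matrix(sig, nrow = n_img, dimnames = list(NULL, classes))
  if (protocol$readout != "ideal") {
    # receiver gain: a transient readout attenuates the recorded signal by a
    # roughly constant factor; scanners renormalize, so the brightest tissue
    # at prep 0 is scaled back to its proton density before noise is added
    # (fitted T2 is invariant to this common scaling)
    sc <- max(sig[1, ])
    if (sc > 0) sig <- sig / sc
  }

  disp <- series_displacements(spec, protocol)
  images <- array(0, dim = c(nr, nc, n_img))
  for (i in seq_len(n_img)) {
    dr <- -disp[i, "dy_mm"] / spec$pixel_size_mm[1]
    dc <- disp[i, "dx_mm"] / spec$pixel_size_mm[2]
    img <- matrix(0, nr, nc)
    for (k in seq_along(classes)) {
      if (sig[i, k] == 0) next
      fk <- fractions[, , k]
      if (dr != 0 || dc != 0)
        fk <- shift_image(fk, dr, dc,
                          fill = as.numeric(classes[k] == "background"))
      img <- img + fk * sig[i, k]
    }
    images[, , i] <- img
  }
  if (noise != "none" && noise_sigma > 0) {
    images <- with_seed(seed, {
      if (noise == "rician") {
        n1 <- array(stats::rnorm(length(images), 0, noise_sigma), dim(images))
        n2 <- array(stats::rnorm(length(images), 0, noise_sigma), dim(images))
        sqrt((images + n1)^2 + n2^2)
      } else {
        images + array(stats::rnorm(length(images), 0, noise_sigma),
                       dim(images))
      }
    })
  }
  dom <- apply(fractions, c(1, 2), which.max)
  t2_true <- matrix(tissues$t2_ms[match(classes, tissues$class_name)][dom],
                    nr, nc)
  t2_true[matrix(tissues$proton_density[match(classes,
    tissues$class_name)][dom], nr, nc) == 0] <- NA_real_
  structure(list(
    images = images, prep_times_ms = preps, protocol = protocol,
    pixel_size_mm = spec$pixel_size_mm, spec = spec,
    truth = list(t2_ms = t2_true, fractions = fractions,
                 displacements_mm = disp, signals = sig, tissues = tissues)
  ), class = "prepared_series")
}

#' @export
print.prepared_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("T2-prepared series: %d images of %d x %d px (%g x %g mm)\n",
              d[3], d[1], d[2], x$pixel_size_mm[1], x$pixel_size_mm[2]))
  cat("  prep times (ms):", paste(x$prep_times_ms, collapse = ", "),
      "| readout:", x$protocol$readout, "\n")
  if (!is.null(x$truth))
    cat("  ground truth attached (true T2, fractions, displacements)\n")
  invisible(x)
}

#' Simulate a multi-echo spin-echo signal
#'
#' Mono-exponential three-parameter signal
#' \code{amplitude * exp(-TE / t2_ms) + offset} on an echo-time grid. The
#' default grid is the reference measurement's: 32 echoes equally spaced from
#' 7 to 224 ms.
#'
#' @param t2_ms transverse relaxation time (> 0).
#' @param amplitude signal amplitude.
#' @param offset constant offset.
#' @param echo_times_ms strictly increasing, positive echo times.
#' @return numeric signal vector with the echo times as attribute
#'   \code{"echo_times_ms"}.
#' @export
simulate_multiecho_series <- function(t2_ms, amplitude = 1000, offset = 0,
                                      echo_times_ms = seq(7, 224,
                                                          length.out = 32)) {
  if (t2_ms <= 0) stop("t2_ms must be positive")
  if (any(echo_times_ms <= 0) || any(diff(echo_times_ms) <= 0))
    stop("echo times must be positive and strictly increasing")
  s <- amplitude * exp(-echo_times_ms / t2_ms) + offset
  attr(s, "echo_times_ms") <- echo_times_ms
  s
}

#' Simulate a cine frame stack over one cardiac cycle
#'
#' Renders \code{n_frames} frames sampling one RR interval: a systolic
#' contraction (endocardial radius reduced by \code{contraction_mm} with a
#' half-sine time course over the systolic fraction of the cycle) followed by
#' a residual diastolic drift — a rigid translation that ramps linearly from 0
#' to the spec's \code{motion_amplitude_mm} across the acquisition window
#' placed in mid-diastole. Frame intensity is the proton-density-weighted
#' tissue mixture (bright blood, intermediate myocardium), the bSSFP cine
#' appearance.
#'
#' @param spec a \code{\link{phantom_spec}}; cine rendering typically uses a
#'   finer \code{pixel_size_mm} (e.g. 1.8 mm) than the mapping protocol.
#' @param n_frames number of frames (>= 2).
#' @param seed noise seed.
#' @param tissues tissue table.
#' @param systolic_fraction fraction of the cycle spent in systole.
#' @param contraction_mm peak systolic reduction of the endocardial radius.
#' @param window_ms duration of the acquisition-window overlay.
#' @param subgrid_factor rendering oversampling for the frames.
#' @return object of class \code{"cine_stack"}: frames
#'   (rows x cols x n_frames), \code{times_ms} spanning [0, RR), the
#'   acquisition window, and ground-truth per-frame translation.
#' @export
make_cine <- function(spec, n_frames = 25, seed = NULL,
                      tissues = tissue_properties(),
                      systolic_fraction = 0.35, contraction_mm = 4,
                      window_ms = 150, subgrid_factor = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  rr <- spec$rr_interval_ms
  times <- (seq_len(n_frames) - 1) / n_frames * rr
  ts <- systolic_fraction * rr
  w0 <- ts + (rr - ts - window_ms) / 2
  w1 <- w0 + window_ms
  th <- spec$motion_direction_deg * pi / 180
  drift <- spec$motion_amplitude_mm *
    pmin(1, pmax(0, (times - w0) / (w1 - w0)))
  translations <- cbind(dx_mm = drift * cos(th), dy_mm = drift * sin(th))
  pd <- tissues$proton_density[match(tissue_properties()$class_name,
                                     tissues$class_name)]
  frames <- array(0, dim = c(spec$grid_shape[1], spec$grid_shape[2], n_frames))
  for (i in seq_len(n_frames)) {
    h <- if (times[i] < ts) sin(pi * times[i] / ts) else 0
    sp <- spec
    sp$subgrid_factor <- as.integer(subgrid_factor)
    sp$endo_radius_mm <- spec$endo_radius_mm - contraction_mm * h
    sp$motion_amplitude_mm <- 0
    # shift the LV center by the frame's translation
    sp$lv_center <- spec$lv_center +
      c(-translations[i, "dy_mm"] / spec$pixel_size_mm[1],
        translations[i, "dx_mm"] / spec$pixel_size_mm[2])
    fr <- render_phantom(sp)
    img <- matrix(0, spec$grid_shape[1], spec$grid_shape[2])
    for (k in seq_along(pd)) if (pd[k] > 0) img <- img + fr[, , k] * pd[k]
    frames[, , i] <- img
  }
  if (spec$noise_sigma > 0) {
    frames <- with_seed(seed, frames +
      array(stats::rnorm(length(frames), 0, spec$noise_sigma), dim(frames)))
  }
  structure(list(
    frames = frames, times_ms = times, pixel_size_mm = spec$pixel_size_mm,
    acquisition_window_ms = c(w0, w1), spec = spec,
    truth = list(translations_mm = translations,
                 endo_radius_mm = spec$endo_radius_mm -
                   contraction_mm * ifelse(times < ts,
                                           sin(pi * times / ts), 0))
  ), class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cine stack: %d frames of %d x %d px, RR %g ms\n",
              d[3], d[1], d[2], x$spec$rr_interval_ms))
  cat(sprintf("  acquisition window %.0f-%.0f ms, diastolic drift %g mm\n",
              x$acquisition_window_ms[1], x$acquisition_window_ms[2],
              x$spec$motion_amplitude_mm))
  invisible(x)
}
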