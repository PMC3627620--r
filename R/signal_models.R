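#' Acquisition protocol for T2-prepared single-shot mapping
#'
#' Describes the T2-prepared acquisition used both by the simulator and by the
#' fitting code: the set of T2-preparation times, the single-shot readout
#' family and its per-TR parameters, and the cardiac timing. The defaults
#' follow the clinical protocol the package emulates: three preparation times
#' of 0, 24 and 55 ms, a maximum acquisition window of 150 ms per single-shot
#' image, and a 12-heartbeat scan, i.e. one shot every
#' \code{scan_time_beats / length(prep_times_ms)} heartbeats.
#'
#' The readout family determines the k-space trajectory: a spoiled
#' gradient-echo (FLASH) shot is acquired with centric ordering, so the
#' contrast-defining center line is the \emph{first} line of the shot, while a
#' balanced SSFP shot uses linear ordering and samples the center at the
#' middle of the shot. \code{readout = "ideal"} bypasses the readout entirely
#' and records the prepared magnetization itself.
#'
#' The mapping sequence's flip angle and TR are not part of the published
#' protocol; the defaults (15 degrees for FLASH, 70 degrees for SSFP, TR
#' 2.8 ms) are explicit assumptions and freely configurable.
#'
#' @param prep_times_ms numeric vector of distinct, non-negative
#'   T2-preparation times in ms. At least two are required for fitting; the
#'   reference protocol uses three.
#' @param readout one of \code{"ideal"}, \code{"flash_centric"},
#'   \code{"ssfp_linear"}.
#' @param acquisition_window_ms maximum duration of one single-shot readout.
#' @param readout_tr_ms,readout_te_ms per-line repetition/echo time (ms).
#' @param flip_angle_deg readout flip angle in degrees, in (0, 180]. Default
#'   depends on the readout family (15 FLASH, 70 SSFP, 90 ideal).
#' @param n_readout_lines phase-encode lines per shot; default fills the
#'   acquisition window (\code{floor(acquisition_window_ms / readout_tr_ms)}).
#' @param trajectory_center_index 1-based index of the line that samples the
#'   k-space center. Defaults to 1 (centric) or the middle line (linear).
#' @param rr_interval_ms simulated cardiac period (ms).
#' @param scan_time_beats total heartbeats for the whole map acquisition.
#' @return an object of class \code{"acquisition_protocol"}.
#' @examples
#' p <- acquisition_protocol(readout = "ssfp_linear")
#' p$trajectory_center_index  # middle line for a linear trajectory
#' @export
acquisition_protocol <- function(prep_times_ms = c(0, 24, 55),
                                 readout = c("ideal", "flash_centric", "ssfp_linear"),
                                 acquisition_window_ms = 150,
                                 readout_tr_ms = 2.8,
                                 readout_te_ms = 1.2,
                                 flip_angle_deg = NULL,
                                 n_readout_lines = NULL,
                                 trajectory_center_index = NULL,
                                 rr_interval_ms = 1000,
                                 scan_time_beats = 12) {
  readout <- match.arg(readout)
  prep_times_ms <- as.numeric(prep_times_ms)
  if (length(prep_times_ms) < 2L)
    stop("at least two prep times are required for fitting")
  if (anyDuplicated(prep_times_ms) || any(prep_times_ms < 0))
    stop("prep times must be distinct and non-negative")
  if (acquisition_window_ms <= 0 || acquisition_window_ms > 150)
    stop("acquisition_window_ms must be in (0, 150]")
  if (is.null(flip_angle_deg))
    flip_angle_deg <- switch(readout, ideal = 90, flash_centric = 15,
                             ssfp_linear = 70)
  if (flip_angle_deg <= 0 || flip_angle_deg > 180)
    stop("flip angle must be in (0, 180] degrees")
  if (is.null(n_readout_lines))
    n_readout_lines <- max(1L, floor(acquisition_window_ms / readout_tr_ms))
  n_readout_lines <- as.integer(n_readout_lines)
  if (n_readout_lines * readout_tr_ms > acquisition_window_ms + 1e-9)
    stop("n_readout_lines * readout_tr_ms exceeds the acquisition window")
  default_center <- if (readout == "ssfp_linear")
    as.integer(ceiling(n_readout_lines / 2)) else 1L
  if (is.null(trajectory_center_index))
    trajectory_center_index <- default_center
  trajectory_center_index <- as.integer(trajectory_center_index)
  if (trajectory_center_index < 1L || trajectory_center_index > n_readout_lines)
    stop("trajectory_center_index outside the shot")
  if (readout == "flash_centric" && trajectory_center_index != 1L)
    stop("centric trajectory samples k-space center on the first line")
  if (readout == "ssfp_linear" && trajectory_center_index == 1L)
    stop("linear trajectory does not sample k-space center first")
  structure(list(
    prep_times_ms = prep_times_ms,
    readout = readout,
    acquisition_window_ms = acquisition_window_ms,
    readout_tr_ms = readout_tr_ms,
    readout_te_ms = readout_te_ms,
    flip_angle_deg = flip_angle_deg,
    n_readout_lines = n_readout_lines,
    trajectory_center_index = trajectory_center_index,
    rr_interval_ms = rr_interval_ms,
    scan_time_beats = scan_time_beats
  ), class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("T2-prepared acquisition protocol\n")
  cat("  prep times (ms):", paste(x$prep_times_ms, collapse = ", "), "\n")
  cat("  readout:", x$readout,
      sprintf("(flip %g deg, TR %g ms, %d lines, center line %d)\n",
              x$flip_angle_deg, x$readout_tr_ms, x$n_readout_lines,
              x$trajectory_center_index))
  cat(sprintf("  acquisition window %g ms, RR %g ms, scan %d beats\n",
              x$acquisition_window_ms, x$rr_interval_ms, x$scan_time_beats))
  invisible(x)
}

#' T2-prepared signal of a single tissue
#'
#' Mono-exponential T2 preparation: the magnetization stored after a
#' preparation block of duration \code{prep_time_ms} is
#' \code{proton_density * exp(-prep_time_ms / t2_ms)}.
#'
#' @param proton_density relative equilibrium signal (>= 0).
#' @param t2_ms transverse relaxation time, > 0.
#' @param prep_time_ms preparation duration(s), >= 0. Vectorized.
#' @return prepared magnetization, same length as \code{prep_time_ms}.
#' @examples
#' t2prep_signal(1, 55, 55)  # exp(-1)
#' @export
t2prep_signal <- function(proton_density, t2_ms, prep_time_ms) {
  if (any(t2_ms <= 0)) stop("t2_ms must be positive")
  if (any(prep_time_ms < 0)) stop("prep_time_ms must be non-negative")
  proton_density * exp(-prep_time_ms / t2_ms)
}

# 3x3 rotation about x by angle a (radians); magnetization vectors are
# column vectors (Mx, My, Mz).
rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
}

# One single-shot readout starting from longitudinal magnetization mz0.
# Returns list(signal = recorded k-space-center signal, mz_end = longitudinal
# magnetization at the end of the shot). pd is the tissue's equilibrium
# magnetization. Bloch iteration per TR; instantaneous on-resonance pulses.
readout_shot <- function(mz0, pd, t1_ms, t2_ms, protocol) {
  n <- protocol$n_readout_lines
  tr <- protocol$readout_tr_ms
  alpha <- protocol$flip_angle_deg * pi / 180
  center <- protocol$trajectory_center_index
  e1 <- exp(-tr / t1_ms)
  sig <- NA_real_
  if (protocol$readout == "flash_centric") {
    # ideal spoiling: transverse magnetization discarded each TR
    mz <- mz0
    for (k in seq_len(n)) {
      if (k == center) sig <- mz * sin(alpha)
      mz <- pd + (mz * cos(alpha) - pd) * e1
    }
    list(signal = sig, mz_end = mz)
  } else if (protocol$readout == "ssfp_linear") {
    e2 <- exp(-tr / t2_ms)
    eh1 <- exp(-tr / 2 / t1_ms)
    eh2 <- exp(-tr / 2 / t2_ms)
    relax <- function(m, ex, ez) c(m[1] * ex, m[2] * ex, pd + (m[3] - pd) * ez)
    # alpha/2 catalyzation, TR/2 gap, then alternating +/- alpha pulses
    m <- c(0, 0, mz0)
    m <- rot_x(-alpha / 2) %*% m
    m <- relax(m, eh2, eh1)
    sgn <- 1
    for (k in seq_len(n)) {
      m <- rot_x(sgn * alpha) %*% m
      sgn <- -sgn
      if (k == center) sig <- sqrt(m[1]^2 + m[2]^2)
      m <- relax(m, e2, e1)
    }
    list(signal = sig, mz_end = m[3])
  } else {
    # ideal: no readout evolution, record the magnetization itself
    list(signal = mz0, mz_end = mz0)
  }
}

#' Recorded signal of one prepared single-shot readout
#'
#' Simulates the transient single-shot readout by iterating the Bloch
#' equations over the pulse train (per TR: instantaneous flip, relaxation with
#' the tissue's T1/T2), starting from the prepared longitudinal magnetization,
#' and returns the transverse signal at the k-space-center line
#' (\code{trajectory_center_index}) under the low-frequency-dominance
#' approximation: the recorded image intensity of a homogeneous region equals
#' the center line's signal. FLASH is modeled with ideal spoiling and centric
#' ordering; balanced SSFP with an alpha/2 catalyzation pulse, alternating
#' +/-alpha phase and linear ordering. An \code{"ideal"} readout returns the
#' input unchanged.
#'
#' This per-shot function assumes fully recovered magnetization at the start
#' of the shot; the inter-shot saturation of a multi-prep-time acquisition is
#' handled by \code{\link{effective_prep_signals}}.
#'
#' @param prepared_magnetization longitudinal magnetization after the
#'   preparation block.
#' @param tissue a single-row tissue description with \code{t1_ms},
#'   \code{t2_ms}, \code{proton_density} (see \code{\link{tissue_properties}}).
#' @param protocol an \code{\link{acquisition_protocol}}.
#' @return recorded scalar signal.
#' @export
readout_effective_signal <- function(prepared_magnetization, tissue, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  tissue <- as.list(tissue)
  if (protocol$readout == "ideal") return(prepared_magnetization)
  readout_shot(prepared_magnetization, tissue$proton_density,
               tissue$t1_ms, tissue$t2_ms, protocol)$signal
}

#' Effective recorded signals across the prep-time shot train
#'
#' Computes, for a single tissue, the signal actually recorded for every
#' preparation time of the protocol when the shots are played out
#' sequentially: one shot every \code{scan_time_beats / n_preps} heartbeats,
#' prep times in the order given by the protocol, T1 recovery (generally
#' incomplete) during the interval between the end of one shot and the next
#' preparation block. For the \code{"ideal"} readout this reduces to the pure
#' prepared signal \code{\link{t2prep_signal}}.
#'
#' The inter-shot saturation matters: because later shots start from slightly
#' saturated magnetization and prep times are acquired in increasing order,
#' the apparent decay across prep times is steepened, which biases the fitted
#' T2 of a spoiled (FLASH) readout slightly \emph{below} the true value, while
#' the balanced-SSFP transient toward its T2/T1-weighted steady state biases
#' it \emph{above} — reproducing the characteristic readout ordering
#' FLASH < reference < SSFP.
#'
#' @param tissue single tissue (list or single-row data.frame) with
#'   \code{t1_ms}, \code{t2_ms}, \code{proton_density}.
#' @param protocol an \code{\link{acquisition_protocol}}.
#' @return numeric vector of recorded signals, one per
#'   \code{protocol$prep_times_ms}.
#' @export
effective_prep_signals <- function(tissue, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  tissue <- as.list(tissue)
  preps <- protocol$prep_times_ms
  pd <- tissue$proton_density
  t1 <- tissue$t1_ms; t2 <- tissue$t2_ms
  if (pd <= 0) return(rep(0, length(preps)))
  if (protocol$readout == "ideal")
    return(t2prep_signal(pd, t2, preps))
  beats_per_shot <- max(1, protocol$scan_time_beats / length(preps))
  shot_dur <- protocol$n_readout_lines * protocol$readout_tr_ms
  mz <- pd
  out <- numeric(length(preps))
  for (i in seq_along(preps)) {
    mprep <- mz * exp(-preps[i] / t2)
    sh <- readout_shot(mprep, pd, t1, t2, protocol)
    out[i] <- sh$signal
    recovery_ms <- max(0, beats_per_shot * protocol$rr_interval_ms -
                         preps[i] - shot_dur)
    mz <- pd + (sh$mz_end - pd) * exp(-recovery_ms / t1)
  }
  out
}
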