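# NIfTI/JSON/CSV interfaces: image stacks with a JSON sidecar carrying the
# acquisition metadata, ground-truth companion volumes, contour CSVs.

spec_to_list <- function(spec) {
  s <- unclass(spec)
  s$motion_profile <- NULL  # functions are not serialized
  s
}

#' Write a prepared series as NIfTI + JSON sidecar
#'
#' The image stack is written as one 3D NIfTI volume (third dimension =
#' prep time index) with the in-plane pixel size in its header; acquisition
#' metadata (prep times, readout, acquisition window, pixel size, slice
#' thickness, phantom spec) goes to a JSON sidecar. Ground truth, when
#' present, is written as companion volumes with suffixes \code{_truthT2}
#' and \code{_fractions}.
#'
#' @param series a \code{"prepared_series"}.
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return invisibly, the sidecar path.
#' @export
write_prepared_series <- function(series, dir, prefix = "series") {
  stopifnot(inherits(series, "prepared_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(prefix, ".nii.gz"))
  pix <- c(series$pixel_size_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(series$images, pixdim = pix), img_path)
  meta <- list(
    prep_times_ms = series$prep_times_ms,
    readout = series$protocol$readout,
    acquisition_window_ms = series$protocol$acquisition_window_ms,
    pixel_size_mm = series$pixel_size_mm,
    slice_thickness_mm = series$spec$slice_thickness_mm %||% NA,
    protocol = unclass(series$protocol),
    spec = if (!is.null(series$spec)) spec_to_list(series$spec)
  )
  side_path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(meta, side_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(series$truth)) {
    RNifti::writeNifti(RNifti::asNifti(series$truth$t2_ms, pixdim = pix),
                       file.path(dir, paste0(prefix, "_truthT2.nii.gz")))
    fr <- series$truth$fractions
    attr(fr, "spec") <- NULL
    RNifti::writeNifti(RNifti::asNifti(unclass(fr), pixdim = c(pix, 1)),
                       file.path(dir, paste0(prefix, "_fractions.nii.gz")))
  }
  invisible(side_path)
}

#' Read a prepared series written by \code{write_prepared_series}
#'
#' @param dir directory holding the NIfTI stack and JSON sidecar.
#' @param prefix file name stem.
#' @return a \code{"prepared_series"} (truth maps attached when the companion
#'   volumes exist; the spec's motion profile function is not round-tripped).
#' @export
read_prepared_series <- function(dir, prefix = "series") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(dir, paste0(prefix, ".nii.gz")))
  pr <- side$protocol
  protocol <- acquisition_protocol(
    prep_times_ms = pr$prep_times_ms, readout = pr$readout,
    acquisition_window_ms = pr$acquisition_window_ms,
    readout_tr_ms = pr$readout_tr_ms, readout_te_ms = pr$readout_te_ms,
    flip_angle_deg = pr$flip_angle_deg,
    n_readout_lines = pr$n_readout_lines,
    trajectory_center_index = pr$trajectory_center_index,
    rr_interval_ms = pr$rr_interval_ms,
    scan_time_beats = pr$scan_time_beats)
  spec <- NULL
  if (!is.null(side$spec)) {
    s <- side$spec
    spec <- phantom_spec(
      grid_shape = s$grid_shape, pixel_size_mm = s$pixel_size_mm,
      slice_thickness_mm = s$slice_thickness_mm, lv_center = s$lv_center,
      endo_radius_mm = s$endo_radius_mm, epi_radius_mm = s$epi_radius_mm,
      thin_thickness_mm = s$thin_thickness_mm,
      thin_angle_deg = s$thin_angle_deg,
      rv_insertion_angle_deg = s$rv_insertion_angle_deg,
      motion_amplitude_mm = s$motion_amplitude_mm,
      motion_direction_deg = s$motion_direction_deg,
      noise_sigma = s$noise_sigma, rr_interval_ms = s$rr_interval_ms,
      subgrid_factor = s$subgrid_factor)
  }
  truth <- NULL
  t2_path <- file.path(dir, paste0(prefix, "_truthT2.nii.gz"))
  fr_path <- file.path(dir, paste0(prefix, "_fractions.nii.gz"))
  if (file.exists(t2_path)) {
    truth <- list(t2_ms = matrix(RNifti::readNifti(t2_path),
                                 dim(img)[1], dim(img)[2]))
    if (file.exists(fr_path)) {
      fr <- RNifti::readNifti(fr_path)
      truth$fractions <- array(as.numeric(fr), dim(fr))
    }
  }
  structure(list(
    images = array(as.numeric(img), dim(img)),
    prep_times_ms = side$prep_times_ms, protocol = protocol,
    pixel_size_mm = side$pixel_size_mm, spec = spec, truth = truth
  ), class = "prepared_series")
}

#' Write a fitted T2 map as NIfTI
#'
#' Writes the T2 map plus companion volumes for amplitude, fit error and the
#' validity/clamp masks.
#'
#' @param map a \code{"t2map"}.
#' @param dir output directory.
#' @param prefix file name stem.
#' @return invisibly, the map path.
#' @export
write_t2_map <- function(map, dir, prefix = "t2map") {
  stopifnot(inherits(map, "t2map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pix <- c(map$pixel_size_mm, 1)
  w <- function(m, suffix) RNifti::writeNifti(
    RNifti::asNifti(m, pixdim = pix),
    file.path(dir, paste0(prefix, suffix, ".nii.gz")))
  w(map$t2_ms, "")
  w(map$amplitude, "_amplitude")
  w(map$fit_error, "_fiterror")
  w(map$valid_mask * 1, "_valid")
  w(map$clamped * 1, "_clamped")
  invisible(file.path(dir, paste0(prefix, ".nii.gz")))
}

#' Read contours from a CSV polyline file
#'
#' Expects columns \code{contour} ("endo"/"epi"), \code{row}, \code{col} in
#' 1-based pixel coordinates.
#'
#' @param path CSV file.
#' @param ... passed to \code{\link{contour_set}} (view, reference angles).
#' @return a \code{\link{contour_set}}.
#' @export
read_contours_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contour", "row", "col") %in% names(df)))
  contour_set(as.matrix(df[df$contour == "endo", c("row", "col")]),
              as.matrix(df[df$contour == "epi", c("row", "col")]), ...)
}
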