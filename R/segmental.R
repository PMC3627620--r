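# AHA 6-segment division of the myocardium and ROI statistics.

aha_sax_labels <- c("anterior", "anteroseptal", "inferoseptal",
                    "inferior", "inferolateral", "anterolateral")
territory_4cv_labels <- c("basal septal", "mid septal", "apical septal",
                          "apical lateral", "mid lateral", "basal lateral")

# TRUE if the closed polyline (n x 2, (row, col)) self-intersects.
# Pairwise proper-intersection test over non-adjacent edges.
polyline_self_intersects <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1)
  ccw <- function(px, py, qx, qy, rx, ry)
    (qx - px) * (ry - py) - (qy - py) * (rx - px) > 0
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    ax <- p[i, 1]; ay <- p[i, 2]; bx <- p[nxt[i], 1]; by <- p[nxt[i], 2]
    cx <- p[js, 1]; cy <- p[js, 2]
    dx <- p[nxt[js], 1]; dy <- p[nxt[js], 2]
    inter <- (ccw(ax, ay, cx, cy, dx, dy) != ccw(bx, by, cx, cy, dx, dy)) &
      (ccw(ax, ay, bx, by, cx, cy) != ccw(ax, ay, bx, by, dx, dy))
    if (any(inter)) return(TRUE)
  }
  FALSE
}

#' Endocardial/epicardial contour pair
#'
#' Closed contours in 1-based pixel coordinates (columns \code{row},
#' \code{col}), with the angular reference used for segment numbering.
#' Contours must be simple (non-self-intersecting) and the endocardial
#' contour must lie strictly inside the epicardial one.
#'
#' @param endo,epi closed polylines as n x 2 matrices (row, col); an
#'   unclosed polyline is closed implicitly.
#' @param rv_insertion_angle_deg angular reference (anterior RV insertion),
#'   mathematical image angle in degrees.
#' @param view \code{"SAX"} (short axis, AHA sectors) or \code{"4CV"}
#'   (four-chamber view, wall territories).
#' @param apex_angle_deg for 4CV only: direction from base toward apex.
#' @return object of class \code{"contour_set"}.
#' @export
contour_set <- function(endo, epi, rv_insertion_angle_deg = 90,
                        view = c("SAX", "4CV"), apex_angle_deg = 180) {
  view <- match.arg(view)
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  stopifnot(ncol(endo) == 2, ncol(epi) == 2,
            nrow(endo) >= 3, nrow(epi) >= 3)
  if (polyline_self_intersects(endo) || polyline_self_intersects(epi))
    stop("contour self-intersects")
  inside <- pracma::inpolygon(endo[, 2], endo[, 1], epi[, 2], epi[, 1])
  if (!all(inside))
    stop("contours cross: endocardium not strictly inside epicardium")
  crossing <- pracma::inpolygon(epi[, 2], epi[, 1], endo[, 2], endo[, 1])
  if (any(crossing))
    stop("contours cross: epicardium enters the endocardial contour")
  structure(list(endo = endo, epi = epi,
                 rv_insertion_angle_deg = rv_insertion_angle_deg,
                 view = view, apex_angle_deg = apex_angle_deg),
            class = "contour_set")
}

#' Contours of a phantom's myocardial annulus
#'
#' Convenience constructor tracing the phantom geometry (including any thin
#' sector) as endo/epi polylines in pixel coordinates, optionally offset
#' radially to emulate tighter or looser manual contouring.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_points vertices per contour.
#' @param endo_offset_mm,epi_offset_mm radial offsets applied to the traced
#'   radii (positive = outward).
#' @return a \code{\link{contour_set}} in the spec's pixel grid.
#' @export
annulus_contours <- function(spec, n_points = 180, endo_offset_mm = 0,
                             epi_offset_mm = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  phi <- seq(0, 360, length.out = n_points + 1)[-(n_points + 1)]
  r_endo <- spec$endo_radius_mm + endo_offset_mm
  r_epi <- spec$endo_radius_mm + wall_thickness_at(spec, phi) + epi_offset_mm
  to_px <- function(r, phi) {
    x <- r * cos(phi * pi / 180); y <- r * sin(phi * pi / 180)
    cbind(row = spec$lv_center[1] - y / spec$pixel_size_mm[1],
          col = spec$lv_center[2] + x / spec$pixel_size_mm[2])
  }
  contour_set(to_px(r_endo, phi), to_px(r_epi, phi),
              rv_insertion_angle_deg = spec$rv_insertion_angle_deg)
}

#' Divide the myocardium into 6 segments
#'
#' Labels every pixel whose center lies between the endocardial and
#' epicardial contours (pixel-center-in-polygon rule, no fractional
#' weighting). For a short-axis view, labels 1-6 are 60-degree sectors
#' starting at the RV-insertion reference and proceeding clockwise in AHA
#' order: anterior, anteroseptal, inferoseptal, inferior, inferolateral,
#' anterolateral. For a four-chamber view, labels 1-6 are wall territories
#' (basal/mid/apical septal, then apical/mid/basal lateral) defined by
#' fractional position along the base-to-apex axis (thirds) and by the side
#' of the axis; the septal wall is the side to the left of the base-to-apex
#' direction.
#'
#' @param contours a \code{\link{contour_set}}.
#' @param grid_shape image size \code{c(rows, cols)}.
#' @param pixel_size_mm in-plane resolution, used only for angle/axis
#'   geometry on anisotropic grids.
#' @return integer label matrix (0 outside the myocardium) with attributes
#'   \code{"segment_labels"} (names of segments 1-6) and \code{"view"}.
#' @export
segment_myocardium <- function(contours, grid_shape,
                               pixel_size_mm = c(1, 1)) {
  stopifnot(inherits(contours, "contour_set"))
  nr <- grid_shape[1]; nc <- grid_shape[2]
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  in_epi <- pracma::inpolygon(cols, rows, contours$epi[, 2], contours$epi[, 1])
  in_endo <- pracma::inpolygon(cols, rows, contours$endo[, 2],
                               contours$endo[, 1])
  myo <- in_epi & !in_endo
  lab <- integer(nr * nc)
  if (any(myo)) {
    if (contours$view == "SAX") {
      cy <- mean(contours$endo[, 1]); cx <- mean(contours$endo[, 2])
      x <- (cols[myo] - cx) * pixel_size_mm[2]
      y <- (cy - rows[myo]) * pixel_size_mm[1]
      phi <- atan2(y, x) * 180 / pi
      rel <- (contours$rv_insertion_angle_deg - phi) %% 360
      lab[myo] <- pmin(floor(rel / 60) + 1L, 6L)
    } else {
      th <- contours$apex_angle_deg * pi / 180
      ux <- cos(th); uy <- sin(th)
      x <- cols[myo] * pixel_size_mm[2]
      y <- -rows[myo] * pixel_size_mm[1]
      x <- x - mean(x); y <- y - mean(y)     # center on the wall
      s <- x * ux + y * uy                   # along base->apex
      p <- -x * uy + y * ux                  # perpendicular (left positive)
      frac <- (s - min(s)) / (max(s) - min(s) + 1e-12)
      third <- pmin(floor(frac * 3) + 1L, 3L) # 1 basal .. 3 apical
      septal <- p > 0
      lab[myo] <- ifelse(septal, third, 7L - third)
    }
  }
  out <- matrix(lab, nr, nc)
  attr(out, "segment_labels") <-
    if (contours$view == "SAX") aha_sax_labels else territory_4cv_labels
  attr(out, "view") <- contours$view
  out
}

#' Global and segmental T2 statistics
#'
#' Per-segment mean/SD of fitted T2 over valid pixels, the global slice value
#' (pixel-wise mean over all labeled valid pixels, not the mean of segment
#' means), each segment's absolute deviation from the global value, and
#' outlier flagging of segments (and the global value) whose mean T2 is at or
#' above \code{threshold_ms} — the "T2 >= 70 ms" rule used to screen for
#' spuriously elevated segments.
#'
#' @param map a \code{"t2map"}.
#' @param labels segment label matrix from \code{\link{segment_myocardium}}
#'   (or any integer matrix, 0 = outside).
#' @param threshold_ms outlier flag threshold; the boundary value flags.
#' @return a \code{"segment_report"}: data.frame with one row per segment plus
#'   a global row (\code{id = 0}), columns \code{id}, \code{label},
#'   \code{mean_t2_ms}, \code{sd_t2_ms}, \code{n_pixels},
#'   \code{abs_dev_from_global_ms}, \code{flagged}. An empty segment is
#'   reported with \code{n_pixels = 0} and \code{NA} statistics.
#' @export
roi_stats <- function(map, labels, threshold_ms = 70) {
  stopifnot(inherits(map, "t2map"))
  if (!all(dim(labels) == dim(map$t2_ms)))
    stop("labels must share the map grid")
  seg_names <- attr(labels, "segment_labels") %||% paste("segment", 1:6)
  ids <- sort(unique(labels[labels > 0]))
  ids <- union(seq_len(max(c(ids, 6L))), ids)
  use <- map$valid_mask & labels > 0
  vals <- map$t2_ms[use]
  segs <- labels[use]
  per <- lapply(ids, function(k) {
    v <- vals[segs == k]
    data.frame(id = k,
               label = if (k <= length(seg_names)) seg_names[k] else
                 paste("segment", k),
               mean_t2_ms = if (length(v)) mean(v) else NA_real_,
               sd_t2_ms = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_pixels = length(v), stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, per)
  global <- data.frame(id = 0L, label = "global",
                       mean_t2_ms = if (length(vals)) mean(vals) else NA_real_,
                       sd_t2_ms = if (length(vals) > 1) stats::sd(vals) else
                         NA_real_,
                       n_pixels = length(vals), stringsAsFactors = FALSE)
  rep_df <- rbind(rep_df, global)
  rep_df$abs_dev_from_global_ms <- abs(rep_df$mean_t2_ms - global$mean_t2_ms)
  rep_df$flagged <- !is.na(rep_df$mean_t2_ms) &
    rep_df$mean_t2_ms >= threshold_ms
  attr(rep_df, "threshold_ms") <- threshold_ms
  class(rep_df) <- c("segment_report", "data.frame")
  rep_df
}

#' @export
print.segment_report <- function(x, ...) {
  cat(sprintf("segmental T2 report (flag threshold %g ms)\n",
              attr(x, "threshold_ms")))
  df <- as.data.frame(x)
  df$mean_t2_ms <- round(df$mean_t2_ms, 1)
  df$sd_t2_ms <- round(df$sd_t2_ms, 1)
  df$abs_dev_from_global_ms <- round(df$abs_dev_from_global_ms, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Edema-versus-remote comparison with MVO exclusion
#'
#' Compares fitted T2 in a focal-abnormality ROI against remote myocardium.
#' Hypointense microvascular-obstruction (MVO) core pixels are removed from
#' the edema ROI first and appear in neither group. Reports mean +/- SD per
#' ROI, their difference, and a Welch two-sample t summary.
#'
#' @param map a \code{"t2map"}.
#' @param edema_mask,remote_mask logical matrices on the map grid.
#' @param mvo_mask optional logical matrix of core pixels to exclude.
#' @return object of class \code{"edema_report"}.
#' @export
edema_vs_remote <- function(map, edema_mask, remote_mask, mvo_mask = NULL) {
  stopifnot(inherits(map, "t2map"))
  if (!is.null(mvo_mask)) edema_mask <- edema_mask & !mvo_mask
  if (any(edema_mask & remote_mask))
    stop("edema and remote masks overlap after MVO exclusion")
  ed <- map$t2_ms[edema_mask & map$valid_mask]
  rem <- map$t2_ms[remote_mask & map$valid_mask]
  if (!length(ed)) stop("edema ROI empty after MVO exclusion")
  if (!length(rem)) stop("remote ROI empty")
  tt <- if (length(ed) > 1 && length(rem) > 1 &&
            (stats::sd(ed) > 0 || stats::sd(rem) > 0))
    stats::t.test(ed, rem) else NULL
  structure(list(
    edema_mean_ms = mean(ed), edema_sd_ms = stats::sd(ed),
    n_edema = length(ed),
    remote_mean_ms = mean(rem), remote_sd_ms = stats::sd(rem),
    n_remote = length(rem),
    difference_ms = mean(ed) - mean(rem),
    t_statistic = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
    p_value = if (!is.null(tt)) tt$p.value else NA_real_
  ), class = "edema_report")
}

#' @export
print.edema_report <- function(x, ...) {
  cat(sprintf("edema %.1f +/- %.1f ms (n=%d) vs remote %.1f +/- %.1f ms (n=%d)\n",
              x$edema_mean_ms, x$edema_sd_ms, x$n_edema,
              x$remote_mean_ms, x$remote_sd_ms, x$n_remote))
  cat(sprintf("  difference %.1f ms, Welch t = %.2f, p = %.3g\n",
              x$difference_ms, x$t_statistic, x$p_value))
  invisible(x)
}
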