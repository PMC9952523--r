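#' Sample bird depth from depth frames along a keypoint track
#'
#' For each depth frame, finds the keypoint sample nearest in time
#' (within half the depth frame interval), and reads the median depth of
#' the odd `window` x `window` pixel neighbourhood centred on the
#' keypoint.  Zero-valued pixels are sensor holes and are excluded from
#' the median; frames with no keypoint within tolerance, or whose whole
#' window is invalid, are skipped.
#'
#' @param depth_frames List of depth matrices (mm).
#' @param depth_t Time stamps (s) of the depth frames; defaults to a
#'   10 Hz grid starting at the first keypoint time.
#' @param track Data frame with columns `t`, `u`, `v` giving keypoint
#'   positions in *depth-image* pixel coordinates.
#' @param window Odd window size in px (default 5).
#' @param fps_z Depth sampling rate in Hz, used for the default time
#'   stamps and pairing tolerance (default 10).
#' @return A `depth_track` tibble with columns `t` (s) and `depth` (mm).
#' @export
sample_depth <- function(depth_frames, track, depth_t = NULL, window = 5L,
                         fps_z = 10) {
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  if (is.null(depth_t)) {
    depth_t <- track$t[1L] + (seq_along(depth_frames) - 1L) / fps_z
  }
  if (length(depth_t) != length(depth_frames)) {
    stop("`depth_t` must match `depth_frames` in length", call. = FALSE)
  }
  tol <- 0.5 / fps_z
  r <- (window - 1L) / 2L
  out_t <- numeric(0)
  out_d <- numeric(0)
  for (i in seq_along(depth_frames)) {
    j <- which.min(abs(track$t - depth_t[i]))
    if (abs(track$t[j] - depth_t[i]) > tol) next
    fr <- depth_frames[[i]]
    cx <- round(track$u[j]); cy <- round(track$v[j])
    rows <- pmax(1L, cy + 1L - r):pmin(nrow(fr), cy + 1L + r)
    cols <- pmax(1L, cx + 1L - r):pmin(ncol(fr), cx + 1L + r)
    vals <- fr[rows, cols]
    vals <- vals[vals > 0]
    if (length(vals) == 0L) next
    out_t <- c(out_t, depth_t[i])
    out_d <- c(out_d, stats::median(vals))
  }
  tibble::tibble(t = out_t, depth = out_d)
}

#' Assemble a 3D trajectory from planar and depth series
#'
#' Combines the planar millimetre series (30 Hz) with a depth track
#' (10 Hz) into a `trajectory3d`.  Height above the platform is
#' `z(t) = camera_height - depth(t)`; the two series keep their native
#' sampling grids and time stamps (no resampling), because speed along Z
#' is formed with the depth frame rate while X/Y speeds use the video
#' frame rate.
#'
#' @param planar Tibble with columns `t`, `x`, `y` (mm) from
#'   [pixels_to_mm()].
#' @param depth_track Tibble with columns `t`, `depth` (mm); may have
#'   zero rows, in which case planar-only analyses remain valid.
#' @param camera_height Camera height above the platform in mm
#'   (default 2390).
#' @param fps_xy,fps_z Sampling rates of the two grids in Hz.
#' @return A `trajectory3d`: list with tibbles `planar` (`t`, `x`, `y`
#'   and optional `segment`) and `vertical` (`t`, `z`), plus attributes
#'   `camera_height`, `fps_xy`, `fps_z`, `bird_id`.
#' @export
assemble_trajectory <- function(planar, depth_track = NULL,
                                camera_height = 2390, fps_xy = 30,
                                fps_z = 10) {
  if (nrow(planar) == 0L) stop("planar series is empty", call. = FALSE)
  if (is.null(depth_track)) {
    depth_track <- tibble::tibble(t = numeric(), depth = numeric())
  }
  if (nrow(depth_track) > 0L && camera_height <= max(depth_track$depth)) {
    stop("negative height: camera_height (", camera_height,
         " mm) does not exceed the maximum depth (",
         max(depth_track$depth), " mm)", call. = FALSE)
  }
  vertical <- tibble::tibble(t = depth_track$t,
                             z = camera_height - depth_track$depth)
  new_trajectory3d(planar, vertical, camera_height = camera_height,
                   fps_xy = fps_xy, fps_z = fps_z,
                   bird_id = attr(planar, "bird_id"))
}

new_trajectory3d <- function(planar, vertical, camera_height, fps_xy, fps_z,
                             bird_id = NULL) {
  structure(
    list(planar = tibble::as_tibble(planar),
         vertical = tibble::as_tibble(vertical)),
    camera_height = camera_height, fps_xy = fps_xy, fps_z = fps_z,
    bird_id = bird_id, class = "trajectory3d"
  )
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf(
    "<trajectory3d>%s %d planar samples at %g Hz, %d vertical at %g Hz\n",
    if (is.null(attr(x, "bird_id"))) "" else paste0(" bird ", attr(x, "bird_id"), ":"),
    nrow(x$planar), attr(x, "fps_xy"), nrow(x$vertical), attr(x, "fps_z")))
  if (nrow(x$planar) > 0L) {
    cat(sprintf("  t in [%.2f, %.2f] s; x in [%.0f, %.0f] mm; y in [%.0f, %.0f] mm\n",
                min(x$planar$t), max(x$planar$t), min(x$planar$x),
                max(x$planar$x), min(x$planar$y), max(x$planar$y)))
  }
  invisible(x)
}

#' Plot a trajectory's plane projections
#'
#' XY (top view) and YZ (lateral/vertical view) projections of a bird's
#' path, mirroring the plane-projection displays used to compare walking
#' styles across gait scores.
#'
#' @param object A `trajectory3d`.
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @method autoplot trajectory3d
#' @export
autoplot.trajectory3d <- function(object, ...) {
  xy <- tibble::tibble(plane = "XY (top view)",
                       h = object$planar$x, v = object$planar$y)
  df <- xy
  if (nrow(object$vertical) > 0L) {
    # pair y with z by nearest planar sample
    yz_y <- stats::approx(object$planar$t, object$planar$y,
                          xout = object$vertical$t, rule = 2)$y
    df <- dplyr::bind_rows(xy, tibble::tibble(plane = "YZ (rear view)",
                                              h = yz_y,
                                              v = object$vertical$z))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::labs(x = "position (mm)", y = "position (mm)",
                  title = attr(object, "bird_id"))
}
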