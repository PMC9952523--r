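#' Read a pose-estimation keypoint CSV
#'
#' Parses the three-header-row pose CSV dialect (scorer / bodyparts /
#' coords) exported by keypoint-tracking tools, expecting exactly one
#' body part (the bird's back) with `x`, `y` and `likelihood` columns.
#'
#' @param path CSV file path.
#' @param bird_id Bird label; defaults to the file name without
#'   extension.
#' @param fps Planar sampling rate in Hz (default 30).
#' @return A `keypoint_track`: a tibble with columns `frame` (0-based
#'   frame index), `t` (s), `u`, `v` (px) and `confidence`, plus
#'   attributes `bird_id` and `fps`.
#' @export
read_keypoint_csv <- function(path, bird_id = NULL, fps = 30) {
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) {
    stop("pose CSV needs three header rows (scorer/bodyparts/coords); got ",
         length(hdr), call. = FALSE)
  }
  parts <- strsplit(hdr, ",", fixed = TRUE)
  bodyparts <- unique(parts[[2L]][-1L])
  bodyparts <- bodyparts[nzchar(bodyparts)]
  if (length(bodyparts) != 1L) {
    stop("expected exactly one body part in header row 2, found ",
         length(bodyparts), call. = FALSE)
  }
  coords <- parts[[3L]][-1L]
  need <- c("x", "y", "likelihood")
  if (!identical(tolower(coords[1:3]), need)) {
    stop("header row 3 must name coords x, y, likelihood", call. = FALSE)
  }
  dat <- utils::read.csv(path, skip = 3L, header = FALSE,
                         col.names = c("frame", "u", "v", "confidence"))
  if (nrow(dat) == 0L) stop("pose CSV has no data rows", call. = FALSE)
  if (any(diff(dat$frame) <= 0)) {
    bad <- which(diff(dat$frame) <= 0)[1L] + 1L
    stop("frame indices not strictly increasing at data row ", bad,
         call. = FALSE)
  }
  if (is.null(bird_id)) bird_id <- sub("\\.[^.]*$", "", basename(path))
  new_keypoint_track(
    tibble::tibble(frame = as.integer(dat$frame), t = dat$frame / fps,
                   u = dat$u, v = dat$v, confidence = dat$confidence),
    bird_id = bird_id, fps = fps
  )
}

new_keypoint_track <- function(df, bird_id, fps) {
  structure(df, bird_id = bird_id, fps = fps,
            class = c("keypoint_track", class(tibble::as_tibble(df))))
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("<keypoint_track> bird %s, %d samples at %g fps\n",
              attr(x, "bird_id"), nrow(x), attr(x, "fps")))
  NextMethod()
}

#' Write a keypoint track in the pose CSV dialect
#'
#' @param track A `keypoint_track` (or a data frame with columns
#'   `frame`, `u`, `v`, `confidence`).
#' @param path Output path.
#' @param scorer,bodypart Header labels.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(track, path, scorer = "synthetic",
                               bodypart = "back") {
  lines <- c(
    paste("scorer", scorer, scorer, scorer, sep = ","),
    paste("bodyparts", bodypart, bodypart, bodypart, sep = ","),
    "coords,x,y,likelihood",
    sprintf("%d,%.6f,%.6f,%.6f", track$frame, track$u, track$v,
            track$confidence)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Clean a keypoint track
#'
#' Drops samples below a confidence threshold, linearly interpolates
#' `(u, v)` across dropped gaps of at most `max_gap` frames, and splits
#' the track into independent segments across longer gaps.  Interpolated
#' samples carry the confidence of the weaker anchor.
#'
#' @param track A `keypoint_track`.
#' @param conf_min Minimum confidence kept, in `[0, 1]` (default 0.6).
#' @param max_gap Longest gap (in frames) bridged by interpolation
#'   (default 5).
#' @return A `keypoint_track` with an added `segment` column (integer,
#'   1-based) and gaps either interpolated or split.
#' @export
clean_track <- function(track, conf_min = 0.6, max_gap = 5L) {
  if (conf_min < 0 || conf_min > 1) stop("`conf_min` must be in [0, 1]", call. = FALSE)
  fps <- attr(track, "fps")
  keep <- track$confidence >= conf_min
  if (!any(keep)) stop("empty track after filtering", call. = FALSE)
  good <- track[keep, , drop = FALSE]
  gaps <- diff(good$frame)                      # >1 marks missing frames
  seg <- cumsum(c(1L, as.integer(gaps > max_gap + 1L)))
  pieces <- lapply(split(seq_len(nrow(good)), seg), function(ii) {
    g <- good[ii, , drop = FALSE]
    frames <- g$frame[1L]:g$frame[nrow(g)]
    if (length(frames) == nrow(g)) {
      out <- g
    } else {
      out <- tibble::tibble(
        frame = frames,
        t = frames / fps,
        u = stats::approx(g$frame, g$u, xout = frames)$y,
        v = stats::approx(g$frame, g$v, xout = frames)$y,
        confidence = pmin(
          stats::approx(g$frame, g$confidence, xout = frames,
                        method = "constant", f = 0)$y,
          stats::approx(g$frame, g$confidence, xout = frames,
                        method = "constant", f = 1)$y
        )
      )
      known <- match(g$frame, frames)
      out$confidence[known] <- g$confidence
    }
    out
  })
  seg_id <- rep(seq_along(pieces), vapply(pieces, nrow, integer(1L)))
  out <- dplyr::bind_rows(pieces)
  out$segment <- seg_id
  new_keypoint_track(out, bird_id = attr(track, "bird_id"), fps = fps)
}

#' Convert pixel keypoints to platform-plane millimetres
#'
#' Applies the pixel-to-distance factor and the top-view Cartesian
#' convention: `x = (u - u0) / px_per_mm` points along the platform's
#' long (forward) axis, and `y = (v0 - v) / px_per_mm` points laterally,
#' flipping the image's downward v axis.  The origin `(u0, v0)` is the
#' platform's start-line corner in the rectified crop.
#'
#' @param track A `keypoint_track` (cleaned or raw).
#' @param px_per_mm Pixel-to-distance factor in px/mm (default 0.62).
#' @param origin_px Numeric `c(u0, v0)` in pixels.
#' @return A tibble with columns `t` (s), `x`, `y` (mm) and, when
#'   present in the input, `segment`; attribute `fps` is carried over.
#' @export
pixels_to_mm <- function(track, px_per_mm = 0.62, origin_px = c(0, 0)) {
  if (px_per_mm <= 0) stop("`px_per_mm` must be > 0", call. = FALSE)
  out <- tibble::tibble(
    t = track$t,
    x = (track$u - origin_px[1L]) / px_per_mm,
    y = (origin_px[2L] - track$v) / px_per_mm
  )
  if ("segment" %in% names(track)) out$segment <- track$segment
  attr(out, "fps") <- attr(track, "fps")
  attr(out, "bird_id") <- attr(track, "bird_id")
  out
}

#' Invert the millimetre conversion back to pixels
#'
#' @param planar Tibble with `x`, `y` in mm.
#' @inheritParams pixels_to_mm
#' @return Tibble with `u`, `v` in px.
#' @export
mm_to_pixels <- function(planar, px_per_mm = 0.62, origin_px = c(0, 0)) {
  tibble::tibble(
    t = planar$t,
    u = origin_px[1L] + planar$x * px_per_mm,
    v = origin_px[2L] - planar$y * px_per_mm
  )
}

#' Root-mean-square keypoint error
#'
#' RMSE between predicted and ground-truth planar positions: the square
#' root of the mean squared Euclidean distance per matched sample, in mm.
#'
#' @param predicted,truth Data frames with matched columns `x`, `y`
#'   (mm) of equal length.
#' @return RMSE in mm (single number).
#' @export
keypoint_rmse <- function(predicted, truth) {
  if (nrow(predicted) != nrow(truth)) {
    stop("predicted and truth series differ in length (", nrow(predicted),
         " vs ", nrow(truth), ")", call. = FALSE)
  }
  sqrt(mean((predicted$x - truth$x)^2 + (predicted$y - truth$y)^2))
}

#' Export a trajectory as tidy CSV
#'
#' Long format with columns `bird_id`, `t`, `axis`, `value_mm`, covering
#' the planar (x, y at 30 Hz) and vertical (z at 10 Hz) series.
#'
#' @param traj A `trajectory3d` object (see [assemble_trajectory()]).
#' @param path Output CSV path.
#' @param bird_id Bird label; defaults to the trajectory's own.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, bird_id = attr(traj, "bird_id")) {
  if (is.null(bird_id)) bird_id <- "unknown"
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(traj$planar[, c("t", "x", "y")], c("x", "y"),
                        names_to = "axis", values_to = "value_mm"),
    tibble::tibble(t = traj$vertical$t, axis = "z",
                   value_mm = traj$vertical$z)
  )
  long <- dplyr::arrange(tibble::add_column(long, bird_id = bird_id,
                                            .before = 1L),
                         .data$axis, .data$t)
  readr::write_csv(long, path)
  invisible(path)
}
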