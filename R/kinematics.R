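#' Per-axis absolute linear speed
#'
#' Adjacent-sample displacements multiplied by the axis's frame rate:
#' 30 Hz for the planar X and Y axes, 10 Hz for the vertical Z axis,
#' then rectified with the absolute operator.  Each speed sample is
#' stamped at the midpoint of its interval.  When the planar series
#' carries a `segment` column (from [clean_track()] splits), differences
#' are never taken across segment boundaries.
#'
#' @param traj A `trajectory3d`.
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return A tibble with columns `t` (s), `value` (mm/s) and `axis`.
#' @export
linear_speed <- function(traj, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  s <- signed_speed(traj, axis)
  if (nrow(s) < 1L) stop("insufficient samples for speed along ", axis, call. = FALSE)
  tibble::tibble(t = s$t, value = abs(s$value), axis = axis)
}

# signed adjacent-difference speeds, segment-aware
signed_speed <- function(traj, axis) {
  if (axis == "z") {
    pos <- traj$vertical$z
    tt <- traj$vertical$t
    fps <- attr(traj, "fps_z")
    seg <- rep(1L, length(pos))
  } else {
    pos <- traj$planar[[axis]]
    tt <- traj$planar$t
    fps <- attr(traj, "fps_xy")
    seg <- if ("segment" %in% names(traj$planar)) traj$planar$segment else rep(1L, length(pos))
  }
  if (length(pos) < 2L) {
    return(tibble::tibble(t = numeric(), value = numeric(), segment = integer()))
  }
  d <- diff(pos) * fps
  tm <- (tt[-1L] + tt[-length(tt)]) / 2
  keep <- diff(seg) == 0L
  tibble::tibble(t = tm[keep], value = d[keep], segment = seg[-1L][keep])
}

#' Per-axis absolute linear acceleration
#'
#' Differences of the *signed* adjacent-frame speeds divided by the
#' axis's sampling interval (1/30 s for X and Y, 1/10 s for Z), then
#' rectified with the absolute operator.
#'
#' @inheritParams linear_speed
#' @return A tibble with columns `t` (s), `value` (mm/s^2) and `axis`.
#' @export
linear_acceleration <- function(traj, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  s <- signed_speed(traj, axis)
  fps <- if (axis == "z") attr(traj, "fps_z") else attr(traj, "fps_xy")
  if (nrow(s) < 2L) stop("insufficient samples for acceleration along ", axis, call. = FALSE)
  d <- diff(s$value) * fps
  tm <- (s$t[-1L] + s$t[-nrow(s)]) / 2
  keep <- diff(s$segment) == 0L
  tibble::tibble(t = tm[keep], value = abs(d[keep]), axis = axis)
}

# maximal runs of TRUE in a logical vector: tibble(start, length)
runs_of <- function(flag) {
  if (length(flag) == 0L) return(tibble::tibble(start = integer(), length = integer()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], length = r$lengths[r$values])
}

#' Forward-moving bouts along the platform
#'
#' A bird is forward-moving in a frame interval when its X displacement
#' to the next frame exceeds `d_min` (positive direction only).  Maximal
#' runs of at least `n_min` consecutive moving intervals become bouts;
#' shorter runs are discarded as sensor noise.  Bout duration is the run
#' length divided by the planar frame rate.
#'
#' @param traj A `trajectory3d`.
#' @param d_min Displacement threshold between adjacent frames in mm
#'   (default 5).
#' @param n_min Minimum run length in frames (default 3, about 0.1 s at
#'   30 fps).
#' @return A tibble of bouts with columns `start_t`, `end_t`,
#'   `duration` (s); zero rows for an immobile bird.
#' @export
forward_bouts <- function(traj, d_min = 5, n_min = 3L) {
  fps <- attr(traj, "fps_xy")
  s <- signed_speed(traj, "x")
  out <- list()
  for (sg in split(s, s$segment)) {
    disp <- sg$value / fps                     # back to mm per interval
    runs <- runs_of(disp > d_min)
    runs <- runs[runs$length >= n_min, , drop = FALSE]
    if (nrow(runs) == 0L) next
    start_t <- sg$t[runs$start] - 0.5 / fps    # interval start time
    out[[length(out) + 1L]] <- tibble::tibble(
      start_t = start_t,
      end_t = start_t + runs$length / fps,
      duration = runs$length / fps
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start_t = numeric(), end_t = numeric(),
                          duration = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_t)
}

#' Half-cycles of lateral body oscillation
#'
#' Lateral movement frames are those whose Y displacement to the next
#' frame exceeds `d_min` in magnitude.  Maximal same-sign runs of at
#' least `n_min` such frames qualify as directional sweeps; each pair of
#' consecutive opposite-sign sweeps separated by a pause of at most
#' `max_pause` seconds forms a half-cycle of oscillation.  Duration is
#' the time between the onsets of the two sweeps, which for a sinusoidal
#' sway equals half the oscillation period.  A sweep already underway on
#' the first interval of a segment has an unobserved onset and never
#' anchors a half-cycle.
#'
#' @inheritParams forward_bouts
#' @param max_pause Longest sub-threshold pause (s) allowed between the
#'   two sweeps of a half-cycle (default 0.5); a sway's turning point is
#'   always sub-threshold, so some tolerance is required.
#' @return A tibble with columns `start_t`, `end_t`, `duration` (s) and
#'   `direction` (+1 when the first sweep moves towards +Y); zero rows
#'   when the bird never oscillates.
#' @export
lateral_half_cycles <- function(traj, d_min = 5, n_min = 3L, max_pause = 0.5) {
  fps <- attr(traj, "fps_xy")
  s <- signed_speed(traj, "y")
  out <- list()
  for (sg in split(s, s$segment)) {
    disp <- sg$value / fps
    state <- integer(length(disp))             # -1, 0, +1 movement sign
    state[disp > d_min] <- 1L
    state[disp < -d_min] <- -1L
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values != 0L & r$lengths >= n_min
    if (sum(ok) < 2L) next
    rs <- starts[ok]; re <- ends[ok]; sgn <- r$values[ok]
    onset <- sg$t[rs] - 0.5 / fps
    offset <- sg$t[re] + 0.5 / fps
    for (k in seq_len(length(rs) - 1L)) {
      if (rs[k] == 1L) next      # sweep truncated at the segment start: onset unobserved
      if (sgn[k] == sgn[k + 1L]) next
      if (onset[k + 1L] - offset[k] > max_pause + 1e-9) next
      out[[length(out) + 1L]] <- tibble::tibble(
        start_t = onset[k], end_t = onset[k + 1L],
        duration = onset[k + 1L] - onset[k], direction = sgn[k]
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start_t = numeric(), end_t = numeric(),
                          duration = numeric(), direction = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_t)
}

metric_base_names <- c("speed_x", "speed_y", "speed_z",
                       "accel_x", "accel_y", "accel_z",
                       "forward_duration", "half_cycle_duration")

#' The 16 locomotive-behavior metrics of one bird
#'
#' Average and maximum of eight base quantities: absolute linear speed
#' and acceleration along X, Y and Z, forward-moving duration per bout,
#' and half-cycle duration of lateral body oscillation.  Speed and
#' acceleration summaries run over all frames (stationary frames
#' included) unless `moving_only` is set; duration summaries run over
#' events.  Birds with no depth data get `NA` Z metrics, and birds with
#' no bouts or half-cycles get `NA` duration metrics — absence, not
#' zero.
#'
#' @param traj A `trajectory3d`.
#' @param bouts,half_cycles Optional precomputed event tables; computed
#'   from `traj` with the given thresholds when `NULL`.
#' @param d_min,n_min,max_pause Detection thresholds, see
#'   [forward_bouts()] and [lateral_half_cycles()].
#' @param moving_only When `TRUE`, speed and acceleration averages use
#'   only frames whose displacement exceeds `d_min`.
#' @return A one-row tibble: `bird_id` plus 16 columns named
#'   `<base>_avg` / `<base>_max` for the eight base quantities.
#' @export
summarize_metrics <- function(traj, bouts = NULL, half_cycles = NULL,
                              d_min = 5, n_min = 3L, max_pause = 0.5,
                              moving_only = FALSE) {
  if (nrow(traj$planar) < 2L) stop("trajectory unusable: no planar speed series", call. = FALSE)
  if (is.null(bouts)) bouts <- forward_bouts(traj, d_min, n_min)
  if (is.null(half_cycles)) {
    half_cycles <- lateral_half_cycles(traj, d_min, n_min, max_pause)
  }
  avg_max <- function(v) {
    if (length(v) == 0L || all(is.na(v))) c(avg = NA_real_, max = NA_real_)
    else c(avg = mean(v), max = max(v))
  }
  series <- list()
  for (ax in c("x", "y")) {
    series[[paste0("speed_", ax)]] <- linear_speed(traj, ax)$value
    series[[paste0("accel_", ax)]] <- linear_acceleration(traj, ax)$value
  }
  if (nrow(traj$vertical) >= 3L) {
    series$speed_z <- linear_speed(traj, "z")$value
    series$accel_z <- linear_acceleration(traj, "z")$value
  } else {
    series$speed_z <- numeric()
    series$accel_z <- numeric()
  }
  if (moving_only) {
    thr <- d_min * attr(traj, "fps_xy")
    thr_z <- d_min * attr(traj, "fps_z")
    series$speed_x <- series$speed_x[series$speed_x > thr]
    series$speed_y <- series$speed_y[series$speed_y > thr]
    series$speed_z <- series$speed_z[series$speed_z > thr_z]
  }
  series$forward_duration <- bouts$duration
  series$half_cycle_duration <- half_cycles$duration
  vals <- lapply(metric_base_names, function(nm) avg_max(series[[nm]]))
  row <- stats::setNames(
    as.list(unlist(vals)),
    as.vector(t(outer(metric_base_names, c("avg", "max"), paste, sep = "_")))
  )
  tibble::as_tibble(c(list(bird_id = attr(traj, "bird_id") %||% NA_character_),
                      row))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
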