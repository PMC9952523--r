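#' Default gait-score walking profiles
#'
#' Parameter sets describing the three walking styles seen on the
#' platform: score 0 birds walk near-continuously with a pronounced
#' zigzag (lateral sway coupled to forward steps), score 1 birds walk in
#' short bouts separated by pauses, and score 2 birds stay near their
#' starting spot, with sub-threshold waddling and occasional attempts to
#' stand that show up as vertical excursions.  Magnitudes sit inside the
#' physically plausible ranges for 5-7-week broilers on a 1.5 m walking
#' space; they are generator parameters, not estimates of any real
#' flock.
#'
#' @return A tibble with one row per score (0, 1, 2) and columns
#'   `score`, `forward_speed` (mm/s while walking), `zigzag_amplitude`
#'   (mm), `zigzag_period` (s), `move_fraction`, `sit_attempts` (count
#'   per minute), `noise_sd` (mm per-frame positional jitter).
#' @export
default_profiles <- function() {
  tibble::tibble(
    score = c(0L, 1L, 2L),
    forward_speed = c(300, 180, 40),
    zigzag_amplitude = c(40, 35, 6),
    zigzag_period = c(1.2, 1.2, 1.6),
    move_fraction = c(0.75, 0.30, 0.06),
    sit_attempts = c(0L, 1L, 3L),
    noise_sd = c(1, 1, 1)
  )
}

platform_bounds <- function() {
  list(x = c(0, 1500), y = c(0, 460), x_walk = c(50, 1450), y_center = 230)
}

#' Simulate one bird's trajectory with known ground truth
#'
#' The latent (noise-free) path is a gated walk: movement bouts with
#' exponential-length move/pause alternation, constant forward speed
#' while moving (direction reversing at the ends of the 1.5 m walking
#' space), sinusoidal lateral sway whose phase only advances while
#' moving, and a 10 Hz vertical series with standing height, walking
#' bob, and (for sitting birds) stand-attempt excursions.  Observed
#' planar positions add Gaussian jitter to the latent path.  True bout
#' and half-cycle lists are derived from the latent path with the same
#' threshold rules the detectors use.
#'
#' @param profile One row of [default_profiles()] (or a list with the
#'   same fields).
#' @param duration Episode length in seconds, in `[0.5, 210]`.
#' @param seed Integer seed; everything is reproducible from it.
#' @param d_min,n_min Threshold rules used to derive the truth lists.
#' @return A `synthetic_truth` list: `trajectory` (observed
#'   `trajectory3d`), `latent` (noise-free `trajectory3d`), `true_bouts`,
#'   `true_half_cycles`, `profile`, `seed`.
#' @export
simulate_trajectory <- function(profile, duration = 60, seed = 1L,
                                d_min = 5, n_min = 3L) {
  p <- as.list(profile)
  num <- unlist(p[c("forward_speed", "zigzag_amplitude", "zigzag_period",
                    "move_fraction", "noise_sd")])
  if (any(!is.finite(num))) stop("profile parameters must be finite", call. = FALSE)
  if (duration < 0.5 || duration > 210) {
    stop("`duration` must be in [0.5, 210] seconds", call. = FALSE)
  }
  set.seed(seed)
  fps <- 30; fps_z <- 10
  n <- round(duration * fps) + 1L
  tt <- (seq_len(n) - 1L) / fps
  gate <- movement_gate(n, fps, p$move_fraction)
  b <- platform_bounds()

  # forward walk with direction bounce at the walking-space ends
  v_step <- p$forward_speed / fps
  x <- numeric(n)
  x[1L] <- b$x_walk[1L]
  dir <- 1
  for (i in 2:n) {
    xi <- x[i - 1L] + dir * v_step * gate[i - 1L]
    if (xi > b$x_walk[2L]) { dir <- -1; xi <- 2 * b$x_walk[2L] - xi }
    if (xi < b$x_walk[1L]) { dir <- 1; xi <- 2 * b$x_walk[1L] - xi }
    x[i] <- xi
  }

  # lateral sway: phase advances only while moving
  phase <- 2 * pi / (p$zigzag_period * fps) * cumsum(c(0, gate[-n]))
  y <- b$y_center + p$zigzag_amplitude * sin(phase)

  # vertical series on its native 10 Hz grid
  tz <- seq(0, duration, by = 1 / fps_z)
  gate_z <- gate[pmin(n, round(tz * fps) + 1L)]
  sitting <- p$move_fraction < 0.1
  base_z <- if (sitting) 130 else 260
  z <- base_z + 15 * gate_z * sin(2 * pi * tz / 0.8)
  n_att <- round(p$sit_attempts * duration / 60)
  if (n_att > 0 && sitting) {
    att_t <- sort(stats::runif(n_att, 2, max(2.1, duration - 3)))
    for (a in att_t) {
      # rise over 0.5 s, hold 1 s, fall over 0.5 s
      up <- pmin(1, pmax(0, (tz - a) / 0.5))
      down <- pmin(1, pmax(0, (tz - a - 1.5) / 0.5))
      z <- z + (260 - 130) * (up - down)
    }
  }

  latent_planar <- tibble::tibble(t = tt, x = x, y = y)
  latent <- new_trajectory3d(latent_planar, tibble::tibble(t = tz, z = z),
                             camera_height = 2390, fps_xy = fps, fps_z = fps_z,
                             bird_id = p$bird_id %||% NULL)
  obs_planar <- tibble::tibble(
    t = tt,
    x = x + stats::rnorm(n, 0, p$noise_sd),
    y = y + stats::rnorm(n, 0, p$noise_sd)
  )
  observed <- new_trajectory3d(obs_planar, tibble::tibble(t = tz, z = z),
                               camera_height = 2390, fps_xy = fps,
                               fps_z = fps_z, bird_id = p$bird_id %||% NULL)
  structure(
    list(trajectory = observed, latent = latent,
         true_bouts = forward_bouts(latent, d_min, n_min),
         true_half_cycles = lateral_half_cycles(latent, d_min, n_min),
         profile = tibble::as_tibble(p[setdiff(names(p), "bird_id")]),
         seed = seed),
    class = "synthetic_truth"
  )
}

# per-frame 0/1 movement gate from alternating exponential move/pause bouts
movement_gate <- function(n, fps, move_fraction) {
  if (move_fraction <= 0) return(numeric(n))
  if (move_fraction >= 1) return(rep(1, n))
  mean_move <- 2
  mean_pause <- mean_move * (1 / move_fraction - 1)
  gate <- numeric(0)
  state <- stats::runif(1) < move_fraction
  while (length(gate) < n) {
    len <- if (state) {
      max(0.4, stats::rexp(1, 1 / mean_move))
    } else {
      max(0.3, stats::rexp(1, 1 / mean_pause))
    }
    gate <- c(gate, rep(as.numeric(state), round(len * fps)))
    state <- !state
  }
  gate[seq_len(n)]
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> score %s, seed %d: %d true bouts, %d true half-cycles\n",
              x$profile$score, x$seed, nrow(x$true_bouts),
              nrow(x$true_half_cycles)))
  print(x$trajectory)
  invisible(x)
}

#' Render a synthetic platform image with known rotation
#'
#' A bright platform rectangle (long side much longer than the short
#' side) on a dark, mildly textured background, rotated by `alpha_true`
#' degrees about the image centroid with sensor noise added.  Returns
#' the image together with the true polar parameters of the platform's
#' long edge, for validating the rectification chain.
#'
#' @param alpha_true Rotation in degrees, `|alpha_true| < 45`.
#' @param size Canvas `c(height, width)` in px.
#' @param seed Integer seed for the texture and noise.
#' @param noise_sd Pixel noise standard deviation (intensity units).
#' @return A list: `img` (matrix), `truth` (tibble with `rho`, `theta`
#'   of the top long edge after rotation, degrees/px) and `alpha_true`.
#' @export
render_platform_image <- function(alpha_true, size = c(240L, 320L),
                                  seed = 1L, noise_sd = 0.02) {
  if (abs(alpha_true) >= 45) stop("|alpha_true| must be < 45 degrees", call. = FALSE)
  set.seed(seed)
  h <- size[1L]; w <- size[2L]
  half_len <- 0.36 * w
  half_wid <- 0.11 * h
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  if (half_len * abs(sin(alpha_true * pi / 180)) +
      half_wid * abs(cos(alpha_true * pi / 180)) > min(cx, cy)) {
    stop("platform rectangle exceeds the canvas at this rotation", call. = FALSE)
  }
  img <- matrix(0.15 + stats::rnorm(h * w, 0, 0.01), h, w)
  xs <- rep(0:(w - 1), each = h) - cx
  ys <- rep(0:(h - 1), times = w) - cy
  inside <- abs(xs) <= half_len & abs(ys) <= half_wid
  img[matrix(inside, h, w)] <- 0.85
  img <- rotate_image(img, alpha_true)
  img <- img + stats::rnorm(h * w, 0, noise_sd)
  img[img < 0] <- 0; img[img > 1] <- 1
  theta_t <- (90 + alpha_true) %% 180
  # top long edge passes through the rotated image of (cx, cy - half_wid)
  a <- alpha_true * pi / 180
  px <- cx + sin(a) * half_wid      # R_alpha applied to (0, -half_wid)
  py <- cy - cos(a) * half_wid
  rho_t <- px * cos(theta_t * pi / 180) + py * sin(theta_t * pi / 180)
  list(img = img,
       truth = tibble::tibble(rho = rho_t, theta = theta_t),
       alpha_true = alpha_true)
}

#' Synthesize 10 Hz depth frames for a trajectory
#'
#' Each frame is a flat platform-depth field (`camera_height` mm from
#' the camera) with a bird-shaped Gaussian depression of depth
#' `camera_height - z(t)` at the keypoint position, Gaussian sensor
#' noise, and a seeded fraction of zero-valued hole pixels.
#'
#' @param truth A `synthetic_truth` from [simulate_trajectory()].
#' @param camera_height Camera height above the platform (mm).
#' @param noise_sd Depth noise (mm).
#' @param seed Integer seed.
#' @param size Frame `c(height, width)` in px.
#' @param px_per_mm Depth-image scale (px/mm); the default 0.2 fits the
#'   platform into a 320 px frame.
#' @param hole_frac Fraction of pixels zeroed as sensor holes.
#' @param sigma_px Gaussian footprint of the bird (px).
#' @return A list: `frames` (list of matrices, mm), `t` (time stamps),
#'   `track_px` (tibble `t`, `u`, `v`: the 30 Hz keypoint track in
#'   depth-image pixels), `px_per_mm`, `origin_px`.
#' @export
make_depth_frames <- function(truth, camera_height = 2390, noise_sd = 0,
                              seed = 1L, size = c(240L, 320L),
                              px_per_mm = 0.2, hole_frac = 0,
                              sigma_px = 25) {
  set.seed(seed)
  h <- size[1L]; w <- size[2L]
  b <- platform_bounds()
  u0 <- (w - diff(b$x) * px_per_mm) / 2
  v0 <- (h + diff(b$y) * px_per_mm) / 2
  if (camera_height <= max(truth$trajectory$vertical$z)) {
    stop("camera_height must exceed the bird's height", call. = FALSE)
  }
  planar <- truth$trajectory$planar
  track_px <- tibble::tibble(t = planar$t,
                             u = u0 + planar$x * px_per_mm,
                             v = v0 - planar$y * px_per_mm)
  tz <- truth$trajectory$vertical$t
  zz <- truth$trajectory$vertical$z
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  frames <- vector("list", length(tz))
  for (i in seq_along(tz)) {
    j <- which.min(abs(planar$t - tz[i]))
    cu <- track_px$u[j]; cv <- track_px$v[j]
    bump <- zz[i] * exp(-((xg - cu)^2 + (yg - cv)^2) / (2 * sigma_px^2))
    fr <- camera_height - bump
    if (noise_sd > 0) fr <- fr + stats::rnorm(h * w, 0, noise_sd)
    fr <- round(pmax(fr, 1))
    if (hole_frac > 0) {
      holes <- which(stats::runif(h * w) < hole_frac)
      fr[holes] <- 0
    }
    frames[[i]] <- fr
  }
  list(frames = frames, t = tz, track_px = track_px,
       px_per_mm = px_per_mm, origin_px = c(u0, v0))
}

#' Write a synthetic trajectory as a pose-estimation CSV
#'
#' Applies the inverse of the millimetre conversion to the observed
#' planar positions and writes the three-header pose CSV dialect.
#' Confidence is constant-high with seeded dips so track cleaning is
#' exercised deterministically.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output CSV path.
#' @param px_per_mm,origin_px Calibration used for the inverse
#'   conversion (the default origin keeps all v coordinates positive).
#' @param conf_base Baseline confidence.
#' @param dip_frames Integer vector of 0-based frames forced to low
#'   confidence (default: a seeded 1% of frames).
#' @param dip_value Confidence assigned to dip frames.
#' @param seed Seed for the default dips.
#' @return `path`, invisibly.
#' @export
make_pose_csv <- function(truth, path, px_per_mm = 0.62,
                          origin_px = c(0, 300), conf_base = 0.95,
                          dip_frames = NULL, dip_value = 0.2, seed = 1L) {
  if (px_per_mm <= 0) stop("`px_per_mm` must be > 0", call. = FALSE)
  planar <- truth$trajectory$planar
  px <- mm_to_pixels(planar, px_per_mm, origin_px)
  n <- nrow(px)
  if (is.null(dip_frames)) {
    set.seed(seed)
    dip_frames <- which(stats::runif(n) < 0.01) - 1L
  }
  conf <- rep(conf_base, n)
  conf[dip_frames + 1L] <- dip_value
  track <- tibble::tibble(frame = seq_len(n) - 1L, u = px$u, v = px$v,
                          confidence = conf)
  write_keypoint_csv(track, path)
  invisible(path)
}

#' Simulate a cohort of gait-scored birds
#'
#' Draws `n_per_score` birds per gait score with the given profiles,
#' returning the per-bird ground truths and a metadata table.  Per-bird
#' seeds are derived reproducibly from `seed`.
#'
#' @param n_per_score Birds per score (default 4).
#' @param duration Episode length (s) per bird.
#' @param seed Cohort seed.
#' @param profiles Profile table as from [default_profiles()].
#' @return A list: `birds` (named list of `synthetic_truth`),
#'   `metadata` (tibble `bird_id`, `gait_score`).
#' @export
simulate_cohort <- function(n_per_score = 4L, duration = 60, seed = 1L,
                            profiles = default_profiles()) {
  set.seed(seed)
  n_birds <- n_per_score * nrow(profiles)
  sub_seeds <- sample.int(.Machine$integer.max, n_birds)
  birds <- list()
  meta <- list()
  k <- 0L
  for (si in seq_len(nrow(profiles))) {
    for (j in seq_len(n_per_score)) {
      k <- k + 1L
      prof <- as.list(profiles[si, ])
      prof$bird_id <- sprintf("bird_s%d_%02d", profiles$score[si], j)
      birds[[prof$bird_id]] <- simulate_trajectory(prof, duration,
                                                   seed = sub_seeds[k])
      meta[[k]] <- tibble::tibble(bird_id = prof$bird_id,
                                  gait_score = profiles$score[si])
    }
  }
  list(birds = birds, metadata = dplyr::bind_rows(meta))
}

#' Per-bird metric summaries for a simulated cohort
#'
#' Runs the kinematic metric extraction on every bird of a cohort and
#' joins the gait scores.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param ... Passed to [summarize_metrics()].
#' @return A tibble with one row per bird: `bird_id`, `gait_score`, and
#'   the 16 metric columns.
#' @export
cohort_metrics <- function(cohort, ...) {
  rows <- lapply(names(cohort$birds), function(id) {
    m <- summarize_metrics(cohort$birds[[id]]$trajectory, ...)
    m$bird_id <- id
    m
  })
  dplyr::left_join(dplyr::bind_rows(rows), cohort$metadata, by = "bird_id")
}
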