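# Independent brute-force oracles, written as plain loops so they share
# no code path with the package implementations they check.

# Hough accumulator by direct enumeration over every edge pixel and
# every (rho, theta) bin.
brute_hough <- function(edges, rho_res = 1, theta_res = 1, top_k = 3L) {
  h <- nrow(edges); w <- ncol(edges)
  thetas <- seq(0, 180 - theta_res, by = theta_res)
  nr <- floor(sqrt((h - 1)^2 + (w - 1)^2) / rho_res) + 1L
  acc <- matrix(0L, nrow = 2L * nr + 1L, ncol = length(thetas))
  cs <- cos(thetas * pi / 180); sn <- sin(thetas * pi / 180)
  for (row in seq_len(h)) {
    for (col in seq_len(w)) {
      if (edges[row, col] == 0) next
      x <- col - 1L; y <- row - 1L
      for (ti in seq_along(thetas)) {
        rb <- round((x * cs[ti] + y * sn[ti]) / rho_res)
        acc[rb + nr + 1L, ti] <- acc[rb + nr + 1L, ti] + 1L
      }
    }
  }
  out <- data.frame(rho = numeric(0), theta = numeric(0), votes = integer(0))
  for (ti in seq_along(thetas)) {
    for (ri in seq_len(nrow(acc))) {
      if (acc[ri, ti] > 0L) {
        out <- rbind(out, data.frame(rho = (ri - nr - 1L) * rho_res,
                                     theta = thetas[ti],
                                     votes = acc[ri, ti]))
      }
    }
  }
  out <- out[order(-out$votes, out$theta, out$rho), ]
  head(out, top_k)
}

# Run-scanning oracle for forward bouts on a per-interval displacement
# sequence (mm); interval i spans [(i-1)/fps, i/fps).
brute_bouts <- function(disp, d_min = 5, n_min = 3L, fps = 30) {
  n <- length(disp)
  res <- data.frame(start_t = numeric(0), end_t = numeric(0),
                    duration = numeric(0))
  i <- 1L
  while (i <= n) {
    if (disp[i] > d_min) {
      j <- i
      while (j <= n && disp[j] > d_min) j <- j + 1L
      len <- j - i
      if (len >= n_min) {
        res <- rbind(res, data.frame(start_t = (i - 1L) / fps,
                                     end_t = (i - 1L + len) / fps,
                                     duration = len / fps))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  res
}

# Sign-run oracle for lateral half-cycles: qualifying sweeps are maximal
# same-sign runs of |disp| > d_min with length >= n_min; consecutive
# opposite-sign sweeps separated by at most max_pause seconds pair into a
# half-cycle with duration = onset2 - onset1.  A sweep starting on the
# first interval has an unobserved onset and never anchors a pair.
brute_half_cycles <- function(disp, d_min = 5, n_min = 3L, fps = 30,
                              max_pause = 0.5) {
  n <- length(disp)
  sweeps <- data.frame(start = integer(0), end = integer(0), sgn = integer(0))
  i <- 1L
  while (i <= n) {
    s <- if (disp[i] > d_min) 1L else if (disp[i] < -d_min) -1L else 0L
    if (s != 0L) {
      j <- i
      while (j <= n && ((s == 1L && disp[j] > d_min) ||
                        (s == -1L && disp[j] < -d_min))) j <- j + 1L
      if (j - i >= n_min) {
        sweeps <- rbind(sweeps, data.frame(start = i, end = j - 1L, sgn = s))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  res <- data.frame(start_t = numeric(0), end_t = numeric(0),
                    duration = numeric(0), direction = integer(0))
  if (nrow(sweeps) >= 2L) {
    for (k in seq_len(nrow(sweeps) - 1L)) {
      if (sweeps$start[k] == 1L) next
      if (sweeps$sgn[k] == sweeps$sgn[k + 1L]) next
      gap <- (sweeps$start[k + 1L] - 1L) / fps - sweeps$end[k] / fps
      if (gap > max_pause + 1e-9) next
      on1 <- (sweeps$start[k] - 1L) / fps
      on2 <- (sweeps$start[k + 1L] - 1L) / fps
      res <- rbind(res, data.frame(start_t = on1, end_t = on2,
                                   duration = on2 - on1,
                                   direction = sweeps$sgn[k]))
    }
  }
  res
}

# Build a planar-only trajectory from a per-axis displacement sequence.
traj_from_disp <- function(dx = NULL, dy = NULL, fps = 30) {
  n <- max(length(dx), length(dy)) + 1L
  if (is.null(dx)) dx <- rep(0, n - 1L)
  if (is.null(dy)) dy <- rep(0, n - 1L)
  broilergait:::new_trajectory3d(
    tibble::tibble(t = (seq_len(n) - 1L) / fps,
                   x = cumsum(c(100, dx)), y = cumsum(c(230, dy))),
    tibble::tibble(t = numeric(), z = numeric()),
    camera_height = 2390, fps_xy = fps, fps_z = 10
  )
}

# Planar + vertical trajectory from explicit position series.
traj_from_positions <- function(x, y = NULL, z = NULL, fps_xy = 30,
                                fps_z = 10) {
  n <- length(x)
  if (is.null(y)) y <- rep(230, n)
  planar <- tibble::tibble(t = (seq_len(n) - 1L) / fps_xy, x = x, y = y)
  vert <- if (is.null(z)) {
    tibble::tibble(t = numeric(), z = numeric())
  } else {
    tibble::tibble(t = (seq_along(z) - 1L) / fps_z, z = z)
  }
  broilergait:::new_trajectory3d(planar, vert, camera_height = 2390,
                                 fps_xy = fps_xy, fps_z = fps_z)
}

# Random displacement mixture used by the oracle-equivalence checks:
# i.i.d. draws from {0, below-threshold, above-threshold +, above -}.
random_disp <- function(n, seed) {
  set.seed(seed)
  pool <- c(0, 2, 6, 8, -6, -8, 4, -2)
  sample(pool, n, replace = TRUE)
}
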