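test_that("speed is displacement times the axis frame rate, exactly", {
  traj <- traj_from_positions(x = 100 + 10 * (0:29), z = 100 + 8 * (0:9))
  sx <- linear_speed(traj, "x")
  expect_equal(sx$value, rep(300, 29))   # 10 mm/frame at 30 fps
  sy <- linear_speed(traj, "y")
  expect_equal(sy$value, rep(0, 29))     # stationary laterally
  sz <- linear_speed(traj, "z")
  expect_equal(sz$value, rep(80, 9))     # 8 mm/frame at 10 fps
  expect_error(linear_speed(traj_from_positions(x = 1), "x"), "insufficient")
})

test_that("acceleration is zero for constant velocity and uses signed speeds", {
  traj <- traj_from_positions(x = 100 + 10 * (0:29))
  expect_equal(linear_acceleration(traj, "x")$value, rep(0, 28))
  # speed rising 10 mm/s per planar frame -> 300 mm/s^2
  v <- cumsum(seq(0, by = 10, length.out = 30)) / 30
  traj2 <- traj_from_positions(x = 100 + v)
  expect_equal(linear_acceleration(traj2, "x")$value, rep(300, 28))
  # oscillation: |ddx|*fps^2 differs from d|dx|*fps^2; check signed handling
  x3 <- c(0, 10, 0, 10, 0, 10)
  traj3 <- traj_from_positions(x = x3)
  expect_equal(linear_acceleration(traj3, "x")$value,
               rep(600 * 30, 4))         # signed speeds alternate +-300
  expect_error(linear_acceleration(traj_from_positions(x = c(1, 2)), "x"),
               "insufficient")
})

test_that("sinusoidal acceleration matches double finite differencing", {
  t <- (0:149) / 30
  x <- 200 + 35 * sin(2 * pi * t / 1.3)
  traj <- traj_from_positions(x = x)
  got <- linear_acceleration(traj, "x")$value
  oracle <- abs(diff(diff(x) * 30) * 30)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("forward bouts follow the threshold-and-persistence rules", {
  got <- forward_bouts(traj_from_disp(dx = c(6, 6, 6, 0, 0, 6, 6)))
  expect_equal(nrow(got), 1L)
  expect_equal(got$duration, 0.1)
  expect_equal(got$start_t, 0)

  expect_equal(nrow(forward_bouts(traj_from_disp(dx = rep(5, 30)))), 0L)
  one_sec <- forward_bouts(traj_from_disp(dx = rep(6, 30)))
  expect_equal(one_sec$duration, 1)
  # backward movement does not count as forward-moving
  expect_equal(nrow(forward_bouts(traj_from_disp(dx = rep(-8, 30)))), 0L)
})

test_that("half-cycles pair opposite sweeps and drift never oscillates", {
  got <- lateral_half_cycles(traj_from_disp(dy = c(0, 0, 6, 6, 6, -6, -6, -6)))
  expect_equal(nrow(got), 1L)
  expect_equal(got$duration, 0.1)
  expect_equal(got$direction, 1L)
  expect_equal(nrow(lateral_half_cycles(traj_from_disp(dy = rep(6, 30)))), 0L)
})

test_that("a 1.2 s sinusoidal sway yields ~0.6 s half-cycles, 9-10 of them", {
  t <- seq(0, 6, by = 1 / 30)
  traj <- traj_from_positions(x = rep(0, length(t)),
                              y = 230 + 40 * sin(2 * pi * t / 1.2))
  hc <- lateral_half_cycles(traj)
  expect_true(nrow(hc) %in% c(9L, 10L))
  expect_true(all(abs(hc$duration - 0.6) <= 2 / 30))
})

test_that("bout and half-cycle detectors agree exactly with scanning oracles", {
  for (seed in 1:20) {
    disp <- random_disp(500, seed)
    traj <- traj_from_disp(dx = disp, dy = disp)
    got_b <- forward_bouts(traj)
    ob <- brute_bouts(disp)
    expect_equal(nrow(got_b), nrow(ob))
    expect_equal(got_b$start_t, ob$start_t)
    expect_equal(got_b$duration, ob$duration)
    got_h <- lateral_half_cycles(traj)
    oh <- brute_half_cycles(disp)
    expect_equal(nrow(got_h), nrow(oh))
    if (nrow(oh) > 0) {
      expect_equal(got_h$start_t, oh$start_t)
      expect_equal(got_h$duration, oh$duration)
      expect_equal(got_h$direction, oh$direction)
    }
  }
})

test_that("bout durations are frame-quantized and bounded by track time", {
  for (seed in 21:30) {
    disp <- random_disp(300, seed)
    traj <- traj_from_disp(dx = disp)
    b <- forward_bouts(traj)
    if (nrow(b) == 0) next
    expect_true(all(abs(b$duration * 30 - round(b$duration * 30)) < 1e-9))
    expect_true(all(b$duration >= 3 / 30 - 1e-9))
    expect_lte(sum(b$duration), 300 / 30)
    expect_true(all(diff(b$start_t) > 0))
    expect_true(all(b$end_t[-nrow(b)] <= b$start_t[-1] + 1e-9))
  }
})

test_that("raising thresholds never increases the number of bouts", {
  for (seed in 31:40) {
    disp <- random_disp(400, seed)
    traj <- traj_from_disp(dx = disp)
    n_base <- nrow(forward_bouts(traj, d_min = 5, n_min = 3))
    expect_lte(nrow(forward_bouts(traj, d_min = 7, n_min = 3)), n_base)
    expect_lte(nrow(forward_bouts(traj, d_min = 5, n_min = 5)), n_base)
  }
})

test_that("doubling displacements doubles speeds and accelerations exactly", {
  set.seed(50)
  x <- cumsum(runif(100, -10, 12))
  t1 <- traj_from_positions(x = 500 + x)
  t2 <- traj_from_positions(x = 500 + 2 * x)
  expect_equal(linear_speed(t2, "x")$value, 2 * linear_speed(t1, "x")$value)
  expect_equal(linear_acceleration(t2, "x")$value,
               2 * linear_acceleration(t1, "x")$value)
})

test_that("metric summaries have the 16 avg/max columns with max >= avg", {
  traj <- traj_from_positions(x = 100 + 10 * (0:59),
                              y = 230 + 40 * sin(2 * pi * (0:59) / 36),
                              z = 250 + 10 * sin((0:19) / 3))
  m <- summarize_metrics(traj)
  bases <- c("speed_x", "speed_y", "speed_z", "accel_x", "accel_y",
             "accel_z", "forward_duration", "half_cycle_duration")
  expect_true(all(c(paste0(bases, "_avg"), paste0(bases, "_max")) %in%
                    names(m)))
  expect_equal(m$speed_x_avg, 300)
  expect_equal(m$speed_x_max, 300)
  for (b in bases) {
    av <- m[[paste0(b, "_avg")]]; mx <- m[[paste0(b, "_max")]]
    if (!is.na(av)) expect_gte(mx, av)
  }
})

test_that("event-free birds get absent (NA) duration metrics, not zero", {
  traj <- traj_from_positions(x = rep(100, 40), y = rep(230, 40))
  m <- summarize_metrics(traj)
  expect_true(is.na(m$forward_duration_avg))
  expect_true(is.na(m$half_cycle_duration_max))
  expect_equal(m$speed_x_avg, 0)
  expect_error(summarize_metrics(traj_from_positions(x = 1)), "unusable")
})

test_that("bout/event averages follow the stated arithmetic", {
  # bouts of 0.1 s and 0.5 s -> avg 0.3, max 0.5
  dx <- c(rep(6, 3), 0, 0, rep(6, 15))
  m <- summarize_metrics(traj_from_disp(dx = dx))
  expect_equal(m$forward_duration_avg, 0.3)
  expect_equal(m$forward_duration_max, 0.5)
})
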