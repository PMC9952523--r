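write_pose_fixture <- function(path, frames, u, v, conf,
                               bodyparts = "back") {
  n_bp <- length(bodyparts)
  lines <- c(
    paste(c("scorer", rep("s", 3 * n_bp)), collapse = ","),
    paste(c("bodyparts", rep(bodyparts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), n_bp)), collapse = ","),
    paste(frames, u, v, conf, sep = ",")
  )
  writeLines(lines, path)
  path
}

test_that("well-formed pose CSVs parse into keypoint tracks", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f, 0:4, 10 + 0:4, 20 - 0:4, rep(0.9, 5))
  tr <- read_keypoint_csv(f, bird_id = "b1")
  expect_s3_class(tr, "keypoint_track")
  expect_equal(nrow(tr), 5L)
  expect_equal(tr$t, (0:4) / 30)
  expect_equal(tr$u, 10 + 0:4)
  expect_equal(attr(tr, "bird_id"), "b1")
})

test_that("frame gaps parse but malformed files are rejected with row info", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f, c(0, 1, 3), c(1, 2, 3), c(1, 2, 3), rep(1, 3))
  expect_equal(read_keypoint_csv(f)$frame, c(0L, 1L, 3L))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f2, c(0, 2, 1), c(1, 2, 3), c(1, 2, 3), rep(1, 3))
  expect_error(read_keypoint_csv(f2), "row 3")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,s", "bodyparts,back,back,back,side,side,side",
               "coords,x,y,likelihood,x,y,likelihood",
               "0,1,2,0.9,3,4,0.9"), f3)
  expect_error(read_keypoint_csv(f3), "one body part")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,2,0.9"), f4)
  expect_error(read_keypoint_csv(f4), "three header rows")
})

test_that("clean_track is the identity on fully confident tracks", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f, 0:9, 1:10, 11:20, rep(1, 10))
  tr <- read_keypoint_csv(f)
  cl <- clean_track(tr)
  expect_equal(cl$u, tr$u)
  expect_equal(cl$v, tr$v)
  expect_equal(cl$segment, rep(1L, 10))
})

test_that("clean_track interpolates short gaps at the linear midpoint", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f, 0:2, c(10, 99, 20), c(5, 99, 9), c(1, 0.1, 1))
  cl <- clean_track(f |> read_keypoint_csv(), conf_min = 0.6, max_gap = 5)
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$u[2], 15)
  expect_equal(cl$v[2], 7)
})

test_that("long low-confidence stretches split the track into segments", {
  conf <- rep(1, 30); conf[11:20] <- 0.2
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f, 0:29, 1:30, 1:30, conf)
  cl <- clean_track(read_keypoint_csv(f), conf_min = 0.6, max_gap = 5)
  expect_equal(sort(unique(cl$segment)), c(1L, 2L))
  expect_equal(nrow(cl), 20L)            # nothing interpolated across the split
  expect_error(clean_track(read_keypoint_csv(f), conf_min = 1.1), "conf_min")

  conf_all_bad <- rep(0.1, 30)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pose_fixture(f2, 0:29, 1:30, 1:30, conf_all_bad)
  expect_error(clean_track(read_keypoint_csv(f2)), "empty track")
})

test_that("interpolation never leaves the segment between its anchors", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 20
    conf <- rep(1, n)
    conf[sample(2:(n - 1), 4)] <- 0.2
    u <- cumsum(runif(n, -3, 3)) + 50
    v <- cumsum(runif(n, -3, 3)) + 80
    f <- withr::local_tempfile(fileext = ".csv")
    write_pose_fixture(f, 0:(n - 1), u, v, conf)
    cl <- clean_track(read_keypoint_csv(f), conf_min = 0.6, max_gap = 5)
    good <- which(conf >= 0.6)
    for (i in seq_len(nrow(cl))) {
      fr <- cl$frame[i]
      if (fr %in% (good - 1)) next
      lo <- max(good[good - 1 < fr]); hi <- min(good[good - 1 > fr])
      expect_gte(cl$u[i], min(u[lo], u[hi]) - 1e-9)
      expect_lte(cl$u[i], max(u[lo], u[hi]) + 1e-9)
    }
  }
})

test_that("pixel-mm conversion applies the 0.62 factor and sign convention", {
  tr <- broilergait:::new_keypoint_track(
    tibble::tibble(frame = 0:2, t = (0:2) / 30,
                   u = c(100, 162, 100), v = c(300, 300, 269),
                   confidence = 1),
    bird_id = "b", fps = 30
  )
  mm <- pixels_to_mm(tr, px_per_mm = 0.62, origin_px = c(100, 300))
  expect_equal(mm$x, c(0, 100, 0))       # 62 px / 0.62 = 100 mm
  expect_equal(mm$y, c(0, 0, 50))        # v down by 31 px -> y up 50 mm
  expect_error(pixels_to_mm(tr, px_per_mm = 0), "px_per_mm")
})

test_that("pixel-mm conversion round-trips to numerical precision", {
  set.seed(3)
  tr <- broilergait:::new_keypoint_track(
    tibble::tibble(frame = 0:49, t = (0:49) / 30,
                   u = runif(50, 0, 900), v = runif(50, 0, 290),
                   confidence = 1),
    bird_id = "b", fps = 30
  )
  mm <- pixels_to_mm(tr, 0.62, c(10, 295))
  px <- mm_to_pixels(mm, 0.62, c(10, 295))
  expect_equal(px$u, tr$u, tolerance = 1e-9)
  expect_equal(px$v, tr$v, tolerance = 1e-9)
})

test_that("keypoint RMSE matches closed forms and is error-translation consistent", {
  p <- tibble::tibble(x = rnorm(40), y = rnorm(40))
  expect_equal(keypoint_rmse(p, p), 0)
  off <- p; off$x <- off$x + 5
  expect_equal(keypoint_rmse(off, p), 5)
  off2 <- p; off2$x <- off2$x + 3; off2$y <- off2$y - 4
  expect_equal(keypoint_rmse(off2, p), 5)   # 3-4-5 triangle
  expect_error(keypoint_rmse(p[1:10, ], p), "length")
})
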