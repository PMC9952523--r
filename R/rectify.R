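#' Rectify a top-view platform image
#'
#' Full geometric rectification: detect edges (Canny), find straight
#' lines (Hough transform), take the top-ranked near-horizontal line as
#' the platform's long side, rotate the image by `alpha = 90 - theta`
#' about the image centroid so bird movement runs horizontally, and crop
#' the platform region.  Lines implying a rotation of 45 degrees or more
#' are treated as the platform's short side and skipped.
#'
#' @param img Grayscale or RGB raster (RGB is reduced by luminance for
#'   detection; only the grayscale channel is rectified).
#' @param sigma,low,high Canny parameters, see [detect_edges()].
#' @param rho_res,theta_res Hough grid resolutions, see [hough_lines()].
#' @param top_k Number of Hough candidates to consider.
#' @param crop_box Optional fixed crop `c(xmin, ymin, xmax, ymax)`
#'   (0-based, half-open) applied to the rotated image; if `NULL`, the
#'   crop is derived automatically as the bounding box of
#'   above-Otsu-threshold pixels in the rotated image.
#' @return An object of class `rectification` (a list) with elements
#'   `alpha` (degrees), `center` (x0, y0), `crop_box`, `line` (the
#'   selected Hough line, one-row tibble), `rotated` (full rotated
#'   raster) and `rectified` (cropped raster).
#' @export
rectify_pipeline <- function(img, sigma = 2, low = 0.1, high = 0.3,
                             rho_res = 1, theta_res = 1, top_k = 10L,
                             crop_box = NULL) {
  gray <- as_grayscale(img)
  edges <- detect_edges(gray, sigma = sigma, low = low, high = high)
  lines <- hough_lines(edges, rho_res = rho_res, theta_res = theta_res,
                       top_k = top_k)
  lines <- lines[abs(90 - lines$theta) < 45, , drop = FALSE]
  if (nrow(lines) == 0L) {
    stop("platform edge not found", call. = FALSE)
  }
  line <- lines[1L, , drop = FALSE]
  alpha <- rotation_angle(line)
  center <- c((ncol(gray) - 1) / 2, (nrow(gray) - 1) / 2)
  rotated <- rotate_image(gray, alpha, center = center)
  if (is.null(crop_box)) {
    crop_box <- auto_crop_box(rotated)
  }
  rectified <- crop_platform(rotated, crop_box)
  structure(
    list(alpha = alpha, center = center, crop_box = crop_box,
         line = line, rotated = rotated, rectified = rectified),
    class = "rectification"
  )
}

#' @export
print.rectification <- function(x, ...) {
  cat(sprintf("<rectification> alpha = %.2f deg about (%.1f, %.1f)\n",
              x$alpha, x$center[1L], x$center[2L]))
  cat(sprintf("  crop box [%d, %d) x [%d, %d); rectified %d x %d px\n",
              x$crop_box[1L], x$crop_box[3L], x$crop_box[2L], x$crop_box[4L],
              ncol(x$rectified), nrow(x$rectified)))
  invisible(x)
}

# bounding box of above-Otsu pixels, 0-based half-open
auto_crop_box <- function(rotated) {
  thr <- otsu_threshold(rotated)
  idx <- which(rotated > thr)
  if (length(idx) == 0L) stop("auto-crop found no platform pixels", call. = FALSE)
  h <- nrow(rotated)
  x <- (idx - 1L) %/% h
  y <- (idx - 1L) %% h
  c(min(x), min(y), max(x) + 1L, max(y) + 1L)
}

# Otsu's threshold maximizing between-class variance on a 256-bin histogram
otsu_threshold <- function(img, breaks = 256L) {
  r <- range(img)
  if (r[1L] == r[2L]) return(r[1L])
  mids <- seq(r[1L], r[2L], length.out = breaks + 1L)
  mids <- (mids[-1L] + mids[-length(mids)]) / 2
  cnt <- tabulate(findInterval(img, seq(r[1L], r[2L], length.out = breaks + 1L),
                               all.inside = TRUE), nbins = breaks)
  w1 <- cumsum(cnt)
  mu <- cumsum(cnt * mids)
  mu_t <- mu[breaks]
  n <- w1[breaks]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bc <- numeric(breaks)
  bc[valid] <- (mu_t * w1[valid] - n * mu[valid])^2 / (w1[valid] * w2[valid])
  mids[which.max(bc)]
}

#' Write the sidecar record of a rectification
#'
#' Plain-text key: value record of the rotation angle, center and crop
#' box, next to a rectified image written as PNG.
#'
#' @param res A `rectification` object.
#' @param img_path Output PNG path for the rectified raster.
#' @param sidecar_path Output text path; defaults to `img_path` with a
#'   `.txt` extension.
#' @return `img_path`, invisibly.
#' @export
write_rectification <- function(res, img_path,
                                sidecar_path = sub("\\.png$", ".txt", img_path)) {
  write_raster_png(res$rectified, img_path)
  lines <- c(
    sprintf("alpha_deg: %.6f", res$alpha),
    sprintf("center_px: %.2f %.2f", res$center[1L], res$center[2L]),
    sprintf("crop_box: %d %d %d %d", res$crop_box[1L], res$crop_box[2L],
            res$crop_box[3L], res$crop_box[4L])
  )
  writeLines(lines, sidecar_path)
  invisible(img_path)
}
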