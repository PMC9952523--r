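#' Raster images
#'
#' A raster is a plain numeric matrix (grayscale or depth) or a
#' height x width x 3 array (RGB).  The origin is the top-left pixel;
#' pixel coordinates are 0-based, with `x` increasing rightwards along
#' columns and `y` increasing downwards along rows, so pixel `(x, y)`
#' lives at `m[y + 1, x + 1]`.  8-bit imagery is carried on the `[0, 1]`
#' scale used by [png::readPNG()]; depth rasters carry millimetres.
#'
#' @name raster
NULL

#' Convert an image to a single-channel luminance raster
#'
#' RGB arrays are reduced with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale matrices pass through.
#'
#' @param img A numeric matrix or an RGB array with 3 (or 4, alpha
#'   dropped) planes.
#' @return A numeric matrix.
#' @export
as_grayscale <- function(img) {
  if (is.matrix(img)) {
    return(img)
  }
  if (is.array(img) && length(dim(img)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    return(img[, , 1L] * w[1L] + img[, , 2L] * w[2L] + img[, , 3L] * w[3L])
  }
  stop("`img` must be a matrix or an RGB array", call. = FALSE)
}

raster_check <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  invisible(img)
}

#' Crop a raster to a half-open pixel window
#'
#' Returns the window `[xmin, xmax) x [ymin, ymax)` in 0-based pixel
#' coordinates, so the result is `(xmax - xmin)` pixels wide and
#' `(ymax - ymin)` pixels tall.
#'
#' @param img A raster (matrix or RGB array).
#' @param crop_box Numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @return The cropped raster.
#' @export
crop_platform <- function(img, crop_box) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  b <- as.numeric(crop_box)
  if (length(b) != 4L) stop("`crop_box` must be c(xmin, ymin, xmax, ymax)", call. = FALSE)
  names(b) <- c("xmin", "ymin", "xmax", "ymax")
  if (b["xmin"] >= b["xmax"]) stop("crop box has xmin >= xmax", call. = FALSE)
  if (b["ymin"] >= b["ymax"]) stop("crop box has ymin >= ymax", call. = FALSE)
  for (k in c("xmin", "ymin")) {
    if (b[k] < 0) stop(sprintf("crop box %s = %g is out of bounds", k, b[k]), call. = FALSE)
  }
  if (b["xmax"] > w) stop(sprintf("crop box xmax = %g exceeds image width %d", b["xmax"], w), call. = FALSE)
  if (b["ymax"] > h) stop(sprintf("crop box ymax = %g exceeds image height %d", b["ymax"], h), call. = FALSE)
  rows <- (b["ymin"] + 1L):b["ymax"]
  cols <- (b["xmin"] + 1L):b["xmax"]
  if (is.matrix(img)) img[rows, cols, drop = FALSE] else img[rows, cols, , drop = FALSE]
}

#' Rotate a raster about a center with black fill
#'
#' Rotates the image content by `alpha` degrees about `center` (default:
#' the image centroid), keeping the output dimensions identical to the
#' input and filling uncovered regions with black.  The rotation is the
#' affine map about the centroid used for platform rectification: a line
#' whose Hough normal angle is theta appears at theta + alpha afterwards,
#' so rotating by `alpha = 90 - theta` makes the platform's long side
#' horizontal.  Each output pixel is sampled from the source by the
#' inverse map with bilinear interpolation (or nearest-neighbour).
#'
#' @param img A grayscale raster (matrix).
#' @param alpha Rotation angle in degrees.
#' @param center Rotation center `c(x0, y0)` in 0-based pixel
#'   coordinates; defaults to the image centroid.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return A matrix with the same dimensions as `img`.
#' @export
rotate_image <- function(img, alpha, center = NULL,
                         interpolation = c("bilinear", "nearest")) {
  raster_check(img)
  if (!is.finite(alpha)) stop("`alpha` must be finite", call. = FALSE)
  interpolation <- match.arg(interpolation)
  h <- nrow(img); w <- ncol(img)
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  x0 <- center[1L]; y0 <- center[2L]
  if (x0 < 0 || x0 > w - 1 || y0 < 0 || y0 > h - 1) {
    stop("`center` must lie inside the image", call. = FALSE)
  }
  a <- alpha * pi / 180
  ca <- cos(a); sa <- sin(a)
  # inverse map: output (x, y) is sourced from R(-alpha) (p - c) + c
  xo <- rep(0:(w - 1), each = h) - x0
  yo <- rep(0:(h - 1), times = w) - y0
  xs <- ca * xo + sa * yo + x0
  ys <- -sa * xo + ca * yo + y0
  out <- numeric(h * w)
  if (interpolation == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
  } else {
    x1 <- floor(xs); y1 <- floor(ys)
    fx <- xs - x1; fy <- ys - y1
    ok <- x1 >= 0 & x1 <= w - 2 & y1 >= 0 & y1 <= h - 2
    # pixels whose 2x2 support sits on the last row/col but still inside
    edge <- !ok & xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
    if (any(ok)) {
      i1 <- cbind(y1[ok] + 1, x1[ok] + 1)
      v00 <- img[i1]
      v10 <- img[cbind(y1[ok] + 1, x1[ok] + 2)]
      v01 <- img[cbind(y1[ok] + 2, x1[ok] + 1)]
      v11 <- img[cbind(y1[ok] + 2, x1[ok] + 2)]
      fxk <- fx[ok]; fyk <- fy[ok]
      out[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v10) +
        fyk * ((1 - fxk) * v01 + fxk * v11)
    }
    if (any(edge)) {
      out[edge] <- img[cbind(round(ys[edge]) + 1, round(xs[edge]) + 1)]
    }
  }
  matrix(out, nrow = h, ncol = w)
}

#' Read and write 8-bit grayscale/RGB PNG rasters
#'
#' Thin wrappers over the png package keeping the `[0, 1]` intensity
#' scale and the top-left origin convention.
#'
#' @param path File path.
#' @rdname raster_png
#' @export
read_raster_png <- function(path) {
  png::readPNG(path)
}

#' @param img Raster to write (values clamped to `[0, 1]`).
#' @rdname raster_png
#' @export
write_raster_png <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Read and write 16-bit depth rasters (millimetre units)
#'
#' Depth frames are stored as 16-bit grayscale TIFF with pixel value =
#' depth in mm (losslessly, up to 65535 mm).  Zero marks an invalid
#' ("hole") pixel.
#'
#' @param path File path.
#' @return `read_depth_raster()` returns a numeric matrix of depths in mm.
#' @rdname raster_depth
#' @export
read_depth_raster <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}

#' @param depth Matrix of depths in mm (integers in `[0, 65535]`).
#' @rdname raster_depth
#' @export
write_depth_raster <- function(depth, path) {
  raster_check(depth, "depth")
  if (any(depth < 0 | depth > 65535)) {
    stop("depth values must be within [0, 65535] mm", call. = FALSE)
  }
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
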