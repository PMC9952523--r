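#' Canny edge detection
#'
#' Classic Canny detector: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding.  Thresholds are expressed as fractions of
#' the maximum gradient magnitude, so they are invariant to the image's
#' dynamic range.
#'
#' @param img Single-channel raster (convert color with
#'   [as_grayscale()] first).
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high Hysteresis thresholds as fractions of the peak
#'   gradient magnitude; `0 <= low < high`.
#' @return A binary matrix (0/1) of the same dimensions: 1 marks edge
#'   pixels that are local gradient-magnitude maxima surviving
#'   hysteresis.
#' @export
detect_edges <- function(img, sigma = 2, low = 0.1, high = 0.3) {
  raster_check(img)
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high) {
    stop("hysteresis thresholds need 0 <= low < high", call. = FALSE)
  }
  sm <- gaussian_blur(img, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  if (mmax == 0) {
    return(matrix(0, nrow(img), ncol(img)))
  }
  nms <- nonmax_suppress(mag, g$gx, g$gy)
  strong <- nms >= high * mmax
  weak <- nms >= low * mmax
  hysteresis_grow(strong, weak)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) {
    return(1)
  }
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with edge replication
convolve_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  padr <- img[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  tmp <- matrix(0, h, w)
  for (i in seq_along(k)) tmp <- tmp + k[i] * padr[i:(i + h - 1L), , drop = FALSE]
  padc <- tmp[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * padc[, i:(i + w - 1L), drop = FALSE]
  out
}

gaussian_blur <- function(img, sigma) {
  convolve_sep(img, gaussian_kernel_1d(sigma))
}

shift_mat <- function(m, dy, dx) {
  # shift with edge replication; positive dy moves content down
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

# nb(dy, dx): matrix of the neighbour values at (row + dy, col + dx)
neighbour_at <- function(m, dy, dx) shift_mat(m, -dy, -dx)

sobel_gradients <- function(img) {
  # gx: response to intensity increasing with x; gy: with y (downwards)
  nb <- function(dy, dx) neighbour_at(img, dy, dx)
  gx <- (nb(0, 1) - nb(0, -1)) * 2 + (nb(-1, 1) - nb(-1, -1)) + (nb(1, 1) - nb(1, -1))
  gy <- (nb(1, 0) - nb(-1, 0)) * 2 + (nb(1, -1) - nb(-1, -1)) + (nb(1, 1) - nb(-1, 1))
  list(gx = gx / 8, gy = gy / 8)
}

nonmax_suppress <- function(mag, gx, gy) {
  h <- nrow(mag); w <- ncol(mag)
  ang <- atan2(gy, gx)                       # (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)     # 0:E-W 1:SE-NW 2:N-S 3:SW-NE
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  s0 <- sector == 0; s1 <- sector == 1; s2 <- sector == 2; s3 <- sector == 3
  m <- function(dy, dx) neighbour_at(mag, dy, dx)
  e <- m(0, 1); wv <- m(0, -1); n <- m(-1, 0); s <- m(1, 0)
  ne <- m(-1, 1); sw <- m(1, -1); nw <- m(-1, -1); se <- m(1, 1)
  n1[s0] <- e[s0];  n2[s0] <- wv[s0]
  n1[s1] <- se[s1]; n2[s1] <- nw[s1]
  n1[s2] <- s[s2];  n2[s2] <- n[s2]
  n1[s3] <- sw[s3]; n2[s3] <- ne[s3]
  keep <- mag > n1 & mag >= n2 & mag > 0
  out <- matrix(0, h, w)
  out[keep] <- mag[keep]
  # border gradients come from replicated padding; drop them
  out[c(1L, h), ] <- 0
  out[, c(1L, w)] <- 0
  out
}

hysteresis_grow <- function(strong, weak) {
  cur <- strong & weak
  repeat {
    nb <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- nb | shift_pad_false(cur, dy, dx)
    }
    grown <- weak & nb
    if (identical(grown, cur)) break
    cur <- grown
  }
  mode(cur) <- "numeric"
  cur
}

shift_pad_false <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) - dy; cs <- seq_len(w) - dx
  rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= w
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}
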