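#' Hough line detection
#'
#' Detects straight lines in a binary edge map by voting in the polar
#' parameterization `rho = x*cos(theta) + y*sin(theta)`, with the image
#' top-left corner as origin, `x` along columns and `y` down rows
#' (0-based).  `theta` spans `[0, 180)` degrees so `rho` may be negative
#' for steep lines.
#'
#' @param edges Binary matrix (nonzero = edge pixel).
#' @param rho_res Radius resolution in pixels (> 0).
#' @param theta_res Angle resolution in degrees, in `(0, 5]`.
#' @param top_k Maximum number of lines to return.
#' @return A tibble with columns `rho` (px), `theta` (degrees) and
#'   `votes`, sorted by decreasing votes; ties broken by smaller theta,
#'   then smaller rho.  Fewer than `top_k` rows when the accumulator has
#'   fewer nonzero cells; zero rows for an empty edge map.
#' @export
hough_lines <- function(edges, rho_res = 1, theta_res = 1, top_k = 5L) {
  raster_check(edges, "edges")
  if (rho_res <= 0) stop("`rho_res` must be > 0", call. = FALSE)
  if (theta_res <= 0 || theta_res > 5) {
    stop("`theta_res` must be in (0, 5] degrees", call. = FALSE)
  }
  idx <- which(edges != 0)
  if (length(idx) == 0L) {
    return(tibble::tibble(rho = numeric(), theta = numeric(), votes = integer()))
  }
  h <- nrow(edges)
  x <- (idx - 1L) %/% h          # 0-based column
  y <- (idx - 1L) %% h           # 0-based row
  thetas <- seq(0, 180 - theta_res, by = theta_res)
  diag_len <- sqrt((h - 1)^2 + (ncol(edges) - 1)^2)
  nr <- floor(diag_len / rho_res) + 1L     # rho bin index range [-nr, nr]
  best <- vector("list", length(thetas))
  for (i in seq_along(thetas)) {
    th <- thetas[i] * pi / 180
    rbin <- round((x * cos(th) + y * sin(th)) / rho_res)
    tab <- tabulate(rbin + nr + 1L, nbins = 2L * nr + 1L)
    nz <- which(tab > 0L)
    best[[i]] <- tibble::tibble(
      rho = (nz - nr - 1L) * rho_res,
      theta = thetas[i],
      votes = tab[nz]
    )
  }
  acc <- dplyr::bind_rows(best)
  acc <- dplyr::arrange(acc, dplyr::desc(.data$votes), .data$theta, .data$rho)
  utils::head(acc, top_k)
}

#' Rotation angle from the platform's long-side line
#'
#' The signed rotation (degrees) that makes the detected long side
#' horizontal: `alpha = 90 - theta`.
#'
#' @param line A one-row data frame with a `theta` column (degrees), as
#'   returned by [hough_lines()], or a bare numeric theta.
#' @return Rotation angle alpha in degrees.
#' @export
rotation_angle <- function(line) {
  theta <- if (is.data.frame(line)) line$theta[[1L]] else as.numeric(line)[[1L]]
  90 - theta
}
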