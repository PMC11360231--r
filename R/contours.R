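#' Polygon area and centroid (shoelace)
#'
#' Contours are tibbles with `x`, `y` columns in um, vertices in order and
#' not repeated at closure. `polygon_area()` returns the unsigned area;
#' `polygon_centroid()` the area centroid.
#'
#' @param contour a tibble/data.frame with numeric `x`, `y` (um).
#' @return `polygon_area()`: scalar um^2; `polygon_centroid()`: length-2
#'   numeric `c(x, y)`.
#' @export
polygon_area <- function(contour) {
  xy <- check_contour(contour)
  abs(signed_area(xy$x, xy$y))
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(contour) {
  xy <- check_contour(contour)
  x <- xy$x; y <- xy$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

check_contour <- function(contour) {
  if (!is.data.frame(contour) || !all(c("x", "y") %in% names(contour))) {
    abort("A contour must be a data frame with `x` and `y` columns (um).")
  }
  if (nrow(contour) < 3L) {
    abort("A contour needs at least 3 vertices.")
  }
  x <- as.numeric(contour$x); y <- as.numeric(contour$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Contour coordinates must be finite.")
  }
  # drop a duplicated closing vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  list(x = x, y = y)
}

#' Resample a star-shaped contour at equal polar angles
#'
#' The tumor outlines handled by this package are star-shaped about their
#' centroid: every ray from the centroid crosses the boundary exactly once,
#' so the contour is a single-valued radius function r(theta). This is the
#' common parameterisation used for averaging replicate outlines,
#' interpolating geometry in time, and polar meshing.
#'
#' @param contour contour tibble (`x`, `y` in um).
#' @param n_theta number of equally spaced angles (default 180).
#' @return tibble with `theta` (radians, in `[0, 2*pi)`), `radius` (um),
#'   `x`, `y` (um, about the original centroid), and attribute `centroid`.
#' @export
resample_contour_polar <- function(contour, n_theta = 180L) {
  xy <- check_contour(contour)
  ctr <- polygon_centroid(contour)
  x <- xy$x - ctr[1]; y <- xy$y - ctr[2]
  # orient counter-clockwise
  if (signed_area(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  ang <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  if (any(r <= 0)) abort("Contour passes through its centroid; not star-shaped.")
  d <- diff(c(ang, ang[1]))
  d <- ((d + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
  if (any(d <= 0) || abs(sum(d) - 2 * pi) > 1e-9) {
    abort(paste("Contour is not star-shaped about its centroid:",
                "radius is multivalued at some angle."))
  }
  # unwrap to a strictly increasing angle sequence, then periodic linear interp
  ang_un <- ang[1] + cumsum(c(0, d[-length(d)]))
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  radius <- periodic_interp(ang_un, r, theta)
  tibble(
    theta = theta, radius = radius,
    x = ctr[1] + radius * cos(theta),
    y = ctr[2] + radius * sin(theta)
  ) |>
    structure(centroid = ctr)
}

# linear interpolation of a 2*pi-periodic function given at increasing xs
periodic_interp <- function(xs, ys, xq) {
  x0 <- xs[1]
  xs <- xs - x0
  xq <- (xq - x0) %% (2 * pi)
  xs_ext <- c(xs, xs[1] + 2 * pi)
  ys_ext <- c(ys, ys[1])
  approx(xs_ext, ys_ext, xout = xq %% (2 * pi), rule = 2)$y
}

#' Average replicate tumor contours
#'
#' Aligns each contour's centroid at the origin, resamples every contour at
#' `n_theta` equal polar angles, and returns the polygon whose radius at each
#' angle is the mean over contours. This is how replicate section outlines at
#' one time point are combined into one representative geometry.
#'
#' @param contours a list of contour tibbles (each `x`, `y` in um).
#' @param n_theta number of polar samples for the output (default 180).
#' @return a contour tibble (`x`, `y`) centred at the origin.
#' @examples
#' circ <- function(r) tibble::tibble(
#'   x = r * cos(seq(0, 2 * pi, length.out = 73)[-73]),
#'   y = r * sin(seq(0, 2 * pi, length.out = 73)[-73]))
#' avg <- average_contours(list(circ(40), circ(60)))
#' sqrt(polygon_area(avg) / pi) # ~50
#' @export
average_contours <- function(contours, n_theta = 180L) {
  if (!is.list(contours) || length(contours) < 1L || is.data.frame(contours)) {
    abort("`contours` must be a non-empty list of contour tibbles.")
  }
  rad <- purrr::map(contours, function(ct) {
    resample_contour_polar(ct, n_theta = n_theta)$radius
  })
  radius <- purrr::reduce(rad, `+`) / length(rad)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  tibble(x = radius * cos(theta), y = radius * sin(theta))
}

#' Linearly interpolate between two contours
#'
#' Geometry between observation times is interpolated linearly in shape and
#' size: both contours are resampled at matching polar angles and the radius
#' at each angle (and the centroid) is mixed as `(1 - alpha) * A + alpha * B`.
#'
#' @param contour_a,contour_b star-shaped contour tibbles.
#' @param alpha interpolation weight in `[0, 1]`; 0 returns `contour_a`'s
#'   polar resampling, 1 returns `contour_b`'s.
#' @param n_theta number of polar samples (default: vertex count of
#'   `contour_a`).
#' @return a contour tibble (`x`, `y` in um).
#' @export
interpolate_contours <- function(contour_a, contour_b, alpha,
                                 n_theta = nrow(contour_a)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1].")
  }
  pa <- resample_contour_polar(contour_a, n_theta = n_theta)
  pb <- resample_contour_polar(contour_b, n_theta = n_theta)
  ca <- attr(pa, "centroid"); cb <- attr(pb, "centroid")
  radius <- (1 - alpha) * pa$radius + alpha * pb$radius
  ctr <- (1 - alpha) * ca + alpha * cb
  tibble(
    x = ctr[1] + radius * cos(pa$theta),
    y = ctr[2] + radius * sin(pa$theta)
  )
}
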