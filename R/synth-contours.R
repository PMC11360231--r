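#' Generate a seeded series of growing tumor contours
#'
#' Emulates the averaged section outlines of a growing flank tumor: a
#' star-shaped base shape r(theta) = R (1 + irregularity * s(theta)) with
#' smooth low-order Fourier noise s, elliptically stretched to the requested
#' axis ratio, then scaled over time so the cross-section area tracks the
#' growth model as `area ~ volume^(2/3)` (a medial slice of a scaling solid).
#' The shape is held fixed over time; only size changes, which matches the
#' linear shape/size interpolation used downstream.
#'
#' @param seed integer seed; identical seeds give identical output.
#' @param times observation days (default days 7, 10, 13, 16, i.e. roughly
#'   15/25/60/80% of final growth under the default [growth_model()]).
#' @param base_radius radius scale of the first contour (um); default 3000 um,
#'   a realistic medial-slice radius for a 100-300 mm^3 flank tumor.
#' @param eccentricity target fitted-ellipse axis ratio (>= 1); applied as an
#'   area-preserving stretch.
#' @param irregularity radial roughness amplitude in `[0, 1)`.
#' @param growth a [growth_model()] used to scale areas over time.
#' @param n_theta vertices per contour (default 180).
#' @param area_scaling `"growth"` (default) scales areas as V(t)^(2/3);
#'   `"none"` keeps all contours at `base_radius` scale. Exposed because
#'   replicate outlines can be normalised either way before averaging.
#' @return a tibble with columns `time_day`, `vertex`, `x`, `y` (um).
#' @examples
#' cs <- gen_contour_series(seed = 1, eccentricity = 1, irregularity = 0)
#' head(cs)
#' @export
gen_contour_series <- function(seed,
                               times = c(7, 10, 13, 16),
                               base_radius = 3000,
                               eccentricity = 1.3,
                               irregularity = 0.15,
                               growth = growth_model(),
                               n_theta = 180L,
                               area_scaling = c("growth", "none")) {
  area_scaling <- match.arg(area_scaling)
  if (!is.numeric(base_radius) || base_radius <= 0) {
    abort("`base_radius` must be positive (um).")
  }
  if (!is.numeric(eccentricity) || eccentricity < 1) {
    abort("`eccentricity` must be >= 1 (axis ratio).")
  }
  if (!is.numeric(irregularity) || irregularity < 0 || irregularity >= 1) {
    abort("`irregularity` must be in [0, 1): larger values can fold the contour.")
  }
  if (length(times) < 1L || any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing days.")
  }
  stopifnot(inherits(growth, "growth_model"))
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta

  shape <- withr::with_seed(seed, {
    if (irregularity > 0) {
      k <- 2:5
      amp <- stats::runif(length(k))
      phs <- stats::runif(length(k), 0, 2 * pi)
      s <- colSums(amp * sin(outer(k, theta) + phs))
      s <- s / max(abs(s))
    } else {
      s <- rep(0, n_theta)
    }
    1 + irregularity * s
  })

  # area-preserving elliptic stretch
  ax <- sqrt(eccentricity); ay <- 1 / sqrt(eccentricity)
  bx <- shape * cos(theta) * ax
  by <- shape * sin(theta) * ay

  vols <- growth_volume(times, growth)
  scale_t <- if (area_scaling == "growth") {
    (vols / vols[1])^(1 / 3)  # sqrt of the area ratio (vols ratio)^(2/3)
  } else {
    rep(1, length(times))
  }

  purrr::map2_dfr(times, scale_t, function(tt, sc) {
    r <- base_radius * sc
    tibble(
      time_day = tt,
      vertex = seq_len(n_theta),
      x = r * bx,
      y = r * by
    )
  })
}

#' Split a contour-series tibble into a list of contours
#'
#' @param series tibble from [gen_contour_series()] or read from CSV
#'   (`time_day`, `x`, `y`).
#' @return named list of contour tibbles, names are the times.
#' @export
contour_series_split <- function(series) {
  if (!all(c("time_day", "x", "y") %in% names(series))) {
    abort("`series` needs columns time_day, x, y.")
  }
  out <- split(series[c("x", "y")], series$time_day)
  lapply(out, as_tibble)
}
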