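#' Field specification for synthetic heatmaps
#'
#' Describes the three per-cell fields of a gridded tumor heatmap —
#' vasculature coverage (%), mean capillary diameter (um) and perfused /
#' cell-covered area (%) — as a smooth base surface plus independent
#' cell-level Gaussian noise. The base surface is linear across the tumor
#' bounding box: `base + trend[1] * xn + trend[2] * yn` with `xn`, `yn` the
#' cell-centre coordinates normalised to `[-1, 1]`. A nonzero trend is how
#' anisotropic vascularisation is emulated.
#'
#' Defaults are typical of the murine flank-tumor sections this package
#' models: a few percent vasculature coverage, ~5 um capillaries, and
#' ~75% perfused/cell-covered area.
#'
#' @param vasculature_base,vasculature_sd,vasculature_trend base (%), noise
#'   s.d. (%) and linear trend (% per normalised coordinate) of vasculature
#'   coverage.
#' @param diameter_base,diameter_sd,diameter_trend same for capillary
#'   diameter (um).
#' @param perfusion_base,perfusion_sd,perfusion_trend same for perfusion
#'   coverage (%).
#' @return a `heatmap_field_spec` list.
#' @export
heatmap_field_spec <- function(vasculature_base = 4, vasculature_sd = 1,
                               vasculature_trend = c(0, 0),
                               diameter_base = 5, diameter_sd = 0.5,
                               diameter_trend = c(0, 0),
                               perfusion_base = 75, perfusion_sd = 5,
                               perfusion_trend = c(0, 0)) {
  spec <- list(
    vasculature = list(base = vasculature_base, sd = vasculature_sd,
                       trend = vasculature_trend, range = c(0, 100)),
    diameter = list(base = diameter_base, sd = diameter_sd,
                    trend = diameter_trend, range = c(0.5, Inf)),
    perfusion = list(base = perfusion_base, sd = perfusion_sd,
                     trend = perfusion_trend, range = c(0, 100))
  )
  for (f in spec) {
    if (f$sd < 0) abort("Field noise s.d. must be >= 0.")
    if (length(f$trend) != 2L) abort("Field trends must have two components (x, y).")
  }
  structure(spec, class = "heatmap_field_spec")
}

#' Generate a synthetic gridded heatmap over a tumor contour
#'
#' Lays a `grid_shape` grid over the contour's bounding box and draws the
#' three heatmap fields from a [heatmap_field_spec()]: smooth base surface
#' plus seeded cell-level noise, clipped to each field's physical range.
#' Cells whose centre falls outside the contour are flagged `masked` and get
#' `NA` values, mirroring what an imaging pipeline reports outside tissue.
#'
#' @param contour tumor contour tibble (`x`, `y` in um).
#' @param grid_shape integer `c(rows, cols)`, each >= 2 (default 9 x 9, the
#'   grid used for whole-section quantification).
#' @param field_spec a [heatmap_field_spec()].
#' @param seed integer seed; same seed, same heatmap.
#' @return a heatmap tibble: `row`, `col`, `x_um`, `y_um` (cell centres),
#'   `vasculature_pct`, `diameter_um`, `perfusion_pct`, `masked`.
#' @examples
#' ct <- contour_series_split(gen_contour_series(seed = 1))[[1]]
#' hm <- gen_heatmaps(ct, seed = 1)
#' dplyr::filter(hm, !masked)
#' @export
gen_heatmaps <- function(contour, grid_shape = c(9L, 9L),
                         field_spec = heatmap_field_spec(), seed = 1L) {
  stopifnot(inherits(field_spec, "heatmap_field_spec"))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 2L)) {
    abort("`grid_shape` must be c(rows, cols) with both >= 2.")
  }
  xy <- check_contour(contour)
  bbox <- c(range(xy$x), range(xy$y))  # xmin xmax ymin ymax
  grid <- grid_centres(bbox, grid_shape)
  inside <- point_in_polygon(grid$x_um, grid$y_um, contour)

  xn <- norm_unit(grid$x_um, bbox[1], bbox[2])
  yn <- norm_unit(grid$y_um, bbox[3], bbox[4])
  n <- nrow(grid)

  vals <- withr::with_seed(seed, {
    purrr::map(field_spec, function(f) {
      v <- f$base + f$trend[1] * xn + f$trend[2] * yn +
        stats::rnorm(n, sd = f$sd)
      pmin(pmax(v, f$range[1]), f$range[2])
    })
  })

  out <- grid
  out$vasculature_pct <- ifelse(inside, vals$vasculature, NA_real_)
  out$diameter_um <- ifelse(inside, vals$diameter, NA_real_)
  out$perfusion_pct <- ifelse(inside, vals$perfusion, NA_real_)
  out$masked <- !inside
  out
}

# cell centres of an nrow x ncol grid over a bounding box
grid_centres <- function(bbox, grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  cw <- (bbox[2] - bbox[1]) / nc
  ch <- (bbox[4] - bbox[3]) / nr
  g <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  g$x_um <- bbox[1] + (g$col - 0.5) * cw
  g$y_um <- bbox[3] + (g$row - 0.5) * ch
  g
}

norm_unit <- function(v, lo, hi) {
  if (hi == lo) return(rep(0, length(v)))
  2 * (v - lo) / (hi - lo) - 1
}

#' Point-in-polygon test
#'
#' Even-odd ray-crossing rule; used to mask grid cells and mesh nodes by the
#' tumor contour. Points exactly on an edge may fall on either side.
#'
#' @param px,py query coordinates (um).
#' @param contour contour tibble.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, contour) {
  xy <- check_contour(contour)
  x <- xy$x; y <- xy$y
  n <- length(x)
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yj[i] > py)) &
      (px < (xj[i] - x[i]) * (py - y[i]) / (yj[i] - y[i]) + x[i])
    inside <- xor(inside, crosses)
  }
  inside
}
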