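#' Threshold a fluorescence channel
#'
#' Over/under thresholding of a single channel: a pixel is positive when its
#' intensity exceeds a fixed fraction of the full-scale intensity (default
#' interpretation of an over/under display threshold with a "minimum below"
#' setting, e.g. 0.79 for the perfusion stain and 0.95 for the vascular
#' stain). `mode = "percentile"` instead thresholds at the given quantile of
#' the image's own intensity histogram; both are provided because threshold
#' settings quoted as percentages are ambiguous between the two readings.
#'
#' @param channel numeric intensity matrix.
#' @param fraction threshold in `[0, 1]`.
#' @param mode `"fraction"` (of `full_scale`) or `"percentile"` (of the
#'   intensity histogram).
#' @param full_scale full-scale intensity (1 for normalised images, 255 for
#'   8-bit).
#' @return logical matrix, `TRUE` = positively stained.
#' @examples
#' m <- matrix(c(0, 0.5, 1, 1), 2, 2)
#' threshold_channel(m, 0.79)
#' @export
threshold_channel <- function(channel, fraction,
                              mode = c("fraction", "percentile"),
                              full_scale = 1) {
  mode <- match.arg(mode)
  if (!is.matrix(channel) || length(channel) == 0L) {
    abort("`channel` must be a non-empty numeric matrix.")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single value in [0, 1].")
  }
  cutoff <- switch(mode,
    fraction = fraction * full_scale,
    percentile = stats::quantile(channel, probs = fraction, names = FALSE)
  )
  channel > cutoff
}

#' Per-cell coverage of a binary mask
#'
#' Overlays a `grid_shape` grid on the image frame and reports, per grid
#' cell, 100 x (positive pixels) / (total pixels in the cell).
#'
#' @param mask logical matrix from [threshold_channel()].
#' @param grid_shape integer `c(rows, cols)`.
#' @return tibble `row`, `col`, `coverage_pct`.
#' @export
grid_coverage <- function(mask, grid_shape = c(9L, 9L)) {
  if (!is.matrix(mask)) abort("`mask` must be a logical matrix.")
  mask_grid_coverage(mask, grid_shape)
}

#' Mean capillary diameter per grid cell
#'
#' Emulates the manual protocol of sampling a handful of stained capillaries
#' per grid cell and averaging their diameters, but measures width
#' automatically: connected components of the vessel mask are assigned to
#' cells by centroid, up to `n_samples` components per cell are drawn
#' uniformly at random (seeded), and each component's width is read off the
#' Euclidean distance transform along its medial ridge
#' (width = (2 x median ridge distance - 0.5) x pixel size; the half-pixel
#' corrects the centre-vs-edge bias of the transform). Cells without any
#' component get `NA` — a valid "no vessel sampled" outcome.
#'
#' @param mask logical vessel mask.
#' @param grid_shape integer `c(rows, cols)`.
#' @param n_samples components sampled per cell (default 6).
#' @param pixel_size_um physical pixel size (um/px).
#' @param seed integer seed for the per-cell sampling.
#' @return tibble `row`, `col`, `diameter_um`, `n_vessels`.
#' @export
measure_capillary_diameters <- function(mask, grid_shape = c(9L, 9L),
                                        n_samples = 6L, pixel_size_um = 1,
                                        seed = 1L) {
  if (!is.matrix(mask)) abort("`mask` must be a logical matrix.")
  if (n_samples < 1L) abort("`n_samples` must be >= 1.")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  cells <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))

  storage.mode(mask) <- "double"
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0L) {
    cells$diameter_um <- NA_real_
    cells$n_vessels <- 0L
    return(cells)
  }
  dm <- EBImage::distmap(mask)
  ridge <- ridge_mask(dm)

  ny <- nrow(mask); nx <- ncol(mask)
  labv <- as.integer(lab)
  on <- which(labv > 0L)
  comp <- labv[on]
  py <- (on - 1L) %% ny + 1L
  px <- (on - 1L) %/% ny + 1L

  # per-component width from ridge distances (fallback: component max)
  dmv <- as.numeric(dm)[on]
  rv <- as.logical(ridge)[on]
  width_of <- vapply(seq_len(nlab), function(k) {
    sel <- comp == k
    dsel <- if (any(rv & sel)) dmv[rv & sel] else max(dmv[sel])
    (2 * median(dsel) - 0.5) * pixel_size_um
  }, numeric(1))

  # assign components to grid cells by centroid
  cy <- tapply(py, comp, mean); cx <- tapply(px, comp, mean)
  crow <- pmin(nr, 1L + floor((cy - 0.5) * nr / ny))
  ccol <- pmin(nc, 1L + floor((cx - 0.5) * nc / nx))
  comp_cell <- as.integer(crow) + nr * (as.integer(ccol) - 1L)

  means <- withr::with_seed(seed, {
    vapply(seq_len(nr * nc), function(cell) {
      ks <- which(comp_cell == cell)
      if (length(ks) == 0L) return(c(NA_real_, 0))
      if (length(ks) > n_samples) ks <- sample(ks, n_samples)
      c(mean(width_of[ks]), length(ks))
    }, numeric(2))
  })
  cellidx <- cells$row + nr * (cells$col - 1L)
  cells$diameter_um <- means[1, cellidx]
  cells$n_vessels <- as.integer(means[2, cellidx])
  cells
}

# medial ridge: foreground pixels whose distance value is a local maximum
# over their 8-neighbourhood
ridge_mask <- function(dm) {
  ny <- nrow(dm); nx <- ncol(dm)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- dm
  nb <- matrix(-Inf, ny, nx)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pmax(nb, pad[(2:(ny + 1L)) + di, (2:(nx + 1L)) + dj])
  }
  dm > 0 & dm >= nb - 1e-9
}

#' Build the three heatmaps from a two-channel image
#'
#' Composes [threshold_channel()], [grid_coverage()] and
#' [measure_capillary_diameters()]: the vascular channel yields vasculature
#' coverage and capillary diameter, the perfusion channel yields perfusion
#' coverage. When a tumor `contour` is supplied, cells whose centre lies
#' outside it are flagged `masked` (values kept as measured); otherwise the
#' whole frame is in-tumor.
#'
#' @param image a `synthetic_if_image`, or a named list with `channels`
#'   (list of `vascular`, `perfusion` matrices) and `pixel_size_um`.
#' @param grid_shape integer `c(rows, cols)` (default 9 x 9).
#' @param thresholds named fractions, default
#'   `c(vascular = 0.95, perfusion = 0.79)`.
#' @param contour optional tumor contour (um, image frame: x right, y down
#'   from the top-left pixel corner).
#' @param n_samples capillaries sampled per cell for diameters.
#' @param seed integer seed (diameter sampling).
#' @param threshold_mode passed to [threshold_channel()].
#' @return heatmap tibble: `row`, `col`, `x_um`, `y_um`,
#'   `vasculature_pct`, `diameter_um`, `perfusion_pct`, `masked` — the
#'   interchange table consumed by [nodal_params_from_heatmaps()].
#' @examples
#' img <- gen_fluorescence_image(n_vessels = 8, dim_px = c(180, 180), seed = 2)
#' hm <- build_heatmaps(img, grid_shape = c(3, 3))
#' @export
build_heatmaps <- function(image, grid_shape = c(9L, 9L),
                           thresholds = c(vascular = 0.95, perfusion = 0.79),
                           contour = NULL, n_samples = 6L, seed = 1L,
                           threshold_mode = "fraction") {
  ch <- image$channels
  if (is.null(ch$vascular) || is.null(ch$perfusion)) {
    abort("`image` must carry `channels$vascular` and `channels$perfusion`.")
  }
  px <- image$pixel_size_um %||% 1
  vmask <- threshold_channel(ch$vascular, thresholds[["vascular"]],
                             mode = threshold_mode)
  pmask <- threshold_channel(ch$perfusion, thresholds[["perfusion"]],
                             mode = threshold_mode)

  vas <- grid_coverage(vmask, grid_shape) |>
    dplyr::rename(vasculature_pct = "coverage_pct")
  per <- grid_coverage(pmask, grid_shape) |>
    dplyr::rename(perfusion_pct = "coverage_pct")
  dia <- measure_capillary_diameters(vmask, grid_shape, n_samples = n_samples,
                                     pixel_size_um = px, seed = seed)

  ny <- nrow(ch$vascular); nx <- ncol(ch$vascular)
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  out <- vas |>
    dplyr::left_join(per, by = c("row", "col")) |>
    dplyr::left_join(dia[, c("row", "col", "diameter_um")],
                     by = c("row", "col"))
  out$x_um <- (out$col - 0.5) * nx * px / nc
  out$y_um <- (out$row - 0.5) * ny * px / nr
  out$masked <- if (is.null(contour)) FALSE else
    !point_in_polygon(out$x_um, out$y_um, contour)
  out[, c("row", "col", "x_um", "y_um", "vasculature_pct", "diameter_um",
          "perfusion_pct", "masked")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
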