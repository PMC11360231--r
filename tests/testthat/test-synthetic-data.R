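test_that("caliper volume follows V = D d^2 / 2 and validates axes", {
  expect_equal(tumor_volume_caliper(10, 10), 500)
  expect_equal(tumor_volume_caliper(12, 8), 384)
  expect_equal(tumor_volume_caliper(0, 0), 0)
  expect_error(tumor_volume_caliper(8, 12), "swapped")
  expect_error(tumor_volume_caliper(-1, -2), "non-negative")
})

test_that("growth model is exponential and monotone", {
  m <- growth_model(v0 = 60, rate = 0.2)
  expect_equal(growth_volume(0, m), 60)
  flat <- growth_model(v0 = 42, rate = 0)
  expect_equal(growth_volume(c(0, 3, 11), flat), rep(42, 3))
  v <- growth_volume(seq(0, 20, by = 0.5), m)
  expect_true(all(diff(v) > 0))
  # default coefficients reproduce the day-7 and day-16 volumes of the fit
  expect_equal(growth_volume(7), 59.98 * exp(0.1874 * 7))
  expect_error(growth_model(v0 = -1), "positive")
  expect_error(growth_volume(-2), "non-negative")
})

test_that("contour generator is deterministic and respects the growth law", {
  a <- gen_contour_series(seed = 11)
  b <- gen_contour_series(seed = 11)
  expect_identical(a, b)
  d <- gen_contour_series(seed = 12)
  expect_false(identical(a, d))

  contours <- contour_series_split(a)
  areas <- vapply(contours, polygon_area, numeric(1))
  vols <- growth_volume(c(7, 10, 13, 16))
  ratio <- areas / areas[1]
  expect_equal(ratio, (vols / vols[1])^(2 / 3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("degenerate generator settings give circles of the requested radii", {
  cs <- gen_contour_series(seed = 1, eccentricity = 1, irregularity = 0,
                           base_radius = 500, times = c(0, 1),
                           growth = growth_model(rate = 0))
  for (ct in contour_series_split(cs)) {
    r <- sqrt(ct$x^2 + ct$y^2)
    expect_equal(r, rep(500, nrow(ct)), tolerance = 1e-12)
  }
})

test_that("eccentric contours have the requested fitted-ellipse axis ratio", {
  cs <- contour_series_split(
    gen_contour_series(seed = 5, eccentricity = 2, irregularity = 0.1))[[1]]
  # independent oracle: second moments of the polygon vertex cloud
  xc <- cs$x - mean(cs$x); yc <- cs$y - mean(cs$y)
  S <- cov(cbind(xc, yc))
  axis_ratio <- sqrt(max(eigen(S)$values) / min(eigen(S)$values))
  expect_gt(axis_ratio, 2 * 0.9)
  expect_lt(axis_ratio, 2 * 1.1)
})

test_that("generator rejects parameters outside the star-shaped regime", {
  expect_error(gen_contour_series(seed = 1, irregularity = 1), "\\[0, 1\\)")
  expect_error(gen_contour_series(seed = 1, base_radius = -5), "positive")
  expect_error(gen_contour_series(seed = 1, times = c(3, 2)), "increasing")
})

test_that("noise-free heatmaps reproduce the constant field spec exactly", {
  ct <- circle_contour(200)
  hm <- gen_heatmaps(ct, field_spec = heatmap_field_spec(
    vasculature_base = 4, vasculature_sd = 0,
    diameter_base = 5, diameter_sd = 0,
    perfusion_base = 75, perfusion_sd = 0), seed = 3)
  inside <- !hm$masked
  expect_true(any(inside))
  expect_equal(unique(hm$vasculature_pct[inside]), 4)
  expect_equal(unique(hm$diameter_um[inside]), 5)
  expect_equal(unique(hm$perfusion_pct[inside]), 75)
  expect_true(all(is.na(hm$vasculature_pct[!inside])))
})

test_that("heatmap masking follows the contour and grids must be >= 2x2", {
  ct <- circle_contour(100)
  hm <- gen_heatmaps(ct, grid_shape = c(9, 9), seed = 1)
  # corner cells of a circle's bounding box lie outside the disc
  corner <- hm[hm$row == 1 & hm$col == 1, ]
  expect_true(corner$masked)
  centre <- hm[hm$row == 5 & hm$col == 5, ]
  expect_false(centre$masked)
  expect_error(gen_heatmaps(ct, grid_shape = c(1, 9)), ">= 2")
})

test_that("heatmap cell noise matches the requested s.d.", {
  ct <- circle_contour(300)
  sds <- vapply(1:12, function(s) {
    hm <- gen_heatmaps(ct, field_spec = heatmap_field_spec(
      perfusion_base = 50, perfusion_sd = 5), seed = s)
    sd(hm$perfusion_pct[!hm$masked])
  }, numeric(1))
  expect_gt(mean(sds), 5 * 0.7)
  expect_lt(mean(sds), 5 * 1.3)
})

test_that("pseudo-IF truth equals the exact rasterised pixel count", {
  # one 8-px band across a 100 x 100 frame: 8% coverage in a 1x1 grid
  v <- tibble::tibble(x0 = 0, y0 = 50, x1 = 100, y1 = 50, width_um = 8)
  img <- gen_fluorescence_image(vessels = v, dim_px = c(100, 100),
                                grid_shape = c(1, 1), halo_radius_um = 10,
                                seed = 1)
  expect_equal(img$truth$vascular_truth_pct, 8)
  # truth equals direct pixel count of the rendered channel
  rendered <- img$channels$vascular > 0.5
  expect_equal(img$truth$vascular_truth_pct, 100 * sum(rendered) / 1e4)

  # random scene: per-cell truth equals the rendered mask's per-cell count
  img2 <- gen_fluorescence_image(n_vessels = 15, dim_px = c(270, 270),
                                 grid_shape = c(3, 3), seed = 9)
  m <- img2$channels$perfusion > 0.5
  counts <- sapply(1:3, function(r) sapply(1:3, function(c) {
    100 * sum(m[(r - 1) * 90 + 1:90, (c - 1) * 90 + 1:90]) / 8100
  }))
  truth <- matrix(img2$truth$perfusion_truth_pct, 3, 3, byrow = TRUE)
  expect_equal(truth, t(counts), ignore_attr = TRUE)
})

test_that("empty scenes and invalid widths are handled", {
  v0 <- tibble::tibble(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                       y1 = numeric(0), width_um = numeric(0))
  img <- gen_fluorescence_image(vessels = v0, dim_px = c(50, 50), seed = 1)
  expect_equal(sum(img$truth$vascular_truth_pct), 0)
  expect_equal(sum(img$truth$perfusion_truth_pct), 0)
  thin <- tibble::tibble(x0 = 0, y0 = 10, x1 = 50, y1 = 10, width_um = 1)
  expect_error(gen_fluorescence_image(vessels = thin, pixel_size_um = 1),
               "2 px")
})

test_that("generators are pure functions of spec and seed", {
  a <- gen_fluorescence_image(n_vessels = 5, dim_px = c(80, 80), seed = 4)
  b <- gen_fluorescence_image(n_vessels = 5, dim_px = c(80, 80), seed = 4)
  expect_identical(a$channels, b$channels)
  h1 <- gen_heatmaps(circle_contour(100), seed = 2)
  h2 <- gen_heatmaps(circle_contour(100), seed = 2)
  expect_identical(h1, h2)
})
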