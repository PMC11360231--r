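uniform_spec <- heatmap_field_spec(vasculature_sd = 0, diameter_sd = 0,
                                   perfusion_sd = 0)

disc_config <- function(radii, times, substeps = 3L, n_rings = 10L,
                        n_sectors = 20L) {
  contours <- lapply(radii, circle_contour, n = 181L)
  hms <- lapply(contours, gen_heatmaps, field_spec = uniform_spec, seed = 1)
  timecourse_config(contours, hms, times = times, substeps = substeps,
                    n_rings = n_rings, n_sectors = n_sectors)
}

test_that("constant knots give constant fields over time", {
  cfg <- disc_config(c(120, 120), times = c(7, 16), substeps = 3)
  tc <- run_timecourse(cfg)
  s <- tc$summary
  expect_equal(s$mean_p_ex_pa, rep(s$mean_p_ex_pa[1], nrow(s)),
               tolerance = 1e-9)
  expect_equal(s$mean_speed_ex, rep(s$mean_speed_ex[1], nrow(s)),
               tolerance = 1e-9)
  expect_equal(s$area_um2, rep(s$area_um2[1], nrow(s)), tolerance = 1e-9)
})

test_that("growing uniform disc: mean pressure rises, mean speed falls", {
  # radii follow the growth model's V^(1/3) scaling from a 300 um slice;
  # the tumors sit in the boundary-layer regime R >> lambda (~56 um)
  radii <- round(300 * exp(0.1874 * (c(7, 10, 13, 16) - 7) / 3))
  cfg <- disc_config(radii, times = c(7, 10, 13, 16), n_rings = 14L,
                     n_sectors = 28L)
  tc <- run_timecourse(cfg)
  s <- tc$summary
  expect_true(all(diff(s$mean_p_ex_pa) > 0))
  expect_true(all(diff(s$mean_speed_ex) < 0))
  expect_true(all(diff(s$day) > 0))
  expect_true(all(s$relative_imbalance < 1e-8))

  # independent closed-form check: the analytic mean disc pressure shows
  # the same rising trend, and the FE knots track it
  lam <- bench_lambda()
  analytic_means <- disc_mean_pressure_analytic(radii, lam, bench_pc())
  expect_true(all(diff(analytic_means) > 0))
  knots <- s$mean_p_ex_pa[match(c(7, 10, 13, 16), s$day)]
  expect_equal(knots / analytic_means, rep(1, 4), tolerance = 0.02)
})

test_that("the time course is deterministic given its config", {
  cfg <- disc_config(c(90, 140), times = c(7, 16), substeps = 2)
  t1 <- run_timecourse(cfg)
  t2 <- run_timecourse(cfg)
  expect_identical(t1$summary, t2$summary)
})

test_that("knot validation rejects unsorted times and mismatched lengths", {
  ct <- circle_contour(100)
  hm <- gen_heatmaps(ct, field_spec = uniform_spec, seed = 1)
  expect_error(timecourse_config(list(ct, ct), list(hm, hm), times = c(9, 7)),
               "increasing")
  expect_error(timecourse_config(list(ct), list(hm, hm), times = c(7, 9)),
               "One contour per knot")
  expect_error(timecourse_config(list(ct, ct), list(hm), times = c(7, 9)),
               "One heatmap per knot")
})

test_that("centreline pressure peaks centrally, speed peaks at the boundary", {
  cfg <- disc_config(c(100, 150), times = c(7, 16), substeps = 2,
                     n_rings = 16L, n_sectors = 32L)
  tc <- run_timecourse(cfg)
  for (ax in c("x", "y")) {
    pr <- centerline_profile(tc, axis = ax, what = "pressure", n = 81L)
    # symmetric about the centre within 1%
    expect_lt(max(abs(pr$value - rev(pr$value))) / max(pr$value), 0.01)
    # maximal at the centre, ~zero at both ends
    expect_equal(which.max(pr$value), 41L, tolerance = 2)
    expect_lt(pr$value[1] / max(pr$value), 0.05)
    expect_lt(pr$value[81] / max(pr$value), 0.05)
    # profile shape matches the Bessel oracle
    R <- max(pr$coord)
    pan <- disc_pressure_analytic(abs(pr$coord), R, bench_lambda(),
                                  bench_pc())
    expect_lt(max(abs(pr$value - pan)) / max(pan), 0.05)

    sp <- centerline_profile(tc, axis = ax, what = "speed", n = 81L)
    edge <- max(sp$value[c(1, 81)])
    expect_gt(edge, max(sp$value[30:52]))
  }
})

test_that("anisotropic vasculature produces direction-dependent boundary speeds", {
  ct <- circle_contour(150, 181L)
  aniso <- heatmap_field_spec(vasculature_base = 4, vasculature_sd = 0,
                              vasculature_trend = c(2.5, 0),
                              diameter_sd = 0, perfusion_sd = 0)
  hm <- gen_heatmaps(ct, field_spec = aniso, seed = 1)
  cfg <- timecourse_config(list(ct, ct), list(hm, hm), times = c(7, 16),
                           substeps = 1, n_rings = 12L, n_sectors = 24L)
  tc <- run_timecourse(cfg)
  sp <- centerline_profile(tc, axis = "x", what = "speed", n = 81L)
  # denser vasculature on the +x side drives faster boundary outflow there
  expect_gt(sp$value[81], 1.05 * sp$value[1])
})

test_that("group summaries report mean and s.e.m.", {
  d <- data.frame(g = c("a", "a", "a", "b", "c", "c"),
                  v = c(2, 4, 6, 5, 3, 3))
  s <- summarize_groups(d, g, v)
  expect_equal(s$mean[s$g == "a"], 4)
  expect_equal(s$sem[s$g == "a"], 2 / sqrt(3))
  expect_true(is.na(s$sem[s$g == "b"]))   # single value: no spread estimate
  expect_equal(s$sem[s$g == "c"], 0)      # constant group
})

test_that("tidiers expose step summaries and one-row overviews", {
  cfg <- disc_config(c(90, 120), times = c(7, 16), substeps = 2)
  tc <- run_timecourse(cfg)
  td <- tidy(tc)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("day", "mean_p_ex_pa", "mean_speed_ex") %in% names(td)))
  g <- glance(tc)
  expect_equal(nrow(g), 1L)
  expect_gt(g$mean_p_last_pa, g$mean_p_first_pa)

  f <- tc$steps[[1]]$field
  expect_equal(nrow(glance(f)), 1L)
  expect_true(all(c("node", "p_ex_pa") %in% names(tidy(f))))
})

test_that("autoplot methods return ggplot objects", {
  cfg <- disc_config(c(90, 120), times = c(7, 16), substeps = 1)
  tc <- run_timecourse(cfg)
  expect_s3_class(autoplot(tc), "ggplot")
  expect_s3_class(autoplot(tc$steps[[1]]$field), "ggplot")
  expect_s3_class(autoplot(tc$steps[[1]]$field, what = "speed"), "ggplot")
  hm <- gen_heatmaps(circle_contour(100), seed = 1)
  expect_s3_class(plot_heatmap(hm), "ggplot")
})
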