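#' Configuration for a growing-tumor perfusion simulation
#'
#' Bundles the geometry and heatmap knots with solver settings. Knots are
#' the observation times (default days 7, 10, 13 and 16, roughly 15/25/60/
#' 80% of final growth); between consecutive knots, geometry and heatmap
#' values are interpolated linearly and the domain is remeshed at every
#' substep. No extrapolation outside the first/last knot is performed —
#' growth outside the observed window would have to be assumed, not
#' measured.
#'
#' @param contours list of star-shaped contour tibbles, one per knot (or a
#'   contour-series tibble with `time_day`, to be split).
#' @param heatmaps list of heatmap tibbles, one per knot, sharing one
#'   `grid_shape`.
#' @param times knot days, strictly increasing, same length as `contours`.
#' @param substeps solver steps per knot interval (default 3).
#' @param n_rings,n_sectors remeshing density (default 16 x 32).
#' @param h_cap wall hydraulic coefficient (um/(Pa s)).
#' @param k_tissue tissue Darcy coefficient (um^2/(Pa s)).
#' @param mu blood viscosity (Pa s).
#' @param p_cap_mmhg capillary pressure (mmHg).
#' @param idw_power IDW exponent for heatmap-to-node mapping.
#' @param transfer_k neighbours for mesh-to-mesh pressure transfer.
#' @param seed integer seed (carried for provenance; the pipeline is
#'   deterministic given the config).
#' @return a `timecourse_config` list.
#' @export
timecourse_config <- function(contours, heatmaps, times = c(7, 10, 13, 16),
                              substeps = 3L, n_rings = 16L, n_sectors = 32L,
                              h_cap = 1.57e-3, k_tissue = 1, mu = 3e-3,
                              p_cap_mmhg = 10, idw_power = 2,
                              transfer_k = 4L, seed = 1L) {
  if (is.data.frame(contours)) contours <- contour_series_split(contours)
  if (length(times) < 2L || any(!is.finite(times)) ||
      is.unsorted(times, strictly = TRUE)) {
    abort("Knot `times` must be >= 2 strictly increasing days.")
  }
  if (length(contours) != length(times)) {
    abort("One contour per knot time is required.")
  }
  if (length(heatmaps) != length(times)) {
    abort("One heatmap per knot time is required.")
  }
  if (substeps < 1L) abort("`substeps` must be >= 1.")
  structure(
    list(contours = contours, heatmaps = heatmaps, times = times,
         substeps = as.integer(substeps), n_rings = as.integer(n_rings),
         n_sectors = as.integer(n_sectors), h_cap = h_cap,
         k_tissue = k_tissue, mu = mu, p_cap_mmhg = p_cap_mmhg,
         idw_power = idw_power, transfer_k = as.integer(transfer_k),
         seed = as.integer(seed)),
    class = "timecourse_config"
  )
}

#' Run the growing-tumor perfusion time course
#'
#' For every substep time: interpolate the contour (shape and size) and the
#' heatmap fields linearly between the bracketing knots, remesh the domain,
#' map heatmaps to nodal smeared parameters, transfer the previous step's
#' pressures to the new mesh (inverse-distance weighting) as the starting
#' field, and solve the quasi-static pressure problem. The governing system
#' has no storage term, so time enters only through the evolving geometry
#' and parameters. Deterministic given the config.
#'
#' All supplied knots are treated as interpolation knots. (Protocol
#' descriptions of this kind of study sometimes speak of interpolating
#' "between the three data points" even though four observation days exist;
#' with four knots there are three interpolation intervals, and this driver
#' interpolates across all of them.)
#'
#' @param config a [timecourse_config()].
#' @return a `perfusion_timecourse`: list with `steps` (per-step `day`,
#'   `mesh`, `params`, `field`) and `summary` (tibble of area-weighted mean
#'   and max extracellular pressure and Darcy speed, domain area, and
#'   conservation diagnostics per step).
#' @examples
#' circ <- function(r) tibble::tibble(
#'   x = r * cos(seq(0, 2 * pi, length.out = 73)[-73]),
#'   y = r * sin(seq(0, 2 * pi, length.out = 73)[-73]))
#' hm <- function(ct) gen_heatmaps(ct, field_spec = heatmap_field_spec(
#'   vasculature_sd = 0, diameter_sd = 0, perfusion_sd = 0), seed = 1)
#' cfg <- timecourse_config(
#'   contours = list(circ(80), circ(120)), heatmaps = list(hm(circ(80)),
#'   hm(circ(120))), times = c(7, 16), substeps = 2, n_rings = 8,
#'   n_sectors = 16)
#' tc <- run_timecourse(cfg)
#' tc$summary
#' @export
run_timecourse <- function(config) {
  stopifnot(inherits(config, "timecourse_config"))
  times <- config$times
  nk <- length(times)
  step_days <- unique(unlist(lapply(seq_len(nk - 1L), function(i) {
    times[i] + (times[i + 1L] - times[i]) *
      (seq_len(config$substeps) - 1L) / config$substeps
  })))
  step_days <- c(step_days, times[nk])

  steps <- vector("list", length(step_days))
  prev <- NULL
  for (s in seq_along(step_days)) {
    day <- step_days[s]
    i <- max(which(times <= day + 1e-12))
    if (i == nk) i <- nk - 1L
    alpha <- (day - times[i]) / (times[i + 1L] - times[i])
    contour <- interpolate_contours(config$contours[[i]],
                                    config$contours[[i + 1L]], alpha,
                                    n_theta = max(config$n_sectors * 4L, 96L))
    heatmap <- interpolate_heatmaps(config$heatmaps[[i]],
                                    config$heatmaps[[i + 1L]], alpha)
    mesh <- mesh_polygon(contour, config$n_rings, config$n_sectors)
    params <- nodal_params_from_heatmaps(
      heatmap, mesh, h_cap = config$h_cap, k_tissue = config$k_tissue,
      mu = config$mu, idw_power = config$idw_power)
    p0 <- NULL
    if (!is.null(prev)) {
      tr <- transfer_fields(
        prev$mesh,
        tibble(p_cap = prev$field$pressure$p_cap_pa,
               p_ex = prev$field$pressure$p_ex_pa),
        mesh, k = config$transfer_k)
      p0 <- c(tr$p_cap, tr$p_ex)
    }
    field <- solve_perfusion(mesh, params, p_cap_mmhg = config$p_cap_mmhg,
                             p0 = p0)
    steps[[s]] <- list(day = day, mesh = mesh, params = params, field = field)
    prev <- steps[[s]]
  }

  summary <- purrr::map_dfr(steps, function(st) {
    dplyr::bind_cols(tibble(day = st$day), step_summary(st$field))
  })
  structure(list(steps = steps, summary = summary, config = config),
            class = "perfusion_timecourse")
}

# area-weighted summaries of one solved step
step_summary <- function(field) {
  mesh <- field$system$mesh
  el <- mesh$elements
  pr <- field$pressure
  vel <- field$velocity
  M <- element_index_matrix(mesh)
  p_centre <- vapply(seq_len(nrow(M)), function(e) {
    mean(pr$p_ex_pa[matrix_node_ids(M, e)])
  }, numeric(1))
  a <- vel$area
  mb <- mass_balance(field)
  tibble(
    area_um2 = sum(a),
    mean_p_ex_pa = sum(a * p_centre) / sum(a),
    max_p_ex_pa = max(pr$p_ex_pa),
    mean_speed_ex = sum(a * vel$speed_ex) / sum(a),
    max_speed_ex = max(vel$speed_ex),
    wall_influx = mb$wall_influx,
    boundary_outflux = mb$boundary_outflux,
    relative_imbalance = mb$relative_imbalance
  )
}

# linear time interpolation of two heatmaps aligned by (row, col); cell
# centres interpolate too. A cell masked at only one knot takes the other
# knot's value.
interpolate_heatmaps <- function(ha, hb, alpha) {
  j <- dplyr::inner_join(ha, hb, by = c("row", "col"),
                         suffix = c("_a", "_b"))
  if (nrow(j) != nrow(ha) || nrow(j) != nrow(hb)) {
    abort("Heatmap knots must share one grid shape.")
  }
  mix <- function(a, b) {
    out <- (1 - alpha) * a + alpha * b
    out[is.na(a)] <- b[is.na(a)]
    out[is.na(b)] <- a[is.na(b)]
    out
  }
  tibble(
    row = j$row, col = j$col,
    x_um = (1 - alpha) * j$x_um_a + alpha * j$x_um_b,
    y_um = (1 - alpha) * j$y_um_a + alpha * j$y_um_b,
    vasculature_pct = mix(j$vasculature_pct_a, j$vasculature_pct_b),
    diameter_um = mix(j$diameter_um_a, j$diameter_um_b),
    perfusion_pct = mix(j$perfusion_pct_a, j$perfusion_pct_b),
    masked = j$masked_a & j$masked_b
  )
}

#' @export
print.perfusion_timecourse <- function(x, ...) {
  cat(sprintf("<perfusion_timecourse> %d steps, days %.3g-%.3g\n",
              length(x$steps), min(x$summary$day), max(x$summary$day)))
  print(x$summary)
  invisible(x)
}

#' Centreline profile through the tumor centre
#'
#' Samples a solved field along the line through the domain centroid
#' parallel to the chosen axis, from boundary to boundary, by
#' inverse-distance weighting (`k = 4`) from the nodes (pressure) or
#' element centres (Darcy speed).
#'
#' @param x a `perfusion_timecourse` or a single step's `perfusion_field`.
#' @param axis `"x"` or `"y"`.
#' @param day for a timecourse: which step day (default: last).
#' @param what `"pressure"` (extracellular, Pa) or `"speed"`
#'   (extracellular Darcy speed, um/s).
#' @param n number of sample points.
#' @return tibble `coord` (um, along the axis), `value`.
#' @export
centerline_profile <- function(x, axis = c("x", "y"), day = NULL,
                               what = c("pressure", "speed"), n = 101L) {
  axis <- match.arg(axis)
  what <- match.arg(what)
  field <- if (inherits(x, "perfusion_timecourse")) {
    days <- vapply(x$steps, `[[`, numeric(1), "day")
    idx <- if (is.null(day)) length(days) else which.min(abs(days - day))
    x$steps[[idx]]$field
  } else if (inherits(x, "perfusion_field")) {
    x
  } else {
    abort("`x` must be a perfusion_timecourse or perfusion_field.")
  }
  mesh <- field$system$mesh
  bnd <- mesh$nodes[mesh$nodes$boundary, ]
  ctr <- c(mean(bnd$x), mean(bnd$y))
  # boundary radius along the +/- axis direction
  ang <- atan2(bnd$y - ctr[2], bnd$x - ctr[1])
  rad <- sqrt((bnd$x - ctr[1])^2 + (bnd$y - ctr[2])^2)
  o <- order(ang)
  a_s <- ang[o]; r_s <- rad[o]
  keep <- c(TRUE, diff(a_s) > 0)
  a_s <- a_s[keep]; r_s <- r_s[keep]
  r_at <- function(a) periodic_interp(a_s, r_s, a)
  a0 <- if (axis == "x") 0 else pi / 2
  r_plus <- r_at(a0); r_minus <- r_at(a0 + pi)
  svals <- seq(-r_minus, r_plus, length.out = n)
  dx <- if (axis == "x") c(1, 0) else c(0, 1)
  queries <- tibble(x = ctr[1] + svals * dx[1], y = ctr[2] + svals * dx[2])
  samples <- if (what == "pressure") {
    tibble(x = field$pressure$x, y = field$pressure$y,
           value = field$pressure$p_ex_pa)
  } else {
    if (is.null(field$velocity)) field <- darcy_velocity(field)
    tibble(x = field$velocity$x, y = field$velocity$y,
           value = field$velocity$speed_ex)
  }
  res <- idw_interpolate(samples, queries, power = 2, k = 4L)
  tibble(coord = svals, value = res$value)
}

#' Mean and standard error by group
#'
#' @param data a data frame.
#' @param group,value column names (unquoted) of the grouping and value
#'   variables.
#' @return tibble `group`, `n`, `mean`, `sem` (`NA` for single-value
#'   groups).
#' @examples
#' summarize_groups(data.frame(g = c("a", "a", "a"), v = c(2, 4, 6)), g, v)
#' @export
summarize_groups <- function(data, group, value) {
  gq <- rlang::enquo(group); vq <- rlang::enquo(value)
  out <- data |>
    dplyr::group_by(!!gq) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(!!vq),
      sem = ifelse(dplyr::n() > 1L, sd(!!vq) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    )
  if (any(out$n == 0L)) abort("Empty group.")
  if (nrow(out) == 0L) abort("No groups present.")
  out
}
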