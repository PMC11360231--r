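#' Plot a gridded heatmap
#'
#' Tile plot of one heatmap field; masked (extratumoral) cells are blank.
#'
#' @param heatmap a heatmap tibble.
#' @param field `"vasculature_pct"`, `"perfusion_pct"` or `"diameter_um"`.
#' @return a ggplot.
#' @export
plot_heatmap <- function(heatmap, field = c("vasculature_pct",
                                            "perfusion_pct",
                                            "diameter_um")) {
  field <- match.arg(field)
  d <- heatmap
  d$value <- ifelse(d$masked, NA_real_, d[[field]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = field) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row")
}

#' Plot a solved pressure or velocity field
#'
#' Element-filled polygon map of the extracellular pressure (Pa) or Darcy
#' speed (um/s) over the tumor cross-section.
#'
#' @param object a `perfusion_field`.
#' @param what `"pressure"` or `"speed"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.perfusion_field <- function(object, what = c("pressure", "speed"),
                                     ...) {
  what <- match.arg(what)
  if (is.null(object$velocity)) object <- darcy_velocity(object)
  mesh <- object$system$mesh
  el <- mesh$elements
  polys <- purrr::map_dfr(seq_len(nrow(el)), function(e) {
    nn <- element_node_ids(el[e, ])
    tibble(element = el$element[e],
           x = mesh$nodes$x[nn], y = mesh$nodes$y[nn])
  })
  val <- if (what == "pressure") {
    vapply(seq_len(nrow(el)), function(e) {
      mean(object$pressure$p_ex_pa[element_node_ids(el[e, ])])
    }, numeric(1))
  } else {
    object$velocity$speed_ex
  }
  polys$value <- val[match(polys$element, el$element)]
  lab <- if (what == "pressure") "p_ex (Pa)" else "|v_ex| (um/s)"
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$element,
                                      fill = .data$value)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot time-course summaries
#'
#' Mean extracellular pressure and mean Darcy speed against time.
#'
#' @param object a `perfusion_timecourse`.
#' @param ... unused.
#' @return a ggplot (two facets).
#' @export
autoplot.perfusion_timecourse <- function(object, ...) {
  s <- object$summary
  d <- dplyr::bind_rows(
    tibble(day = s$day, metric = "mean p_ex (Pa)", value = s$mean_p_ex_pa),
    tibble(day = s$day, metric = "mean |v_ex| (um/s)",
           value = s$mean_speed_ex)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL)
}
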