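#' Tidy and glance at solved perfusion objects
#'
#' Broom-style accessors. For a `perfusion_field`, `tidy()` returns the
#' nodal pressure table (with wall fluxes) and `glance()` a one-row summary
#' (extrema, conservation residuals). For a `perfusion_timecourse`,
#' `tidy()` returns the per-step summary table and `glance()` one row over
#' the whole course.
#'
#' @param x a `perfusion_field` or `perfusion_timecourse`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.perfusion_field <- function(x, ...) {
  x$pressure
}

#' @rdname tidy.perfusion_field
#' @export
glance.perfusion_field <- function(x, ...) {
  mb <- mass_balance(x)
  s <- step_summary(if (is.null(x$velocity)) darcy_velocity(x) else x)
  tibble(
    n_nodes = nrow(x$pressure),
    mean_p_ex_pa = s$mean_p_ex_pa,
    max_p_ex_pa = s$max_p_ex_pa,
    mean_speed_ex = s$mean_speed_ex,
    solver_residual = x$residual,
    relative_imbalance = mb$relative_imbalance
  )
}

#' @rdname tidy.perfusion_field
#' @export
tidy.perfusion_timecourse <- function(x, ...) {
  x$summary
}

#' @rdname tidy.perfusion_field
#' @export
glance.perfusion_timecourse <- function(x, ...) {
  s <- x$summary
  tibble(
    n_steps = nrow(s),
    first_day = min(s$day), last_day = max(s$day),
    mean_p_first_pa = s$mean_p_ex_pa[1],
    mean_p_last_pa = s$mean_p_ex_pa[nrow(s)],
    mean_speed_first = s$mean_speed_ex[1],
    mean_speed_last = s$mean_speed_ex[nrow(s)],
    worst_imbalance = max(s$relative_imbalance)
  )
}
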