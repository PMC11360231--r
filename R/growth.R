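#' Caliper estimate of tumor volume
#'
#' Standard two-axis caliper formula for flank tumors,
#' \eqn{V = D d^2 / 2}, with `D` the major and `d` the minor axis in mm.
#' Vectorised over both axes.
#'
#' @param D major axis (mm).
#' @param d minor axis (mm), `d <= D`.
#' @return tumor volume in mm^3.
#' @examples
#' tumor_volume_caliper(12, 8) # 384
#' @export
tumor_volume_caliper <- function(D, d) {
  if (any(!is.finite(D)) || any(!is.finite(d))) {
    abort("`D` and `d` must be finite numbers.")
  }
  if (any(D < 0) || any(d < 0)) {
    abort("Caliper axes must be non-negative.")
  }
  if (any(d > D)) {
    abort("Minor axis `d` exceeds major axis `D`; axes are likely swapped.")
  }
  D * d^2 / 2
}

#' Exponential tumor growth model
#'
#' Describes flank-tumor volume as \eqn{V(t) = v_0 e^{rt}} with `t` in days.
#' The default coefficients are the exponential fit to a Lewis lung carcinoma
#' growth curve (v0 = 59.98 mm^3, rate = 0.1874 / day), under which days
#' 7, 10, 13 and 16 correspond to roughly 15%, 25%, 60% and 80% of final
#' tumor volume.
#'
#' @param v0 volume scale (mm^3), > 0.
#' @param rate growth rate (1/day), >= 0.
#' @return an object of class `growth_model`.
#' @examples
#' m <- growth_model()
#' growth_volume(c(7, 10, 13, 16), m)
#' @export
growth_model <- function(v0 = 59.98, rate = 0.1874) {
  if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0) || v0 <= 0) {
    abort("`v0` must be a single positive number (mm^3).")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    abort("`rate` must be a single non-negative number (1/day).")
  }
  structure(list(v0 = v0, rate = rate), class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> V(t) = %.4g * exp(%.4g t)  [mm^3, t in days]\n",
              x$v0, x$rate))
  invisible(x)
}

#' Tumor volume at a time point under a growth model
#'
#' @param t time in days, >= 0.
#' @param model a [growth_model()].
#' @return volume(s) in mm^3.
#' @export
growth_volume <- function(t, model = growth_model()) {
  stopifnot(inherits(model, "growth_model"))
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative (days).")
  }
  model$v0 * exp(model$rate * t)
}
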