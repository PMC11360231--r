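#' Analytic screened-Poisson benchmarks
#'
#' With capillary pressure held at `p_c` everywhere, the extracellular
#' pressure of the smeared model satisfies a screened Poisson equation with
#' screening length `lambda` (see [screening_length()]). On a uniform disc
#' of radius `R` with zero contour pressure the solution is the Krogh-type
#' profile
#' `p(r) = p_c (1 - I0(r/lambda) / I0(R/lambda))`,
#' with radial Darcy velocity
#' `v(r) = k_t p_c I1(r/lambda) / (lambda I0(R/lambda))`
#' and area-mean pressure
#' `p_c (1 - 2 lambda I1(R/lambda) / (R I0(R/lambda)))`.
#' On a 1D strip `|x| <= L` the profile is
#' `p(x) = p_c (1 - cosh(x/lambda) / cosh(L/lambda))`.
#' Exponentially scaled Bessel/cosh ratios are used so the formulas stay
#' finite for `R >> lambda`.
#'
#' @param r,x evaluation radius / coordinate (um; `x` measured from the
#'   strip centre).
#' @param R,L disc radius / strip half-length (um).
#' @param lambda screening length (um).
#' @param p_c capillary pressure (Pa).
#' @param k_t tissue Darcy coefficient (um^2/(Pa s)).
#' @return pressures in Pa; velocity in um/s.
#' @examples
#' disc_pressure_analytic(0, R = 100, lambda = 20, p_c = 1333.22)
#' @export
disc_pressure_analytic <- function(r, R, lambda, p_c) {
  ratio <- bessel_i0_ratio(r / lambda, R / lambda)
  p_c * (1 - ratio)
}

#' @rdname disc_pressure_analytic
#' @export
disc_velocity_analytic <- function(r, R, lambda, p_c, k_t) {
  num <- besselI(r / lambda, 1, expon.scaled = TRUE)
  den <- besselI(R / lambda, 0, expon.scaled = TRUE)
  k_t * p_c * exp((r - R) / lambda) * num / (lambda * den)
}

#' @rdname disc_pressure_analytic
#' @export
disc_mean_pressure_analytic <- function(R, lambda, p_c) {
  num <- besselI(R / lambda, 1, expon.scaled = TRUE)
  den <- besselI(R / lambda, 0, expon.scaled = TRUE)
  p_c * (1 - 2 * lambda / R * num / den)
}

#' @rdname disc_pressure_analytic
#' @export
strip_pressure_analytic <- function(x, L, lambda, p_c) {
  # cosh(x/l)/cosh(L/l) in overflow-safe form
  a <- x / lambda; b <- L / lambda
  ratio <- (exp(a - b) + exp(-a - b)) / (1 + exp(-2 * b))
  p_c * (1 - ratio)
}

bessel_i0_ratio <- function(a, b) {
  exp(a - b) * besselI(a, 0, expon.scaled = TRUE) /
    besselI(b, 0, expon.scaled = TRUE)
}
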