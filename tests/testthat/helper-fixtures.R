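# shared fixtures, built in code

circle_contour <- function(r, n = 181L, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n)[-n]
  tibble::tibble(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

# uniform benchmark configuration: the defaults of uniform_params()
# (4% coverage, 5 um capillaries, 75% perfused) with k_tissue = 1
bench_lambda <- function() screening_length(0.2, 0.05, 1, 5, h_cap = 1.57e-3)

bench_pc <- function() mmhg_to_pa(10)

# solved uniform disc, cached per radius/resolution within a test run
solved_disc <- local({
  cache <- list()
  function(R = 100, n_rings = 32, n_sectors = 64) {
    key <- paste(R, n_rings, n_sectors)
    if (is.null(cache[[key]])) {
      m <- mesh_polygon(circle_contour(R, 721L), n_rings, n_sectors)
      cache[[key]] <<- solve_perfusion(m, uniform_params(m))
    }
    cache[[key]]
  }
})

# relative L2 error of the nodal extracellular pressure against the disc
# closed form
disc_rel_l2 <- function(field, R) {
  pr <- field$pressure
  rr <- sqrt(pr$x^2 + pr$y^2)
  pan <- disc_pressure_analytic(rr, R, bench_lambda(), bench_pc())
  sqrt(sum((pr$p_ex_pa - pan)^2) / sum(pan^2))
}
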