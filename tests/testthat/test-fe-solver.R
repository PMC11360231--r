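test_that("element conductivity reproduces the bilinear Laplace element", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  Ke <- element_conductivity(sq, 1, diag(2))
  ref <- matrix(c(4, -1, -2, -1,
                  -1, 4, -1, -2,
                  -2, -1, 4, -1,
                  -1, -2, -1, 4), 4, 4) / 6
  expect_equal(Ke, ref)
  expect_equal(rowSums(Ke), rep(0, 4))

  expect_equal(element_conductivity(sq, 0, diag(2)), matrix(0, 4, 4))
  expect_equal(element_conductivity(sq, 1, diag(3.7, 2)), 3.7 * ref)

  # distorted quad: energy of the linear field u = x equals kD * area
  quad <- rbind(c(0, 0), c(2, 0.2), c(1.8, 1.5), c(-0.3, 1.1))
  Kq <- element_conductivity(quad, 1, diag(2))
  u <- quad[, 1]
  area <- abs(perfusim:::signed_area(quad[, 1], quad[, 2]))
  expect_equal(as.numeric(t(u) %*% Kq %*% u), area)

  # triangle energy check too
  tri <- rbind(c(0, 0), c(1.5, 0.1), c(0.4, 1.2))
  Kt <- element_conductivity(tri, 1, diag(2))
  at <- abs(perfusim:::signed_area(tri[, 1], tri[, 2]))
  expect_equal(as.numeric(t(tri[, 1]) %*% Kt %*% tri[, 1]), at)

  flipped <- sq[4:1, ]
  expect_error(element_conductivity(flipped, 1, diag(2)), "Jacobian")
})

test_that("assembled system is symmetric, conservative and couples correctly", {
  m <- mesh_polygon(circle_contour(100), 5, 12)
  p <- uniform_params(m)
  sys <- assemble_system(m, p)
  n <- sys$n
  expect_equal(Matrix::norm(sys$K - Matrix::t(sys$K), "M"), 0)
  expect_lt(max(abs(Matrix::rowSums(sys$K))), 1e-9)

  # h_cap = 0: block-diagonal (decoupled) system
  p0 <- uniform_params(m, h_cap = 0)
  sys0 <- assemble_system(m, p0)
  off <- sys0$K[seq_len(n), n + seq_len(n), drop = FALSE]
  expect_equal(Matrix::nnzero(off), 0)

  bad <- p[-1, ]
  expect_error(assemble_system(m, bad), "one row per mesh node")
})

test_that("a Laplace strip solve gives the exact linear profile", {
  m <- mesh_rectangle(100, 10, nx = 20, ny = 2)
  p <- uniform_params(m, h_cap = 0)
  sys <- assemble_system(m, p)
  bcs <- dplyr::bind_rows(
    tibble::tibble(node = m$nodes$node, domain = 1L, value = 0),
    tibble::tibble(node = m$nodes$node[m$nodes$x == 0], domain = 2L, value = 0),
    tibble::tibble(node = m$nodes$node[m$nodes$x == 100], domain = 2L,
                   value = 1333.22))
  f <- solve_pressure(sys, bcs)
  expect_equal(f$pressure$p_ex_pa, f$pressure$x / 100 * 1333.22,
               tolerance = 1e-10)
  expect_lt(f$residual, 1e-10)

  none <- tibble::tibble(node = integer(), domain = integer(),
                         value = numeric())
  expect_error(solve_pressure(sys, none), "singular")
})

test_that("uniform disc pressure matches the Bessel closed form", {
  R <- 100
  f <- solved_disc(R, 32, 64)
  expect_lt(disc_rel_l2(f, R), 0.01)

  # observed convergence order ~ 2 under uniform refinement
  errs <- vapply(list(c(8L, 16L), c(16L, 32L), c(32L, 64L)), function(nn) {
    disc_rel_l2(solved_disc(R, nn[1], nn[2]), R)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  orders <- log2(errs[-3] / errs[-1])
  expect_gt(mean(orders), 1.6)
})

test_that("disc boundary velocity matches the Bessel derivative", {
  R <- 100
  f <- solved_disc(R, 32, 64)
  vel <- f$velocity
  rr <- sqrt(vel$x^2 + vel$y^2)
  sel <- rr > max(rr) - 1e-9
  van <- disc_velocity_analytic(rr[sel], R, bench_lambda(), bench_pc(), 1)
  expect_lt(max(abs(vel$speed_ex[sel] - van) / van), 0.02)

  # uniform pressure implies zero velocity; capillary field is uniform here
  expect_lt(max(f$velocity$speed_cap), 1e-10)
})

test_that("velocity recovery is exact for linear pressure fields", {
  m <- mesh_rectangle(10, 4, nx = 5, ny = 2)
  p <- uniform_params(m, h_cap = 0, k_tissue = 2)
  sys <- assemble_system(m, p)
  f <- solve_pressure(sys, dplyr::bind_rows(
    tibble::tibble(node = m$nodes$node, domain = 1L, value = 0),
    tibble::tibble(node = m$nodes$node, domain = 2L,
                   value = 3 * m$nodes$x)))
  f <- darcy_velocity(f)
  expect_equal(f$velocity$vx_ex, rep(-2 * 3, nrow(f$velocity)))
  expect_equal(f$velocity$vy_ex, rep(0, nrow(f$velocity)), tolerance = 1e-12)
})

test_that("mass balance closes to 1e-8 and scales linearly with pressure", {
  f <- solved_disc(100, 16, 32)
  mb <- mass_balance(f)
  expect_lt(mb$relative_imbalance, 1e-8)
  expect_gt(mb$wall_influx, 0)

  m <- mesh_polygon(circle_contour(100, 721L), 16, 32)
  f2 <- solve_perfusion(m, uniform_params(m), p_cap_mmhg = 20)
  mb2 <- mass_balance(f2)
  expect_equal(mb2$wall_influx, 2 * mb$wall_influx, tolerance = 1e-9)
  expect_equal(mb2$boundary_outflux, 2 * mb$boundary_outflux,
               tolerance = 1e-9)

  # impermeable wall: no flow at all
  p0 <- uniform_params(m, h_cap = 0)
  f0 <- solve_pressure(assemble_system(m, p0))
  mb0 <- mass_balance(f0)
  expect_equal(mb0$wall_influx, 0)
  expect_equal(mb0$boundary_outflux, 0)
})

test_that("maximum principle and wall-permeability limits hold", {
  f <- solved_disc(100, 16, 32)
  pc <- bench_pc()
  expect_true(all(f$pressure$p_ex_pa >= -1e-9))
  expect_true(all(f$pressure$p_ex_pa <= pc + 1e-9))

  m <- mesh_polygon(circle_contour(100, 721L), 16, 32)
  # h_cap -> 0: extracellular pressure collapses to zero
  flow0 <- solve_perfusion(m, uniform_params(m, h_cap = 1.57e-9))
  expect_lt(max(flow0$pressure$p_ex_pa), 0.01 * pc)
  # h_cap large: interior pressure pinned at p_cap
  flow1 <- solve_perfusion(m, uniform_params(m, h_cap = 1.57))
  interior <- !flow1$pressure$boundary
  inner <- sqrt(flow1$pressure$x^2 + flow1$pressure$y^2) < 50
  expect_gt(min(flow1$pressure$p_ex_pa[inner]), 0.99 * pc)
})

test_that("raising wall permeability never lowers extracellular pressure", {
  m <- mesh_polygon(circle_contour(100, 361L), 10, 20)
  p_lo <- uniform_params(m, h_cap = 1e-3)
  p_hi <- uniform_params(m, h_cap = 2e-3)
  f_lo <- solve_pressure(assemble_system(m, p_lo))
  f_hi <- solve_pressure(assemble_system(m, p_hi))
  expect_true(all(f_hi$pressure$p_ex_pa >= f_lo$pressure$p_ex_pa - 1e-9))
})

test_that("vascular anisotropy shifts the pressure field", {
  m <- mesh_polygon(circle_contour(100, 361L), 12, 24)
  p <- uniform_params(m)
  right <- m$nodes$x > 0
  p$r_vcap[right] <- 2 * p$r_vcap[right]
  p$r_ex <- 1 - p$r_vcap - p$r_vcell
  p$k_wall[right] <- 2 * p$k_wall[right]
  f <- solve_pressure(assemble_system(m, p))
  mean_right <- mean(f$pressure$p_ex_pa[f$pressure$x > 1e-9])
  mean_left <- mean(f$pressure$p_ex_pa[f$pressure$x < -1e-9])
  expect_gt(mean_right, mean_left)
})
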