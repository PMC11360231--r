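#' Element conductivity matrix
#'
#' Integrates `r_V * grad(N_I) . kD grad(N_J)` over one element (times the
#' out-of-plane thickness `h_z`): 2 x 2 Gauss quadrature for 4-node
#' quadrilaterals, one-point for 3-node triangles. The volumetric fraction
#' and the Darcy tensor are interpolated from their nodal values to each
#' quadrature point.
#'
#' @param xy element node coordinates, an `n x 2` matrix (n = 3 or 4, um),
#'   counter-clockwise.
#' @param r_nodes volumetric fraction at the element nodes (length n, or a
#'   scalar).
#' @param kd_nodes Darcy tensor at the nodes: a single 2 x 2 matrix
#'   (constant over the element) or a list of n such matrices (um^2/(Pa s)).
#' @param h_z thickness (um).
#' @return the n x n symmetric element conductivity matrix (um^3/(Pa s) per
#'   Pa, i.e. flux per pressure).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' element_conductivity(sq, 1, diag(2)) # bilinear Laplace element, diag 2/3
#' @export
element_conductivity <- function(xy, r_nodes, kd_nodes, h_z = 1) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (!n %in% c(3L, 4L)) abort("Elements have 3 or 4 nodes.")
  r_nodes <- rep_len(r_nodes, n)
  kd_list <- if (is.matrix(kd_nodes)) rep(list(kd_nodes), n) else kd_nodes
  if (length(kd_list) != n) abort("`kd_nodes` must give one 2x2 tensor per node.")

  if (n == 4L) {
    g <- 1 / sqrt(3)
    qp <- rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
    wq <- rep(1, 4)
    shape <- function(q) quad_shape_fun(qp[q, 1], qp[q, 2])
    deriv <- function(q) quad_shape_deriv(qp[q, 1], qp[q, 2])
    nq <- 4L
  } else {
    qp <- matrix(c(1 / 3, 1 / 3), 1)
    wq <- 0.5
    shape <- function(q) c(1 / 3, 1 / 3, 1 / 3)
    deriv <- function(q) rbind(c(-1, -1), c(1, 0), c(0, 1))
    nq <- 1L
  }

  Ke <- matrix(0, n, n)
  for (q in seq_len(nq)) {
    dN <- deriv(q)
    J <- t(dN) %*% xy
    detJ <- det(J)
    if (detJ <= 0) abort("Non-positive Jacobian in element integration.")
    B <- dN %*% t(solve(J))  # global gradients: dN/dx = dN/dxi . dxi/dx
    Nq <- shape(q)
    r_q <- sum(Nq * r_nodes)
    kd_q <- Reduce(`+`, Map(`*`, kd_list, Nq))
    Ke <- Ke + wq[q] * detJ * h_z * r_q * (B %*% kd_q %*% t(B))
  }
  (Ke + t(Ke)) / 2
}

#' Assemble the coupled two-domain pressure system
#'
#' Builds the global sparse conductivity matrix of the composite smeared
#' model: one Darcy block per domain (capillary with fraction `r_vcap` and
#' tensor `kd_cap_iso * I`; extracellular with `r_ex` and `kd_tissue * I`),
#' plus, at every node, a fictitious zero-length connectivity element of
#' conductance `k_wall` coupling the two domains (see
#' [connectivity_matrix()]). Degrees of freedom are ordered capillary nodes
#' first, then extracellular nodes. The unconstrained matrix is symmetric
#' with zero row sums (pure-Neumann conservation).
#'
#' @param mesh a `perfusion_mesh`.
#' @param params a `perfusion_params` tibble on the same mesh.
#' @param coupling set `FALSE` to drop the wall connectivity (decoupled
#'   domains; diagnostic use).
#' @return a `perfusion_system`: list with sparse `K` (2n x 2n), source
#'   vector `Q` (zero by default; volumetric sources can be added before
#'   solving), `mesh`, `params`, `n`.
#' @export
assemble_system <- function(mesh, params, coupling = TRUE) {
  n <- nrow(mesh$nodes)
  if (nrow(params) != n) abort("`params` must have one row per mesh node.")
  el <- mesh$elements

  M <- element_index_matrix(mesh)
  xs <- mesh$nodes$x; ys <- mesh$nodes$y
  r_vcap <- params$r_vcap; r_ex <- params$r_ex
  kd_cap_iso <- params$kd_cap_iso; kd_tissue <- params$kd_tissue
  ne <- nrow(M)
  ti <- vector("list", 2L * ne + 1L)
  tj <- vector("list", 2L * ne + 1L)
  tx <- vector("list", 2L * ne + 1L)
  for (e in seq_len(ne)) {
    nn <- matrix_node_ids(M, e)
    xy <- cbind(xs[nn], ys[nn])
    k <- length(nn)
    idx <- rep(nn, times = k)
    jdx <- rep(nn, each = k)
    Ke1 <- element_conductivity(xy, r_vcap[nn],
                                lapply(kd_cap_iso[nn], diag, nrow = 2),
                                h_z = mesh$h_z)
    Ke2 <- element_conductivity(xy, r_ex[nn],
                                lapply(kd_tissue[nn], diag, nrow = 2),
                                h_z = mesh$h_z)
    ti[[2L * e - 1L]] <- idx; tj[[2L * e - 1L]] <- jdx
    tx[[2L * e - 1L]] <- as.vector(Ke1)
    ti[[2L * e]] <- idx + n; tj[[2L * e]] <- jdx + n
    tx[[2L * e]] <- as.vector(Ke2)
  }
  if (coupling) {
    kw <- params$k_wall
    nodes <- seq_len(n)
    ti[[2L * ne + 1L]] <- c(nodes, nodes + n, nodes, nodes + n)
    tj[[2L * ne + 1L]] <- c(nodes, nodes + n, nodes + n, nodes)
    tx[[2L * ne + 1L]] <- c(kw, kw, -kw, -kw)
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(2L * n, 2L * n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, Q = numeric(2L * n), mesh = mesh, params = params,
                 n = n),
            class = "perfusion_system")
}

#' @export
print.perfusion_system <- function(x, ...) {
  cat(sprintf("<perfusion_system> %d nodes x 2 domains, %d nonzeros\n",
              x$n, Matrix::nnzero(x$K)))
  invisible(x)
}

#' Standard boundary conditions of the tumor perfusion problem
#'
#' Capillary pressure is prescribed at every node (default 10 mmHg =
#' 1333.22 Pa — an effective value folding hydrostatic and oncotic
#' contributions), and the extracellular pressure is zero on the tumor
#' contour, expressing balance between perfusion and reabsorption outside.
#'
#' @param mesh a `perfusion_mesh`.
#' @param p_cap_mmhg capillary pressure (mmHg).
#' @param p_boundary_pa extracellular contour pressure (Pa).
#' @return a tibble `node`, `domain` (1 capillary, 2 extracellular),
#'   `value` (Pa).
#' @export
perfusion_bcs <- function(mesh, p_cap_mmhg = 10, p_boundary_pa = 0) {
  dplyr::bind_rows(
    tibble(node = mesh$nodes$node, domain = 1L,
           value = mmhg_to_pa(p_cap_mmhg)),
    tibble(node = mesh$nodes$node[mesh$nodes$boundary], domain = 2L,
           value = p_boundary_pa)
  )
}

#' Solve the pressure system
#'
#' Applies the Dirichlet data and performs one incremental solve
#' `K dP = Q - K P0` (the system is linear, so a single increment reaches
#' the steady state from any starting field `P0`, e.g. pressures transferred
#' from the previous time point's mesh). Direct sparse Cholesky
#' factorisation; the relative residual of the reduced system is checked
#' against 1e-10.
#'
#' @param system a `perfusion_system` from [assemble_system()].
#' @param bcs Dirichlet tibble (`node`, `domain`, `value`), e.g. from
#'   [perfusion_bcs()].
#' @param p0 optional starting nodal pressures, length `2n` (capillary dofs
#'   first); defaults to zero.
#' @return a `perfusion_field`: list with `pressure` tibble (`node`, `x`,
#'   `y`, `boundary`, `p_cap_pa`, `p_ex_pa`, `wall_flux` in um^3/s),
#'   `system`, `bcs`, `residual`.
#' @export
solve_pressure <- function(system, bcs = NULL, p0 = NULL) {
  stopifnot(inherits(system, "perfusion_system"))
  mesh <- system$mesh
  n <- system$n
  if (is.null(bcs)) bcs <- perfusion_bcs(mesh)
  if (nrow(bcs) == 0L) {
    abort("No Dirichlet data anywhere: the pure-Neumann system is singular.")
  }
  if (!all(bcs$domain %in% c(1L, 2L))) abort("`bcs$domain` must be 1 or 2.")
  fixed <- bcs$node + (bcs$domain - 1L) * n
  if (anyDuplicated(fixed)) abort("Conflicting Dirichlet data at a dof.")

  P <- if (is.null(p0)) numeric(2L * n) else as.numeric(p0)
  if (length(P) != 2L * n) abort("`p0` must have length 2 * n.")
  P[fixed] <- bcs$value

  free <- setdiff(seq_len(2L * n), fixed)
  rhs <- system$Q - as.numeric(system$K %*% P)
  if (length(free) > 0L) {
    Kff <- system$K[free, free, drop = FALSE]
    dP <- Matrix::solve(Kff, rhs[free])
    P[free] <- P[free] + as.numeric(dP)
    res <- as.numeric(Kff %*% dP) - rhs[free]
    denom <- max(sqrt(sum(rhs[free]^2)), 1e-300)
    residual <- sqrt(sum(res^2)) / denom
    if (residual > 1e-10) {
      warn(sprintf("Pressure solve residual %.2e exceeds 1e-10.", residual))
    }
  } else {
    residual <- 0
  }

  p_cap <- P[seq_len(n)]
  p_ex <- P[n + seq_len(n)]
  pressure <- tibble(
    node = mesh$nodes$node, x = mesh$nodes$x, y = mesh$nodes$y,
    boundary = mesh$nodes$boundary,
    p_cap_pa = p_cap, p_ex_pa = p_ex,
    wall_flux = system$params$k_wall * (p_cap - p_ex)
  )
  structure(list(pressure = pressure, system = system, bcs = bcs,
                 residual = residual),
            class = "perfusion_field")
}

#' @export
print.perfusion_field <- function(x, ...) {
  pr <- x$pressure
  cat(sprintf(
    "<perfusion_field> %d nodes; p_ex in [%.4g, %.4g] Pa; residual %.1e\n",
    nrow(pr), min(pr$p_ex_pa), max(pr$p_ex_pa), x$residual))
  invisible(x)
}

#' Darcy velocities at element centres
#'
#' Recovers the superficial (Darcy) velocity `v = -kD grad(p)` per domain
#' from the solved pressures, evaluated at each element centre with the
#' element's interpolated Darcy tensor.
#'
#' @param field a `perfusion_field` from [solve_pressure()].
#' @return the field with a `velocity` tibble added: `element`, `x`, `y`,
#'   `area`, `vx_cap`, `vy_cap`, `vx_ex`, `vy_ex`, `speed_cap`, `speed_ex`
#'   (um/s).
#' @export
darcy_velocity <- function(field) {
  stopifnot(inherits(field, "perfusion_field"))
  mesh <- field$system$mesh
  params <- field$system$params
  el <- mesh$elements
  pr <- field$pressure

  M <- element_index_matrix(mesh)
  xs <- mesh$nodes$x; ys <- mesh$nodes$y
  dN_quad <- quad_shape_deriv(0, 0); N_quad <- quad_shape_fun(0, 0)
  dN_tri <- rbind(c(-1, -1), c(1, 0), c(0, 1)); N_tri <- rep(1 / 3, 3)
  res <- vapply(seq_len(nrow(M)), function(e) {
    nn <- matrix_node_ids(M, e)
    xy <- cbind(xs[nn], ys[nn])
    if (length(nn) == 4L) { dN <- dN_quad; Nc <- N_quad }
    else { dN <- dN_tri; Nc <- N_tri }
    J <- t(dN) %*% xy
    B <- dN %*% t(solve(J))
    g_cap <- as.numeric(t(B) %*% pr$p_cap_pa[nn])
    g_ex <- as.numeric(t(B) %*% pr$p_ex_pa[nn])
    kd_cap <- sum(Nc * params$kd_cap_iso[nn])
    kd_ex <- sum(Nc * params$kd_tissue[nn])
    c(mean(xy[, 1]), mean(xy[, 2]),
      -kd_cap * g_cap, -kd_ex * g_ex)
  }, numeric(6))
  out <- tibble(
    element = el$element, x = res[1, ], y = res[2, ],
    vx_cap = res[3, ], vy_cap = res[4, ],
    vx_ex = res[5, ], vy_ex = res[6, ]
  )
  out$area <- element_areas(mesh)
  out$speed_cap <- sqrt(out$vx_cap^2 + out$vy_cap^2)
  out$speed_ex <- sqrt(out$vx_ex^2 + out$vy_ex^2)
  field$velocity <- out
  field
}

#' Mass-balance report of a solved field
#'
#' Checks discrete conservation: the total capillary-to-tissue wall flux
#' must equal the total outflux through the contour. Reactions are read from
#' the residual `K P - Q` at constrained dofs.
#'
#' @param field a `perfusion_field`.
#' @return tibble with `wall_influx`, `boundary_outflux` (um^3/s) and
#'   `relative_imbalance`.
#' @export
mass_balance <- function(field) {
  stopifnot(inherits(field, "perfusion_field"))
  sys <- field$system
  n <- sys$n
  P <- c(field$pressure$p_cap_pa, field$pressure$p_ex_pa)
  R <- as.numeric(sys$K %*% P) - sys$Q
  wall_influx <- sum(field$pressure$wall_flux)
  tis_dir <- field$bcs$node[field$bcs$domain == 2L] + n
  boundary_outflux <- -sum(R[tis_dir])
  denom <- max(abs(wall_influx), abs(boundary_outflux), 1e-300)
  tibble(
    wall_influx = wall_influx,
    boundary_outflux = boundary_outflux,
    relative_imbalance = abs(wall_influx - boundary_outflux) / denom
  )
}

#' One-call perfusion solve
#'
#' Convenience wrapper: assemble, apply standard boundary conditions, solve,
#' and recover velocities.
#'
#' @param mesh a `perfusion_mesh`.
#' @param params a `perfusion_params` tibble.
#' @param p_cap_mmhg capillary pressure (mmHg), default 10.
#' @param p0 optional starting pressures (see [solve_pressure()]).
#' @return a `perfusion_field` with pressures and velocities.
#' @examples
#' circ <- tibble::tibble(
#'   x = 100 * cos(seq(0, 2 * pi, length.out = 91)[-91]),
#'   y = 100 * sin(seq(0, 2 * pi, length.out = 91)[-91]))
#' m <- mesh_polygon(circ, 8, 24)
#' f <- solve_perfusion(m, uniform_params(m))
#' range(f$pressure$p_ex_pa)
#' @export
solve_perfusion <- function(mesh, params, p_cap_mmhg = 10, p0 = NULL) {
  sys <- assemble_system(mesh, params)
  field <- solve_pressure(sys, perfusion_bcs(mesh, p_cap_mmhg), p0 = p0)
  darcy_velocity(field)
}
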