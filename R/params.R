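#' Capillary volumetric fraction from areal coverage
#'
#' Converts a per-cell vasculature coverage percentage (stained capillary
#' area over cell area) to the volumetric fraction of the capillary domain.
#' Treating the stained area as the projected internal surface of cylinders
#' of diameter `d` and total length L (A_cap = d L) and their volume as
#' d^2 pi L / 4, the slice of thickness `h_z` gives
#' `r_Vcap = d * Acap_pct / (400 * h_z)`.
#'
#' @param acap_pct coverage in `[0, 100]` (%).
#' @param d capillary diameter (um); must be > 0 wherever `acap_pct > 0`.
#' @param h_z slice thickness (um), default 1.
#' @return capillary volumetric fraction in `[0, 1]`. Errors if the
#'   combination implies a fraction above 1 (unphysical input).
#' @examples
#' rvcap_from_coverage(4, 5) # 0.05
#' @export
rvcap_from_coverage <- function(acap_pct, d, h_z = 1) {
  if (any(!is.finite(acap_pct)) || any(acap_pct < 0) || any(acap_pct > 100)) {
    abort("`acap_pct` must be in [0, 100].")
  }
  if (h_z <= 0) abort("`h_z` must be positive (um).")
  if (any(acap_pct > 0 & (!is.finite(d) | d <= 0))) {
    abort("`d` must be positive wherever coverage is positive.")
  }
  r <- ifelse(acap_pct > 0, d * acap_pct / (400 * h_z), 0)
  if (any(r > 1)) {
    abort("Implied capillary fraction exceeds 1: coverage/diameter combination is unphysical.")
  }
  r
}

#' Extracellular volumetric fraction by closure
#'
#' The three smeared domains (capillaries, cells, extracellular space)
#' partition the continuum, so `r_ex = 1 - r_Vcap - r_Vcell`.
#'
#' @param r_vcap,r_vcell fractions in `[0, 1]`.
#' @return `r_ex`; errors if the capillary and cell fractions already
#'   overfill the volume.
#' @export
rex_from_fractions <- function(r_vcap, r_vcell) {
  if (any(r_vcap < 0) || any(r_vcap > 1) || any(r_vcell < 0) || any(r_vcell > 1)) {
    abort("Fractions must be in [0, 1].")
  }
  r <- 1 - r_vcap - r_vcell
  if (any(r < 0)) {
    abort("r_Vcap + r_Vcell exceeds 1: no extracellular volume left.")
  }
  r
}

#' Capillary-wall connectivity conductance matrix
#'
#' The two pressure domains are coupled at each FE node by a fictitious
#' zero-length connectivity element whose conductance is the capillary wall
#' area inside the node's tributary volume times the wall hydraulic
#' coefficient: for cylinders, wall area per volume is `4/d`, so
#' `k = (4 * r_vcap * V / d) * h_cap` and the 2 x 2 matrix is
#' `k * [[1, -1], [-1, 1]]` (row sums zero: what leaves the capillary enters
#' the tissue).
#'
#' @param d capillary diameter (um).
#' @param r_vcap capillary volumetric fraction.
#' @param V tributary continuum volume at the node (um^3).
#' @param h_cap wall hydraulic coefficient (um/(Pa s)); default 1.57e-3, a
#'   literature filtration coefficient reduced to unit wall surface.
#' @return 2 x 2 conductance matrix (um^3/(Pa s)); row/col 1 = capillary,
#'   2 = extracellular.
#' @examples
#' connectivity_matrix(d = 10, r_vcap = 0.05, V = 1e4)[1, 1] # 0.314
#' @export
connectivity_matrix <- function(d, r_vcap, V, h_cap = 1.57e-3) {
  if (any(c(r_vcap, V, h_cap) < 0)) abort("Inputs must be non-negative.")
  if (r_vcap > 0 && d <= 0) abort("`d` must be positive when `r_vcap` > 0.")
  k <- connectivity_conductance(d, r_vcap, V, h_cap)
  k * matrix(c(1, -1, -1, 1), 2, 2)
}

connectivity_conductance <- function(d, r_vcap, V, h_cap) {
  ifelse(r_vcap > 0, 4 * r_vcap * V / d * h_cap, 0)
}

#' Darcy tensors of the two domains
#'
#' `darcy_tensor_tissue()` returns the isotropic extracellular tensor
#' `diag(k_iso, k_iso)` (um^2/(Pa s)). `darcy_tensor_capillary()` builds the
#' capillary tensor from Poiseuille conductivity `d^2 / (32 mu)`: aligned
#' capillaries give `(d^2 / (32 mu)) * t t'` for unit direction `t`;
#' orientation-averaged in-plane capillaries give half that on the diagonal,
#' `(d^2 / (64 mu)) * I`.
#'
#' @param k_iso isotropic tissue Darcy coefficient (um^2/(Pa s)), >= 0.
#' @return a symmetric positive-semidefinite 2 x 2 matrix.
#' @export
darcy_tensor_tissue <- function(k_iso) {
  if (!is.numeric(k_iso) || length(k_iso) != 1L || !is.finite(k_iso) || k_iso < 0) {
    abort("`k_iso` must be a single non-negative number.")
  }
  diag(k_iso, 2)
}

#' @rdname darcy_tensor_tissue
#' @param d capillary diameter (um), >= 0.
#' @param orientation `"isotropic"` or a length-2 direction vector.
#' @param mu blood/plasma viscosity (Pa s), default 3e-3.
#' @export
darcy_tensor_capillary <- function(d, orientation = "isotropic", mu = 3e-3) {
  if (!is.numeric(d) || d < 0) abort("`d` must be >= 0 (um).")
  if (!is.numeric(mu) || mu <= 0) abort("`mu` must be > 0 (Pa s).")
  k_pois <- d^2 / (32 * mu)
  if (identical(orientation, "isotropic")) {
    return(diag(k_pois / 2, 2))
  }
  if (!is.numeric(orientation) || length(orientation) != 2L ||
      sum(orientation^2) == 0) {
    abort("`orientation` must be \"isotropic\" or a nonzero length-2 vector.")
  }
  t_hat <- orientation / sqrt(sum(orientation^2))
  k_pois * tcrossprod(t_hat)
}

#' Map heatmaps to per-node smeared parameters
#'
#' Interpolates the unmasked heatmap cells to the mesh nodes by
#' inverse-distance weighting (diameter uses only cells where a diameter was
#' measured), then applies the volumetric-fraction relations per node:
#' `r_Vcap` from coverage and diameter, `r_Vcell = perfusion_pct / 100`
#' (perfused/stained area taken as the cell-covered area), and
#' `r_ex = 1 - r_Vcap - r_Vcell`. Nodal tributary volumes come from
#' element areas (x `h_z`), lumped equally to the element's nodes, so they
#' partition the mesh volume exactly.
#'
#' @param heatmap heatmap tibble (from [gen_heatmaps()], [build_heatmaps()]
#'   or [read_heatmap_csv()]).
#' @param mesh a `perfusion_mesh`.
#' @param h_cap wall hydraulic coefficient (um/(Pa s)), default 1.57e-3.
#' @param k_tissue isotropic tissue Darcy coefficient (um^2/(Pa s)),
#'   default 1.
#' @param mu blood viscosity (Pa s), default 3e-3.
#' @param idw_power IDW exponent for the heatmap-to-node interpolation.
#' @return a `perfusion_params` tibble: `node`, `x`, `y`,
#'   `vasculature_pct`, `diameter_um`, `perfusion_pct`, `r_vcap`,
#'   `r_vcell`, `r_ex`, `v_j` (um^3), `k_wall` (um^3/(Pa s)),
#'   `kd_tissue`, `kd_cap_iso` (um^2/(Pa s)); model constants in
#'   attributes `h_cap`, `k_tissue`, `mu`, `h_z`.
#' @examples
#' circ <- tibble::tibble(
#'   x = 100 * cos(seq(0, 2 * pi, length.out = 91)[-91]),
#'   y = 100 * sin(seq(0, 2 * pi, length.out = 91)[-91]))
#' hm <- gen_heatmaps(circ, field_spec = heatmap_field_spec(
#'   vasculature_sd = 0, diameter_sd = 0, perfusion_sd = 0), seed = 1)
#' m <- mesh_polygon(circ, 4, 12)
#' p <- nodal_params_from_heatmaps(hm, m)
#' all.equal(p$r_vcap + p$r_vcell + p$r_ex, rep(1, nrow(p)))
#' @export
nodal_params_from_heatmaps <- function(heatmap, mesh, h_cap = 1.57e-3,
                                       k_tissue = 1, mu = 3e-3,
                                       idw_power = 2) {
  need <- c("x_um", "y_um", "vasculature_pct", "diameter_um",
            "perfusion_pct", "masked")
  if (!all(need %in% names(heatmap))) {
    abort("`heatmap` is missing required columns.")
  }
  hm <- heatmap[!heatmap$masked, ]
  if (nrow(hm) == 0L) abort("All heatmap cells are masked.")

  nodes <- mesh$nodes[, c("x", "y")]
  cov <- idw_interpolate(
    tibble(x = hm$x_um, y = hm$y_um,
           vasculature_pct = hm$vasculature_pct,
           perfusion_pct = hm$perfusion_pct),
    nodes, power = idw_power
  )
  hd <- hm[!is.na(hm$diameter_um), ]
  if (nrow(hd) == 0L) abort("No heatmap cell carries a capillary diameter.")
  dia <- idw_interpolate(
    tibble(x = hd$x_um, y = hd$y_um, diameter_um = hd$diameter_um),
    nodes, power = idw_power
  )

  v_j <- tributary_volumes(mesh)
  r_vcap <- rvcap_from_coverage(pmin(pmax(cov$vasculature_pct, 0), 100),
                                dia$diameter_um, h_z = mesh$h_z)
  r_vcell <- pmin(pmax(cov$perfusion_pct, 0), 100) / 100
  r_ex <- 1 - r_vcap - r_vcell
  bad <- which(r_ex < 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Node %d: r_Vcap + r_Vcell = %.3f > 1, no extracellular volume left.",
      bad[1], r_vcap[bad[1]] + r_vcell[bad[1]]))
  }

  out <- tibble(
    node = mesh$nodes$node, x = mesh$nodes$x, y = mesh$nodes$y,
    vasculature_pct = cov$vasculature_pct,
    diameter_um = dia$diameter_um,
    perfusion_pct = cov$perfusion_pct,
    r_vcap = r_vcap, r_vcell = r_vcell, r_ex = r_ex,
    v_j = v_j,
    k_wall = connectivity_conductance(dia$diameter_um, r_vcap, v_j, h_cap),
    kd_tissue = k_tissue,
    kd_cap_iso = dia$diameter_um^2 / (64 * mu)
  )
  structure(out, h_cap = h_cap, k_tissue = k_tissue, mu = mu, h_z = mesh$h_z,
            class = c("perfusion_params", class(out)))
}

# element volumes lumped equally to element nodes; sums to mesh volume
tributary_volumes <- function(mesh) {
  v <- numeric(nrow(mesh$nodes))
  areas <- element_areas(mesh)
  M <- element_index_matrix(mesh)
  for (e in seq_len(nrow(M))) {
    nn <- matrix_node_ids(M, e)
    v[nn] <- v[nn] + areas[e] * mesh$h_z / length(nn)
  }
  v
}

#' Uniform nodal parameters for benchmark problems
#'
#' Builds a `perfusion_params` table with the same smeared parameters at
#' every node; the configuration of the analytic disc and strip benchmarks.
#'
#' @param mesh a `perfusion_mesh`.
#' @param acap_pct vasculature coverage (%), default 4.
#' @param diameter_um capillary diameter (um), default 5.
#' @param perfusion_pct perfused/cell-covered area (%), default 75.
#' @inheritParams nodal_params_from_heatmaps
#' @return a `perfusion_params` tibble (see
#'   [nodal_params_from_heatmaps()]).
#' @export
uniform_params <- function(mesh, acap_pct = 4, diameter_um = 5,
                           perfusion_pct = 75, h_cap = 1.57e-3,
                           k_tissue = 1, mu = 3e-3) {
  n <- nrow(mesh$nodes)
  r_vcap <- rvcap_from_coverage(acap_pct, diameter_um, h_z = mesh$h_z)
  r_vcell <- perfusion_pct / 100
  r_ex <- rex_from_fractions(r_vcap, r_vcell)
  v_j <- tributary_volumes(mesh)
  out <- tibble(
    node = mesh$nodes$node, x = mesh$nodes$x, y = mesh$nodes$y,
    vasculature_pct = acap_pct, diameter_um = diameter_um,
    perfusion_pct = perfusion_pct,
    r_vcap = r_vcap, r_vcell = r_vcell, r_ex = r_ex,
    v_j = v_j,
    k_wall = connectivity_conductance(diameter_um, r_vcap, v_j, h_cap),
    kd_tissue = k_tissue,
    kd_cap_iso = diameter_um^2 / (64 * mu)
  )
  structure(out, h_cap = h_cap, k_tissue = k_tissue, mu = mu, h_z = mesh$h_z,
            class = c("perfusion_params", class(out)))
}

#' Pressure screening length of the smeared model
#'
#' In the limit where capillary pressure is held fixed, the extracellular
#' pressure obeys a screened Poisson equation with decay length
#' `lambda = sqrt(r_ex * k_t * d / (4 * r_vcap * h_cap))` (um). Reported so
#' the effect of the (configurable) tissue Darcy coefficient on the boundary
#' layer is visible.
#'
#' @param r_ex,r_vcap volumetric fractions.
#' @param k_tissue tissue Darcy coefficient (um^2/(Pa s)).
#' @param d capillary diameter (um).
#' @param h_cap wall hydraulic coefficient (um/(Pa s)).
#' @return screening length in um.
#' @examples
#' screening_length(0.2, 0.05, 1, 5) # ~17.8 um
#' @export
screening_length <- function(r_ex, r_vcap, k_tissue, d, h_cap = 1.57e-3) {
  sqrt(r_ex * k_tissue * d / (4 * r_vcap * h_cap))
}
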