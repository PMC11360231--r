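#' Polar transfinite mesh of a star-shaped tumor contour
#'
#' Meshes the tumor cross-section with `n_rings` concentric rings of
#' `n_sectors` 4-node quadrilaterals each, plus a fan of 3-node triangles at
#' the centroid (a degenerate quad there would have a singular Jacobian).
#' Ring radii are equal fractions of the boundary radius per sector angle.
#' The sampled boundary polygon is radially rescaled by a single factor so
#' the mesh conserves the input polygon's area exactly; boundary nodes
#' therefore sit on a contour dilated by the (sub-percent) polygonisation
#' deficit rather than exactly on the input vertices.
#'
#' @param contour star-shaped contour tibble (`x`, `y` in um).
#' @param n_rings number of rings, >= 2.
#' @param n_sectors number of sectors, >= 6.
#' @param h_z out-of-plane model thickness (um), default 1.
#' @return a `perfusion_mesh`: list with `nodes` (tibble `node`, `x`, `y`,
#'   `boundary`), `elements` (tibble `element`, `n1`..`n4`, `type`;
#'   `n4 = NA` for triangles), `h_z`, and `centroid`.
#' @examples
#' circ <- tibble::tibble(
#'   x = cos(seq(0, 2 * pi, length.out = 181)[-181]),
#'   y = sin(seq(0, 2 * pi, length.out = 181)[-181])) * 100
#' m <- mesh_polygon(circ, n_rings = 8, n_sectors = 24)
#' mesh_area(m) / polygon_area(circ) # 1 up to float rounding
#' @export
mesh_polygon <- function(contour, n_rings = 16L, n_sectors = 32L, h_z = 1) {
  n_rings <- as.integer(n_rings); n_sectors <- as.integer(n_sectors)
  if (n_rings < 2L) abort("`n_rings` must be >= 2.")
  if (n_sectors < 6L) abort("`n_sectors` must be >= 6.")
  if (h_z <= 0) abort("`h_z` must be positive (um).")
  pol <- resample_contour_polar(contour, n_theta = n_sectors)
  ctr <- attr(pol, "centroid")
  if (any(pol$radius <= 0)) abort("Degenerate contour (non-positive radius).")

  # conserve the input polygon's area under n_sectors polygonisation
  a_poly <- polygon_area(contour)
  a_ngon <- abs(signed_area(pol$radius * cos(pol$theta),
                            pol$radius * sin(pol$theta)))
  radius <- pol$radius * sqrt(a_poly / a_ngon)

  frac <- seq_len(n_rings) / n_rings
  xs <- ctr[1]; ys <- ctr[2]
  for (i in seq_len(n_rings)) {
    xs <- c(xs, ctr[1] + frac[i] * radius * cos(pol$theta))
    ys <- c(ys, ctr[2] + frac[i] * radius * sin(pol$theta))
  }
  nodes <- tibble(
    node = seq_along(xs), x = xs, y = ys,
    boundary = seq_along(xs) > 1L + (n_rings - 1L) * n_sectors
  )

  ring_node <- function(i, j) {            # i ring (1..n_rings), j sector wrapped
    1L + (i - 1L) * n_sectors + ((j - 1L) %% n_sectors) + 1L
  }
  j <- seq_len(n_sectors)
  tri <- tibble(n1 = 1L, n2 = ring_node(1L, j), n3 = ring_node(1L, j + 1L),
                n4 = NA_integer_, type = "tri3")
  quads <- purrr::map_dfr(seq_len(n_rings - 1L), function(i) {
    tibble(n1 = ring_node(i, j), n2 = ring_node(i + 1L, j),
           n3 = ring_node(i + 1L, j + 1L), n4 = ring_node(i, j + 1L),
           type = "quad4")
  })
  elements <- dplyr::bind_rows(tri, quads)
  elements$element <- seq_len(nrow(elements))
  elements <- elements[, c("element", "n1", "n2", "n3", "n4", "type")]

  mesh <- structure(
    list(nodes = nodes, elements = elements, h_z = h_z, centroid = ctr),
    class = "perfusion_mesh"
  )
  check_mesh_jacobians(mesh)
  mesh
}

#' Structured rectangular mesh
#'
#' A quad mesh of an `nx` x `ny` grid over `[0, width] x [0, height]`; used
#' for strip and slab verification problems where the analytic solution is
#' one-dimensional.
#'
#' @param width,height side lengths (um).
#' @param nx,ny element counts per side.
#' @param h_z out-of-plane thickness (um).
#' @return a `perfusion_mesh` (all outer nodes flagged `boundary`).
#' @export
mesh_rectangle <- function(width, height, nx = 10L, ny = 1L, h_z = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (width <= 0 || height <= 0 || nx < 1L || ny < 1L) {
    abort("Rectangle dimensions and element counts must be positive.")
  }
  xs <- seq(0, width, length.out = nx + 1L)
  ys <- seq(0, height, length.out = ny + 1L)
  nodes <- tidyr::expand_grid(yi = seq_len(ny + 1L), xi = seq_len(nx + 1L))
  nodes$node <- seq_len(nrow(nodes))
  nodes$x <- xs[nodes$xi]; nodes$y <- ys[nodes$yi]
  nodes$boundary <- nodes$xi %in% c(1L, nx + 1L) | nodes$yi %in% c(1L, ny + 1L)
  nid <- function(xi, yi) (yi - 1L) * (nx + 1L) + xi
  g <- tidyr::expand_grid(yi = seq_len(ny), xi = seq_len(nx))
  elements <- tibble(
    element = seq_len(nrow(g)),
    n1 = nid(g$xi, g$yi), n2 = nid(g$xi + 1L, g$yi),
    n3 = nid(g$xi + 1L, g$yi + 1L), n4 = nid(g$xi, g$yi + 1L),
    type = "quad4"
  )
  structure(
    list(nodes = nodes[, c("node", "x", "y", "boundary")],
         elements = elements, h_z = h_z,
         centroid = c(width / 2, height / 2)),
    class = "perfusion_mesh"
  )
}

#' @export
print.perfusion_mesh <- function(x, ...) {
  cat(sprintf("<perfusion_mesh> %d nodes, %d elements (%d tri, %d quad), h_z = %g um\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$elements$type == "tri3"), sum(x$elements$type == "quad4"),
              x$h_z))
  invisible(x)
}

#' Mesh accessors and measures
#'
#' `mesh_nodes()` / `mesh_elements()` return the node and element tables;
#' `element_areas()` the per-element areas (um^2); `mesh_area()` their sum;
#' `element_centres()` element centroids with areas.
#'
#' @param mesh a `perfusion_mesh`.
#' @return tibbles, or a numeric vector for `element_areas()` / scalar for
#'   `mesh_area()`.
#' @export
mesh_nodes <- function(mesh) mesh$nodes

#' @rdname mesh_nodes
#' @export
mesh_elements <- function(mesh) mesh$elements

#' @rdname mesh_nodes
#' @export
element_areas <- function(mesh) {
  M <- element_index_matrix(mesh)
  x <- mesh$nodes$x; y <- mesh$nodes$y
  vapply(seq_len(nrow(M)), function(e) {
    nn <- matrix_node_ids(M, e)
    abs(signed_area(x[nn], y[nn]))
  }, numeric(1))
}

#' @rdname mesh_nodes
#' @export
mesh_area <- function(mesh) sum(element_areas(mesh))

#' @rdname mesh_nodes
#' @export
element_centres <- function(mesh) {
  M <- element_index_matrix(mesh)
  x <- mesh$nodes$x; y <- mesh$nodes$y
  ctr <- t(vapply(seq_len(nrow(M)), function(e) {
    nn <- matrix_node_ids(M, e)
    c(mean(x[nn]), mean(y[nn]))
  }, numeric(2)))
  tibble(element = mesh$elements$element, x = ctr[, 1], y = ctr[, 2],
         area = element_areas(mesh))
}

element_node_ids <- function(elrow) {
  nn <- c(elrow$n1, elrow$n2, elrow$n3, elrow$n4)
  nn[!is.na(nn)]
}

# plain integer matrix of element connectivity (fast row access)
element_index_matrix <- function(mesh) {
  as.matrix(mesh$elements[, c("n1", "n2", "n3", "n4")])
}

matrix_node_ids <- function(M, e) {
  nn <- M[e, ]
  nn[!is.na(nn)]
}

# positive Jacobian at every quadrature point of every element
check_mesh_jacobians <- function(mesh) {
  M <- element_index_matrix(mesh)
  x <- mesh$nodes$x; y <- mesh$nodes$y
  for (e in seq_len(nrow(M))) {
    nn <- matrix_node_ids(M, e)
    dets <- element_jacobians(cbind(x[nn], y[nn]))
    if (any(dets <= 0)) {
      abort(sprintf("Element %d has a non-positive Jacobian.",
                    mesh$elements$element[e]))
    }
  }
  invisible(TRUE)
}

# Jacobian determinants at the element's quadrature points
element_jacobians <- function(xy) {
  if (nrow(xy) == 3L) {
    J <- rbind(xy[2, ] - xy[1, ], xy[3, ] - xy[1, ])
    return(det(J))
  }
  g <- 1 / sqrt(3)
  pts <- rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g))
  vapply(seq_len(4), function(q) {
    dN <- quad_shape_deriv(pts[q, 1], pts[q, 2])
    det(t(dN) %*% xy)
  }, numeric(1))
}

# derivatives (4 x 2) of bilinear shape functions wrt (xi, eta);
# node order (-1,-1), (1,-1), (1,1), (-1,1)
quad_shape_deriv <- function(xi, eta) {
  0.25 * cbind(
    c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
    c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
  )
}

quad_shape_fun <- function(xi, eta) {
  0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
}
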