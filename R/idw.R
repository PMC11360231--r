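#' Inverse-distance-weighted interpolation
#'
#' Shepard interpolation: the value at a query point is the weighted mean of
#' sample values with weights `|q - x_i|^(-power)`. A query coinciding with a
#' sample (within `tol`) returns that sample's value (the limiting
#' convention), so the interpolant is exact at samples and always bounded by
#' the sample extrema. With `k` set, only the `k` nearest samples enter the
#' weighting — the variant used for mesh-to-mesh field transfer.
#'
#' @param samples tibble with `x`, `y` and one or more value columns.
#' @param queries tibble with `x`, `y`.
#' @param power positive IDW exponent (default 2).
#' @param k optional number of nearest neighbours (default: all samples).
#' @param tol distance below which a query is considered on a sample.
#' @return tibble: `queries`' coordinates plus interpolated value columns.
#' @examples
#' s <- tibble::tibble(x = c(0, 1), y = 0, v = c(0, 10))
#' idw_interpolate(s, tibble::tibble(x = 0.5, y = 0))$v # 5
#' @export
idw_interpolate <- function(samples, queries, power = 2, k = NULL,
                            tol = 1e-9) {
  if (!is.data.frame(samples) || nrow(samples) < 1L ||
      !all(c("x", "y") %in% names(samples))) {
    abort("`samples` must have >= 1 row and columns x, y plus values.")
  }
  if (!all(c("x", "y") %in% names(queries))) {
    abort("`queries` must have columns x, y.")
  }
  if (!is.numeric(power) || power <= 0) abort("`power` must be > 0.")
  valcols <- setdiff(names(samples), c("x", "y"))
  if (length(valcols) == 0L) abort("`samples` has no value columns.")

  # duplicated sample locations must agree
  key <- paste(signif(samples$x, 12), signif(samples$y, 12))
  if (anyDuplicated(key)) {
    for (vc in valcols) {
      rng <- tapply(samples[[vc]], key, function(v) diff(range(v)))
      if (any(rng > tol, na.rm = TRUE)) {
        abort("Duplicate sample points with conflicting values.")
      }
    }
  }

  sx <- samples$x; sy <- samples$y
  n <- length(sx)
  kk <- if (is.null(k)) n else min(as.integer(k), n)
  vals <- as.matrix(samples[valcols])
  out <- matrix(NA_real_, nrow(queries), length(valcols))
  for (q in seq_len(nrow(queries))) {
    d <- sqrt((sx - queries$x[q])^2 + (sy - queries$y[q])^2)
    if (min(d) <= tol) {
      out[q, ] <- vals[which.min(d), ]
      next
    }
    use <- if (kk < n) order(d)[seq_len(kk)] else seq_len(n)
    w <- d[use]^(-power)
    for (j in seq_along(valcols)) {
      vj <- vals[use, j]
      ok <- !is.na(vj)
      out[q, j] <- if (any(ok)) sum(w[ok] * vj[ok]) / sum(w[ok]) else NA_real_
    }
  }
  res <- tibble(x = queries$x, y = queries$y)
  for (j in seq_along(valcols)) res[[valcols[j]]] <- out[, j]
  res
}

#' Transfer nodal fields between meshes
#'
#' Carries nodal fields from one mesh to another by k-nearest
#' inverse-distance weighting (default `k = 4`), the remeshing transfer used
#' by the time-course driver so that values from the previous time point's
#' mesh are available on the next one. Constant fields are preserved
#' exactly; values never overshoot the old field's range.
#'
#' @param old_mesh,new_mesh `perfusion_mesh` objects.
#' @param fields tibble of nodal values on `old_mesh` (one row per node, in
#'   node order), or a named list / data frame of columns.
#' @param k neighbours used per query node.
#' @param power IDW exponent.
#' @return tibble with `node`, `x`, `y` of `new_mesh` plus the field columns.
#' @export
transfer_fields <- function(old_mesh, fields, new_mesh, k = 4L, power = 2) {
  fields <- as_tibble(fields)
  if (nrow(old_mesh$nodes) == 0L) abort("`old_mesh` has no nodes.")
  if (nrow(fields) != nrow(old_mesh$nodes)) {
    abort("`fields` must have one row per node of `old_mesh`.")
  }
  samples <- dplyr::bind_cols(old_mesh$nodes[, c("x", "y")], fields)
  res <- idw_interpolate(samples, new_mesh$nodes[, c("x", "y")],
                         power = power, k = k)
  dplyr::bind_cols(new_mesh$nodes[, "node"], res)
}
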