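# P1 finite-element solution of the electrostatic Laplace equation
# on the liquid cross-section: phi = +V/2 on one electrode, -V/2 on the
# other (Dirichlet), zero normal flux on the insulating well wall
# (natural Neumann). The medium is treated as purely conductive and
# quasi-static, so the solve is conductivity-independent and linear in
# the applied voltage.

# per-triangle shape-function gradient coefficients and areas
tri_gradients <- function(mesh) {
  p <- mesh$nodes; tri <- mesh$triangles
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  # grad N_i = (b_i, c_i) / (2A)
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  area <- (c3 * b2 - c2 * b3) / 2  # = ((x2-x1)(y3-y1)-(x3-x1)(y2-y1))/2
  list(b = cbind(b1, b2, b3), c = cbind(c1, c2, c3), area = area)
}

# sparse P1 stiffness matrix for the unit-conductivity Laplacian
assemble_stiffness <- function(mesh) {
  g <- tri_gradients(mesh)
  tri <- mesh$triangles
  n <- nrow(mesh$nodes)
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (r in 1:3) {
    for (s in 1:3) {
      k <- k + 1
      ii[[k]] <- tri[, r]
      jj[[k]] <- tri[, s]
      vv[[k]] <- (g$b[, r] * g$b[, s] + g$c[, r] * g$c[, s]) / (4 * g$area)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(n, n))
}

# node indices carrying each electrode's Dirichlet condition
electrode_nodes <- function(mesh, tag) {
  be <- mesh$boundary_edges
  sort(unique(c(be$n1[be$tag == tag], be$n2[be$tag == tag])))
}

#' Solve the electrostatic potential in the well
#'
#' Piecewise-linear (P1) finite-element solution of `Laplace(phi) = 0`
#' with `phi = +V/2` on the `electrode_pos` boundary, `phi = -V/2` on
#' `electrode_neg`, and zero normal flux on the wall. The electric field
#' `E = -grad(phi)` is constant per triangle; a nodal field is also
#' recovered by area-weighted averaging over the triangles incident to
#' each node (used for point queries and the centerline profile).
#'
#' @param mesh A [generate_mesh()] or [parallel_plate_mesh()] result.
#' @param voltage_difference Applied electrode voltage difference V (V).
#' @return An object of class `potential_field`: list with `mesh`, `phi`
#'   (per node, V), `efield` (m x 2, V/m, per triangle),
#'   `nodal_efield` (n x 2), `voltage_difference`, and `flux` (the
#'   consistent boundary flux integral of `grad(phi) . n` over each
#'   electrode, used for currents).
#' @export
solve_potential <- function(mesh, voltage_difference) {
  stopifnot(inherits(mesh, "well_mesh"), is.finite(voltage_difference))
  pos <- electrode_nodes(mesh, "electrode_pos")
  neg <- electrode_nodes(mesh, "electrode_neg")
  if (length(pos) == 0 || length(neg) == 0) {
    stop("configuration error: mesh lacks an electrode_pos or ",
         "electrode_neg boundary tag", call. = FALSE)
  }
  n <- nrow(mesh$nodes)
  K <- assemble_stiffness(mesh)
  phi <- numeric(n)
  phi[pos] <- voltage_difference / 2
  phi[neg] <- -voltage_difference / 2
  dir <- c(pos, neg)
  free <- setdiff(seq_len(n), dir)
  if (length(free) > 0 && voltage_difference != 0) {
    rhs <- -(K[free, dir, drop = FALSE] %*% phi[dir])
    phi[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  }
  g <- tri_gradients(mesh)
  tri <- mesh$triangles
  p1 <- phi[tri[, 1]]; p2 <- phi[tri[, 2]]; p3 <- phi[tri[, 3]]
  ex <- -(g$b[, 1] * p1 + g$b[, 2] * p2 + g$b[, 3] * p3) / (2 * g$area)
  ey <- -(g$c[, 1] * p1 + g$c[, 2] * p2 + g$c[, 3] * p3) / (2 * g$area)
  efield <- cbind(ex = ex, ey = ey)

  # area-weighted nodal recovery of the per-triangle field
  wsum <- numeric(n); nex <- numeric(n); ney <- numeric(n)
  for (v in 1:3) {
    idx <- tri[, v]
    wsum <- wsum + tabulate_add(idx, g$area, n)
    nex <- nex + tabulate_add(idx, g$area * ex, n)
    ney <- ney + tabulate_add(idx, g$area * ey, n)
  }
  nodal <- cbind(ex = nex / wsum, ey = ney / wsum)

  # consistent flux: residual of the full stiffness system at the
  # Dirichlet nodes equals the boundary integral of grad(phi) . n
  r <- as.numeric(K %*% phi)
  flux <- c(electrode_pos = sum(r[pos]), electrode_neg = sum(r[neg]))

  structure(
    list(mesh = mesh, phi = phi, efield = efield, nodal_efield = nodal,
         voltage_difference = voltage_difference, flux = flux),
    class = "potential_field"
  )
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Rescale a solved field to a different voltage
#'
#' The Laplace problem is linear in the applied voltage, so a solution
#' at one voltage yields any other by scalar multiplication without a
#' re-solve.
#'
#' @param field A [solve_potential()] result.
#' @param new_voltage Target voltage difference (V).
#' @return A `potential_field` at the new voltage.
#' @export
scale_to_voltage <- function(field, new_voltage) {
  stopifnot(inherits(field, "potential_field"))
  if (field$voltage_difference == 0) {
    stop("invalid scale: the field was solved at zero voltage difference",
         call. = FALSE)
  }
  s <- new_voltage / field$voltage_difference
  field$phi <- field$phi * s
  field$efield <- field$efield * s
  field$nodal_efield <- field$nodal_efield * s
  field$flux <- field$flux * s
  field$voltage_difference <- new_voltage
  field
}

#' Analytic infinite-plate field
#'
#' In the ideal plate-capacitor limit (infinitely wide plates) the field
#' is uniform and equals the voltage difference over the gap.
#'
#' @param voltage_difference Applied voltage (V).
#' @param gap Electrode spacing (m).
#' @return Field strength in V/m.
#' @export
#' @examples
#' analytic_plate_field(1, 0.011)  # 90.91 V/m
analytic_plate_field <- function(voltage_difference, gap) {
  if (!is.finite(gap) || gap <= 0) {
    stop("invalid geometry: gap must be positive", call. = FALSE)
  }
  voltage_difference / gap
}

#' Evaluate the solved field at arbitrary points
#'
#' Locates each query point in the mesh and linearly interpolates the
#' potential and the recovered nodal electric field. Points outside the
#' liquid domain yield `NA`.
#'
#' @param field A [solve_potential()] result.
#' @param points Numeric n x 2 matrix of (x, y) coordinates in m.
#' @return data.frame with `x`, `y`, `ex`, `ey`, `phi`, `e_mag`.
#' @export
field_at <- function(field, points) {
  stopifnot(inherits(field, "potential_field"))
  pts <- matrix(points, ncol = 2)
  mesh <- field$mesh
  p <- mesh$nodes; tri <- mesh$triangles
  g <- tri_gradients(mesh)
  out <- matrix(NA_real_, nrow(pts), 4)
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  for (q in seq_len(nrow(pts))) {
    px <- pts[q, 1]; py <- pts[q, 2]
    d <- 2 * g$area
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / d
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / d
    l3 <- 1 - l1 - l2
    tol <- 1e-9
    hit <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (length(hit) == 0) next
    t0 <- hit[1]
    lam <- c(l1[t0], l2[t0], l3[t0])
    vs <- tri[t0, ]
    ex <- sum(lam * field$nodal_efield[vs, 1])
    ey <- sum(lam * field$nodal_efield[vs, 2])
    ph <- sum(lam * field$phi[vs])
    out[q, ] <- c(ex, ey, ph, sqrt(ex^2 + ey^2))
  }
  data.frame(x = pts[, 1], y = pts[, 2], ex = out[, 1], ey = out[, 2],
             phi = out[, 3], e_mag = out[, 4])
}

#' Field-strength profile along the inter-electrode centerline
#'
#' Samples |E| at equally spaced points on the segment joining the
#' midpoints of the two electrode faces (the line y = 0 from one inner
#' face to the other); the endpoints lie on the electrode faces.
#'
#' @param field A [solve_potential()] result on a chamber mesh.
#' @param n_samples Number of sample points (>= 3).
#' @return Class `centerline_profile`: data.frame with `position` (m,
#'   measured from the negative electrode face) and `e_mag` (V/m).
#' @export
centerline_profile <- function(field, n_samples = 101) {
  stopifnot(inherits(field, "potential_field"), n_samples >= 3)
  geom <- field$mesh$geometry
  if (is.null(geom)) {
    # generic mesh: use the extent of the electrode boundary in x
    a <- max(abs(field$mesh$nodes[unlist(field$mesh$boundary_edges[
      field$mesh$boundary_edges$tag == "electrode_pos", c("n1", "n2")]), 1]))
  } else {
    a <- geom$electrode_gap / 2
  }
  xs <- seq(-a, a, length.out = n_samples)
  vals <- field_at(field, cbind(xs, 0))
  structure(
    data.frame(position = xs + a, e_mag = vals$e_mag),
    class = c("centerline_profile", "data.frame")
  )
}

#' Area fraction of the liquid within a field-strength band
#'
#' Area-weighted fraction of the liquid cross-section whose per-element
#' field magnitude lies in `[band_low, band_high]` — the quantity the
#' field-homogeneity isoline maps summarize.
#'
#' @param field A [solve_potential()] result.
#' @param band_low,band_high Field band limits in V/m (`band_low <
#'   band_high`).
#' @return A fraction in [0, 1].
#' @export
homogeneity_fraction <- function(field, band_low, band_high) {
  stopifnot(inherits(field, "potential_field"), band_low < band_high)
  area <- abs(triangle_areas(field$mesh))
  e <- sqrt(field$efield[, 1]^2 + field$efield[, 2]^2)
  sum(area[e >= band_low & e <= band_high]) / sum(area)
}

#' Electrode current per unit depth
#'
#' In the 2D model the current carried per metre of liquid depth equals
#' the conductivity times the normal electric field integrated along one
#' electrode's wetted boundary. The integral is evaluated with the
#' consistent (residual-based) boundary-flux formulation, which is
#' superconvergent compared with pointwise gradient sampling.
#'
#' @param field A [solve_potential()] result.
#' @param conductivity Medium conductivity sigma in S/m.
#' @return Class `current_result`: list with `current_per_depth` (A/m,
#'   mean magnitude over the two electrodes), `conductivity`,
#'   `balance` (relative flux imbalance between electrodes, a
#'   discretization check), `voltage_difference`.
#' @export
electrode_current_per_depth <- function(field, conductivity) {
  stopifnot(inherits(field, "potential_field"))
  if (!is.finite(conductivity) || conductivity <= 0) {
    stop("conductivity must be positive", call. = FALSE)
  }
  i_pos <- conductivity * field$flux["electrode_pos"]
  i_neg <- conductivity * field$flux["electrode_neg"]
  mag <- (abs(i_pos) + abs(i_neg)) / 2
  balance <- if (mag > 0) abs(i_pos + i_neg) / mag else 0
  structure(
    list(current_per_depth = unname(mag),
         conductivity = conductivity,
         balance = unname(balance),
         voltage_difference = field$voltage_difference),
    class = "current_result"
  )
}

#' Total electrode current
#'
#' Scales the per-depth 2D current by the liquid fill level, and
#' linearly in conductivity from the value used when the current was
#' computed to the requested one.
#'
#' @param result An [electrode_current_per_depth()] result.
#' @param fill_level Liquid fill height h in m (> 0).
#' @param conductivity Conductivity at which to report the current
#'   (default: the one stored in `result`).
#' @return Total current in A.
#' @export
total_current <- function(result, fill_level,
                          conductivity = result$conductivity) {
  stopifnot(inherits(result, "current_result"))
  if (!is.finite(fill_level) || fill_level <= 0) {
    stop("fill_level must be positive", call. = FALSE)
  }
  result$current_per_depth * fill_level * conductivity / result$conductivity
}

#' Mesh-refinement self-convergence study
#'
#' Re-solves the chamber at a sequence of decreasing edge lengths and
#' reports the centerline midpoint field and the per-depth current at
#' unit conductivity for each resolution.
#'
#' @param geometry A [chamber_geometry()] object.
#' @param voltage Applied voltage difference (V).
#' @param edge_lengths Strictly decreasing vector (length >= 2) of
#'   target edge lengths in m.
#' @return data.frame with `edge_length`, `n_triangles`, `midpoint_e`
#'   (V/m) and `current_per_depth` (A/m at 1 S/m).
#' @export
convergence_study <- function(geometry, voltage, edge_lengths) {
  stopifnot(length(edge_lengths) >= 2, all(diff(edge_lengths) < 0))
  rows <- lapply(edge_lengths, function(h) {
    mesh <- generate_mesh(geometry, h)
    field <- solve_potential(mesh, voltage)
    mid <- field_at(field, cbind(0, 0))$e_mag
    i2d <- electrode_current_per_depth(field, 1)$current_per_depth
    data.frame(edge_length = h, n_triangles = nrow(mesh$triangles),
               midpoint_e = mid, current_per_depth = i2d)
  })
  do.call(rbind, rows)
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("Potential field: %d nodes, V = %g V\n",
              length(x$phi), x$voltage_difference))
  cat(sprintf("  phi range: [%.4g, %.4g] V\n", min(x$phi), max(x$phi)))
  emag <- sqrt(x$efield[, 1]^2 + x$efield[, 2]^2)
  cat(sprintf("  |E| range: [%.4g, %.4g] V/m\n", min(emag), max(emag)))
  invisible(x)
}
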