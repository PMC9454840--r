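# Multi-block structured triangulation of the liquid cross-section:
# the well disc minus the two electrode rectangles. Five blocks share
# conforming interfaces: the central inter-electrode rectangle, two
# curved caps behind the electrodes, and the two curved lens regions
# above/below the electrode span. 1D node distributions are graded so
# that edges near the electrode corners are ~4x shorter than the target
# edge length (the field is singular at re-entrant corners).

# graded subdivision of [0, L]: spacing ~ h in the interior, shrinking
# geometrically to h/ratio at a refined end; endpoints hit exactly.
graded_seq <- function(L, h, refine0 = FALSE, refine1 = FALSE,
                       ratio = 4, growth = 1.4) {
  stopifnot(L > 0, h > 0)
  end_spacings <- function(refine) {
    if (!refine) return(numeric(0))
    s <- h / ratio
    out <- numeric(0)
    while (s < h && sum(out) < L / 2) {
      out <- c(out, s)
      s <- s * growth
    }
    out
  }
  s0 <- end_spacings(refine0)
  s1 <- end_spacings(refine1)
  rem <- L - sum(s0) - sum(s1)
  if (rem <= 0) {
    n <- max(2L, ceiling(L / (h / ratio)))
    return(seq(0, L, length.out = n + 1L))
  }
  nmid <- max(1L, round(rem / h))
  spacings <- c(s0, rep(rem / nmid, nmid), rev(s1))
  pts <- cumsum(c(0, spacings))
  pts * (L / pts[length(pts)])
}

# triangulate a logical lattice of node ids (n1 x n2 matrix); cells are
# split along their shorter diagonal. Degenerate triangles (collapsed
# lattice columns on the curved blocks) are dropped by the caller.
lattice_triangles <- function(id, xx, yy) {
  n1 <- nrow(id); n2 <- ncol(id)
  if (n1 < 2 || n2 < 2) return(matrix(integer(0), ncol = 3))
  i <- rep(seq_len(n1 - 1L), n2 - 1L)
  j <- rep(seq_len(n2 - 1L), each = n1 - 1L)
  a <- id[cbind(i, j)]; b <- id[cbind(i + 1L, j)]
  c_ <- id[cbind(i + 1L, j + 1L)]; d <- id[cbind(i, j + 1L)]
  diag_ac <- (xx[a] - xx[c_])^2 + (yy[a] - yy[c_])^2
  diag_bd <- (xx[b] - xx[d])^2 + (yy[b] - yy[d])^2
  # split along the shorter diagonal; break (near-)ties by quadrant so
  # the triangulation is mirror-symmetric in both axes
  tie <- abs(diag_ac - diag_bd) <= 1e-9 * (diag_ac + diag_bd)
  ctr <- (xx[a] + xx[b] + xx[c_] + xx[d]) * (yy[a] + yy[b] + yy[c_] + yy[d])
  use_ac <- ifelse(tie, ctr >= 0, diag_ac < diag_bd)
  t1 <- ifelse(use_ac, a, a); t2 <- ifelse(use_ac, b, b)
  t3 <- ifelse(use_ac, c_, d)
  s1 <- ifelse(use_ac, a, b); s2 <- ifelse(use_ac, c_, c_)
  s3 <- ifelse(use_ac, d, d)
  rbind(cbind(t1, t2, t3), cbind(s1, s2, s3))
}

#' Triangulate the liquid cross-section of a stimulation well
#'
#' Generates a conforming triangular mesh of the well disc minus the two
#' electrode rectangles, with graded refinement (about 4x finer) near
#' the electrode corners and tagged boundary edges: `electrode_pos`
#' (plate at +V/2, on the +x side), `electrode_neg` (-x side) and
#' `wall` (insulating well perimeter). The construction is deterministic
#' and mirror-symmetric in both axes.
#'
#' @param geometry A [chamber_geometry()] object.
#' @param target_edge_length Nominal interior edge length in m
#'   (default 0.3 mm).
#' @return An object of class `well_mesh`: list with `nodes` (n x 2
#'   matrix, m), `triangles` (m x 3 integer matrix, counter-clockwise),
#'   `boundary_edges` (data.frame `n1`, `n2`, `tag`), `geometry`,
#'   `target_edge_length`.
#' @export
generate_mesh <- function(geometry, target_edge_length = 3e-4) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (!is.finite(target_edge_length) || target_edge_length <= 0) {
    stop("target_edge_length must be positive", call. = FALSE)
  }
  h <- target_edge_length
  R <- geometry$well_diameter / 2
  a <- geometry$electrode_gap / 2       # inner electrode face
  tt <- geometry$electrode_thickness
  b <- a + tt                           # outer electrode face
  w <- geometry$electrode_width / 2     # half plate width
  if (sqrt(b^2 + w^2) >= R) {
    stop("invalid geometry: electrode corners touch or cross the well wall",
         call. = FALSE)
  }
  xc <- sqrt(R^2 - w^2)                 # chord end at y = +/- w

  # shared 1D grids (refined toward electrode corners)
  sym0 <- function(L, h) graded_seq(L, h, TRUE, TRUE) - L / 2
  Xc <- sym0(2 * a, h)                            # [-a, a]
  Ye <- sym0(2 * w, h)                            # [-w, w]
  Xe <- graded_seq(tt, h, TRUE, TRUE)             # electrode top, [0, tt]
  cap_xi <- graded_seq(xc - b, h, TRUE, FALSE) / (xc - b)  # [0, 1]
  eta <- graded_seq(R - w, h, TRUE, FALSE) / (R - w)       # [0, 1]

  nodes_x <- numeric(0); nodes_y <- numeric(0)
  tris <- list()
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  add_nodes <- function(px, py) {
    ids <- integer(length(px))
    for (k in seq_along(px)) {
      key <- sprintf("%.9e_%.9e", round(px[k], 12), round(py[k], 12))
      id <- key_env[[key]]
      if (is.null(id)) {
        nodes_x[[length(nodes_x) + 1L]] <<- px[k]
        nodes_y[[length(nodes_y) + 1L]] <<- py[k]
        id <- length(nodes_x)
        key_env[[key]] <- id
      }
      ids[k] <- id
    }
    ids
  }
  add_block <- function(Xmat, Ymat) {
    ids <- matrix(add_nodes(as.vector(Xmat), as.vector(Ymat)),
                  nrow = nrow(Xmat))
    tris[[length(tris) + 1L]] <<- lattice_triangles(ids, nodes_x, nodes_y)
  }

  # central rectangle between the electrode faces
  add_block(outer(Xc, Ye, function(x, y) x),
            outer(Xc, Ye, function(x, y) y))

  # caps behind the electrodes: x from the outer face to the wall
  cap_x <- outer(cap_xi, Ye, function(xi, y) b + xi * (sqrt(R^2 - y^2) - b))
  cap_y <- outer(cap_xi, Ye, function(xi, y) y)
  add_block(cap_x, cap_y)
  add_block(-cap_x, cap_y)

  # lens above the electrode span: columns from the chord y = w up to the
  # wall; chord nodes must match the central/electrode-top/cap grids.
  cap_top <- b + cap_xi * (xc - b)
  chord_right <- c(a + Xe[-1], cap_top[-1])
  chord <- c(-rev(chord_right), Xc, chord_right)
  lens_x <- outer(chord, eta, function(x, e) x)
  lens_y <- outer(chord, eta, function(x, e) w + e * (sqrt(R^2 - x^2) - w))
  add_block(lens_x, lens_y)
  add_block(lens_x, -lens_y)

  nodes <- cbind(x = nodes_x, y = nodes_y)
  tri <- do.call(rbind, tris)

  # orient counter-clockwise, drop collapsed (zero-area) triangles
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  area2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  flip <- area2 < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  keep <- abs(area2) > 1e-12 * h^2
  tri <- tri[keep, , drop = FALSE]
  dimnames(tri) <- NULL

  boundary <- boundary_edges(tri)
  tag <- classify_boundary(nodes, boundary, R, a, b, w)

  structure(
    list(nodes = nodes, triangles = tri,
         boundary_edges = data.frame(n1 = boundary[, 1], n2 = boundary[, 2],
                                     tag = tag, stringsAsFactors = FALSE),
         geometry = geometry, target_edge_length = h),
    class = "well_mesh"
  )
}

# edges that belong to exactly one triangle
boundary_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e_sorted <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e_sorted[, 1], e_sorted[, 2])
  counts <- table(key)
  on_boundary <- counts[key] == 1
  unique(e_sorted[on_boundary, , drop = FALSE])
}

classify_boundary <- function(nodes, edges, R, a, b, w) {
  tol <- 1e-9
  on_circle <- function(i) abs(sqrt(nodes[i, 1]^2 + nodes[i, 2]^2) - R) < tol
  on_electrode <- function(i) {
    x <- abs(nodes[i, 1]); y <- abs(nodes[i, 2])
    x >= a - tol & x <= b + tol & y <= w + tol &
      (abs(x - a) < tol | abs(x - b) < tol | abs(y - w) < tol)
  }
  tag <- character(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (on_circle(i) && on_circle(j)) {
      tag[k] <- "wall"
    } else if (on_electrode(i) && on_electrode(j)) {
      mx <- (nodes[i, 1] + nodes[j, 1]) / 2
      tag[k] <- if (mx > 0) "electrode_pos" else "electrode_neg"
    } else {
      stop("internal error: untagged boundary edge at (",
           signif(nodes[i, 1], 4), ", ", signif(nodes[i, 2], 4), ")")
    }
  }
  tag
}

#' Rectangular parallel-plate mesh
#'
#' Uniform triangulation of a `width` x `height` rectangle whose left
#' and right sides are the two electrodes and whose top and bottom are
#' insulating walls. The exact parallel-plate solution (a linear
#' potential ramp, uniform field V/width) lies in the P1 space on this
#' mesh, which makes it the closed-form verification case for the
#' solver.
#'
#' @param width Electrode gap in m.
#' @param height Electrode (and wall) length in m.
#' @param target_edge_length Nominal edge length in m.
#' @return A `well_mesh` object (with `geometry = NULL`).
#' @export
parallel_plate_mesh <- function(width = 1, height = 1,
                                target_edge_length = 0.1) {
  h <- target_edge_length
  xs <- seq(-width / 2, width / 2, length.out = max(2L, ceiling(width / h)) + 1L)
  ys <- seq(-height / 2, height / 2,
            length.out = max(2L, ceiling(height / h)) + 1L)
  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(x = rep(xs, ny), y = rep(ys, each = nx))
  id <- matrix(seq_len(nx * ny), nrow = nx)
  tri <- lattice_triangles(id, nodes[, 1], nodes[, 2])
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  flip <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay) < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  edges <- boundary_edges(tri)
  tol <- 1e-12 * max(width, height)
  mid_x <- (nodes[edges[, 1], 1] + nodes[edges[, 2], 1]) / 2
  vertical <- abs(nodes[edges[, 1], 1] - nodes[edges[, 2], 1]) < tol
  tag <- ifelse(vertical & mid_x > 0, "electrode_pos",
                ifelse(vertical & mid_x < 0, "electrode_neg", "wall"))
  structure(
    list(nodes = nodes, triangles = tri,
         boundary_edges = data.frame(n1 = edges[, 1], n2 = edges[, 2],
                                     tag = tag, stringsAsFactors = FALSE),
         geometry = NULL, target_edge_length = h),
    class = "well_mesh"
  )
}

# signed areas of all triangles (positive for CCW orientation)
triangle_areas <- function(mesh) {
  p <- mesh$nodes; tri <- mesh$triangles
  ax <- p[tri[, 1], 1]; ay <- p[tri[, 1], 2]
  bx <- p[tri[, 2], 1]; by <- p[tri[, 2], 2]
  cx <- p[tri[, 3], 1]; cy <- p[tri[, 3], 2]
  ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

#' @export
print.well_mesh <- function(x, ...) {
  cat(sprintf("Triangular mesh: %d nodes, %d triangles\n",
              nrow(x$nodes), nrow(x$triangles)))
  cat("  boundary edges:",
      paste(sprintf("%s=%d", names(table(x$boundary_edges$tag)),
                    table(x$boundary_edges$tag)), collapse = ", "), "\n")
  invisible(x)
}
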