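# Hexahedral tissue mesh: construction, quadrature bookkeeping, point location.
#
# Conventions: physical coordinates in mm, 1-based node/element indexing in R,
# local (natural) coordinates in [-1,1]^3 on the standard trilinear hexahedron
# with VTK node ordering. The two opposite faces that carry the vessel inlets
# and outlets are tagged; all fields and the vascular network live on the
# reference (undeformed) configuration.

# VTK hexahedron local node coordinates
HEX_LC <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                   -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                 ncol = 3, byrow = TRUE)

# local edges of a hexahedron (pairs of local node indices)
HEX_EDGES <- matrix(c(1, 2, 2, 3, 3, 4, 4, 1,
                      5, 6, 6, 7, 7, 8, 8, 5,
                      1, 5, 2, 6, 3, 7, 4, 8), ncol = 2, byrow = TRUE)

#' Trilinear shape functions and local derivatives
#'
#' @param lc numeric(3) local coordinates in \code{[-1,1]^3}.
#' @return list with \code{N} (length 8) and \code{dN} (8 x 3 matrix of
#'   derivatives with respect to the local coordinates).
#' @keywords internal
shapeHex <- function(lc) {
  x <- lc[1]; y <- lc[2]; z <- lc[3]
  a <- HEX_LC
  N <- (1 + a[, 1] * x) * (1 + a[, 2] * y) * (1 + a[, 3] * z) / 8
  dN <- cbind(a[, 1] * (1 + a[, 2] * y) * (1 + a[, 3] * z),
              (1 + a[, 1] * x) * a[, 2] * (1 + a[, 3] * z),
              (1 + a[, 1] * x) * (1 + a[, 2] * y) * a[, 3]) / 8
  list(N = N, dN = dN)
}

# 2x2x2 Gauss quadrature points (weight 1 each), deterministic order
hexQuadPoints <- function() {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(x = c(-g, g), y = c(-g, g), z = c(-g, g)))
  dimnames(pts) <- NULL
  pts
}

#' Construct a hexahedral tissue mesh
#'
#' Builds the full mesh object (quadrature data, element sizes, bounding boxes)
#' from raw arrays. Used by the cube generator and the Gmsh reader.
#'
#' @param nodes N x 3 matrix of node coordinates (mm).
#' @param elems E x 8 integer matrix of hexahedron connectivity (VTK order).
#' @param label integer vector, 1 = host, 2 = tumour.
#' @param inlet_nodes,outlet_nodes node indices on the two tagged
#'   (inlet/outlet) boundary faces.
#' @return an object of class \code{angio_mesh}.
#' @export
hexMesh <- function(nodes, elems, label, inlet_nodes, outlet_nodes) {
  nodes <- as.matrix(nodes)
  storage.mode(elems) <- "integer"
  E <- nrow(elems); N <- nrow(nodes)
  if (length(label) != E) stopf("label length %d != %d elements", length(label), E)
  qp <- hexQuadPoints()
  nq <- nrow(qp)
  # per-qpt shape data
  shp <- lapply(seq_len(nq), function(q) shapeHex(qp[q, ]))
  # element node coordinates, arranged per axis: E x 8
  Xs <- lapply(1:3, function(d) matrix(nodes[elems, d], E, 8))
  gradN <- numeric(E * nq * 8 * 3)  # layout [e][q][a][d], C order
  dV <- matrix(0, nq, E)
  Nq <- matrix(0, nq, 8)            # shape values at qpts
  for (q in seq_len(nq)) {
    dN <- shp[[q]]$dN               # 8 x 3
    Nq[q, ] <- shp[[q]]$N
    # Jacobian J_{ij} = sum_a X[a,i] dN[a,j]  -> E x 9 (row-major i,j)
    J <- matrix(0, E, 9)
    for (i in 1:3) for (j in 1:3)
      J[, 3 * (i - 1) + j] <- Xs[[i]] %*% dN[, j]
    dJ <- J[, 1] * (J[, 5] * J[, 9] - J[, 6] * J[, 8]) -
          J[, 2] * (J[, 4] * J[, 9] - J[, 6] * J[, 7]) +
          J[, 3] * (J[, 4] * J[, 8] - J[, 5] * J[, 7])
    if (any(dJ <= 0))
      stopf("non-positive Jacobian in %d element(s); first: element %d",
            sum(dJ <= 0), which(dJ <= 0)[1])
    # inverse Jacobian (adjugate / det), row-major
    Ji <- cbind( (J[, 5] * J[, 9] - J[, 6] * J[, 8]),
                -(J[, 2] * J[, 9] - J[, 3] * J[, 8]),
                 (J[, 2] * J[, 6] - J[, 3] * J[, 5]),
                -(J[, 4] * J[, 9] - J[, 6] * J[, 7]),
                 (J[, 1] * J[, 9] - J[, 3] * J[, 7]),
                -(J[, 1] * J[, 6] - J[, 3] * J[, 4]),
                 (J[, 4] * J[, 8] - J[, 5] * J[, 7]),
                -(J[, 1] * J[, 8] - J[, 2] * J[, 7]),
                 (J[, 1] * J[, 5] - J[, 2] * J[, 4])) / dJ
    dV[q, ] <- dJ  # weight 1
    # grad_X N_a [a,i] = sum_j dN[a,j] * Jinv[j,i]
    for (a in 1:8) for (i in 1:3) {
      v <- dN[a, 1] * Ji[, 3 * 0 + i] + dN[a, 2] * Ji[, 3 * 1 + i] +
           dN[a, 3] * Ji[, 3 * 2 + i]
      # position in flattened gradN: ((e-1)*nq + (q-1))*24 + (a-1)*3 + i
      idx <- ((seq_len(E) - 1) * nq + (q - 1)) * 24 + (a - 1) * 3 + i
      gradN[idx] <- v
    }
  }
  volumes <- colSums(dV)
  centroids <- cbind(rowMeans(Xs[[1]]), rowMeans(Xs[[2]]), rowMeans(Xs[[3]]))
  # minimum edge length per element
  e2 <- 0
  for (k in seq_len(nrow(HEX_EDGES))) {
    d2 <- (Xs[[1]][, HEX_EDGES[k, 1]] - Xs[[1]][, HEX_EDGES[k, 2]])^2 +
          (Xs[[2]][, HEX_EDGES[k, 1]] - Xs[[2]][, HEX_EDGES[k, 2]])^2 +
          (Xs[[3]][, HEX_EDGES[k, 1]] - Xs[[3]][, HEX_EDGES[k, 2]])^2
    e2 <- if (k == 1) d2 else pmin(e2, d2)
  }
  elem_min_edge <- sqrt(e2)
  el_lo <- cbind(apply(Xs[[1]], 1, min), apply(Xs[[2]], 1, min), apply(Xs[[3]], 1, min))
  el_hi <- cbind(apply(Xs[[1]], 1, max), apply(Xs[[2]], 1, max), apply(Xs[[3]], 1, max))
  # boundary nodes: nodes on faces used by only one element
  faces_loc <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 1, 2, 6, 5,
                        2, 3, 7, 6, 3, 4, 8, 7, 4, 1, 5, 8), ncol = 4, byrow = TRUE)
  fl <- do.call(rbind, lapply(seq_len(6), function(f) {
    m <- elems[, faces_loc[f, ], drop = FALSE]
    cbind(m, seq_len(E))
  }))
  key <- apply(t(apply(fl[, 1:4, drop = FALSE], 1, sort)), 1, paste, collapse = "_")
  bnd <- fl[key %in% names(which(table(key) == 1)), 1:4, drop = FALSE]
  boundary_nodes <- sort(unique(as.vector(bnd)))
  mesh <- structure(list(
    nodes = nodes, elems = elems, label = as.integer(label),
    inlet_nodes = sort(unique(as.integer(inlet_nodes))),
    outlet_nodes = sort(unique(as.integer(outlet_nodes))),
    boundary_nodes = boundary_nodes, boundary_faces = bnd,
    quad = list(gradN = gradN, dV = as.numeric(dV), Nq = Nq, qp = qp),
    volumes = volumes, centroids = centroids,
    elem_min_edge = elem_min_edge, min_edge = min(elem_min_edge),
    el_lo = el_lo, el_hi = el_hi,
    bbox = rbind(apply(nodes, 2, min), apply(nodes, 2, max))
  ), class = "angio_mesh")
  mesh
}

#' @method print angio_mesh
#' @export
print.angio_mesh <- function(x, ...) {
  cat(sprintf("angio_mesh: %d nodes, %d hexahedra (%d tumour, %d host)\n",
              nrow(x$nodes), nrow(x$elems), sum(x$label == 2L), sum(x$label == 1L)))
  cat(sprintf("  bbox [%g,%g]x[%g,%g]x[%g,%g] mm, min edge %.4g mm\n",
              x$bbox[1, 1], x$bbox[2, 1], x$bbox[1, 2], x$bbox[2, 2],
              x$bbox[1, 3], x$bbox[2, 3], x$min_edge))
  invisible(x)
}

# symmetric sinh grading of [0, L] with n cells; g = 0 gives a uniform grid,
# g > 0 clusters nodes near the centre (where the tumour sits)
gradedAxis <- function(L, n, g) {
  s <- 2 * (0:n) / n - 1
  if (g <= 0) return(L * (0:n) / n)
  L / 2 * (1 + sinh(g * s) / sinh(g))
}

#' Generate a cubic tissue domain with a central spherical tumour
#'
#' Regular (or centre-graded) hexahedral mesh of a cube. Elements whose
#' centroid lies inside the centred sphere of the given diameter are labelled
#' tumour; the faces x = 0 and x = edge_length are tagged as the vessel
#' inlet/outlet faces.
#'
#' @param edge_length cube edge (mm), default 12.
#' @param n_per_side number of elements per side (>= 4).
#' @param tumour_diameter diameter of the central tumour sphere (mm); must be
#'   smaller than half the edge length. Zero gives an all-host mesh.
#' @param grading sinh grading strength (0 = uniform). Positive values refine
#'   the mesh towards the centre so a small tumour is resolved.
#' @return an \code{angio_mesh}.
#' @export
generateCubeMesh <- function(edge_length = 12, n_per_side = 16,
                             tumour_diameter = 1, grading = 4.6) {
  if (n_per_side < 4) stopf("n_per_side must be >= 4")
  if (tumour_diameter >= edge_length / 2)
    stopf("tumour_diameter must be < edge_length/2")
  n <- as.integer(n_per_side)
  ax <- gradedAxis(edge_length, n, grading)
  np <- n + 1L
  grid <- expand.grid(x = ax, y = ax, z = ax)  # x fastest
  nodes <- as.matrix(grid)
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + np * (j - 1L) + np * np * (k - 1L)
  cells <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  i <- cells$i; j <- cells$j; k <- cells$k
  elems <- cbind(nid(i, j, k),     nid(i + 1L, j, k),
                 nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                 nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                 nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  centre <- rep(edge_length / 2, 3)
  cx <- (ax[i] + ax[i + 1L]) / 2
  cy <- (ax[j] + ax[j + 1L]) / 2
  cz <- (ax[k] + ax[k + 1L]) / 2
  r2 <- (cx - centre[1])^2 + (cy - centre[2])^2 + (cz - centre[3])^2
  label <- ifelse(tumour_diameter > 0 & r2 < (tumour_diameter / 2)^2, 2L, 1L)
  inlet <- which(nodes[, 1] == 0)
  outlet <- which(nodes[, 1] == edge_length)
  mesh <- hexMesh(nodes, elems, label, inlet, outlet)
  attr(mesh, "axis_coords") <- ax  # enables fast lattice point location
  attr(mesh, "centre") <- centre
  attr(mesh, "tumour_diameter") <- tumour_diameter
  mesh
}

#' Locate points in the mesh
#'
#' Finds, for each query point, the hexahedron containing it and the local
#' (natural) coordinates within that element. Points on shared faces resolve
#' to the lowest adjacent element id; points outside the domain return NA
#' (used to freeze vessel tips at the boundary).
#'
#' @param points n x 3 matrix (or length-3 vector) of physical coordinates.
#' @param mesh an \code{angio_mesh}.
#' @return list with integer vector \code{elem} (NA outside) and n x 3 matrix
#'   \code{lc} of local coordinates.
#' @export
locateHostElement <- function(points, mesh) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  n <- nrow(points)
  elem <- rep(NA_integer_, n)
  lc <- matrix(NA_real_, n, 3)
  ax <- attr(mesh, "axis_coords")
  if (!is.null(ax)) {
    # tensor-product lattice: elements are axis-aligned boxes
    nc <- length(ax) - 1L
    ijk <- matrix(0L, n, 3)
    ok <- rep(TRUE, n)
    for (d in 1:3) {
      # left-open intervals so that a point on a shared face falls in the
      # lower-index (hence lowest-id) element
      idx <- findInterval(points[, d], ax, left.open = TRUE)
      idx[points[, d] == ax[1]] <- 1L
      ok <- ok & idx >= 1L & idx <= nc
      ijk[, d] <- idx
    }
    w <- which(ok)
    if (length(w)) {
      e <- ijk[w, 1] + nc * (ijk[w, 2] - 1L) + nc * nc * (ijk[w, 3] - 1L)
      elem[w] <- e
      for (d in 1:3) {
        lo <- ax[ijk[w, d]]; hi <- ax[ijk[w, d] + 1L]
        lc[w, d] <- 2 * (points[w, d] - lo) / (hi - lo) - 1
      }
    }
    return(list(elem = elem, lc = lc))
  }
  # generic mesh: bbox prefilter + Newton inversion of the trilinear map
  tol <- 1e-8
  for (p in seq_len(n)) {
    x <- points[p, ]
    cand <- which(mesh$el_lo[, 1] <= x[1] + tol & mesh$el_hi[, 1] >= x[1] - tol &
                  mesh$el_lo[, 2] <= x[2] + tol & mesh$el_hi[, 2] >= x[2] - tol &
                  mesh$el_lo[, 3] <= x[3] + tol & mesh$el_hi[, 3] >= x[3] - tol)
    for (e in cand) {  # ascending ids: first hit is the lowest id
      Xe <- mesh$nodes[mesh$elems[e, ], ]
      xi <- c(0, 0, 0)
      conv <- FALSE
      for (it in 1:20) {
        s <- shapeHex(xi)
        r <- drop(s$N %*% Xe) - x
        if (max(abs(r)) < 1e-12) { conv <- TRUE; break }
        J <- t(s$dN) %*% Xe  # dx_i/dxi_j = sum_a dN[a,j] X[a,i] -> [j,i]; transpose below
        xi <- xi - drop(solve(t(J), r))
      }
      if (conv && all(abs(xi) <= 1 + tol)) {
        elem[p] <- e
        lc[p, ] <- clamp(xi, -1, 1)
        break
      }
    }
  }
  list(elem = elem, lc = lc)
}

#' Interpolate a nodal field at points given by (element, local coords)
#' @keywords internal
fieldAtLocal <- function(field, mesh, elem, lc) {
  out <- rep(NA_real_, length(elem))
  w <- which(!is.na(elem))
  if (!length(w)) return(out)
  a <- HEX_LC
  # N (nw x 8) built vectorised
  Nm <- sapply(1:8, function(k)
    (1 + a[k, 1] * lc[w, 1]) * (1 + a[k, 2] * lc[w, 2]) * (1 + a[k, 3] * lc[w, 3]) / 8)
  if (is.null(dim(Nm))) Nm <- matrix(Nm, 1)
  fv <- matrix(field[mesh$elems[elem[w], , drop = FALSE]], length(w), 8)
  out[w] <- rowSums(Nm * fv)
  out
}

# interpolate a nodal vector field (N x 3) at (elem, lc) points
vectorFieldAtLocal <- function(field, mesh, elem, lc) {
  cbind(fieldAtLocal(field[, 1], mesh, elem, lc),
        fieldAtLocal(field[, 2], mesh, elem, lc),
        fieldAtLocal(field[, 3], mesh, elem, lc))
}

# gradient of a nodal scalar field at a single (elem, lc) point
gradientAtLocal <- function(field, mesh, elem, lc) {
  s <- shapeHex(lc)
  Xe <- mesh$nodes[mesh$elems[elem, ], ]
  fe <- field[mesh$elems[elem, ]]
  J <- t(s$dN) %*% Xe            # J[j,i] = dx_i/dxi_j
  drop(solve(J, drop(t(s$dN) %*% fe)))  # grad_x f = J^{-T}... see note
}
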