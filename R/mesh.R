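#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated boundary surface in mm. Vertices
#' are stored as an `n x 3` matrix in the anatomical frame (x medial->lateral,
#' y posterior->anterior, z distal->proximal), triangles as 1-based index
#' triplets with consistent outward orientation. Optional per-vertex region
#' labels (e.g. `"shaft"`, `"head"`) travel with the mesh and are preserved by
#' linear operations such as model instantiation.
#'
#' @param vertices Numeric `n x 3` matrix.
#' @param triangles Integer `m x 3` matrix of 1-based vertex indices.
#' @param regions Optional character vector of length `n`.
#' @param stations Optional integer vector of length `n`: cross-section
#'   (ring) index along the shaft for diaphyseal vertices, `NA` elsewhere.
#' @param frame Name of the coordinate convention.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, regions = NULL,
                         stations = NULL, frame = "anatomical_RAS_femur") {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop("vertices and triangles must have 3 columns")
  if (nrow(vertices) == 0 || nrow(triangles) == 0)
    stop("empty mesh")
  if (max(triangles) > nrow(vertices) || min(triangles) < 1)
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 regions = regions, stations = stations, frame = frame),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles (%s)\n",
              nrow(x$vertices), nrow(x$triangles), x$frame))
  invisible(x)
}

#' Tetrahedral mesh with per-cell intensity
#'
#' @param nodes Numeric `n x 3` matrix of node coordinates (mm).
#' @param tets Integer `m x 4` matrix of 1-based node indices, positively
#'   oriented.
#' @param cell_hu Optional numeric vector of per-cell Hounsfield units.
#' @param node_region,cell_region Optional region labels.
#' @param boundary Optional precomputed boundary (as from
#'   [tet_boundary()]); computed lazily otherwise.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, cell_hu = NULL, node_region = NULL,
                     cell_region = NULL, boundary = NULL) {
  nodes <- as.matrix(nodes)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3 || ncol(tets) != 4) stop("bad tet mesh dimensions")
  if (!is.null(cell_hu) && length(cell_hu) != nrow(tets))
    stop("cell_hu length must equal the number of tetrahedra")
  structure(list(nodes = nodes, tets = tets, cell_hu = cell_hu,
                 node_region = node_region, cell_region = cell_region,
                 boundary = boundary),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets%s\n", nrow(x$nodes), nrow(x$tets),
              if (is.null(x$cell_hu)) "" else " (with HU)"))
  invisible(x)
}

#' Signed volumes of tetrahedra
#' @param tm A `tet_mesh`.
#' @return Numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(tm) {
  a <- tm$nodes[tm$tets[, 1], , drop = FALSE]
  b <- tm$nodes[tm$tets[, 2], , drop = FALSE]
  c_ <- tm$nodes[tm$tets[, 3], , drop = FALSE]
  d <- tm$nodes[tm$tets[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Boundary triangles of a tetrahedral mesh
#'
#' Faces appearing in exactly one tetrahedron, oriented outward (normal
#' pointing away from the owning tet's fourth node).
#'
#' @param tm A `tet_mesh`.
#' @return List with `tri` (boundary triangles as node indices), `nodes`
#'   (boundary node indices) and `tri_local` (triangles reindexed over the
#'   boundary nodes).
#' @export
tet_boundary <- function(tm) {
  tets <- tm$tets
  nt <- nrow(tets)
  faceidx <- rbind(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 4, 2), c(2, 3, 4, 1))
  faces <- matrix(0L, 4L * nt, 3L)
  opp <- integer(4L * nt)
  owner <- integer(4L * nt)
  for (f in 1:4) {
    rows <- seq.int((f - 1L) * nt + 1L, f * nt)
    faces[rows, ] <- tets[, faceidx[f, 1:3], drop = FALSE]
    opp[rows] <- tets[, faceidx[f, 4]]
    owner[rows] <- seq_len(nt)
  }
  key <- apply(faces, 1L, function(r) paste(sort.int(r), collapse = "_"))
  cnt <- table(key)
  bidx <- which(cnt[key] == 1L)
  btri <- faces[bidx, , drop = FALSE]
  bopp <- opp[bidx]
  # orient outward: normal of (a,b,c) must point away from the opposite node
  a <- tm$nodes[btri[, 1], , drop = FALSE]
  b <- tm$nodes[btri[, 2], , drop = FALSE]
  c_ <- tm$nodes[btri[, 3], , drop = FALSE]
  d <- tm$nodes[bopp, , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  s <- (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
        u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
        u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1]))
  flip <- s > 0
  btri[flip, ] <- btri[flip, c(1, 3, 2), drop = FALSE]
  bnodes <- sort(unique(as.vector(btri)))
  remap <- integer(nrow(tm$nodes))
  remap[bnodes] <- seq_along(bnodes)
  tri_local <- matrix(remap[btri], ncol = 3)
  list(tri = btri, nodes = bnodes, tri_local = tri_local)
}

#' Extract the boundary surface of a tet mesh as a `surface_mesh`
#' @param tm A `tet_mesh`.
#' @return A `surface_mesh` whose vertices are the boundary nodes of `tm`.
#' @export
tet_surface <- function(tm) {
  bd <- tm$boundary %||% tet_boundary(tm)
  surface_mesh(tm$nodes[bd$nodes, , drop = FALSE], bd$tri_local,
               regions = if (!is.null(tm$node_region))
                 tm$node_region[bd$nodes] else NULL,
               stations = if (!is.null(tm$node_station))
                 tm$node_station[bd$nodes] else NULL)
}

# Structured tetrahedral mesh of a unit cube scaled to `size`, n cells per
# axis (6 tets per hex, conforming diagonals). Convex; used for Laplace
# morph verification.
cube_tet_mesh <- function(n = 3, size = 1) {
  g <- seq(0, size, length.out = n + 1)
  nodes <- unname(as.matrix(expand.grid(g, g, g))[, 1:3])
  id <- function(i, j, k) i + (n + 1) * (j - 1) + (n + 1)^2 * (k - 1)
  tets <- list()
  for (k in seq_len(n)) for (j in seq_len(n)) for (i in seq_len(n)) {
    n0 <- id(i, j, k); n1 <- id(i + 1, j, k); n2 <- id(i + 1, j + 1, k)
    n3 <- id(i, j + 1, k); n4 <- id(i, j, k + 1); n5 <- id(i + 1, j, k + 1)
    n6 <- id(i + 1, j + 1, k + 1); n7 <- id(i, j + 1, k + 1)
    tets[[length(tets) + 1]] <-
      rbind(c(n0, n1, n2, n6), c(n0, n2, n3, n6), c(n0, n3, n7, n6),
            c(n0, n7, n4, n6), c(n0, n4, n5, n6), c(n0, n5, n1, n6))
  }
  tm <- tet_mesh(nodes, do.call(rbind, tets))
  vol <- tet_volumes(tm)
  flip <- vol < 0
  tm$tets[flip, ] <- tm$tets[flip, c(1, 2, 4, 3), drop = FALSE]
  tm$boundary <- tet_boundary(tm)
  tm
}

# Generic swept solid: stations along a centreline with per-station frames
# (u, v) and elliptical radii (ra, rb), nr radial shells, nc angular samples.
# Node layout per station: 1 axis node then nr*nc shell nodes. Tetrahedra are
# generated with face-diagonal patterns that are consistent across cells so
# the mesh is conforming; orientation is fixed by construction and verified.
gencyl_solid <- function(centers, uax, vax, ra, rb, nr, nc) {
  ns <- nrow(centers)
  per <- 1L + nr * nc
  nodes <- matrix(0, ns * per, 3)
  phi <- 2 * pi * (seq_len(nc) - 1L) / nc
  cphi <- cos(phi); sphi <- sin(phi)
  for (i in seq_len(ns)) {
    base <- (i - 1L) * per
    nodes[base + 1L, ] <- centers[i, ]
    for (k in seq_len(nr)) {
      scale <- k / nr
      rows <- base + 1L + (k - 1L) * nc + seq_len(nc)
      nodes[rows, ] <- matrix(centers[i, ], nc, 3, byrow = TRUE) +
        scale * (outer(cphi * ra[i], uax[i, ]) + outer(sphi * rb[i], vax[i, ]))
    }
  }
  axis_id <- function(i) (i - 1L) * per + 1L
  shell_id <- function(i, k, j) {
    j <- ((j - 1L) %% nc) + 1L
    (i - 1L) * per + 1L + (k - 1L) * nc + j
  }
  tets <- vector("list", ns - 1L)
  for (i in seq_len(ns - 1L)) {
    a <- axis_id(i); b <- axis_id(i + 1L)
    j <- seq_len(nc)
    p1 <- shell_id(i, 1L, j);      p2 <- shell_id(i, 1L, j + 1L)
    q1 <- shell_id(i + 1L, 1L, j); q2 <- shell_id(i + 1L, 1L, j + 1L)
    # wedge between the axis edge and the first shell (3 tets each)
    wt <- rbind(cbind(a, p1, p2, b),
                cbind(p1, p2, q2, b),
                cbind(p1, q2, q1, b))
    ht <- NULL
    if (nr > 1L) {
      hx <- vector("list", nr - 1L)
      for (k in seq_len(nr - 1L)) {
        n0 <- shell_id(i, k, j);          n1 <- shell_id(i, k, j + 1L)
        n2 <- shell_id(i, k + 1L, j + 1L); n3 <- shell_id(i, k + 1L, j)
        n4 <- shell_id(i + 1L, k, j);      n5 <- shell_id(i + 1L, k, j + 1L)
        n6 <- shell_id(i + 1L, k + 1L, j + 1L)
        n7 <- shell_id(i + 1L, k + 1L, j)
        # 6-tet split around the n0-n6 diagonal (consistent across cells)
        hx[[k]] <- rbind(cbind(n0, n1, n2, n6), cbind(n0, n2, n3, n6),
                         cbind(n0, n3, n7, n6), cbind(n0, n7, n4, n6),
                         cbind(n0, n4, n5, n6), cbind(n0, n5, n1, n6))
      }
      ht <- do.call(rbind, hx)
    }
    tets[[i]] <- rbind(wt, ht)
  }
  tets <- do.call(rbind, tets)
  station <- rep(seq_len(ns), each = per)
  tm <- tet_mesh(nodes, tets)
  vol <- tet_volumes(tm)
  neg <- vol < 0
  if (any(neg))
    tm$tets[neg, ] <- tm$tets[neg, c(1, 2, 4, 3), drop = FALSE]
  vol <- abs(vol)
  if (any(vol <= 0)) stop("degenerate tetrahedra in swept solid")
  tm$node_station <- station
  tm
}
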