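# Area-weighted per-vertex normals.
vertex_normals <- function(V, Tr) {
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    idx <- Tr[, k]
    for (cc in 1:3) {
      acc <- rowsum(fn[, cc], idx)
      N[as.integer(rownames(acc)), cc] <-
        N[as.integer(rownames(acc)), cc] + acc
    }
  }
  len <- sqrt(rowSums(N^2)); len[len == 0] <- 1
  N / len
}

# Sparse tensor-product cubic B-spline basis over a box. K control points per
# axis (K >= 4); returns a dgCMatrix of n x K^3 basis weights.
bspline_basis_1d <- function(x, lo, hi, K) {
  pad <- 1e-9 * max(1, hi - lo)
  inner <- seq(lo - pad, hi + pad, length.out = K - 2)
  knots <- c(rep(inner[1], 3), inner, rep(inner[length(inner)], 3))
  splines::splineDesign(knots, pmin(pmax(x, lo), hi), ord = 4)
}

ffd_basis <- function(points, lo, hi, K) {
  n <- nrow(points)
  Bx <- bspline_basis_1d(points[, 1], lo[1], hi[1], K)
  By <- bspline_basis_1d(points[, 2], lo[2], hi[2], K)
  Bz <- bspline_basis_1d(points[, 3], lo[3], hi[3], K)
  trip_i <- vector("list", n); trip_j <- vector("list", n)
  trip_x <- vector("list", n)
  for (i in seq_len(n)) {
    jx <- which(Bx[i, ] != 0); jy <- which(By[i, ] != 0)
    jz <- which(Bz[i, ] != 0)
    grid <- expand.grid(jx = jx, jy = jy, jz = jz)
    w <- Bx[i, grid$jx] * By[i, grid$jy] * Bz[i, grid$jz]
    keep <- w != 0
    trip_i[[i]] <- rep.int(i, sum(keep))
    trip_j[[i]] <- ((grid$jz[keep] - 1) * K + (grid$jy[keep] - 1)) * K +
      grid$jx[keep]
    trip_x[[i]] <- w[keep]
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(n, K^3))
}

#' Free-form-deformation correspondence
#'
#' Morphs a (rigidly pre-aligned) reference mesh onto a target surface with a
#' coarse-to-fine multi-level cubic B-spline control lattice. At each level
#' the displacement of every reference vertex towards its closest point on
#' the target surface is approximated by a smooth B-spline field (ridge
#' least squares on the control lattice) and applied; refinement levels add
#' lattice resolution. The output mesh keeps the reference topology, so its
#' vertices provide a dense correspondence to the target.
#'
#' @param reference,target `surface_mesh` objects, rigidly pre-aligned.
#' @param grid Integer vector of control points per axis for each refinement
#'   level (coarse to fine).
#' @param iter_per_level Fitting iterations at each level.
#' @param lambda Ridge regularisation weight.
#' @param pre_affine Run a global affine point-to-plane ICP before the
#'   lattice fit (recommended; recovers global stretch such as bone length).
#' @return The corresponded `surface_mesh` (reference topology, deformed to
#'   the target), with attributes `level_distance` (mean symmetric surface
#'   distance after each level) and `final_distance`.
#' @export
correspond_ffd <- function(reference, target, grid = c(4, 6, 10),
                           iter_per_level = 3, lambda = 1e-4,
                           pre_affine = TRUE) {
  lo_r <- apply(reference$vertices, 2, min)
  hi_r <- apply(reference$vertices, 2, max)
  lo_t <- apply(target$vertices, 2, min)
  hi_t <- apply(target$vertices, 2, max)
  if (any(hi_r < lo_t) || any(hi_t < lo_r))
    stop("reference and target bounding boxes do not overlap; align first",
         call. = FALSE)
  cur <- reference$vertices
  tris <- reference$triangles
  sym_dist <- function(pts) {
    tmp <- reference; tmp$vertices <- pts
    mean_symmetric_distance(tmp, target)
  }
  best <- sym_dist(cur)
  # global affine pre-fit (point-to-plane ICP): captures overall stretch --
  # e.g. bone length -- which purely local closest-point matching cannot
  # observe on near-cylindrical surfaces
  if (pre_affine) {
    # deterministic initialisation: match per-axis extents about the
    # centroids (captures bone length immediately, avoiding the sliding
    # local minimum of closest-point matching on tubular shapes)
    ctr_c <- colMeans(cur); ctr_t <- colMeans(target$vertices)
    sc <- (hi_t - lo_t) / (apply(cur, 2, max) - apply(cur, 2, min))
    init <- sweep(sweep(sweep(cur, 2, ctr_c), 2, sc, "*"), 2, ctr_t, "+")
    d_init <- sym_dist(init)
    if (d_init < best) { cur <- init; best <- d_init }
    for (it in 1:15) {
      cp <- cpp_closest_point_mesh(cur, target$vertices, target$triangles)
      nrm <- vertex_normals(cur, tris)
      M <- cbind(nrm[, 1] * cur, nrm[, 2] * cur, nrm[, 3] * cur, nrm)
      rhs <- rowSums((cp$closest - cur) * nrm)
      th <- tryCatch(qr.solve(crossprod(M) + 1e-8 * diag(12),
                              crossprod(M, rhs)),
                     error = function(e) NULL)
      if (is.null(th)) break
      A <- diag(3) + matrix(th[1:9], 3, 3, byrow = TRUE)
      new_pts <- sweep(cur %*% t(A), 2, -th[10:12])
      d_new <- sym_dist(new_pts)
      if (d_new < best - 1e-8) { cur <- new_pts; best <- d_new } else break
    }
  }
  lvl_dist <- numeric(0)
  for (K in grid) {
    for (it in seq_len(iter_per_level)) {
      lo <- pmin(apply(cur, 2, min), lo_t) - 1
      hi <- pmax(apply(cur, 2, max), hi_t) + 1
      # forward correspondences constrain only the surface-normal component
      # (point to plane), so tangential stretch stays free and is set by the
      # smooth lattice; reverse correspondences (target vertices pulling
      # their nearest reference surface point) recover stretch at uncovered
      # regions such as the bone ends.
      cpf <- cpp_closest_point_mesh(cur, target$vertices, target$triangles)
      nrm <- vertex_normals(cur, tris)
      cpr <- cpp_closest_point_mesh(target$vertices, cur, tris)
      n <- nrow(cur); m <- nrow(target$vertices); K3 <- K^3
      Bf <- ffd_basis(cur, lo, hi, K)
      Br <- ffd_basis(cpr$closest, lo, hi, K)
      # unknowns vec(W) = (wx, wy, wz); forward rows couple the columns
      Af <- cbind(nrm[, 1] * Bf, nrm[, 2] * Bf, nrm[, 3] * Bf)
      bf <- rowSums((cpf$closest - cur) * nrm)
      Z <- Matrix::Matrix(0, m, K3, sparse = TRUE)
      Ar <- rbind(cbind(Br, Z, Z), cbind(Z, Br, Z), cbind(Z, Z, Br))
      br <- as.vector(target$vertices - cpr$closest)
      A <- rbind(Af, Ar)
      rhs <- c(bf, br)
      G <- Matrix::crossprod(A) + lambda * Matrix::Diagonal(3 * K3)
      w <- as.vector(Matrix::solve(G, Matrix::crossprod(A, rhs)))
      W <- matrix(w, K3, 3)
      new_pts <- cur + as.matrix(Bf %*% W)
      # accept only improving updates so level distances decrease
      d_new <- sym_dist(new_pts)
      if (d_new < best) { cur <- new_pts; best <- d_new } else break
    }
    lvl_dist <- c(lvl_dist, best)
  }
  out <- reference
  out$vertices <- cur
  attr(out, "level_distance") <- lvl_dist
  attr(out, "final_distance") <- lvl_dist[length(lvl_dist)]
  out
}
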