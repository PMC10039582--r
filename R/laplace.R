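# Linear tetrahedral FEM stiffness (Laplace) matrix. Piecewise-linear FEM
# reproduces affine fields exactly, which is the property the volumetric
# morph relies on.
tet_stiffness <- function(tm) {
  nt <- nrow(tm$tets)
  nn <- nrow(tm$nodes)
  ii <- integer(16 * nt); jj <- integer(16 * nt); xx <- numeric(16 * nt)
  pos <- 1L
  for (t in seq_len(nt)) {
    id <- tm$tets[t, ]
    v <- tm$nodes[id, , drop = FALSE]
    M <- cbind(1, v)
    Minv <- tryCatch(solve(M), error = function(e)
      stop("singular tetrahedron in stiffness assembly", call. = FALSE))
    G <- Minv[2:4, , drop = FALSE]          # gradients of the 4 hat functions
    vol <- abs(det(M)) / 6
    Ke <- vol * crossprod(G)
    idx <- pos:(pos + 15L)
    ii[idx] <- rep(id, each = 4)
    jj[idx] <- rep(id, times = 4)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 16L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
}

#' Morph a tetrahedral mesh by harmonic interior interpolation
#'
#' Moves the boundary nodes by the given displacements and solves a discrete
#' Laplace (linear-FEM) boundary-value problem per coordinate for the
#' interior nodes, so the interior follows the boundary smoothly. Affine
#' boundary displacements are reproduced affinely in the interior up to
#' solver tolerance.
#'
#' @param reference_tets A [tet_mesh()].
#' @param boundary_displacement Numeric `nb x 3` matrix of displacements for
#'   the boundary nodes, in the order of `tet_boundary(reference_tets)$nodes`.
#' @return The morphed `tet_mesh`; `attr(, "inverted_fraction")` reports the
#'   fraction of tetrahedra with non-positive volume after morphing.
#' @export
morph_tet_mesh <- function(reference_tets, boundary_displacement) {
  tm <- reference_tets
  bd <- tm$boundary %||% tet_boundary(tm)
  bn <- bd$nodes
  D <- as.matrix(boundary_displacement)
  if (nrow(D) != length(bn) || ncol(D) != 3)
    stop(sprintf("boundary_displacement must be %d x 3", length(bn)),
         call. = FALSE)
  nn <- nrow(tm$nodes)
  interior <- setdiff(seq_len(nn), bn)
  newnodes <- tm$nodes
  newnodes[bn, ] <- newnodes[bn, , drop = FALSE] + D
  if (length(interior)) {
    K <- tet_stiffness(tm)
    Kii <- K[interior, interior, drop = FALSE]
    Kib <- K[interior, bn, drop = FALSE]
    u <- tryCatch(
      as.matrix(Matrix::solve(Kii, -Kib %*% D)),
      error = function(e)
        stop("Laplace system is singular (disconnected mesh?)",
             call. = FALSE))
    newnodes[interior, ] <- newnodes[interior, , drop = FALSE] + u
  }
  out <- tm
  out$nodes <- newnodes
  vols <- tet_volumes(out)
  attr(out, "inverted_fraction") <- mean(vols <= 0)
  out
}
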