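#' Least-squares sphere fit
#'
#' Algebraic (linearised) fit: solve `|p|^2 = 2 p.c + (r^2 - |c|^2)` in the
#' least-squares sense.
#'
#' @param points `n x 3` matrix (n >= 4, non-coplanar).
#' @return List with `center`, `radius` (mm) and `rms` residual of
#'   `|p - c| - r`.
#' @export
fit_sphere <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 4) stop("need at least 4 points", call. = FALSE)
  A <- cbind(2 * P, 1)
  y <- rowSums(P^2)
  fit <- tryCatch(qr.solve(A, y), error = function(e)
    stop("degenerate (coplanar?) points for sphere fit", call. = FALSE))
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate (coplanar?) points for sphere fit", call. = FALSE)
  ctr <- fit[1:3]
  r2 <- fit[4] + sum(ctr^2)
  if (r2 <= 0) stop("sphere fit failed (non-positive radius)", call. = FALSE)
  r <- sqrt(r2)
  res <- sqrt(rowSums(sweep(P, 2, ctr)^2)) - r
  list(center = ctr, radius = r, rms = sqrt(mean(res^2)))
}

# Internal anatomical frame derived from the mesh itself via region labels,
# so every derived quantity is exactly equivariant under rigid motion:
# z' = principal axis of the shaft (towards the head), x' = medial->lateral
# from the condyle centroids, y' = z' x x'.
anatomical_frame <- function(mesh) {
  reg <- mesh$regions
  if (is.null(reg))
    stop("mesh has no region labels; supply landmarks instead", call. = FALSE)
  need <- c("shaft", "head", "condyle_med", "condyle_lat")
  for (nm in need)
    if (!any(reg == nm))
      stop(sprintf("region '%s' missing from mesh", nm), call. = FALSE)
  V <- mesh$vertices
  shaft <- V[reg == "shaft", , drop = FALSE]
  c_head <- colMeans(V[reg == "head", , drop = FALSE])
  c_med <- colMeans(V[reg == "condyle_med", , drop = FALSE])
  c_lat <- colMeans(V[reg == "condyle_lat", , drop = FALSE])
  e <- eigen(stats::cov(shaft), symmetric = TRUE)
  zax <- e$vectors[, 1]
  if (sum(zax * (c_head - (c_med + c_lat) / 2)) < 0) zax <- -zax
  x0 <- unit3(c_lat - c_med)
  yax <- unit3(cross3(zax, x0))
  xax <- cross3(yax, zax)
  list(x = xax, y = yax, z = unit3(zax),
       origin = (c_med + c_lat) / 2)
}

# centroid of vertices within `band` mm of the extremum of `values`
band_extreme <- function(V, values, side = c("max", "min"), band = 1.5) {
  side <- match.arg(side)
  s <- if (side == "max") values else -values
  sel <- s >= max(s) - band
  colMeans(V[sel, , drop = FALSE])
}

#' Derive the anatomical axis set from a mesh
#'
#' Computes the axes needed by [compute_measures()]: the femoral anatomical
#' (diaphyseal) axis as a line through shaft cross-section centroids
#' (cross-sections perpendicular to the current axis estimate, iterated to
#' convergence, restricted to the central 60% of the bone length), the
#' mechanical axis (head-sphere centre to knee centre), the neck axis
#' through neck cross-section centroids, the trans-epicondylar axis, the
#' posterior condylar axis and the distal condylar axis from band-extremal
#' condylar points. With an explicit `landmark_set` the analytic axes are
#' used instead ([landmark_axes()]).
#'
#' @param mesh A `surface_mesh` with region labels (phantoms and model
#'   instances carry them).
#' @param landmarks Optional `landmark_set` overriding the mesh heuristics.
#' @param n_slabs Number of diaphyseal cross-sections.
#' @return A list of axes; see [landmark_axes()] for the fields.
#' @export
derive_axes <- function(mesh, landmarks = NULL, n_slabs = 12) {
  if (!is.null(landmarks)) return(landmark_axes(landmarks))
  fr <- anatomical_frame(mesh)
  V <- mesh$vertices
  reg <- mesh$regions
  shaft <- V[reg == "shaft", , drop = FALSE]
  zall <- as.vector(V %*% fr$z)
  zmin <- min(zall); zmax <- max(zall)
  blen <- zmax - zmin
  # anatomical axis: iterate slab centroids + line fit
  # diaphyseal cross-section centroids. When the mesh carries shaft station
  # labels (fixed topology of the phantom family and its model instances)
  # the cross-sections are the exact mesh rings; otherwise fall back to
  # slabs perpendicular to the iterated axis estimate.
  st <- mesh$stations
  if (!is.null(st) && any(!is.na(st) & reg == "shaft")) {
    sel <- !is.na(st) & reg == "shaft"
    sv <- V[sel, , drop = FALSE]
    si <- st[sel]
    cnt <- as.vector(table(si))
    poly <- rowsum(sv, si) / cnt
    poly <- poly[order(as.integer(rownames(poly))), , drop = FALSE]
  } else {
    zs <- as.vector(shaft %*% fr$z)
    diap <- shaft[zs >= zmin + 0.2 * blen & zs <= zmin + 0.8 * blen, ,
                  drop = FALSE]
    if (nrow(diap) < 10) stop("diaphysis region unavailable", call. = FALSE)
    d <- fr$z
    poly <- NULL
    for (it in 1:5) {
      s <- as.vector(diap %*% d)
      br <- seq(min(s), max(s), length.out = n_slabs + 1)
      idx <- findInterval(s, br, rightmost.closed = TRUE)
      ctr <- t(sapply(seq_len(n_slabs), function(k) {
        selk <- idx == k
        if (sum(selk) < 3) return(c(NA, NA, NA))
        colMeans(diap[selk, , drop = FALSE])
      }))
      ctr <- ctr[stats::complete.cases(ctr), , drop = FALSE]
      if (nrow(ctr) < 2) stop("diaphysis region unavailable", call. = FALSE)
      ee <- eigen(stats::cov(ctr), symmetric = TRUE)
      dnew <- ee$vectors[, 1]
      if (sum(dnew * d) < 0) dnew <- -dnew
      conv <- vector_angle(dnew, d) < 1e-4
      d <- dnew
      poly <- ctr
      if (conv) break
    }
  }
  # axis direction: least-squares line through the centroids in the central
  # 60% of the bone length
  pz <- as.vector(poly %*% fr$z)
  band <- poly[pz >= zmin + 0.2 * blen & pz <= zmin + 0.8 * blen, ,
               drop = FALSE]
  if (nrow(band) < 2) stop("diaphysis region unavailable", call. = FALSE)
  ee <- eigen(stats::cov(band), symmetric = TRUE)
  d <- ee$vectors[, 1]
  if (sum(d * fr$z) < 0) d <- -d
  anat <- list(point = colMeans(band), direction = unit3(d))
  # head
  headfit <- fit_sphere(V[reg == "head", , drop = FALSE])
  # condylar landmarks (band-extremal centroids in the internal frame)
  med <- V[reg == "condyle_med", , drop = FALSE]
  lat <- V[reg == "condyle_lat", , drop = FALSE]
  if (!nrow(med) || !nrow(lat))
    stop("condylar region unavailable for distal axes", call. = FALSE)
  epi_m <- band_extreme(med, as.vector(med %*% fr$x), "min")
  epi_l <- band_extreme(lat, as.vector(lat %*% fr$x), "max")
  post_m <- band_extreme(med, as.vector(med %*% fr$y), "min", band = 1)
  post_l <- band_extreme(lat, as.vector(lat %*% fr$y), "min", band = 1)
  dist_m <- band_extreme(med, as.vector(med %*% fr$z), "min", band = 1)
  dist_l <- band_extreme(lat, as.vector(lat %*% fr$z), "min", band = 1)
  knee <- (epi_m + epi_l) / 2
  # neck axis through neck cross-section centroids
  neck <- V[reg == "neck", , drop = FALSE]
  if (!nrow(neck)) stop("neck region unavailable", call. = FALSE)
  nd <- unit3(headfit$center - colMeans(neck))
  for (it in 1:3) {
    sn <- as.vector(neck %*% nd)
    brn <- seq(min(sn), max(sn), length.out = 7)
    idx <- findInterval(sn, brn, rightmost.closed = TRUE)
    nctr <- t(sapply(1:6, function(k) {
      sel <- idx == k
      if (sum(sel) < 3) return(c(NA, NA, NA))
      colMeans(neck[sel, , drop = FALSE])
    }))
    nctr <- nctr[stats::complete.cases(nctr), , drop = FALSE]
    ee <- eigen(stats::cov(nctr), symmetric = TRUE)
    ndn <- ee$vectors[, 1]
    if (sum(ndn * nd) < 0) ndn <- -ndn
    nd <- ndn
  }
  list(anatomical = anat, anatomical_poly = poly,
       mechanical = list(point = knee,
                         direction = unit3(headfit$center - knee)),
       neck = list(point = colMeans(neck), direction = nd),
       tea = unit3(epi_l - epi_m),
       pca_condylar = unit3(post_l - post_m),
       distal_condylar = unit3(dist_l - dist_m),
       head_center = headfit$center, head_radius = headfit$radius)
}

#' Anatomical measures of a femur mesh
#'
#' Computes the measures used to judge reconstructions: the bow angle (3D
#' angle between tangents at the proximal and distal ends of the diaphyseal
#' centroid polyline, tangents of a cubic fit evaluated at the 10%/90%
#' stations), the angle between the femoral anatomical and mechanical axes,
#' the femoral neck angle (neck axis vs distal diaphyseal direction), the
#' diaphyseal--condylar angle, version angles of the neck axis against the
#' posterior condylar and trans-epicondylar axes projected onto the
#' transverse plane (perpendicular to the anatomical axis), and the femoral
#' head radius from a least-squares sphere fit.
#'
#' @param mesh A `surface_mesh` with regions, or a `phantom`.
#' @param axes Optional axis set from [derive_axes()] / [landmark_axes()].
#' @return An object of class `anat_measures`: named list of six angles
#'   (degrees) and `head_radius` (mm).
#' @export
compute_measures <- function(mesh, axes = NULL) {
  if (inherits(mesh, "phantom")) mesh <- mesh$mesh
  axes <- axes %||% derive_axes(mesh)
  a <- axes$anatomical$direction
  # bow from a cubic fit to the centroid polyline
  pl <- axes$anatomical_poly
  s <- as.vector(pl %*% a)
  s01 <- (s - min(s)) / (max(s) - min(s))
  X <- cbind(1, s01, s01^2, s01^3)
  cf <- qr.solve(X, pl)                       # 4 x 3 cubic coefficients
  tang <- function(t0) as.vector(c(0, 1, 2 * t0, 3 * t0^2) %*% cf)
  bow <- vector_angle(tang(0.1), tang(0.9))
  faa_fma <- vector_angle(a, axes$mechanical$direction, line = TRUE)
  neck <- vector_angle(axes$neck$direction, -a)
  dca <- vector_angle(axes$distal_condylar, a, line = TRUE)
  proj <- function(v) v - sum(v * a) * a
  version_pca <- vector_angle(proj(axes$neck$direction),
                              proj(axes$pca_condylar), line = TRUE)
  version_tea <- vector_angle(proj(axes$neck$direction),
                              proj(axes$tea), line = TRUE)
  structure(list(bow_angle = bow, faa_fma_angle = faa_fma,
                 neck_angle = neck, diaphyseal_condylar_angle = dca,
                 version_pca = version_pca, version_tea = version_tea,
                 head_radius = axes$head_radius),
            class = "anat_measures")
}

#' @export
print.anat_measures <- function(x, ...) {
  cat("anatomical measures:\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %8.3f %s\n", nm, x[[nm]],
                if (nm == "head_radius") "mm" else "deg"))
  invisible(x)
}

#' Surface root-mean-square error
#'
#' Rigidly aligns the reconstruction to the truth (ICP) and returns the RMS
#' over reconstruction vertices of the distance to the nearest point on the
#' truth surface (point to triangle).
#'
#' @param recon,truth `surface_mesh` objects.
#' @param align Run the ICP alignment first? (default `TRUE`).
#' @return RMSE in mm.
#' @export
surface_rmse <- function(recon, truth, align = TRUE) {
  if (align) recon <- rigid_align(recon, truth)$aligned
  d <- cpp_closest_point_mesh(recon$vertices, truth$vertices,
                              truth$triangles)$dist
  sqrt(mean(d^2))
}

#' Symmetric Hausdorff distance between surfaces
#'
#' Maximum point-to-surface distance over both directions, after the same
#' rigid alignment as [surface_rmse()].
#'
#' @inheritParams surface_rmse
#' @return Hausdorff distance in mm (always >= the RMSE).
#' @export
hausdorff <- function(recon, truth, align = TRUE) {
  if (align) recon <- rigid_align(recon, truth)$aligned
  d1 <- cpp_closest_point_mesh(recon$vertices, truth$vertices,
                               truth$triangles)$dist
  d2 <- cpp_closest_point_mesh(truth$vertices, recon$vertices,
                               recon$triangles)$dist
  max(max(d1), max(d2))
}

#' Score a reconstruction against ground truth
#'
#' Bundles the surface RMSE, the symmetric Hausdorff distance and the
#' absolute differences of every anatomical measure between reconstruction
#' and truth (both measured by the same mesh-based algorithm).
#'
#' @param recon,truth `surface_mesh` objects (or phantoms).
#' @param metadata Named list recorded verbatim (defect level, metric, ...).
#' @param truth_measures Optional precomputed `compute_measures(truth)`,
#'   useful when one truth is scored against many reconstructions.
#' @return An object of class `eval_report`.
#' @export
evaluate_case <- function(recon, truth, metadata = list(),
                          truth_measures = NULL) {
  if (inherits(recon, "phantom")) recon <- recon$mesh
  if (inherits(truth, "phantom")) truth <- truth$mesh
  al <- rigid_align(recon, truth)
  aligned <- al$aligned
  d <- cpp_closest_point_mesh(aligned$vertices, truth$vertices,
                              truth$triangles)$dist
  rmse <- sqrt(mean(d^2))
  d2 <- cpp_closest_point_mesh(truth$vertices, aligned$vertices,
                               aligned$triangles)$dist
  hd <- max(max(d), max(d2))
  mr <- compute_measures(recon)
  mt <- truth_measures %||% compute_measures(truth)
  errs <- mapply(function(a, b) abs(a - b), unclass(mr), unclass(mt))
  structure(list(rmse = rmse, hausdorff = hd, measure_errors = errs,
                 alignment = al$transform, metadata = metadata),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation: RMSE %.3f mm, Hausdorff %.3f mm\n", x$rmse,
              x$hausdorff))
  for (nm in names(x$measure_errors))
    cat(sprintf("  |d %-24s| %8.3f\n", nm, x$measure_errors[[nm]]))
  invisible(x)
}
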