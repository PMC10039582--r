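#' Align a model contour to a target contour in 2D
#'
#' Pre-aligns by translating the model contour so its most proximal point
#' (smallest v; ties broken by the smaller u coordinate) coincides with the
#' target's, then refines with a 2D rigid iterative-closest-point search
#' (point to closest point, least-squares rotation+translation updates).
#'
#' @param model_contour,target_contour [contour_2d()] objects.
#' @param max_iter Maximum ICP iterations.
#' @param tol Stop when the RMS improvement drops below `tol` mm.
#' @return List with `rotation` (scalar radians), `cos`, `sin`, `translation`
#'   (length 2, mm), `rms`, and `transform_points(p)` applying the transform.
#' @export
align_images <- function(model_contour, target_contour, max_iter = 30,
                         tol = 1e-4) {
  P <- model_contour$points
  Q <- target_contour$points
  if (!nrow(P) || !nrow(Q)) stop("empty contour", call. = FALSE)
  prox <- function(X) {
    i <- which(X[, 2] == min(X[, 2]))
    if (length(i) > 1) i <- i[which.min(X[i, 1])]
    X[i, ]
  }
  tr <- prox(Q) - prox(P)
  cur <- sweep(P, 2, tr, "+")
  ang <- 0
  prev <- Inf
  for (it in seq_len(max_iter)) {
    nn <- nn_points(cur, Q)
    rms <- sqrt(mean(nn$dist^2))
    if (prev - rms < tol) break
    prev <- rms
    cp <- colMeans(cur); cq <- colMeans(nn$pts)
    Pc <- sweep(cur, 2, cp); Qc <- sweep(nn$pts, 2, cq)
    # closed-form 2D rotation
    num <- sum(Pc[, 1] * Qc[, 2] - Pc[, 2] * Qc[, 1])
    den <- sum(Pc[, 1] * Qc[, 1] + Pc[, 2] * Qc[, 2])
    a <- atan2(num, den)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    t2 <- cq - as.vector(R %*% cp)
    cur <- sweep(cur %*% t(R), 2, t2, "+")
    ang <- ang + a
    tr <- as.vector(R %*% tr) + t2
    # compose rotation about origin with accumulated translation:
    # x -> R_total x + tr_total, maintained incrementally
  }
  ca <- cos(ang); sa <- sin(ang)
  Rtot <- matrix(c(ca, sa, -sa, ca), 2, 2)
  # recover total translation from the final point positions
  ttot <- colMeans(cur) - as.vector(Rtot %*% colMeans(P))
  list(rotation = ang, cos = ca, sin = sa, translation = ttot,
       rms = sqrt(mean(nn_points(cur, Q)$dist^2)),
       transform_points = function(p)
         sweep(as.matrix(p) %*% t(Rtot), 2, ttot, "+"))
}

# nearest target vertex for each point (2D)
nn_points <- function(P, Q) {
  nn <- cpp_nn_points(P, Q)
  list(pts = Q[nn$idx, , drop = FALSE], dist = nn$dist)
}

#' Mean contour-to-contour distance
#'
#' Average over model-contour points of the distance to the nearest target
#' contour segment (point to segment, not point to vertex). With a defect
#' mask, model points in the masked (distal) region are excluded so the
#' model is not penalised for bone the target image lacks. The symmetric
#' variant averages both directions.
#'
#' @param model_contour,target_contour Aligned [contour_2d()] objects.
#' @param v_cut Detector v coordinate (mm); model points with `v >= v_cut`
#'   are excluded (use [defect_v_cut()] of the target). `Inf` disables
#'   masking.
#' @param symmetric Average both directions?
#' @return Mean distance in mm (>= 0; 0 iff the contours coincide on the
#'   unmasked region).
#' @export
contour_metric <- function(model_contour, target_contour, v_cut = Inf,
                           symmetric = FALSE) {
  P <- model_contour$points
  keep <- P[, 2] < v_cut
  if (!any(keep)) stop("all model contour points masked", call. = FALSE)
  d1 <- mean(cpp_point_polyline_dist(P[keep, , drop = FALSE],
                                     target_contour$points,
                                     target_contour$closed))
  if (!symmetric) return(d1)
  Q <- target_contour$points
  keepq <- Q[, 2] < v_cut
  d2 <- mean(cpp_point_polyline_dist(Q[keepq, , drop = FALSE],
                                     model_contour$points,
                                     model_contour$closed))
  (d1 + d2) / 2
}

#' Pearson intensity similarity between two aligned radiographs
#'
#' Pearson correlation of grey values over unmasked pixels; the optimiser
#' uses `1 - r` as its objective.
#'
#' @param model_image,target_image [radiograph()] objects of identical size
#'   (model already resampled into the target frame).
#' @param mask Logical matrix of pixels to use; defaults to the target's
#'   defect mask.
#' @return Correlation `r` in `[-1, 1]`.
#' @export
intensity_metric <- function(model_image, target_image, mask = NULL) {
  a <- if (inherits(model_image, "radiograph")) model_image$pixels
       else as.matrix(model_image)
  b <- if (inherits(target_image, "radiograph")) target_image$pixels
       else as.matrix(target_image)
  if (!identical(dim(a), dim(b))) stop("image sizes differ", call. = FALSE)
  mask <- mask %||% (if (inherits(target_image, "radiograph"))
    target_image$defect_mask else matrix(TRUE, nrow(b), ncol(b)))
  x <- a[mask]; y <- b[mask]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in unmasked pixels",
         call. = FALSE)
  stats::cor(x, y)
}

#' Resample a radiograph under a 2D rigid transform
#'
#' Applies the detector-plane transform returned by [align_images()] to the
#' image pixels (bilinear interpolation), producing the model image in the
#' target frame.
#'
#' @param image A [radiograph()].
#' @param alignment Result of [align_images()].
#' @return The warped [radiograph()].
#' @export
warp_radiograph <- function(image, alignment) {
  g <- image$geometry
  ps <- g$pixel_spacing
  # convert the mm-frame transform to pixel units: pix = mm/ps + offset
  # u = (col - 0.5 - nu/2) ps; forward map in pixel coords keeps rotation,
  # translation becomes t/ps plus the fixed-point shift of the offset
  ca <- alignment$cos; sa <- alignment$sin
  off <- c(0.5 + g$nu / 2, 0.5 + g$nv / 2) - 1  # 0-based pixel of u=v=0
  tpix <- alignment$translation / ps +
    off - c(ca * off[1] - sa * off[2], sa * off[1] + ca * off[2])
  out <- cpp_warp_rigid(image$pixels, ca, sa, tpix[1], tpix[2], 0)
  out[out < 0] <- 0; out[out > 1] <- 1
  radiograph(out, g, defect_mask = image$defect_mask,
             threshold = image$threshold)
}
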