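#' Opacity transfer function
#'
#' Linear map from Hounsfield units to per-sample opacity,
#' `op = 0.25 * HU / 1700`, clamped to `[0, 1]`; non-positive HU map to 0.
#'
#' @param hu Numeric vector of Hounsfield units.
#' @return Opacities in `[0, 1]`.
#' @examples
#' opacity_transfer(1700)  # 0.25
#' @export
opacity_transfer <- function(hu) {
  op <- 0.25 * hu / 1700
  op[hu <= 0] <- 0
  pmin(pmax(op, 0), 1)
}

#' Projection geometry for a simulated radiograph
#'
#' Defines the standard anterior--posterior (AP) or mediolateral (ML) view in
#' the anatomical frame (x medial->lateral, y posterior->anterior, z
#' distal->proximal): AP rays travel along -y, ML rays along +x; image rows
#' run proximal to distal (row index increases distally). Perspective
#' geometry places the X-ray source `source_distance` mm from the detector
#' with the object centred midway; the parallel model drops magnification.
#'
#' @param view `"AP"` or `"ML"`.
#' @param object Object used to size and centre the detector: a
#'   `surface_mesh`, `volume_image`, phantom, or an `n x 3` point matrix.
#' @param pixel_spacing Detector pixel size in mm.
#' @param mode `"perspective"` (default) or `"parallel"`.
#' @param source_distance Source-to-detector distance in mm (default 1500).
#' @param margin Fractional margin added around the projected bounding box.
#' @param detector_size Optional `c(nu, nv)` pixel counts; computed from the
#'   object when omitted.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(view = c("AP", "ML"), object = NULL,
                                pixel_spacing = 0.5,
                                mode = c("perspective", "parallel"),
                                source_distance = 1500, margin = 0.1,
                                detector_size = NULL) {
  view <- match.arg(view)
  mode <- match.arg(mode)
  if (source_distance <= 0) stop("source_distance must be > 0")
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  pts <- geometry_points(object)
  axes <- switch(view,
    AP = list(ray = c(0, -1, 0), u = c(1, 0, 0), v = c(0, 0, -1)),
    ML = list(ray = c(1, 0, 0), u = c(0, 1, 0), v = c(0, 0, -1)))
  center <- colMeans(rbind(apply(pts, 2, min), apply(pts, 2, max)))
  source <- center - axes$ray * source_distance / 2
  det_center <- center + axes$ray * source_distance / 2
  if (is.null(detector_size)) {
    proj <- project_points(pts, axes, source, det_center, mode)
    du <- diff(range(proj[, 1])); dv <- diff(range(proj[, 2]))
    nu <- 2 * ceiling((du * (1 + margin)) / (2 * pixel_spacing)) + 4
    nv <- 2 * ceiling((dv * (1 + margin)) / (2 * pixel_spacing)) + 4
    off <- colMeans(rbind(apply(proj, 2, min), apply(proj, 2, max)))
    det_center <- det_center + off[1] * axes$u + off[2] * axes$v
  } else {
    nu <- detector_size[1]; nv <- detector_size[2]
  }
  structure(list(view = view, mode = mode,
                 source_distance = source_distance,
                 pixel_spacing = pixel_spacing,
                 nu = as.integer(nu), nv = as.integer(nv),
                 ray = axes$ray, u = axes$u, v = axes$v,
                 det_center = det_center, source = source),
            class = "projection_geometry")
}

geometry_points <- function(object) {
  if (is.null(object)) stop("an object is needed to size the detector")
  if (inherits(object, "phantom")) object <- object$mesh
  if (inherits(object, "surface_mesh")) return(object$vertices)
  if (inherits(object, "tet_mesh")) return(object$nodes)
  if (inherits(object, "volume_image")) {
    d <- dim(object$scalars)
    corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                     c(0, d[3] - 1)))
    return(sweep(sweep(corners, 2, object$spacing, "*"), 2, object$origin,
                 "+"))
  }
  as.matrix(object)
}

# Detector (u, v) mm coordinates of world points under a geometry.
project_points <- function(pts, axes, source, det_center, mode) {
  rel <- sweep(pts, 2, det_center)
  u <- as.vector(rel %*% axes$u)
  v <- as.vector(rel %*% axes$v)
  if (mode == "perspective") {
    # scale about the piercing point by sdd / (distance along ray)
    rels <- sweep(pts, 2, source)
    depth <- as.vector(rels %*% axes$ray)
    sdd <- as.vector((det_center - source) %*% axes$ray)
    us <- as.vector(rels %*% axes$u); vs <- as.vector(rels %*% axes$v)
    u0 <- as.vector((det_center - source) %*% axes$u)
    v0 <- as.vector((det_center - source) %*% axes$v)
    u <- us * sdd / depth - u0
    v <- vs * sdd / depth - v0
  }
  cbind(u, v)
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("projection_geometry: %s %s, %d x %d px @ %.3g mm\n", x$view,
              x$mode, x$nu, x$nv, x$pixel_spacing))
  invisible(x)
}

#' Simulated radiograph
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (`nv x nu`, rows
#'   proximal to distal).
#' @param geometry The [projection_geometry()] that produced it.
#' @param defect_mask Logical matrix, `TRUE` where the image is valid.
#' @param threshold Intensity used to determine the projected bone extent.
#' @return An object of class `radiograph` with the projected `bone_extent`
#'   (first and last image row containing bone).
#' @export
radiograph <- function(pixels, geometry, defect_mask = NULL,
                       threshold = 0.01) {
  pixels <- as.matrix(pixels)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel intensities must lie in [0, 1]")
  if (is.null(defect_mask))
    defect_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (!identical(dim(defect_mask), dim(pixels)))
    stop("defect mask shape must equal the pixel shape")
  rows <- which(apply(pixels >= threshold, 1, any))
  extent <- if (length(rows)) c(min(rows), max(rows)) else c(NA, NA)
  structure(list(pixels = pixels, geometry = geometry,
                 defect_mask = defect_mask, bone_extent = extent,
                 threshold = threshold),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("radiograph: %d x %d px (%s %s), bone rows %s-%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$geometry$view,
              x$geometry$mode, x$bone_extent[1], x$bone_extent[2],
              if (all(x$defect_mask)) "" else " [defect-cropped]"))
  invisible(x)
}

#' Project a volume or intensity tet mesh into a radiograph
#'
#' Casts one ray per detector pixel through the source, accumulating
#' absorption-only transmittance `T = prod(1 - op(sample) * step/step_ref)`
#' with samples every `step` mm; the pixel intensity is `1 - T`. A
#' `tet_mesh` source (e.g. a model instance with per-cell HU) is first
#' rasterized onto a temporary voxel grid.
#'
#' @param source A [volume_image()] or a [tet_mesh()] with `cell_hu`.
#' @param geometry A [projection_geometry()].
#' @param step Ray sampling step in mm (> 0).
#' @param step_ref Reference step normalising the opacity (1 mm).
#' @param voxel_spacing Rasterization spacing for tet-mesh sources
#'   (defaults to the detector pixel spacing).
#' @return A [radiograph()].
#' @export
project <- function(source, geometry, step = 1, step_ref = 1,
                    voxel_spacing = NULL) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (inherits(source, "tet_mesh")) {
    if (is.null(source$cell_hu))
      stop("tet mesh source needs cell_hu (map_appearance or instantiate)")
    source <- rasterize_tets(source,
                             spacing = voxel_spacing %||%
                               geometry$pixel_spacing)
  }
  if (!inherits(source, "volume_image"))
    stop("source must be a volume_image or tet_mesh")
  img <- cpp_project_volume(
    as.vector(source$scalars), dim(source$scalars), source$spacing,
    source$origin, geometry$det_center, geometry$u, geometry$v,
    geometry$ray, geometry$source, geometry$nu, geometry$nv,
    geometry$pixel_spacing, geometry$mode == "perspective",
    step, step_ref, 0.25 / 1700, -1000)
  radiograph(img, geometry)
}

#' Rasterize an intensity tet mesh onto a voxel grid
#'
#' @param tm A [tet_mesh()] with `cell_hu`.
#' @param spacing Isotropic voxel spacing (mm).
#' @param background Background HU.
#' @return A [volume_image()].
#' @export
rasterize_tets <- function(tm, spacing = 1, background = -1000) {
  lo <- apply(tm$nodes, 2, min) - 2 * spacing
  hi <- apply(tm$nodes, 2, max) + 2 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing) + 1)
  vol <- cpp_rasterize_tets(tm$nodes, tm$tets, tm$cell_hu, lo,
                            rep(spacing, 3), dims, background)
  volume_image(array(vol, dims), rep(spacing, 3), lo)
}
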