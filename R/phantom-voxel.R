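#' Calibrated intensity volume
#'
#' A regular 3D grid of Hounsfield units in the anatomical frame.
#'
#' @param scalars 3D numeric array (x, y, z order).
#' @param spacing Voxel spacing per axis in mm (length 3).
#' @param origin World coordinates (mm) of the centre of voxel `[1,1,1]`.
#' @param orientation Named axis convention.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(scalars, spacing, origin,
                         orientation = "anatomical_RAS_femur") {
  if (length(dim(scalars)) != 3) stop("scalars must be a 3D array")
  spacing <- rep(spacing, length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(scalars = scalars, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$scalars)
  cat(sprintf("volume_image: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

# Hounsfield value of the phantom at arbitrary points (n x 3 matrix), from
# the analytic construction: cortical within a shell of thickness
# cortical_thickness under the outer surface, medullary deeper inside,
# air outside.
phantom_hu <- function(points, params, background = -1000) {
  g <- phantom_geometry(params)
  pts <- as.matrix(points)
  depth <- phantom_depth(pts, params, g)
  hu <- rep(background, nrow(pts))
  hu[depth$inside] <- params$cortical_hu
  hu[depth$eroded] <- params$medullary_hu
  hu
}

# inside / eroded-inside indicators per primitive union
phantom_depth <- function(pts, params, g) {
  tc <- params$cortical_thickness
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- rep(FALSE, nrow(pts)); eroded <- rep(FALSE, nrow(pts))
  add <- function(depth) {
    inside <<- inside | (depth >= 0)
    eroded <<- eroded | (depth >= tc)
  }
  # shaft: distance to the bow arc (clamped to its angular range)
  arc <- g$arc
  if (arc$theta < 1e-9) {
    zc <- pmin(pmax(z, arc$z0), arc$z1)
    d <- sqrt(x^2 + y^2 + (z - zc)^2)
  } else {
    R <- arc$chord / (2 * sin(arc$theta / 2))
    zc0 <- (arc$z0 + arc$z1) / 2
    yc <- -R * cos(arc$theta / 2)
    dy <- y - yc; dz <- z - zc0
    phi <- atan2(dz, dy)
    phic <- pmin(pmax(phi, -arc$theta / 2), arc$theta / 2)
    ay <- yc + R * cos(phic); az <- zc0 + R * sin(phic)
    d <- sqrt(x^2 + (y - ay)^2 + (z - az)^2)
  }
  add(params$shaft_radius - d)
  # neck cone
  Ln <- params$neck_length
  rel <- sweep(pts, 2, g$neck_base)
  t <- as.vector(rel %*% g$ndir)
  rad2 <- rowSums(rel^2) - t^2
  rad <- sqrt(pmax(rad2, 0))
  r0 <- params$shaft_radius
  r1 <- 0.7 * params$head_radius
  rneck <- r0 + (t / Ln) * (r1 - r0)
  dn <- ifelse(t >= 0 & t <= Ln, rneck - rad, -Inf)
  add(dn)
  # head sphere
  dh <- params$head_radius -
    sqrt(rowSums(sweep(pts, 2, g$head_center)^2))
  add(dh)
  # condyles (ellipsoids; erosion by scaling semi-axes)
  cd <- g$condyle
  for (sgn in c(-1, 1)) {
    m <- sqrt(((x - sgn * cd$cx) / cd$ax)^2 + ((y - cd$cy) / cd$ay)^2 +
              ((z - cd$cz) / cd$az)^2)
    inside <- inside | (m <= 1)
    me <- sqrt(((x - sgn * cd$cx) / (cd$ax - tc))^2 +
               ((y - cd$cy) / (cd$ay - tc))^2 +
               ((z - cd$cz) / (cd$az - tc))^2)
    eroded <- eroded | (me <= 1)
  }
  list(inside = inside, eroded = eroded & inside)
}

#' Voxelize a femur phantom into a Hounsfield volume
#'
#' Samples the analytic two-compartment density of the phantom construction
#' on a regular grid: voxels within `cortical_thickness` of the outer surface
#' get `cortical_hu`, deeper voxels `medullary_hu`, and voxels outside the
#' bone the background (air) value.
#'
#' @param phantom A `phantom` (from [generate_phantom()]); alternatively pass
#'   `params` and a mesh is not required.
#' @param spacing Isotropic voxel spacing in mm; must not exceed half the
#'   shaft radius so the cortex is resolvable.
#' @param margin Margin around the mesh bounding box, in voxels (>= 2).
#' @param background Background HU (air), default -1000.
#' @return A [volume_image()].
#' @export
voxelize_phantom <- function(phantom, spacing = 1, margin = 2,
                             background = -1000) {
  params <- if (inherits(phantom, "phantom")) phantom$params else phantom
  validate_phantom_params(params)
  if (spacing > params$shaft_radius / 2)
    stop(sprintf(paste0("spacing %g mm too coarse to resolve the cortex ",
                        "(must be <= shaft_radius/2 = %g mm)"),
                 spacing, params$shaft_radius / 2), call. = FALSE)
  if (margin < 2) stop("margin must be at least 2 voxels")
  if (inherits(phantom, "phantom")) {
    lo <- apply(phantom$mesh$vertices, 2, min)
    hi <- apply(phantom$mesh$vertices, 2, max)
  } else {
    g <- phantom_geometry(params)
    ext <- params$condyle_width / 2 + 5
    lo <- c(-ext, -ext, 0) + c(0, 0, -1)
    hi <- c(ext, ext, params$bone_length + 1)
    lo <- pmin(lo, g$head_center - params$head_radius - 1)
    hi <- pmax(hi, g$head_center + params$head_radius + 1)
  }
  origin <- lo - margin * spacing
  dims <- ceiling((hi - origin) / spacing) + margin + 1
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  hu <- phantom_hu(pts, params, background = background)
  volume_image(array(hu, dim = dims), spacing = rep(spacing, 3),
               origin = origin)
}
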