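#' Parametric femur phantom parameters
#'
#' Bundles the twelve scalars that fully determine a femur-like phantom:
#' a bowed tubular shaft, a spherical head joined by a conical neck, and two
#' ellipsoidal condyles, plus a two-compartment internal density (cortical
#' shell over a medullary interior).
#'
#' Angle conventions (see the methods vignette): the neck--shaft angle is the
#' 3D angle between the neck axis (pointing towards the head) and the distal
#' direction of the straight diaphyseal axis; anteversion rotates the neck
#' anteriorly about the diaphyseal axis, measured against the posterior
#' condylar axis in the transverse plane; the bow angle is the tangent angle
#' of the diaphyseal centreline between its 10% and 90% stations, i.e. the
#' value an automated bow measurement recovers.
#'
#' @param bone_length Total proximodistal extent in mm.
#' @param shaft_radius Outer shaft radius in mm.
#' @param cortical_thickness Cortical shell thickness in mm.
#' @param head_radius Femoral head radius in mm.
#' @param neck_length Neck base to head centre distance in mm.
#' @param neck_shaft_angle Neck--shaft angle in degrees (90, 160).
#' @param anteversion_angle Anteversion in degrees, |value| < 45.
#' @param bow_angle Diaphyseal bow in degrees, in [0, 15).
#' @param condyle_width Total mediolateral condylar width in mm.
#' @param condyle_offset Posterior offset of the condylar mass in mm.
#' @param cortical_hu,medullary_hu Hounsfield units of the cortical shell and
#'   medullary interior; cortical must exceed medullary.
#' @return An object of class `phantom_params`.
#' @examples
#' p <- phantom_params(neck_shaft_angle = 127, anteversion_angle = 12)
#' @export
phantom_params <- function(bone_length = 430, shaft_radius = 13,
                           cortical_thickness = 5, head_radius = 23,
                           neck_length = 48, neck_shaft_angle = 127,
                           anteversion_angle = 12, bow_angle = 4,
                           condyle_width = 80, condyle_offset = 10,
                           cortical_hu = 1400, medullary_hu = 150) {
  p <- list(bone_length = bone_length, shaft_radius = shaft_radius,
            cortical_thickness = cortical_thickness, head_radius = head_radius,
            neck_length = neck_length, neck_shaft_angle = neck_shaft_angle,
            anteversion_angle = anteversion_angle, bow_angle = bow_angle,
            condyle_width = condyle_width, condyle_offset = condyle_offset,
            cortical_hu = cortical_hu, medullary_hu = medullary_hu)
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("femur phantom parameters\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Validate phantom parameters
#'
#' Checks the parameter-domain invariants and signals an error naming the
#' violated bound.
#'
#' @param p A `phantom_params` object (or plain named list).
#' @return `p`, invisibly.
#' @export
validate_phantom_params <- function(p) {
  for (nm in c("bone_length", "shaft_radius", "cortical_thickness",
               "head_radius", "neck_length", "condyle_width",
               "condyle_offset"))
    stopifnot_scalar(p[[nm]], nm, lower = 0, strict = TRUE)
  stopifnot_scalar(p$neck_shaft_angle, "neck_shaft_angle", 90, 160,
                   strict = TRUE)
  stopifnot_scalar(p$anteversion_angle, "anteversion_angle", -45, 45,
                   strict = TRUE)
  if (!is.numeric(p$bow_angle) || p$bow_angle < 0 || p$bow_angle >= 15)
    stop("'bow_angle' must lie in [0, 15)", call. = FALSE)
  if (p$cortical_thickness >= p$shaft_radius)
    stop("'cortical_thickness' must be smaller than 'shaft_radius'",
         call. = FALSE)
  if (p$cortical_hu <= p$medullary_hu)
    stop("'cortical_hu' must exceed 'medullary_hu'", call. = FALSE)
  invisible(p)
}

# Derived construction geometry shared by the mesh builder, the voxelizer and
# the analytic landmarks. All in the anatomical frame: x medial->lateral,
# y posterior->anterior, z distal->proximal (right femur).
phantom_geometry <- function(p) {
  cw <- p$condyle_width
  ax <- 0.22 * cw                      # condyle semi-axis, mediolateral
  ay <- 0.26 * cw                      # anteroposterior
  az <- 0.24 * cw                      # proximodistal
  cx <- cw / 2 - ax                    # condyle centre offset from midline
  cy <- -p$condyle_offset
  cz <- az                             # distal condyle pole touches z = 0
  nsa_c <- 180 - p$neck_shaft_angle    # angle of neck axis vs +z
  # neck direction: medial tilt in the coronal plane, rotated anteriorly
  n0 <- c(-sin(nsa_c * pi / 180), 0, cos(nsa_c * pi / 180))
  ndir <- as.vector(rot_z(-p$anteversion_angle) %*% n0)
  z_top <- p$bone_length
  z_s1 <- z_top - p$neck_length * ndir[3] - p$head_radius  # shaft prox end
  z_s0 <- az                                               # shaft distal end
  if (z_s1 <= z_s0 + 4 * p$shaft_radius)
    stop("phantom geometry degenerate: shaft too short for these parameters",
         call. = FALSE)
  # bow: circular arc in the sagittal (y-z) plane, apex anterior. The
  # bow_angle parameter is defined as the tangent turn between the 10% and
  # 90% stations of the centreline, so the full arc turns bow_angle / 0.8.
  chord <- z_s1 - z_s0
  theta <- (p$bow_angle / 0.8) * pi / 180
  arc <- list(chord = chord, theta = theta, z0 = z_s0, z1 = z_s1)
  neck_base <- c(0, arc_point(arc, 1)[2], z_s1)
  head_center <- neck_base + p$neck_length * ndir
  list(condyle = list(ax = ax, ay = ay, az = az, cx = cx, cy = cy, cz = cz),
       arc = arc, ndir = ndir, neck_base = neck_base,
       head_center = head_center, z_s0 = z_s0, z_s1 = z_s1,
       knee_center = c(0, cy, cz))
}

# Point on the bow arc centreline at parameter t in [0,1] (t = 0 distal).
# Circular arc in the y-z plane through (0,0,z0) and (0,0,z1), symmetric,
# turning by theta, bulging towards +y (anterior).
arc_point <- function(arc, t) {
  z <- arc$z0 + t * arc$chord
  if (arc$theta < 1e-9) return(c(0, 0, z))
  R <- arc$chord / (2 * sin(arc$theta / 2))
  # circle centre on the -y side of the chord midpoint
  zc <- (arc$z0 + arc$z1) / 2
  yc <- -R * cos(arc$theta / 2)
  phi <- (t - 0.5) * arc$theta
  c(0, yc + R * cos(phi), zc + R * sin(phi))
}

# Unit tangent of the arc at t (pointing proximally).
arc_tangent <- function(arc, t) {
  if (arc$theta < 1e-9) return(c(0, 0, 1))
  phi <- (t - 0.5) * arc$theta
  c(0, -sin(phi), cos(phi))
}
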