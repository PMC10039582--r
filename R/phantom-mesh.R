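#' Generate a parametric femur phantom
#'
#' Builds a femur-like solid from four swept primitives in the anatomical
#' frame (x medial->lateral, y posterior->anterior, z distal->proximal):
#' a tubular shaft swept along a circular sagittal arc (bow), a conical neck,
#' a spherical head and two ellipsoidal condyles. The tetrahedral and surface
#' topology is identical for every parameter set at a given resolution, so
#' vertex `k` corresponds anatomically across phantoms and populations are
#' corresponded by construction. Analytic landmarks (axes, extremal condylar
#' points, head centre) are returned alongside.
#'
#' @param params A [phantom_params()] object.
#' @param mesh_resolution Positive integer subdivision level; level 1 yields
#'   roughly 1200 nodes / 4700 tetrahedra.
#' @return An object of class `phantom`: list with `mesh` (a
#'   [surface_mesh()]), `landmarks` (a `landmark_set`), `tets` (a
#'   [tet_mesh()], boundary triangles equal to the surface triangles),
#'   and `params`.
#' @examples
#' ph <- generate_phantom(phantom_params(), mesh_resolution = 1)
#' ph$mesh
#' @export
generate_phantom <- function(params, mesh_resolution = 1) {
  validate_phantom_params(params)
  L <- as.integer(mesh_resolution)
  if (is.na(L) || L < 1) stop("mesh_resolution must be a positive integer")
  g <- phantom_geometry(params)
  nc <- 12L * L                      # divisible by 4: rings hit +-y and +-z
  nr <- 2L
  comps <- list()

  # shaft: swept tube along the bow arc
  ns <- 16L * L + 1L
  ts <- seq(0, 1, length.out = ns)
  centers <- t(vapply(ts, function(t) arc_point(g$arc, t), numeric(3)))
  tang <- t(vapply(ts, function(t) arc_tangent(g$arc, t), numeric(3)))
  uax <- matrix(rep(c(1, 0, 0), ns), ns, 3, byrow = TRUE)
  vax <- t(vapply(seq_len(ns), function(i) cross3(tang[i, ], uax[i, ]),
                  numeric(3)))
  r <- rep(params$shaft_radius, ns)
  comps$shaft <- gencyl_solid(centers, uax, vax, r, r, nr, nc)

  # neck: cone from the shaft end towards the head centre
  ns_n <- 4L * L + 1L
  s <- seq(0, 1, length.out = ns_n)
  centers <- t(vapply(s, function(t) g$neck_base + t * params$neck_length *
                        g$ndir, numeric(3)))
  un <- unit3(cross3(c(0, 0, 1), g$ndir))
  vn <- cross3(g$ndir, un)
  uax <- matrix(rep(un, ns_n), ns_n, 3, byrow = TRUE)
  vax <- matrix(rep(vn, ns_n), ns_n, 3, byrow = TRUE)
  r <- params$shaft_radius + s * (0.7 * params$head_radius -
                                  params$shaft_radius)
  comps$neck <- gencyl_solid(centers, uax, vax, r, r, nr, nc)

  # head: sphere swept about the neck direction (tiny polar facets avoid
  # degenerate rings)
  ns_h <- 6L * L + 3L
  th0 <- 8 * pi / 180
  th <- seq(th0, pi - th0, length.out = ns_h)
  centers <- t(vapply(th, function(a) g$head_center +
                        params$head_radius * cos(a) * g$ndir, numeric(3)))
  uax <- matrix(rep(un, ns_h), ns_h, 3, byrow = TRUE)
  vax <- matrix(rep(vn, ns_h), ns_h, 3, byrow = TRUE)
  r <- params$head_radius * sin(th)
  comps$head <- gencyl_solid(centers, uax, vax, r, r, nr, nc)

  # condyles: ellipsoids swept along x; rings in the (y, z) plane so the
  # posterior (-y) and distal (-z) extremes are exact mesh vertices
  ns_c <- 6L * L + 3L
  cd <- g$condyle
  for (side in c("med", "lat")) {
    sgn <- if (side == "med") -1 else 1
    thc <- seq(pi - th0, th0, length.out = ns_c)
    centers <- cbind(sgn * cd$cx + cd$ax * cos(thc), cd$cy, cd$cz)
    uax <- matrix(rep(c(0, 1, 0), ns_c), ns_c, 3, byrow = TRUE)
    vax <- matrix(rep(c(0, 0, 1), ns_c), ns_c, 3, byrow = TRUE)
    comps[[paste0("condyle_", side)]] <-
      gencyl_solid(centers, uax, vax, cd$ay * sin(thc), cd$az * sin(thc),
                   nr, nc)
  }

  # merge components
  nodes <- NULL; tets <- NULL; node_region <- NULL; cell_region <- NULL
  node_station <- NULL
  offset <- 0L
  for (nm in names(comps)) {
    cm <- comps[[nm]]
    nodes <- rbind(nodes, cm$nodes)
    tets <- rbind(tets, cm$tets + offset)
    node_region <- c(node_region, rep(nm, nrow(cm$nodes)))
    cell_region <- c(cell_region, rep(nm, nrow(cm$tets)))
    node_station <- c(node_station,
                      if (nm == "shaft") cm$node_station
                      else rep(NA_integer_, nrow(cm$nodes)))
    offset <- offset + nrow(cm$nodes)
  }
  tm <- tet_mesh(nodes, tets, node_region = node_region,
                 cell_region = cell_region)
  tm$node_station <- node_station
  tm$boundary <- tet_boundary(tm)
  mesh <- tet_surface(tm)

  lm <- phantom_landmarks(params, g)
  structure(list(mesh = mesh, landmarks = lm, tets = tm, params = params),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("femur phantom\n  ")
  print(x$mesh)
  invisible(x)
}

# Analytic landmark set derived from the construction parameters.
phantom_landmarks <- function(params, g = phantom_geometry(params)) {
  cd <- g$condyle
  ts <- seq(0, 1, length.out = 41)
  axis_poly <- t(vapply(ts, function(t) arc_point(g$arc, t), numeric(3)))
  lm <- list(
    head_center = g$head_center,
    head_radius = params$head_radius,
    neck_axis = list(point = g$neck_base, direction = unit3(g$ndir)),
    femoral_anatomical_axis = axis_poly,
    mechanical_axis = rbind(g$head_center, g$knee_center),
    epicondyle_med = c(-params$condyle_width / 2, cd$cy, cd$cz),
    epicondyle_lat = c(params$condyle_width / 2, cd$cy, cd$cz),
    posterior_condyle_med = c(-cd$cx, cd$cy - cd$ay, cd$cz),
    posterior_condyle_lat = c(cd$cx, cd$cy - cd$ay, cd$cz),
    distal_condyle_med = c(-cd$cx, cd$cy, cd$cz - cd$az),
    distal_condyle_lat = c(cd$cx, cd$cy, cd$cz - cd$az))
  class(lm) <- "landmark_set"
  lm
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Analytic axes from a landmark set
#'
#' Converts stored landmarks into the axis set used by the anatomical
#' measures. The diaphyseal (anatomical) axis direction is the chord of the
#' centreline polyline restricted to the central 60% of the bone length; the
#' bow polyline is the full centreline.
#'
#' @param lm A `landmark_set`.
#' @return A list of named axes (see [derive_axes()]).
#' @export
landmark_axes <- function(lm) {
  poly <- lm$femoral_anatomical_axis
  zmin <- 0
  zmax <- lm$head_center[3] + lm$head_radius
  lo <- zmin + 0.2 * (zmax - zmin)
  hi <- zmin + 0.8 * (zmax - zmin)
  band <- poly[poly[, 3] >= lo & poly[, 3] <= hi, , drop = FALSE]
  adir <- unit3(band[nrow(band), ] - band[1, ])
  knee <- (lm$epicondyle_med + lm$epicondyle_lat) / 2
  list(anatomical = list(point = colMeans(band), direction = adir),
       anatomical_poly = poly,
       mechanical = list(point = knee,
                         direction = unit3(lm$head_center - knee)),
       neck = lm$neck_axis,
       tea = unit3(lm$epicondyle_lat - lm$epicondyle_med),
       pca_condylar = unit3(lm$posterior_condyle_lat -
                            lm$posterior_condyle_med),
       distal_condylar = unit3(lm$distal_condyle_lat -
                               lm$distal_condyle_med),
       head_center = lm$head_center, head_radius = lm$head_radius)
}
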