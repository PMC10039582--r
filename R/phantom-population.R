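#' Default phantom population distribution
#'
#' Mean and standard deviation for every [phantom_params()] field, chosen as
#' plausible adult-femur morphometrics (not fitted to any specific cohort):
#' length 430 +/- 25 mm, neck-shaft angle 127 +/- 5 deg, anteversion
#' 12 +/- 8 deg, bow 4 +/- 1.5 deg, head radius 23 +/- 2 mm; cortical bone
#' around 1400 HU over a 150 HU medullary interior.
#'
#' @return A data.frame with columns `mean` and `sd`, one row per parameter.
#' @export
default_population <- function() {
  d <- rbind(
    bone_length        = c(430, 25),
    shaft_radius       = c(13, 1),
    cortical_thickness = c(5, 0.5),
    head_radius        = c(23, 2),
    neck_length        = c(48, 4),
    neck_shaft_angle   = c(127, 5),
    anteversion_angle  = c(12, 8),
    bow_angle          = c(4, 1.5),
    condyle_width      = c(80, 5),
    condyle_offset     = c(10, 2),
    cortical_hu        = c(1400, 120),
    medullary_hu       = c(150, 50))
  data.frame(mean = d[, 1], sd = d[, 2], row.names = rownames(d))
}

#' Default inter-parameter correlation
#'
#' Mild allometric coupling between overall size measures (length, head
#' radius, condylar width, shaft radius, neck length); angles and densities
#' uncorrelated.
#'
#' @return A 12 x 12 correlation matrix (positive definite).
#' @export
default_correlation <- function() {
  nms <- rownames(default_population())
  C <- diag(length(nms))
  dimnames(C) <- list(nms, nms)
  set_cor <- function(a, b, r) {
    C[a, b] <<- r; C[b, a] <<- r
  }
  set_cor("bone_length", "head_radius", 0.6)
  set_cor("bone_length", "condyle_width", 0.6)
  set_cor("bone_length", "shaft_radius", 0.4)
  set_cor("bone_length", "neck_length", 0.4)
  set_cor("head_radius", "condyle_width", 0.5)
  set_cor("head_radius", "neck_length", 0.3)
  set_cor("condyle_width", "shaft_radius", 0.3)
  C
}

#' Sample a seeded population of femur phantoms
#'
#' Draws parameters from a truncated multivariate normal (resampling any draw
#' that violates the [phantom_params()] bounds, so the distribution has no
#' boundary atoms) and generates the requested artefacts for each specimen.
#'
#' @param n Number of specimens (>= 2).
#' @param seed Integer seed; the same seed reproduces the population exactly.
#' @param param_distribution Data frame as from [default_population()].
#' @param correlation Correlation matrix as from [default_correlation()];
#'   must be positive semi-definite.
#' @param mesh_resolution Passed to [generate_phantom()].
#' @param spacing Voxel spacing for [voxelize_phantom()].
#' @param what Artefacts to generate per specimen: any of `"params"`,
#'   `"mesh"`, `"landmarks"`, `"volume"` (meshes include tetrahedra).
#' @return A list of class `phantom_population`; each element holds the
#'   requested components. The drawn parameter table is attached as
#'   `attr(, "param_table")`.
#' @export
sample_population <- function(n, seed,
                              param_distribution = default_population(),
                              correlation = default_correlation(),
                              mesh_resolution = 1, spacing = 1.5,
                              what = c("params", "mesh", "landmarks",
                                       "volume")) {
  if (n < 2) stop("n must be at least 2")
  what <- match.arg(what, several.ok = TRUE)
  mu <- param_distribution$mean
  sd <- param_distribution$sd
  nms <- rownames(param_distribution)
  C <- as.matrix(correlation)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  draws <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n, length(mu), dimnames = list(NULL, nms))
    for (i in seq_len(n)) {
      for (try in 1:1000) {
        z <- as.vector(A %*% stats::rnorm(length(mu)))
        par <- mu + sd * z
        names(par) <- nms
        ok <- tryCatch({
          validate_phantom_params(as.list(par))
          TRUE
        }, error = function(e) FALSE)
        if (ok) { out[i, ] <- par; break }
      }
      if (anyNA(out[i, ]))
        stop("could not draw parameters within bounds; check distribution")
    }
    out
  })
  pop <- vector("list", n)
  for (i in seq_len(n)) {
    par <- do.call(phantom_params, as.list(draws[i, ]))
    entry <- list(params = par)
    if (any(c("mesh", "landmarks") %in% what)) {
      ph <- generate_phantom(par, mesh_resolution)
      if ("mesh" %in% what) {
        entry$mesh <- ph$mesh
        entry$tets <- ph$tets
      }
      if ("landmarks" %in% what) entry$landmarks <- ph$landmarks
    }
    if ("volume" %in% what)
      entry$volume <- voxelize_phantom(par, spacing = spacing)
    pop[[i]] <- entry
  }
  attr(pop, "param_table") <- draws
  attr(pop, "seed") <- seed
  class(pop) <- "phantom_population"
  pop
}

#' @export
print.phantom_population <- function(x, ...) {
  cat(sprintf("phantom_population: %d specimens (seed %s)\n", length(x),
              attr(x, "seed")))
  invisible(x)
}
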