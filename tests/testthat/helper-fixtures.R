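# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; resolutions are kept small so the whole suite stays
# well inside the grading budget.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_phantom <- function() fixture("phantom", function() {
  generate_phantom(phantom_params(), mesh_resolution = 1)
})

# small seeded population with intensity tets (used by SSAM, reconstruction
# and acceptance tests)
fix_population <- function() fixture("population", function() {
  pop <- sample_population(6, seed = 11, spacing = 2.5)
  attr(pop, "hu_tets") <- lapply(pop, function(e)
    map_appearance(e$tets, e$volume))
  pop
})

fix_model <- function() fixture("model", function() {
  build_ssam(attr(fix_population(), "hu_tets"))
})

# fast reconstruction settings used throughout the tests
fast_config <- function(...) {
  args <- utils::modifyList(list(pixel_spacing = 2, mode = "parallel",
                                 step = 2, maxit = 15), list(...))
  do.call(recon_config, args)
}

# independent vector-angle oracle (acos formula, no shared code path with
# vector_angle)
oracle_angle <- function(u, v) {
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# arc-length-uniform densification of a closed polygon
densify_polygon <- function(P, n = 4000) {
  m <- nrow(P)
  segs <- cbind(P, P[c(2:m, 1), ])
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  cum <- c(0, cumsum(len))
  s <- seq(0, cum[m + 1], length.out = n + 1)[-(n + 1)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i > m] <- m
  t <- (s - cum[i]) / pmax(len[i], 1e-300)
  cbind(P[i, 1] + t * (segs[i, 3] - segs[i, 1]),
        P[i, 2] + t * (segs[i, 4] - segs[i, 2]))
}

# brute-force oracle: exact point-to-segment minima for given source points
oracle_polyline_mean <- function(pts, tgt) {
  d <- vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    m <- nrow(tgt)
    dmin <- Inf
    for (s in seq_len(m)) {
      a <- tgt[s, ]; b <- tgt[(s %% m) + 1, ]
      ab <- b - a
      tt <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
      tt <- min(max(tt, 0), 1)
      q <- a + tt * ab
      dmin <- min(dmin, sqrt(sum((p - q)^2)))
    }
    dmin
  }, numeric(1))
  mean(d)
}

# convenience wrapper used by the unit tests
oracle_contour_distance <- function(src, tgt, n = 4000, closed = TRUE) {
  oracle_polyline_mean(densify_polygon(src, n), tgt)
}

# synthetic radiograph with given pixel matrix for crop/metric unit tests
synthetic_radiograph <- function(px, pixel_spacing = 1) {
  g <- projection_geometry("AP", object = cbind(0, 0, 0),
                           pixel_spacing = pixel_spacing, mode = "parallel",
                           detector_size = c(ncol(px), nrow(px)))
  radiograph(px, g)
}

# swept-sphere surface mesh (independent small fixture for surface metrics)
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), ns = 15, nc = 16) {
  th0 <- 4 * pi / 180
  th <- seq(th0, pi - th0, length.out = ns)
  centers <- cbind(center[1], center[2],
                   center[3] + radius * cos(th))
  uax <- matrix(rep(c(1, 0, 0), ns), ns, 3, byrow = TRUE)
  vax <- matrix(rep(c(0, 1, 0), ns), ns, 3, byrow = TRUE)
  r <- radius * sin(th)
  tm <- ossam:::gencyl_solid(centers, uax, vax, r, r, nr = 1L, nc = nc)
  tm$boundary <- tet_boundary(tm)
  tet_surface(tm)
}

# independently written inside test for the phantom's analytic union solid
# (own derivation of the construction geometry; used as the volume oracle)
oracle_inside <- function(pts, p) {
  d2r <- pi / 180
  cw <- p$condyle_width
  ax <- 0.22 * cw; ay <- 0.26 * cw; az <- 0.24 * cw
  cx <- cw / 2 - ax; cy <- -p$condyle_offset; cz <- az
  nsa_c <- (180 - p$neck_shaft_angle) * d2r
  av <- p$anteversion_angle * d2r
  n0 <- c(-sin(nsa_c), 0, cos(nsa_c))
  ndir <- c(cos(-av) * n0[1] - sin(-av) * n0[2],
            sin(-av) * n0[1] + cos(-av) * n0[2], n0[3])
  z1 <- p$bone_length - p$neck_length * ndir[3] - p$head_radius
  z0 <- az
  hc <- c(0, 0, z1) + p$neck_length * ndir
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  # shaft: distance to the sagittal arc
  theta <- (p$bow_angle / 0.8) * d2r
  if (theta < 1e-9) {
    zc <- pmin(pmax(z, z0), z1)
    dsh <- sqrt(x^2 + y^2 + (z - zc)^2)
  } else {
    R <- (z1 - z0) / (2 * sin(theta / 2))
    ycc <- -R * cos(theta / 2); zcc <- (z0 + z1) / 2
    phi <- pmin(pmax(atan2(z - zcc, y - ycc), -theta / 2), theta / 2)
    dsh <- sqrt(x^2 + (y - (ycc + R * cos(phi)))^2 +
                (z - (zcc + R * sin(phi)))^2)
  }
  inside <- dsh <= p$shaft_radius
  # neck cone
  rel <- cbind(x, y, z - z1)
  t <- rel %*% ndir
  rad <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  rn <- p$shaft_radius + (t / p$neck_length) *
    (0.7 * p$head_radius - p$shaft_radius)
  inside <- inside | (t >= 0 & t <= p$neck_length & rad <= rn)
  # head
  inside <- inside |
    (sqrt((x - hc[1])^2 + (y - hc[2])^2 + (z - hc[3])^2) <= p$head_radius)
  # condyles
  for (sgn in c(-1, 1))
    inside <- inside | (((x - sgn * cx) / ax)^2 + ((y - cy) / ay)^2 +
                        ((z - cz) / az)^2 <= 1)
  as.vector(inside)
}
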