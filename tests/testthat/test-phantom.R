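test_that("parameter validation names the violated bound", {
  expect_error(phantom_params(neck_shaft_angle = 80), "neck_shaft_angle")
  expect_error(phantom_params(anteversion_angle = 60), "anteversion_angle")
  expect_error(phantom_params(bow_angle = 15), "bow_angle")
  expect_error(phantom_params(shaft_radius = -1), "shaft_radius")
  expect_error(phantom_params(cortical_hu = 100, medullary_hu = 150),
               "cortical_hu")
  expect_error(phantom_params(cortical_thickness = 20, shaft_radius = 13),
               "cortical_thickness")
})

test_that("generation is deterministic and topology is parameter-invariant", {
  ph1 <- fix_phantom()
  ph2 <- generate_phantom(phantom_params(), mesh_resolution = 1)
  expect_identical(ph1$mesh$vertices, ph2$mesh$vertices)
  ph3 <- generate_phantom(
    phantom_params(bone_length = 465, neck_shaft_angle = 119,
                   anteversion_angle = -6, bow_angle = 7.5,
                   condyle_width = 90), mesh_resolution = 1)
  expect_identical(ph1$mesh$triangles, ph3$mesh$triangles)
  expect_identical(ph1$tets$tets, ph3$tets$tets)
  # all tetrahedra positively oriented, for any parameters
  expect_gt(min(tet_volumes(ph3$tets)), 0)
  # boundary of the tet mesh is the surface mesh
  expect_identical(ph1$tets$boundary$tri_local, ph1$mesh$triangles)
})

test_that("landmark angles match the generating parameters", {
  ph <- generate_phantom(phantom_params(neck_shaft_angle = 127,
                                        anteversion_angle = 12),
                         mesh_resolution = 1)
  lm <- ph$landmarks
  ax <- landmark_axes(lm)
  # independent acos-based oracle: neck axis vs distal diaphyseal direction
  neck <- oracle_angle(lm$neck_axis$direction, -ax$anatomical$direction)
  expect_lt(abs(neck - 127), 0.5)
  # transverse-plane projection of the neck axis vs posterior condylar axis
  a <- ax$anatomical$direction
  pr <- function(v) v - sum(v * a) * a
  av <- oracle_angle(pr(lm$neck_axis$direction), pr(ax$pca_condylar))
  av <- min(av, 180 - av)
  expect_lt(abs(av - 12), 0.5)
})

test_that("zero bow gives a collinear anatomical axis polyline", {
  ph <- generate_phantom(phantom_params(bow_angle = 0), mesh_resolution = 1)
  poly <- ph$landmarks$femoral_anatomical_axis
  d <- sweep(poly[-1, , drop = FALSE], 2, poly[1, ])
  d <- d / sqrt(rowSums(d^2))
  expect_lt(max(abs(sweep(d, 2, d[nrow(d), ]))), 1e-9)
})

test_that("landmarks lie on or inside the phantom", {
  ph <- fix_phantom()
  lm <- ph$landmarks
  pts <- rbind(lm$head_center, lm$epicondyle_med, lm$epicondyle_lat,
               lm$posterior_condyle_med, lm$posterior_condyle_lat,
               lm$distal_condyle_med, lm$distal_condyle_lat,
               lm$mechanical_axis)
  d <- cpp_closest_point_mesh(pts, ph$mesh$vertices, ph$mesh$triangles)
  inside <- cpp_inside_mesh(pts, ph$mesh$vertices, ph$mesh$triangles,
                            as.integer(factor(
                              ph$mesh$regions[ph$mesh$triangles[, 1]])))
  # each landmark is inside the union solid or within mesh-facet tolerance
  # of the surface (extremal points sit on the analytic surface, which the
  # discretised mesh underestimates slightly)
  expect_true(all(inside | d$dist < 1.5))
  expect_equal(sqrt(sum(lm$neck_axis$direction^2)), 1, tolerance = 1e-12)
})

test_that("voxelization labels the cortical shell and medullary canal", {
  ph <- fix_phantom()
  p <- ph$params
  expect_error(voxelize_phantom(ph, spacing = 10), "coarse")
  vol <- voxelize_phantom(ph, spacing = 2)
  # sample just inside the mid-shaft surface -> cortical; centreline ->
  # medullary (mid-diaphysis is at the arc apex, x = 0 plane)
  g <- ossam:::phantom_geometry(p)
  mid <- ossam:::arc_point(g$arc, 0.5)
  at <- function(pt) {
    idx <- round((pt - vol$origin) / vol$spacing) + 1
    vol$scalars[idx[1], idx[2], idx[3]]
  }
  surf_in <- mid + c(p$shaft_radius - p$cortical_thickness / 2, 0, 0)
  expect_equal(at(surf_in), p$cortical_hu)
  expect_equal(at(mid), p$medullary_hu)
  expect_equal(at(mid + c(3 * p$shaft_radius, 0, 0)), -1000)
  # bounding box covers the mesh with a margin
  lo <- apply(ph$mesh$vertices, 2, min)
  hi <- apply(ph$mesh$vertices, 2, max)
  expect_true(all(vol$origin <= lo - 2 * vol$spacing + 1e-9))
  d <- dim(vol$scalars)
  expect_true(all(vol$origin + (d - 1) * vol$spacing >=
                    hi + 2 * vol$spacing - 1e-9))
})

test_that("voxel volume agrees with an analytic union-solid oracle", {
  ph <- fix_phantom()
  vol <- voxelize_phantom(ph, spacing = 2)
  nbone <- sum(vol$scalars > -1000)
  vox_volume <- nbone * prod(vol$spacing)
  # Monte-Carlo volume of the analytic union of primitives, evaluated by an
  # independently written inside test (helper oracle_inside)
  set.seed(99)
  lo <- apply(ph$mesh$vertices, 2, min) - 2
  hi <- apply(ph$mesh$vertices, 2, max) + 2
  n <- 120000
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
  oracle_volume <- mean(oracle_inside(pts, ph$params)) * prod(hi - lo)
  expect_lt(abs(vox_volume - oracle_volume) / oracle_volume, 0.05)
})

test_that("voxel labels and mesh-interior test agree away from the surface", {
  ph <- fix_phantom()
  vol <- voxelize_phantom(ph, spacing = 2.5)
  d <- dim(vol$scalars)
  set.seed(5)
  idx <- cbind(sample(d[1], 4000, TRUE), sample(d[2], 4000, TRUE),
               sample(d[3], 4000, TRUE))
  pts <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  sd_ <- cpp_closest_point_mesh(pts, ph$mesh$vertices, ph$mesh$triangles)
  away <- sd_$dist > vol$spacing[1]
  comp <- as.integer(factor(ph$mesh$regions[ph$mesh$triangles[, 1]]))
  inside <- cpp_inside_mesh(pts[away, , drop = FALSE], ph$mesh$vertices,
                            ph$mesh$triangles, comp)
  vox_bone <- vol$scalars[idx[away, , drop = FALSE]] > -1000
  expect_gte(mean(inside == vox_bone), 0.99)
})

test_that("population sampling is seeded, truncated and well-calibrated", {
  pop1 <- sample_population(5, seed = 1, what = "params")
  pop2 <- sample_population(5, seed = 1, what = "params")
  expect_identical(attr(pop1, "param_table"), attr(pop2, "param_table"))
  # degenerate distribution: all phantoms equal the mean
  dist0 <- default_population()
  dist0$sd[] <- 0
  popm <- sample_population(3, seed = 2, param_distribution = dist0,
                            what = "params")
  tab <- attr(popm, "param_table")
  expect_true(all(apply(tab, 2, function(x) diff(range(x)) == 0)))
  expect_identical(unname(tab[1, ]), dist0$mean)
  # moments: sample sd within 15% of target for n = 200
  popn <- sample_population(200, seed = 7, what = "params")
  tabn <- attr(popn, "param_table")
  tgt <- default_population()
  for (nm in rownames(tgt)) {
    expect_lt(abs(stats::sd(tabn[, nm]) - tgt[nm, "sd"]) / tgt[nm, "sd"],
              0.15)
  }
  # non-PSD correlation rejected
  C <- default_correlation()
  C[1, 2] <- C[2, 1] <- 2
  expect_error(sample_population(3, seed = 1, correlation = C,
                                 what = "params"), "positive semi-definite")
  expect_error(sample_population(1, seed = 1), "at least 2")
})
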