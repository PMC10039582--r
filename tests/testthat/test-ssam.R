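test_that("rigid ICP recovers a known transform and is non-increasing", {
  ph <- fix_phantom()
  mesh <- ph$mesh
  al0 <- rigid_align(mesh, mesh)
  expect_lt(al0$rms, 1e-9)
  expect_lt(max(abs(al0$transform$rotation - diag(3))), 1e-9)
  R <- ossam:::rot_z(10)
  tr <- c(5, 0, 0)
  moved <- mesh
  moved$vertices <- sweep(mesh$vertices %*% t(R), 2, -tr)
  al <- rigid_align(moved, mesh, max_iter = 80, tol = 1e-9)
  expect_true(all(diff(al$rms_trace) <= 1e-9))
  Rrec <- al$transform$rotation %*% R
  expect_lt(oracle_angle(Rrec %*% c(1, 0, 0), c(1, 0, 0)), 0.1)
  resid <- al$transform$translation +
    as.vector(al$transform$rotation %*% tr)
  expect_lt(sqrt(sum(resid^2)), 0.1)
  # perturbed copy: RMS bounded by the noise scale
  set.seed(3)
  noisy <- mesh
  k <- sample(nrow(noisy$vertices), round(0.2 * nrow(noisy$vertices)))
  noisy$vertices[k, ] <- noisy$vertices[k, ] +
    matrix(stats::rnorm(3 * length(k), sd = 0.5 / sqrt(3)), ncol = 3)
  aln <- rigid_align(noisy, mesh)
  expect_lt(aln$rms, 0.5)
  expect_error(rigid_align(list(), mesh), "surface_mesh")
})

test_that("FFD correspondence handles identity, scaling and phantom pairs", {
  ph <- fix_phantom()
  ident <- correspond_ffd(ph$mesh, ph$mesh)
  expect_equal(attr(ident, "final_distance"), 0, tolerance = 1e-9)
  expect_equal(ident$vertices, ph$mesh$vertices, tolerance = 1e-9)
  tgt <- ph$mesh
  tgt$vertices <- tgt$vertices * 1.05
  sc <- correspond_ffd(ph$mesh, tgt)
  expect_identical(sc$triangles, ph$mesh$triangles)
  expect_lt(attr(sc, "final_distance"), 0.5)
  expect_true(all(diff(attr(sc, "level_distance")) <= 1e-9))
  # known-correspondence phantom pair
  ph2 <- generate_phantom(phantom_params(bone_length = 450,
                                         neck_shaft_angle = 124),
                          mesh_resolution = 1)
  al <- rigid_align(ph$mesh, ph2$mesh)
  cor2 <- correspond_ffd(al$aligned, ph2$mesh)
  err <- sqrt(rowSums((cor2$vertices - ph2$mesh$vertices)^2))
  expect_lt(mean(err), 2)
  far <- ph2$mesh
  far$vertices <- far$vertices + 5000
  expect_error(correspond_ffd(ph$mesh, far), "overlap")
})

test_that("Laplace morph reproduces constants and affine maps exactly", {
  cube <- ossam:::cube_tet_mesh(4, 10)
  nb <- length(cube$boundary$nodes)
  z <- morph_tet_mesh(cube, matrix(0, nb, 3))
  expect_equal(z$nodes, cube$nodes, tolerance = 1e-12)
  tr <- matrix(rep(c(1, -2, 3), each = nb), ncol = 3)
  mt <- morph_tet_mesh(cube, tr)
  expect_equal(mt$nodes, sweep(cube$nodes, 2, c(-1, 2, -3)),
               tolerance = 1e-9)
  A <- matrix(c(1.1, 0.2, 0, -0.1, 0.9, 0.05, 0, 0.1, 1.05), 3, 3,
              byrow = TRUE)
  tv <- c(1, -2, 3)
  bnodes <- cube$nodes[cube$boundary$nodes, , drop = FALSE]
  D <- sweep(bnodes %*% t(A), 2, -tv) - bnodes
  ma <- morph_tet_mesh(cube, D)
  expect_equal(ma$nodes, sweep(cube$nodes %*% t(A), 2, -tv),
               tolerance = 1e-8)
  expect_equal(attr(ma, "inverted_fraction"), 0)
  expect_error(morph_tet_mesh(cube, D[-1, , drop = FALSE]), "boundary")
})

test_that("appearance mapping takes the nearest voxel", {
  ph <- fix_phantom()
  vol <- voxelize_phantom(ph, spacing = 2)
  const <- vol
  const$scalars[] <- 321
  tm <- map_appearance(ph$tets, const)
  expect_true(all(tm$cell_hu == 321))
  # centroid exactly on a voxel centre
  one <- volume_image(array(seq_len(27), c(3, 3, 3)), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0))
  nodes <- rbind(c(1, 1, 1), c(1.04, 1, 1), c(1, 1.04, 1), c(1, 1, 1.04))
  nodes <- sweep(nodes, 2, c(0.03, 0.01, 0.01))  # centroid at (1,1,1)
  tm1 <- tet_mesh(nodes, matrix(1:4, 1))
  tm1 <- map_appearance(tm1, one)
  expect_equal(tm1$cell_hu, one$scalars[2, 2, 2])
  # phantom: mapped values match the analytic construction away from the
  # cortical/medullary and bone/air interfaces
  tm2 <- map_appearance(ph$tets, vol)
  ctr <- (ph$tets$nodes[ph$tets$tets[, 1], ] +
          ph$tets$nodes[ph$tets$tets[, 2], ] +
          ph$tets$nodes[ph$tets$tets[, 3], ] +
          ph$tets$nodes[ph$tets$tets[, 4], ]) / 4
  truth <- ossam:::phantom_hu(ctr, ph$params)
  # "away from the interface": the analytic label is constant within 1.5
  # voxels of the centroid along every axis
  away <- rep(TRUE, nrow(ctr))
  for (k in 1:3) for (dd in c(-1.5, 1.5) * vol$spacing[1]) {
    sh <- ctr
    sh[, k] <- sh[, k] + dd
    away <- away & (ossam:::phantom_hu(sh, ph$params) == truth)
  }
  expect_gt(sum(away), 200)
  expect_gte(mean(tm2$cell_hu[away] == truth[away]), 0.95)
  # out-of-bounds centroids are reported
  small <- volume_image(array(0, c(2, 2, 2)), c(1, 1, 1), c(0, 0, 0))
  expect_error(map_appearance(ph$tets, small), "outside")
})

test_that("PCA model behaves like closed-form two-sample PCA", {
  pop <- fix_population()
  tets <- attr(pop, "hu_tets")
  # identical specimens: zero eigenvalues, mean equals the specimen
  m0 <- build_ssam(list(tets[[1]], tets[[1]]))
  expect_length(m0$eigenvalues, 0)
  expect_equal(instantiate(m0)$tets$nodes, tets[[1]]$nodes,
               tolerance = 1e-9)
  # two distinct specimens: one mode proportional to their difference
  m2 <- build_ssam(list(tets[[1]], tets[[2]]), use_appearance = FALSE)
  expect_length(m2$eigenvalues, 1)
  diffv <- as.vector(t(tets[[1]]$nodes - tets[[2]]$nodes))
  diffv <- diffv / sqrt(sum(diffv^2))
  cosang <- abs(sum(m2$modes[, 1] * diffv))
  expect_equal(cosang, 1, tolerance = 1e-8)
  expect_error(build_ssam(tets[1]), "at least 2")
  bad <- tets[[2]]
  bad$tets <- bad$tets[-1, , drop = FALSE]
  expect_error(build_ssam(list(tets[[1]], bad)), "topology")
})

test_that("a single varying parameter is captured by the first mode", {
  dist1 <- default_population()
  dist1$sd[] <- 0
  dist1["bone_length", "sd"] <- 25
  pop <- sample_population(10, seed = 4, param_distribution = dist1,
                           correlation = diag(12),
                           what = c("params", "mesh"))
  model <- build_ssam(lapply(pop, `[[`, "tets"), use_appearance = FALSE)
  expect_gt(model$eigenvalues[1] / sum(model$eigenvalues), 0.95)
  scores <- vapply(pop, function(e)
    project_weights(model, e$tets)[1], numeric(1))
  lens <- attr(pop, "param_table")[, "bone_length"]
  expect_gt(abs(stats::cor(scores, lens)), 0.99)
})

test_that("model invariants hold on the phantom population", {
  model <- fix_model()
  tets <- attr(fix_population(), "hu_tets")
  G <- crossprod(model$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  expect_lte(length(model$eigenvalues), model$n_specimens - 1)
  # cumulative explained variance is non-decreasing
  expect_true(all(diff(cumsum(model$eigenvalues)) >= 0))
  # training reconstruction to numerical precision
  for (k in c(1, 4)) {
    b <- project_weights(model, tets[[k]])
    rec <- instantiate(model, b)
    expect_lt(max(abs(rec$tets$nodes - tets[[k]]$nodes)), 1e-6)
    expect_lt(max(abs(rec$tets$cell_hu - tets[[k]]$cell_hu)), 1e-4)
  }
})

test_that("instantiation is linear and validates weights", {
  model <- fix_model()
  mean_inst <- instantiate(model)
  expect_equal(as.vector(t(mean_inst$tets$nodes)), model$mean_shape,
               tolerance = 1e-12)
  up <- instantiate(model, c(2))
  dn <- instantiate(model, c(-2))
  expect_equal((up$tets$nodes + dn$tets$nodes) / 2, mean_inst$tets$nodes,
               tolerance = 1e-9)
  expect_error(instantiate(model, rep(0, 99)), "modes")
  # +-3 sd instances stay valid solids (no inverted tetrahedra) and keep
  # each component surface watertight
  for (b1 in c(-3, 3)) {
    inst <- instantiate(model, c(b1))
    expect_gt(min(tet_volumes(inst$tets)), 0)
  }
})

test_that("leave-one-out splits preserve the data", {
  tets <- attr(fix_population(), "hu_tets")
  lo <- leave_one_out(tets, 2)
  expect_identical(lo$held_out, tets[[2]])
  expect_equal(lo$model$n_specimens, length(tets) - 1)
  expect_error(leave_one_out(tets, 99), "range")
  expect_error(leave_one_out(tets[1:2], 1), "at least 3")
  # n = 3: at most one non-zero mode
  m3 <- leave_one_out(tets[1:3], 1)$model
  expect_lte(length(m3$eigenvalues), 1)
  # held-out residual positive under the LOO model, zero under the full one
  full <- fix_model()
  rec_loo <- instantiate(lo$model, project_weights(lo$model, tets[[2]]))
  rec_full <- instantiate(full, project_weights(full, tets[[2]]))
  expect_gt(max(abs(rec_loo$tets$nodes - tets[[2]]$nodes)), 0.1)
  expect_lt(max(abs(rec_full$tets$nodes - tets[[2]]$nodes)), 1e-6)
})

test_that("models persist through the save/load container", {
  model <- fix_model()
  path <- withr::local_tempfile(fileext = ".rds")
  ssam_save(model, path)
  m2 <- ssam_load(path)
  expect_equal(m2$mean_shape, model$mean_shape)
  expect_equal(m2$modes, model$modes)
  inst <- instantiate(m2, c(1, -1))
  expect_s3_class(inst$mesh, "surface_mesh")
})
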