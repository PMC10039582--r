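test_that("2D contour alignment recovers synthetic transforms", {
  # asymmetric notched rectangle, densely sampled: corners make the rigid
  # registration well-conditioned (smooth ovals slide rotationally)
  corners <- rbind(c(-10, -18), c(10, -18), c(10, 2), c(3, 2), c(3, 8),
                   c(10, 8), c(10, 18), c(-10, 18))
  dense <- function(P, per = 14) {
    m <- nrow(P)
    out <- NULL
    for (s in seq_len(m)) {
      a <- P[s, ]; b <- P[(s %% m) + 1, ]
      t <- seq(0, 1, length.out = per + 1)[-(per + 1)]
      out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]),
                              a[2] + t * (b[2] - a[2])))
    }
    out
  }
  P <- dense(corners)
  cp <- contour_2d(P)
  ident <- align_images(cp, cp)
  expect_lt(abs(ident$rotation), 1e-6)
  expect_lt(max(abs(ident$translation)), 1e-6)
  tr <- align_images(contour_2d(sweep(P, 2, c(3, -7), "+")), cp)
  expect_lt(max(abs(tr$translation - c(-3, 7))), 0.1)
  ctr <- colMeans(P)
  a <- 5 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  Prot <- sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, "+")
  rot <- align_images(contour_2d(Prot), cp, max_iter = 60, tol = 1e-7)
  expect_lt(abs(rot$rotation * 180 / pi + 5), 0.2)
  expect_error(align_images(contour_2d(P[0, , drop = FALSE], closed = FALSE),
                            cp), "empty")
})

test_that("contour metric matches a dense-sampling brute-force oracle", {
  sq <- function(h) rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
  # concentric squares, sides 10 and 12: one-way mean distance 1.0
  m10 <- contour_metric(contour_2d(sq(5)), contour_2d(sq(6)))
  expect_equal(m10, 1.0, tolerance = 1e-9)
  # assorted polygon pairs against the oracle, within 1%
  set.seed(21)
  pairs <- list(
    list(sq(5), sq(6)),
    list(sq(5), sweep(sq(5), 2, c(1, 0), "+")),
    list(cbind(3 * cos(seq(0, 2 * pi, length.out = 40)[-40]),
               3 * sin(seq(0, 2 * pi, length.out = 40)[-40])), sq(4)),
    list(sq(2), sq(7)),
    list(sweep(sq(3), 2, c(0.5, -0.25), "+"),
         cbind(4 * cos(seq(0, 2 * pi, length.out = 31)[-31]),
               2 * sin(seq(0, 2 * pi, length.out = 31)[-31]))))
  for (pr in pairs) {
    pts <- densify_polygon(pr[[1]], 6000)
    src_dense <- oracle_polyline_mean(pts, pr[[2]])
    impl <- contour_metric(contour_2d(pts, closed = FALSE),
                           contour_2d(pr[[2]]))
    expect_lt(abs(impl - src_dense) / max(src_dense, 1e-12), 0.01)
  }
  # masking and degenerate masks
  expect_error(contour_metric(contour_2d(sq(5)), contour_2d(sq(6)),
                              v_cut = -10), "masked")
  sym <- contour_metric(contour_2d(sq(5)), contour_2d(sq(6)),
                        symmetric = TRUE)
  expect_gt(sym, 0)
})

test_that("intensity metric is the textbook Pearson correlation", {
  a <- matrix(c(0, 1, 2, 3), 2)
  expect_equal(intensity_metric(a, a), 1)
  expect_equal(intensity_metric(a, 1 - a / 3), -1)
  b <- matrix(c(1, 3, 5, 7), 2)
  expect_equal(intensity_metric(a, b), 1, tolerance = 1e-12)
  b2 <- matrix(c(3, 1, 2, 0), 2)
  x <- as.vector(a); y <- as.vector(b2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(intensity_metric(a, b2), r_hand, tolerance = 1e-12)
  expect_error(intensity_metric(a, matrix(1, 2, 2)), "variance")
  expect_error(intensity_metric(a, matrix(1, 3, 3)), "differ")
})

test_that("objective is additive over views and zero at the truth", {
  model <- fix_model()
  cfg_both <- fast_config(metric = "contour", views = "AP_ML", n_modes = 2)
  bstar <- c(1.0, -0.5)
  tg <- make_reconstruction_targets(instantiate(model, bstar)$tets,
                                    cfg_both)
  expect_equal(objective(bstar, model, tg, cfg_both), 0, tolerance = 0.05)
  pv <- objective(bstar, model, tg, cfg_both, per_view = TRUE)
  expect_named(pv, c("AP", "ML"))
  expect_equal(sum(pv), objective(bstar, model, tg, cfg_both))
  # single-view objective equals the AP component
  cfg_ap <- fast_config(metric = "contour", views = "AP", n_modes = 2)
  tg_ap <- make_reconstruction_targets(instantiate(model, bstar)$tets,
                                       cfg_ap)
  expect_equal(objective(c(0.4, 0), model, tg_ap, cfg_ap),
               objective(c(0.4, 0), model, tg, cfg_both,
                         per_view = TRUE)[["AP"]],
               tolerance = 1e-9)
  # intensity objective: better at the truth than at the mean
  cfg_int <- fast_config(metric = "intensity", views = "AP_ML", n_modes = 2)
  tg_int <- make_reconstruction_targets(instantiate(model, bstar)$tets,
                                        cfg_int)
  expect_lte(objective(bstar, model, tg_int, cfg_int),
             objective(c(0, 0), model, tg_int, cfg_int))
  expect_lt(objective(bstar, model, tg_int, cfg_int), 1e-6)
})

test_that("reconstruction of the model mean stays at the origin", {
  model <- fix_model()
  cfg <- fast_config(metric = "contour", views = "AP_ML", n_modes = 2,
                     maxit = 10)
  tg <- make_reconstruction_targets(instantiate(model)$tets, cfg)
  rec <- reconstruct(model, tg, cfg)
  expect_lt(max(abs(rec$weights)), 0.1)
})

test_that("incremental stages never increase the objective", {
  model <- fix_model()
  cfg <- fast_config(metric = "contour", views = "AP_ML", n_modes = 3,
                     maxit = 10)
  tets <- attr(fix_population(), "hu_tets")
  tg <- make_reconstruction_targets(tets[[2]], cfg)
  rec <- reconstruct(leave_one_out(tets, 2)$model, tg, cfg)
  expect_true(all(diff(rec$objective_trace) <= 1e-6))
  expect_length(rec$weights, 3)
  expect_s3_class(rec$mesh, "surface_mesh")
  # weights respect the configured bounds
  expect_true(all(abs(rec$weights) <= cfg$weight_bounds + 1e-9))
})

test_that("metric zero-consistency links the contour and intensity paths", {
  model <- fix_model()
  cfg <- fast_config(metric = "contour", views = "AP", n_modes = 1)
  tg <- make_reconstruction_targets(instantiate(model, c(0.7))$tets, cfg)
  cfg_i <- fast_config(metric = "intensity", views = "AP", n_modes = 1)
  expect_lt(objective(c(0.7), model, tg, cfg), 0.05)
  expect_lt(objective(c(0.7), model, tg, cfg_i), 1e-6)
})
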