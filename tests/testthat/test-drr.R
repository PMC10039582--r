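test_that("opacity transfer follows the stated linear map", {
  expect_identical(opacity_transfer(1700), 0.25)
  expect_identical(opacity_transfer(0), 0)
  expect_equal(opacity_transfer(850), 0.125)
  expect_identical(opacity_transfer(-500), 0)     # air contributes nothing
  expect_identical(opacity_transfer(1e6), 1)      # clamped
  expect_equal(opacity_transfer(c(1700, 850)), c(0.25, 0.125))
})

test_that("ray compositing matches the closed-form product", {
  # slab of constant HU: thickness t, step s with t/s integer n
  # -> intensity 1 - (1 - op * s / step_ref)^n
  hu <- 900
  vol <- volume_image(array(hu, c(5, 12, 5)), spacing = c(1, 1, 1),
                      origin = c(0, 0, 0))
  g <- projection_geometry("AP", vol, pixel_spacing = 1, mode = "parallel")
  for (step in c(1, 2)) {
    rg <- project(vol, g, step = step)
    n <- 12 / step
    expected <- 1 - (1 - opacity_transfer(hu) * step)^n
    mid <- rg$pixels[round(nrow(rg$pixels) / 2), round(ncol(rg$pixels) / 2)]
    expect_equal(mid, expected, tolerance = 1e-10)
  }
  # empty volume -> all-zero image
  air <- volume_image(array(-1000, c(5, 5, 5)), c(1, 1, 1), c(0, 0, 0))
  rg0 <- project(air, projection_geometry("AP", air, pixel_spacing = 1,
                                          mode = "parallel"))
  expect_true(all(rg0$pixels == 0))
  expect_error(project(vol, g, step = 0), "step")
})

test_that("intensity increases monotonically with path length", {
  # staircase thickness along u: longer y-extent -> brighter pixel
  arr <- array(-1000, c(30, 20, 3))
  for (i in 1:30) arr[i, seq_len(floor(i / 2) + 1), ] <- 800
  vol <- volume_image(arr, c(1, 1, 1), c(0, 0, 0))
  g <- projection_geometry("AP", vol, pixel_spacing = 1, mode = "parallel")
  rg <- project(vol, g, step = 0.5)
  row <- rg$pixels[round(nrow(rg$pixels) / 2), ]
  inten <- row[row > 0]
  expect_true(all(diff(inten) >= -1e-12))
})

test_that("a projected sphere yields a circular contour of the right size", {
  # the volume samples the analytic sphere much finer than the detector so
  # the half-pixel contour bound is meaningful
  r <- 15
  arr_sp <- 0.35
  lo <- rep(-r - 3, 3)
  dims <- rep(ceiling((2 * r + 6) / arr_sp) + 1, 3)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * arr_sp
  pts <- as.matrix(expand.grid(xs, xs, xs))
  hu <- ifelse(rowSums(pts^2) <= r^2, 1200, -1000)
  vol <- volume_image(array(hu, dims), rep(arr_sp, 3), lo)
  g <- projection_geometry("AP", vol, pixel_spacing = 1, mode = "parallel")
  rg <- project(vol, g, step = 0.35)
  ct <- extract_contour(rg, threshold = 0.01)
  rad <- sqrt(rowSums(ct$points^2))
  # DRR iso-contour at a near-zero threshold: within one pixel of the disc
  expect_lt(max(abs(rad - r)), 1)
  expect_lt(abs(mean(rad) - r), 0.5)
  # binary occupancy projection: silhouette within half a pixel
  nu <- g$nu; nv <- g$nv
  u <- ( seq_len(nu) - 0.5 - nu / 2) * g$pixel_spacing
  v <- ( seq_len(nv) - 0.5 - nv / 2) * g$pixel_spacing
  occ <- outer(v, u, function(vv, uu) as.numeric(uu^2 + vv^2 <= r^2))
  rgb_ <- radiograph(occ, g)
  cb <- extract_contour(rgb_, threshold = 0.5)
  radb <- sqrt(rowSums(cb$points^2))
  expect_lt(max(abs(radb - r)), 0.5 * g$pixel_spacing)
})

test_that("contour extraction follows the largest component and borders", {
  px <- matrix(0, 20, 20)
  px[3:16, 4:15] <- 0.8                 # large block
  px[18:19, 17:19] <- 0.9               # small distractor
  rgs <- synthetic_radiograph(px)
  ct <- extract_contour(rgs, threshold = 0.5)
  # contour enclosing the large block only: area ~ 14 x 12 px
  area <- abs(sum(ct$points[, 1] * c(ct$points[-1, 2], ct$points[1, 2]) -
                  c(ct$points[-1, 1], ct$points[1, 1]) * ct$points[, 2]) / 2)
  expect_gt(area, 100)
  expect_lt(area, 200)
  # all-foreground image: contour equals the image border rectangle
  full <- synthetic_radiograph(matrix(1, 10, 12))
  cf <- extract_contour(full, threshold = 0.5)
  expect_equal(diff(range(cf$points[, 1])), 12, tolerance = 1.1)
  expect_equal(diff(range(cf$points[, 2])), 10, tolerance = 1.1)
  expect_error(extract_contour(synthetic_radiograph(matrix(0, 5, 5))),
               "threshold")
})

test_that("defect cropping masks the stated distal rows", {
  px <- matrix(0, 600, 40)
  px[100:499, 10:30] <- 0.6             # bone spans rows 100..499
  rgs <- synthetic_radiograph(px)
  expect_identical(rgs$bone_extent, c(100L, 499L))
  r0 <- crop_defect(rgs, 0)
  expect_identical(r0$pixels, rgs$pixels)
  expect_true(all(r0$defect_mask))
  r50 <- crop_defect(rgs, 0.5)
  masked <- which(!apply(r50$defect_mask, 1, all))
  expect_identical(range(masked), c(300L, 499L))
  expect_true(all(r50$pixels[300:499, ] == 0))
  r20 <- crop_defect(rgs, 0.2)
  expect_identical(sum(!apply(r20$defect_mask, 1, all)), 80L)
  # mask conservation for the standard levels
  for (f in c(0, 0.1, 0.2, 0.5)) {
    rc <- crop_defect(rgs, f)
    expect_identical(sum(!apply(rc$defect_mask, 1, all)),
                     as.integer(round(f * 400)))
  }
  expect_error(crop_defect(rgs, 1), "defect_level")
})

test_that("AP and ML projections agree on the projected bone length", {
  ph <- fix_phantom()
  vol <- voxelize_phantom(ph, spacing = 2.5)
  lens <- sapply(c("AP", "ML"), function(vw) {
    g <- projection_geometry(vw, vol, pixel_spacing = 2, mode = "parallel")
    rg <- project(vol, g, step = 2.5)
    diff(rg$bone_extent)
  })
  expect_lte(abs(lens["AP"] - lens["ML"]), 1)
})

test_that("perspective projection magnifies but stays internally consistent", {
  ph <- fix_phantom()
  vol <- voxelize_phantom(ph, spacing = 2.5)
  gp <- projection_geometry("AP", vol, pixel_spacing = 2,
                            mode = "perspective", source_distance = 1500)
  expect_equal(gp$source_distance, 1500)
  rgp <- project(vol, gp, step = 2.5)
  gpar <- projection_geometry("AP", vol, pixel_spacing = 2,
                              mode = "parallel")
  rpar <- project(vol, gpar, step = 2.5)
  # object midway between source and detector -> magnification about 2
  ratio <- (diff(rgp$bone_extent)) / (diff(rpar$bone_extent))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})
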