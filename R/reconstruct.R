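#' Reconstruction configuration
#'
#' @param metric Image similarity driving the fit: `"contour"` (mean
#'   distance between silhouette contours, mm) or `"intensity"` (1 minus the
#'   Pearson correlation of grey values).
#' @param views `"AP"` (single projection) or `"AP_ML"` (both).
#' @param n_modes Number of modes of variation to recover (default 14).
#' @param weight_bounds Box bound per mode weight, in standard deviations
#'   (default 3).
#' @param defect_level Distal defect fraction applied to the targets.
#' @param pixel_spacing Detector pixel size (mm) for target and model DRRs.
#' @param mode Projection model, `"perspective"` or `"parallel"`.
#' @param step Ray sampling step (mm).
#' @param voxel_spacing Rasterization spacing for model instances; defaults
#'   to `pixel_spacing`.
#' @param threshold Contour / bone-extent threshold.
#' @param maxit L-BFGS-B iteration cap per incremental stage.
#' @param fd_step Finite-difference step (sd units) for the numerical
#'   gradient; must exceed the image-discretisation noise of the metric.
#' @param max_evals Objective-evaluation budget multiplier per incremental
#'   stage (stage k may spend `max_evals * (k + 1)` evaluations).
#' @param factr,pgtol L-BFGS-B convergence controls.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(metric = c("contour", "intensity"),
                         views = c("AP_ML", "AP"), n_modes = 14,
                         weight_bounds = 3, defect_level = 0,
                         pixel_spacing = 1.5,
                         mode = c("perspective", "parallel"), step = 2,
                         voxel_spacing = NULL, threshold = 0.01,
                         maxit = 40, factr = 1e9, pgtol = 1e-6,
                         fd_step = 0.05, max_evals = 30) {
  metric <- match.arg(metric)
  views <- match.arg(views)
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (weight_bounds <= 0) stop("weight_bounds must be > 0")
  structure(list(metric = metric, views = views, n_modes = n_modes,
                 weight_bounds = weight_bounds,
                 defect_level = defect_level,
                 pixel_spacing = pixel_spacing, mode = match.arg(mode),
                 step = step,
                 voxel_spacing = voxel_spacing %||% pixel_spacing,
                 threshold = threshold, maxit = maxit, factr = factr,
                 pgtol = pgtol, fd_step = fd_step, max_evals = max_evals),
            class = "recon_config")
}

view_list <- function(views) if (views == "AP_ML") c("AP", "ML") else "AP"

#' Generate reconstruction targets from a truth specimen
#'
#' Projects the specimen into each configured view with the configured
#' geometry, applies the distal defect crop, and caches the target contour
#' and the masked-region boundary for the objective.
#'
#' @param truth_tets A `tet_mesh` with `cell_hu` (e.g. a held-out specimen or
#'   `instantiate(model, b)$tets`), or a `volume_image`.
#' @param config A [recon_config()].
#' @return Named list (one entry per view) of targets, each with
#'   `radiograph`, `contour` and `v_cut`.
#' @export
make_reconstruction_targets <- function(truth_tets, config) {
  out <- list()
  for (vw in view_list(config$views)) {
    g <- projection_geometry(vw, truth_tets,
                             pixel_spacing = config$pixel_spacing,
                             mode = config$mode)
    rg <- project(truth_tets, g, step = config$step,
                  voxel_spacing = config$voxel_spacing)
    rg <- crop_defect(rg, config$defect_level)
    out[[vw]] <- list(radiograph = rg,
                      contour = extract_contour(rg, config$threshold),
                      v_cut = defect_v_cut(rg))
  }
  out
}

prox_point <- function(P) {
  i <- which(P[, 2] == min(P[, 2]))
  if (length(i) > 1) i <- i[which.min(P[i, 1])]
  P[i, ]
}

#' Reconstruction objective
#'
#' Instantiates the model at the given weights, projects it with each
#' target's geometry, masks the projection with the target's defect region,
#' aligns model and target contours (proximal-point pre-alignment followed
#' by 2D ICP) and evaluates the configured metric. The scalar objective is
#' the unweighted sum of per-view metric values (contour: mm; intensity:
#' `1 - r`).
#'
#' @param b Mode-weight vector (standard deviations).
#' @param model An `ssam`.
#' @param targets From [make_reconstruction_targets()].
#' @param config A [recon_config()].
#' @param per_view Return the per-view values instead of their sum?
#' @return Scalar objective (or named per-view vector).
#' @export
objective <- function(b, model, targets, config, per_view = FALSE) {
  inst <- instantiate(model, b)
  # rasterize once; all views project the same instance volume
  vol <- rasterize_tets(inst$tets, spacing = config$voxel_spacing)
  vals <- vapply(names(targets), function(vw) {
    tg <- targets[[vw]]
    g <- tg$radiograph$geometry
    img <- project(vol, g, step = config$step)
    mc <- extract_contour(img, config$threshold)
    # pre-translate so the most proximal points coincide, then mask the
    # model silhouette with the target's defect region
    shift <- prox_point(tg$contour$points) - prox_point(mc$points)
    P0 <- sweep(mc$points, 2, shift, "+")
    keep <- P0[, 2] < tg$v_cut - 1e-9
    if (sum(keep) < 3) stop("defect mask removed the whole contour")
    mck <- contour_2d(P0[keep, , drop = FALSE], closed = FALSE)
    # subsampled contours are plenty for the rigid 2D refinement
    sub <- function(P) P[seq(1, nrow(P), by = 2), , drop = FALSE]
    al <- align_images(contour_2d(sub(mck$points), closed = FALSE),
                       contour_2d(sub(tg$contour$points), closed = FALSE),
                       max_iter = 12, tol = 1e-3)
    if (config$metric == "contour") {
      Pal <- al$transform_points(mck$points)
      mean(cpp_point_polyline_dist(Pal, tg$contour$points, TRUE))
    } else {
      warped <- warp_radiograph(img, al)
      1 - intensity_metric(warped, tg$radiograph)
    }
  }, numeric(1))
  if (per_view) vals else sum(vals)
}

#' Reconstruct mode weights from radiographs
#'
#' Incremental bound-constrained optimisation: stage `k` (for `k = 1` to
#' `n_modes`) minimises the objective over the first `k` mode weights with
#' L-BFGS-B, bounds `+/- weight_bounds` standard deviations per mode,
#' initialised with the stage `k-1` solution padded by `0`; stage 1 starts
#' at `0`. The pipeline is deterministic.
#'
#' @param model An `ssam` with at least `config$n_modes` modes.
#' @param targets From [make_reconstruction_targets()].
#' @param config A [recon_config()].
#' @return An object of class `recon_result`: `weights`, `mesh`
#'   (reconstructed surface), `tets`, `objective_trace` (final objective per
#'   stage), `converged` (flag per stage), `per_view_residuals`.
#' @export
reconstruct <- function(model, targets, config = recon_config()) {
  if (length(model$eigenvalues) < config$n_modes)
    stop(sprintf("model has %d modes but n_modes = %d",
                 length(model$eigenvalues), config$n_modes), call. = FALSE)
  b <- numeric(0)
  trace <- numeric(config$n_modes)
  conv <- logical(config$n_modes)
  for (k in seq_len(config$n_modes)) {
    b <- c(b, 0)
    # hard evaluation budget per stage: L-BFGS-B line searches can burn
    # dozens of evaluations on the flat regions of image-driven objectives;
    # on exhaustion the best-so-far weights are kept and the stage is
    # flagged unconverged. The first evaluation is the padded previous
    # solution, so the stage trace can never increase.
    budget <- config$max_evals * (k + 1)
    n_eval <- 0L
    best_w <- b
    best_v <- Inf
    fn <- function(w) {
      if (n_eval >= budget)
        stop(structure(class = c("ossam_budget", "error", "condition"),
                       list(message = "evaluation budget exhausted",
                            call = NULL)))
      n_eval <<- n_eval + 1L
      v <- objective(w, model, targets, config)
      if (v < best_v) { best_v <<- v; best_w <<- w }
      v
    }
    # coarse-then-fine finite-difference schedule: the image metrics are
    # mildly rugged at pixel scale, and a small FD step can see only the
    # ruggedness while missing the large-scale slope
    fit <- NULL
    for (fd in unique(c(max(config$fd_step, 0.15), config$fd_step))) {
      fit <- tryCatch(
        stats::optim(b, fn, method = "L-BFGS-B",
                     lower = rep(-config$weight_bounds, k),
                     upper = rep(config$weight_bounds, k),
                     control = list(maxit = config$maxit,
                                    factr = config$factr,
                                    pgtol = config$pgtol,
                                    ndeps = rep(fd, k))),
        ossam_budget = function(e) NULL,
        error = function(e) NULL)
      if (is.finite(best_v)) b <- best_w
      if (n_eval >= budget) break
    }
    if (is.finite(best_v)) {
      b <- best_w
      trace[k] <- best_v
    } else {
      trace[k] <- objective(b, model, targets, config)
    }
    conv[k] <- !is.null(fit) && fit$convergence == 0
  }
  inst <- instantiate(model, b)
  structure(list(weights = b, mesh = inst$mesh, tets = inst$tets,
                 objective_trace = trace, converged = conv,
                 per_view_residuals = objective(b, model, targets, config,
                                                per_view = TRUE),
                 config = config), class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result: %d modes, final objective %.5g (%s, %s)\n",
              length(x$weights), x$objective_trace[length(x$objective_trace)],
              x$config$metric, x$config$views))
  cat("  weights:", paste(sprintf("%.2f", x$weights), collapse = " "), "\n")
  invisible(x)
}
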