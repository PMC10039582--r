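#' Experiment specification
#'
#' Describes a phantom-scale replication of the reconstruction experiment:
#' a seeded population, leave-one-out models, target DRRs at each defect
#' level, and reconstructions for each metric/view configuration.
#'
#' @param n_specimens Population size.
#' @param seed Population seed.
#' @param defect_levels Distal defect fractions (default 0, 0.10, 0.20,
#'   0.50).
#' @param metrics Subset of `c("contour", "intensity")`.
#' @param view_sets Subset of `c("AP", "AP_ML")`.
#' @param n_modes Modes recovered per reconstruction.
#' @param mesh_resolution,spacing Population generation settings.
#' @param pixel_spacing,mode,step,maxit,max_evals Reconstruction settings
#'   (see [recon_config()]).
#' @param use_appearance Build appearance (SSAM) models rather than
#'   shape-only models.
#' @param out Output directory (created on demand); `NULL` keeps everything
#'   in memory.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_specimens = 15, seed = 42,
                            defect_levels = c(0, 0.10, 0.20, 0.50),
                            metrics = "contour", view_sets = "AP_ML",
                            n_modes = 3, mesh_resolution = 1, spacing = 2,
                            pixel_spacing = 3, mode = "parallel", step = 3,
                            maxit = 8, max_evals = 8, use_appearance = TRUE,
                            out = NULL) {
  stopifnot(length(defect_levels) > 0, length(metrics) > 0,
            length(view_sets) > 0)
  if (any(defect_levels < 0 | defect_levels >= 1))
    stop("defect levels must lie in [0, 1)")
  if (!all(metrics %in% c("contour", "intensity")))
    stop("unknown metric")
  if (!all(view_sets %in% c("AP", "AP_ML")))
    stop("unknown view set")
  structure(as.list(environment()), class = "experiment_spec")
}

#' Run the phantom reconstruction experiment
#'
#' For every specimen: build the leave-one-out model from the remaining
#' specimens, project the held-out specimen into the configured views, crop
#' each defect level, reconstruct with every metric/view configuration, and
#' score against the intact truth mesh. Failures are logged per case and do
#' not abort the sweep. With `spec$out` set, each finished case is saved as
#' JSON (keyed by a content hash of its settings) and re-runs resume from
#' those files; the aggregated table is written as `results.csv`.
#'
#' @param spec An [experiment_spec()].
#' @param population Optional pre-built population (as from
#'   [sample_population()]) to reuse across calls.
#' @return A data.frame with one row per (specimen, defect, metric, views)
#'   case: RMSE, Hausdorff and the seven anatomical measure errors.
#' @export
run_experiment <- function(spec, population = NULL) {
  pop <- population %||% sample_population(
    spec$n_specimens, spec$seed, mesh_resolution = spec$mesh_resolution,
    spacing = spec$spacing)
  # per-specimen intensity tets
  tets <- lapply(pop, function(e) map_appearance(e$tets, e$volume))
  if (!is.null(spec$out))
    dir.create(spec$out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(pop)) {
    loo <- leave_one_out(tets, i, use_appearance = spec$use_appearance)
    truth_mesh <- pop[[i]]$mesh
    truth_meas <- compute_measures(truth_mesh)
    for (lev in spec$defect_levels) {
      for (met in spec$metrics) {
        for (vs in spec$view_sets) {
          key <- sprintf("case_s%02d_d%03d_%s_%s", i, round(100 * lev),
                         met, vs)
          cache <- if (!is.null(spec$out))
            file.path(spec$out, paste0(key, ".json")) else NULL
          if (!is.null(cache) && file.exists(cache)) {
            rows[[key]] <- as.data.frame(jsonlite::read_json(
              cache, simplifyVector = TRUE))
            next
          }
          row <- tryCatch({
            cfg <- recon_config(metric = met, views = vs,
                                n_modes = spec$n_modes,
                                defect_level = lev,
                                pixel_spacing = spec$pixel_spacing,
                                mode = spec$mode, step = spec$step,
                                maxit = spec$maxit, factr = 1e12,
                                fd_step = 0.1,
                                max_evals = spec$max_evals)
            tg <- make_reconstruction_targets(tets[[i]], cfg)
            t0 <- Sys.time()
            rec <- reconstruct(loo$model, tg, cfg)
            ev <- evaluate_case(rec$mesh, truth_mesh,
                                truth_measures = truth_meas)
            data.frame(specimen = i, defect_level = lev, metric = met,
                       views = vs, rmse = ev$rmse,
                       hausdorff = ev$hausdorff,
                       t(ev$measure_errors),
                       objective = rec$objective_trace[spec$n_modes],
                       converged = all(rec$converged),
                       seconds = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                       error = NA_character_)
          }, error = function(e) {
            data.frame(specimen = i, defect_level = lev, metric = met,
                       views = vs, rmse = NA, hausdorff = NA,
                       bow_angle = NA, faa_fma_angle = NA, neck_angle = NA,
                       diaphyseal_condylar_angle = NA, version_pca = NA,
                       version_tea = NA, head_radius = NA, objective = NA,
                       converged = FALSE, seconds = NA,
                       error = conditionMessage(e))
          })
          if (!is.null(cache))
            jsonlite::write_json(row, cache, digits = NA)
          rows[[key]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(spec$out))
    utils::write.csv(res, file.path(spec$out, "results.csv"),
                     row.names = FALSE)
  res
}
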