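#' Build a statistical shape and appearance model
#'
#' Stacks each corresponded specimen (tet-mesh node coordinates, optionally
#' followed by per-cell Hounsfield values) into one vector, computes the
#' arithmetic mean and a principal component analysis of the centred data.
#' With `n` specimens far fewer than coordinates, the PCA is computed through
#' the thin SVD (equivalent to the dual n x n Gram formulation). The
#' appearance block is rescaled to the shape block's total standard deviation
#' before the joint decomposition so neither block dominates the covariance;
#' the scaling constant is stored and undone on instantiation.
#'
#' @param specimens List of [tet_mesh()] objects sharing identical topology;
#'   at least 2. For appearance models every specimen needs `cell_hu`.
#' @param use_appearance Model intensities jointly with shape?
#' @return An object of class `ssam` with fields `mean_shape`,
#'   `mean_appearance`, `modes` (orthonormal columns), `eigenvalues`
#'   (descending), `n_specimens`, `appearance_flag`, `topology` and
#'   `app_scale`.
#' @export
build_ssam <- function(specimens, use_appearance = TRUE) {
  n <- length(specimens)
  if (n < 2) stop("need at least 2 specimens")
  ref <- specimens[[1]]
  for (s in specimens) {
    if (!inherits(s, "tet_mesh")) stop("specimens must be tet_mesh objects")
    if (!identical(dim(s$nodes), dim(ref$nodes)) ||
        !identical(s$tets, ref$tets))
      stop("specimens do not share a common topology", call. = FALSE)
    if (use_appearance && is.null(s$cell_hu))
      stop("appearance requested but a specimen lacks cell_hu",
           call. = FALSE)
  }
  nshape <- 3L * nrow(ref$nodes)
  X <- t(vapply(specimens, function(s) {
    v <- as.vector(t(s$nodes))
    if (use_appearance) v <- c(v, s$cell_hu)
    v
  }, numeric(nshape + if (use_appearance) nrow(ref$tets) else 0L)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  app_scale <- 1
  if (use_appearance) {
    sd_shape <- sqrt(sum(Xc[, seq_len(nshape), drop = FALSE]^2))
    sd_app <- sqrt(sum(Xc[, -seq_len(nshape), drop = FALSE]^2))
    if (sd_app > 0 && sd_shape > 0) app_scale <- sd_shape / sd_app
    Xc[, -seq_len(nshape)] <- Xc[, -seq_len(nshape), drop = FALSE] *
      app_scale
  }
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > max(sv$d[1], 1) * 1e-10
  if (length(keep) >= n) keep[n:length(keep)] <- FALSE  # centring: rank <= n-1
  modes <- sv$v[, keep, drop = FALSE]
  eig <- sv$d[keep]^2 / (n - 1)
  bd <- ref$boundary %||% tet_boundary(ref)
  structure(list(
    mean_shape = mu[seq_len(nshape)],
    mean_appearance = if (use_appearance) mu[-seq_len(nshape)] else NULL,
    modes = modes, eigenvalues = eig, n_specimens = n,
    appearance_flag = use_appearance, app_scale = app_scale,
    topology = list(tets = ref$tets, node_region = ref$node_region,
                    cell_region = ref$cell_region,
                    node_station = ref$node_station, boundary = bd,
                    n_nodes = nrow(ref$nodes)),
    n_shape = nshape), class = "ssam")
}

#' @export
print.ssam <- function(x, ...) {
  cat(sprintf(paste0("ssam: %d specimens, %d modes, %d nodes%s\n"),
              x$n_specimens, length(x$eigenvalues), x$topology$n_nodes,
              if (x$appearance_flag) " (+appearance)" else ""))
  if (length(x$eigenvalues)) {
    ev <- x$eigenvalues / sum(x$eigenvalues)
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * utils::head(ev, 5)), collapse = " "),
        if (length(ev) > 5) "...\n" else "\n")
  }
  invisible(x)
}

#' Instantiate a model from mode weights
#'
#' Weights are expressed in standard deviations of each mode:
#' `x = mean + sum_i b_i * sqrt(lambda_i) * e_i`. `b = 0` returns the mean
#' model.
#'
#' @param model An [build_ssam()] model.
#' @param b Numeric weight vector, length at most the number of modes.
#' @return List with `mesh` (a [surface_mesh()]) and `tets` (a [tet_mesh()]
#'   with `cell_hu` when the model has appearance).
#' @export
instantiate <- function(model, b = numeric(0)) {
  m <- length(model$eigenvalues)
  if (length(b) > m)
    stop(sprintf("weight vector has %d entries but the model has %d modes",
                 length(b), m), call. = FALSE)
  x <- c(model$mean_shape, if (model$appearance_flag)
    model$mean_appearance * model$app_scale else NULL)
  if (length(b))
    x <- x + as.vector(model$modes[, seq_along(b), drop = FALSE] %*%
                         (b * sqrt(model$eigenvalues[seq_along(b)])))
  nodes <- matrix(x[seq_len(model$n_shape)], ncol = 3, byrow = TRUE)
  hu <- if (model$appearance_flag)
    x[-seq_len(model$n_shape)] / model$app_scale else NULL
  tm <- tet_mesh(nodes, model$topology$tets, cell_hu = hu,
                 node_region = model$topology$node_region,
                 cell_region = model$topology$cell_region,
                 boundary = model$topology$boundary)
  tm$node_station <- model$topology$node_station
  list(mesh = tet_surface(tm), tets = tm)
}

#' Project a specimen onto the model modes
#'
#' Returns the weight vector (in standard-deviation units) whose
#' [instantiate()] best reproduces the specimen; for a training specimen with
#' all modes retained the reproduction is exact.
#'
#' @param model An `ssam`.
#' @param specimen A `tet_mesh` with the model topology.
#' @return Numeric weight vector, one entry per mode.
#' @export
project_weights <- function(model, specimen) {
  v <- as.vector(t(specimen$nodes))
  if (model$appearance_flag)
    v <- c(v, specimen$cell_hu * model$app_scale)
  mu <- c(model$mean_shape, if (model$appearance_flag)
    model$mean_appearance * model$app_scale else NULL)
  raw <- as.vector(crossprod(model$modes, v - mu))
  raw / sqrt(model$eigenvalues)
}

#' Leave-one-out split
#'
#' @param specimens List of corresponded `tet_mesh` objects (>= 3).
#' @param index Specimen to hold out (1-based).
#' @param use_appearance Passed to [build_ssam()].
#' @return List with `model` (built from the remaining specimens) and
#'   `held_out` (the untouched specimen).
#' @export
leave_one_out <- function(specimens, index, use_appearance = TRUE) {
  if (length(specimens) < 3) stop("need at least 3 specimens")
  if (index < 1 || index > length(specimens))
    stop("index out of range", call. = FALSE)
  list(model = build_ssam(specimens[-index], use_appearance = use_appearance),
       held_out = specimens[[index]])
}

#' Save / load a model
#'
#' Models are persisted as a single serialized container holding the mean
#' vectors, modes, eigenvalues, topology and scaling constants.
#'
#' @param model An `ssam`.
#' @param path File path.
#' @return `ssam_save` returns `path` invisibly; `ssam_load` the model.
#' @export
ssam_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname ssam_save
#' @export
ssam_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ssam")) stop("file does not contain an ssam model")
  m
}
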