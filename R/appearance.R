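#' Attach intensities to a tetrahedral mesh from a volume
#'
#' Sets each cell's Hounsfield value to the scalar of the voxel whose centre
#' is nearest the cell centroid (no interpolation).
#'
#' @param tets A [tet_mesh()].
#' @param volume A [volume_image()] covering every cell centroid.
#' @return The `tet_mesh` with `cell_hu` filled in.
#' @export
map_appearance <- function(tets, volume) {
  ctr <- (tets$nodes[tets$tets[, 1], , drop = FALSE] +
          tets$nodes[tets$tets[, 2], , drop = FALSE] +
          tets$nodes[tets$tets[, 3], , drop = FALSE] +
          tets$nodes[tets$tets[, 4], , drop = FALSE]) / 4
  d <- dim(volume$scalars)
  idx <- cbind(round((ctr[, 1] - volume$origin[1]) / volume$spacing[1]) + 1,
               round((ctr[, 2] - volume$origin[2]) / volume$spacing[2]) + 1,
               round((ctr[, 3] - volume$origin[3]) / volume$spacing[3]) + 1)
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
         idx[, 3] < 1 | idx[, 3] > d[3]
  if (any(bad))
    stop(sprintf("cell centroids outside the volume: %s",
                 paste(utils::head(which(bad), 10), collapse = ", ")),
         call. = FALSE)
  tets$cell_hu <- volume$scalars[cbind(idx[, 1], idx[, 2], idx[, 3])]
  tets
}
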