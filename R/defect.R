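#' Simulate a distal bone defect on a radiograph
#'
#' Masks out the image rows covering the distal `defect_level` fraction of
#' the projected bone length: the affected pixels are set to background and
#' `defect_mask` is cleared there. Rows are counted over the projected bone
#' extent along the image's long axis; distal means larger row indices
#' (rows run proximal to distal). A level of 0 returns the image unchanged.
#'
#' @param image A [radiograph()] with a known bone extent.
#' @param defect_level Fraction of the bone length to remove, in `[0, 1)`.
#' @return The cropped [radiograph()]; the original (pre-crop) extent is
#'   kept in `bone_extent`.
#' @export
crop_defect <- function(image, defect_level) {
  if (!is.numeric(defect_level) || defect_level < 0 || defect_level >= 1)
    stop("defect_level must lie in [0, 1)", call. = FALSE)
  if (defect_level == 0) return(image)
  ext <- image$bone_extent
  if (anyNA(ext)) stop("bone extent unknown (empty image)", call. = FALSE)
  nrows <- ext[2] - ext[1] + 1
  k <- round(defect_level * nrows)
  if (k > 0) {
    rows <- seq.int(ext[2] - k + 1, ext[2])
    image$pixels[rows, ] <- 0
    image$defect_mask[rows, ] <- FALSE
  }
  image
}

# first masked-out v coordinate (mm); +Inf when the image has no defect
defect_v_cut <- function(image) {
  bad <- which(!apply(image$defect_mask, 1, all))
  if (!length(bad)) return(Inf)
  g <- image$geometry
  (min(bad) - 1 - g$nv / 2) * g$pixel_spacing
}
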