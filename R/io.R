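#' Write a surface mesh to STL (ASCII)
#'
#' @param mesh A `surface_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices; Tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid ossam", con)
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  txt <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
    b[, 1], b[, 2], b[, 3], c_[, 1], c_[, 2], c_[, 3])
  writeLines(txt, con)
  writeLines("endsolid ossam", con)
  invisible(path)
}

#' Read an ASCII STL file
#' @param path STL file path.
#' @return A `surface_mesh` (vertices welded by exact coordinate match).
#' @export
read_stl <- function(path) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris)
}

#' Write a surface mesh to PLY (ASCII)
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices; Tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(Tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", Tr[, 1] - 1, Tr[, 2] - 1, Tr[, 3] - 1),
             con)
  invisible(path)
}

#' Write a volume to MetaImage (.mha, local raw payload)
#' @param volume A `volume_image`.
#' @param path Output path (conventionally `.mha`).
#' @return `path`, invisibly.
#' @export
write_mha <- function(volume, path) {
  d <- dim(volume$scalars)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %g %g %g", volume$origin[1], volume$origin[2],
                   volume$origin[3]),
           "CenterOfRotation = 0 0 0",
           "AnatomicalOrientation = RAS",
           sprintf("ElementSpacing = %g %g %g", volume$spacing[1],
                   volume$spacing[2], volume$spacing[3]),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_FLOAT", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$scalars), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a radiograph as 16-bit plain PGM plus a JSON sidecar
#'
#' The portable greymap (P2, plain text) keeps the deliverable text-only;
#' the sidecar records the projection geometry, defect mask rows and bone
#' extent.
#'
#' @param image A `radiograph`.
#' @param path Output stem; `.pgm` and `.json` are appended.
#' @return The two paths, invisibly.
#' @export
write_radiograph <- function(image, path) {
  px <- round(image$pixels * 65535)
  pgm <- paste0(path, ".pgm")
  con <- file(pgm, "w")
  writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)), "65535"), con)
  writeLines(apply(px, 1, paste, collapse = " "), con)
  close(con)
  g <- image$geometry
  meta <- list(view = g$view, mode = g$mode,
               source_distance = g$source_distance,
               pixel_spacing = g$pixel_spacing, nu = g$nu, nv = g$nv,
               det_center = g$det_center, source = g$source,
               bone_extent = image$bone_extent,
               masked_rows = which(!apply(image$defect_mask, 1, all)))
  js <- paste0(path, ".json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(pgm, js))
}

#' Write a contour as CSV
#' @param contour A `contour_2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(data.frame(u = contour$points[, 1],
                              v = contour$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write landmarks to a JSON sidecar
#' @param landmarks A `landmark_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
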