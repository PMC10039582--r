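#' 2D contour in detector coordinates
#'
#' @param points `n x 2` matrix of (u, v) detector coordinates in mm
#'   (v grows distally). Consecutive duplicate points are removed.
#' @param closed Is the polyline closed?
#' @return An object of class `contour_2d`.
#' @export
contour_2d <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("contour points must be n x 2")
  if (nrow(points) > 1) {
    d <- rowSums(abs(diff(points)))
    points <- points[c(TRUE, d > 1e-12), , drop = FALSE]
    if (closed && nrow(points) > 1 &&
        sum(abs(points[1, ] - points[nrow(points), ])) < 1e-12)
      points <- points[-nrow(points), , drop = FALSE]
  }
  if (closed && nrow(points) < 3) stop("closed contour needs >= 3 points")
  structure(list(points = points, closed = closed), class = "contour_2d")
}

#' @export
print.contour_2d <- function(x, ...) {
  cat(sprintf("contour_2d: %d points (%s)\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Extract the outer silhouette contour of a radiograph
#'
#' Thresholds the image, keeps the largest above-threshold connected
#' component, and traces the iso-intensity level around it with a
#' marching-squares contour at sub-pixel positions (linear interpolation
#' along pixel edges). The outermost closed loop (largest enclosed area) is
#' returned in detector mm.
#'
#' @param image A [radiograph()].
#' @param threshold Iso level; defaults to 0.01 of the intensity range.
#' @return A closed [contour_2d()].
#' @export
extract_contour <- function(image, threshold = 0.01) {
  img <- image$pixels
  fg <- img >= threshold
  if (!any(fg)) stop("no pixel above threshold", call. = FALSE)
  lab <- cpp_label_components(fg)
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  work <- img
  work[fg & lab != big] <- 0
  nr <- nrow(work); nc <- ncol(work)
  F <- matrix(0, nr + 2, nc + 2)
  F[2:(nr + 1), 2:(nc + 1)] <- work
  segs <- msq_trace(F, threshold)
  loops <- msq_link(segs)
  if (!length(loops)) stop("no closed contour found", call. = FALSE)
  areas <- vapply(loops, function(P) {
    x <- P[, 1]; y <- P[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  P <- loops[[which.max(areas)]]
  # padded grid coords -> original pixel indices -> detector mm
  col <- P[, 1] - 1; row <- P[, 2] - 1
  g <- image$geometry
  u <- (col - 0.5 - g$nu / 2) * g$pixel_spacing
  v <- (row - 0.5 - g$nv / 2) * g$pixel_spacing
  contour_2d(cbind(u, v), closed = TRUE)
}

# collect marching-squares segments (vectorised); endpoints keyed by
# integer grid-edge ids
msq_trace <- function(F, t) {
  nr <- nrow(F); nc <- ncol(F)
  B <- F >= t
  A <- B[-nr, -nc]; Bc <- B[-nr, -1]; Cc <- B[-1, -1]; D <- B[-1, -nc]
  case <- A + 2L * Bc + 4L * Cc + 8L * D
  act <- which(case > 0L & case < 15L)
  if (!length(act)) return(list(a = integer(0)))
  ncc <- nr - 1L
  i <- ((act - 1L) %% ncc) + 1L
  j <- ((act - 1L) %/% ncc) + 1L
  a <- F[cbind(i, j)]; b <- F[cbind(i, j + 1L)]
  cc <- F[cbind(i + 1L, j + 1L)]; d <- F[cbind(i + 1L, j)]
  cs <- case[act]
  interp <- function(v1, v2) {
    dv <- v2 - v1
    ifelse(abs(dv) < 1e-300, 0.5, pmin(pmax((t - v1) / dv, 0), 1))
  }
  # crossing position and id per edge (1 top, 2 right, 3 bottom, 4 left);
  # edge ids: horizontal edge at (row, col) -> 2*(row*(nc+1)+col),
  # vertical -> that + 1
  ex <- cbind(j + interp(a, b), j + 1, j + interp(d, cc), j)
  ey <- cbind(i, i + interp(b, cc), i + 1, i + interp(a, d))
  eid <- cbind(2L * (i * (nc + 1L) + j),
               2L * ((i + 1L) * (nc + 1L) + j + 1L) + 1L,
               2L * ((i + 1L) * (nc + 1L) + j),
               2L * ((i + 1L) * (nc + 1L) + j) + 1L)
  # first/second edge per segment for each case (0 = none);
  # ambiguous cases 5 and 10 resolved by the cell-centre average
  e1 <- c(4, 1, 4, 2, NA, 1, 4, 3, 1, NA, 2, 2, 1, 4)[cs]
  e2 <- c(1, 2, 2, 3, NA, 3, 3, 4, 3, NA, 3, 4, 2, 1)[cs]
  amb <- is.na(e1)
  if (any(amb)) {
    ctr_in <- (a + b + cc + d)[amb] / 4 >= t
    c5 <- cs[amb] == 5
    # case 5: centre in -> (1,2),(4,3); out -> (1,4),(2,3)
    # case 10: centre in -> (1,4),(2,3); out -> (1,2),(3,4)
    e1[amb] <- 1L
    e2[amb] <- ifelse(xor(c5, ctr_in), 4L, 2L)
    # second segment appended below
    idx2 <- which(amb)
    e1b <- ifelse(xor(c5, ctr_in), 2L, 4L)
    e2b <- 3L
    i <- c(i, i[idx2]); j <- c(j, j[idx2])
    ex <- rbind(ex, ex[idx2, , drop = FALSE])
    ey <- rbind(ey, ey[idx2, , drop = FALSE])
    eid <- rbind(eid, eid[idx2, , drop = FALSE])
    e1 <- c(e1, e1b); e2 <- c(e2, e2b)
  }
  n <- length(e1)
  pick <- function(M, e) M[cbind(seq_len(n), e)]
  list(a = pick(eid, e1), b = pick(eid, e2),
       ax = pick(ex, e1), ay = pick(ey, e1),
       bx = pick(ex, e2), by = pick(ey, e2))
}

# link segments into closed loops by shared edge ids
msq_link <- function(segs) {
  ns <- length(segs$a)
  if (!ns) return(list())
  ids <- unique(c(segs$a, segs$b))
  a <- match(segs$a, ids); b <- match(segs$b, ids)
  coord <- matrix(NA_real_, length(ids), 2)
  coord[a, ] <- cbind(segs$ax, segs$ay)
  coord[b, ] <- cbind(segs$bx, segs$by)
  adj <- vector("list", length(ids))
  for (s in seq_len(ns)) {
    adj[[a[s]]] <- c(adj[[a[s]]], s)
    adj[[b[s]]] <- c(adj[[b[s]]], s)
  }
  used <- logical(ns)
  loops <- list()
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    path <- integer(0)
    cur <- a[s0]; s <- s0
    repeat {
      used[s] <- TRUE
      path <- c(path, cur)
      nxt <- if (a[s] == cur) b[s] else a[s]
      cand <- adj[[nxt]]
      cand <- cand[!used[cand]]
      if (!length(cand)) { path <- c(path, nxt); break }
      cur <- nxt; s <- cand[1]
    }
    pts <- coord[path, , drop = FALSE]
    if (nrow(pts) >= 3 &&
        sum(abs(pts[1, ] - pts[nrow(pts), ])) < 1e-9)
      pts <- pts[-nrow(pts), , drop = FALSE]
    if (nrow(pts) >= 3) loops[[length(loops) + 1]] <- pts
  }
  loops
}
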