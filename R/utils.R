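`%||%` <- function(a, b) if (is.null(a)) b else a

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two 3D vectors
#'
#' Numerically stable angle via `atan2(|u x v|, u . v)`.
#'
#' @param u,v Numeric 3-vectors (need not be unit length).
#' @param line If `TRUE`, treat the vectors as undirected lines and return the
#'   acute angle (in `[0, 90]` degrees).
#' @return Angle in degrees.
#' @export
vector_angle <- function(u, v, line = FALSE) {
  ang <- atan2(sqrt(sum(cross3(u, v)^2)), sum(u * v)) * 180 / pi
  if (line && ang > 90) ang <- 180 - ang
  ang
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  u <- unit3(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %g violates bound (%g, %g)", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}
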