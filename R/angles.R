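#' Normalize angles to the (-180, 180] degree convention
#'
#' All backbone dihedrals in this package live on the torus with each
#' coordinate reported in degrees in the half-open interval (-180, 180].
#' `NA` (an undefined angle, e.g. at a chain terminus) passes through.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each value in (-180, 180].
#' @examples
#' normalize_angle(c(540, -180, 180, 0, 181))
#' @export
normalize_angle <- function(x) {
  stopifnot(is.numeric(x))
  180 - ((180 - x) %% 360)
}

# Wrap an angular difference into [-180, 180]. Used by the torus metric.
wrap_diff <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Euclidean distance on the (phi, psi) torus
#'
#' Each coordinate difference is wrapped to \[-180, 180\] before the usual
#' Euclidean norm, so points separated by a full turn coincide. Both axes
#' are weighted equally. Vectorized over the first pair.
#'
#' @param phi1,psi1 numeric vectors, angles in degrees.
#' @param phi2,psi2 numeric scalars or vectors, angles in degrees.
#' @return numeric vector of distances in degrees.
#' @export
torus_distance <- function(phi1, psi1, phi2, psi2) {
  sqrt(wrap_diff(phi1 - phi2)^2 + wrap_diff(psi1 - psi2)^2)
}

# Signed dihedral angle (degrees) of four 3-D points given as rows of a
# 4 x 3 matrix, by the standard atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3))
# formula. Returns a value in (-180, 180].
dihedral4 <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * c23), sum(c12 * c23)) * 180 / pi
  normalize_angle(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
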