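#' Angular separation on a circle of span `w`
#'
#' Shortest arc between two angular coordinates on a circle whose full span is
#' `w` radians (the similarity dimension of the hyperbolic disc uses `w = 2*pi`
#' by default, but any positive span is supported).
#'
#' @param theta1,theta2 Numeric vectors of angles in `[0, w)`. Recycled.
#' @param w Angular span of the circle in radians (default `2*pi`).
#'
#' @return Numeric vector of separations in `[0, w/2]`.
#' @examples
#' angular_separation(0.1, 2 * pi - 0.1) # wraps around: 0.2
#' @export
angular_separation <- function(theta1, theta2, w = 2 * pi) {
  stopifnot(is.numeric(theta1), is.numeric(theta2), w > 0)
  d <- abs(theta1 - theta2)
  pmin(d, w - d)
}

#' Hyperbolic distance between points of the hyperbolic plane
#'
#' Distance under the native (polar) representation of the hyperbolic plane
#' with curvature -1: `d = acosh(cosh(r1) cosh(r2) - sinh(r1) sinh(r2) cos(dtheta))`,
#' where `dtheta` is [angular_separation()]. Collinear points (`dtheta ~ 0`)
#' are handled as `|r1 - r2|` to avoid catastrophic cancellation, and the
#' `acosh` argument is clamped at 1 against round-off.
#'
#' @param r1,theta1 Polar coordinates of the first point (radius >= 0, angle in
#'   `[0, w)`). Vectors are recycled.
#' @param r2,theta2 Polar coordinates of the second point.
#' @param w Angular span in radians (default `2*pi`).
#'
#' @return Numeric vector of nonnegative distances.
#' @examples
#' hyperbolic_distance(2, 0, 5, 0)   # radial: 3
#' hyperbolic_distance(5, 0, 5, pi)  # diametral: 10
#' @export
hyperbolic_distance <- function(r1, theta1, r2, theta2, w = 2 * pi) {
  stopifnot(all(r1 >= 0), all(r2 >= 0))
  dtheta <- angular_separation(theta1, theta2, w)
  arg <- cosh(r1) * cosh(r2) - sinh(r1) * sinh(r2) * cos(dtheta)
  d <- acosh(pmax(arg, 1))
  collinear <- dtheta < 1e-12
  if (any(collinear)) {
    d[collinear] <- rep_len(abs(r1 - r2), length(d))[collinear]
  }
  d
}

#' Absolute radial difference
#'
#' `|r1 - r2|`, the popularity-dimension gap between two nodes; equals the
#' hyperbolic distance when the angular separation is zero.
#'
#' @param r1,r2 Numeric radius vectors.
#' @return Numeric vector of nonnegative differences.
#' @export
radial_difference <- function(r1, r2) {
  abs(r1 - r2)
}
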