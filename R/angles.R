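#' Angle utilities
#'
#' All user-facing angles in this package are in degrees, normalized to
#' \[0, 360). Angle 0 is the plate-plane projection of the imposed field's
#' north direction; positive rotation follows the compass (clockwise)
#' convention. Only relative angles enter any statistic, so the convention
#' merely has to be applied consistently.
#'
#' @name angles
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize angles to \[0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with each angle reduced modulo 360 into \[0, 360).
#' @examples
#' norm_angle(c(-10, 360, 725))
#' @export
norm_angle <- function(x) {
  stopifnot(is.numeric(x))
  out <- x %% 360
  # %% can return 360 for tiny negative inputs via floating point
  out[out >= 360] <- 0
  out
}

#' Minimal signed angular difference a - b
#'
#' Returns the smallest signed rotation taking direction `b` onto direction
#' `a`, in degrees in (-180, 180]. Antipodal pairs map to +180 by convention.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return signed degrees in (-180, 180].
#' @examples
#' angular_difference(350, 10)   # -20
#' angular_difference(10, 190)   # 180
#' @export
angular_difference <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Absolute circular distance between two directions
#'
#' @param a,b angles in degrees.
#' @return degrees in \[0, 180\].
#' @export
circular_distance <- function(a, b) abs(angular_difference(a, b))
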