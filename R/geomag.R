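#' Local geomagnetic fields and predicted vertical-migration headings
#'
#' The earth's field at a site is described by its horizontal and vertical
#' intensity components (Gauss), total intensity, inclination (dip angle,
#' degrees; positive when the field points into the ground, as in the
#' northern hemisphere) and declination (carried for bookkeeping; the
#' imposed field direction defines the assay frame, so declination enters no
#' prediction).
#'
#' A worm crawling on a plate traversed by the field at inclination I that
#' wants to translate straight up must move at angle 90 + I degrees to the
#' field vector: a movement direction at angle theta from the field, within
#' the vertical plane containing the field, has elevation theta - I, and
#' elevation +90 gives theta = 90 + I. A flat two-dimensional assay cannot
#' distinguish a rotation of +theta from -theta about the field, so the
#' mirror candidate (270 - I mod 360) is reported alongside it rather than
#' silently resolved. Down candidates are the antipodes of the up
#' candidates.
#'
#' @name geomag
NULL

#' Build a geomagnetic field description from its components
#'
#' @param horizontal horizontal intensity, Gauss (>= 0).
#' @param vertical signed vertical intensity, Gauss; positive = downward
#'   (into the ground, northern-hemisphere sense).
#' @param declination degrees east of geographic north; informational only.
#' @return an object of class `geomag_field`: a list with fields
#'   `horizontal_intensity`, `vertical_intensity`, `total_intensity`,
#'   `inclination` (degrees, in \[-90, 90\]) and `declination`.
#' @examples
#' f <- field_from_components(0.245, 0.413)
#' f$total_intensity   # ~0.480 Gauss
#' f$inclination       # ~59.3 degrees, dipping down
#' @export
field_from_components <- function(horizontal, vertical, declination = NA_real_) {
  stopifnot(is.numeric(horizontal), length(horizontal) == 1L,
            is.numeric(vertical), length(vertical) == 1L)
  if (horizontal < 0) stop("horizontal intensity must be >= 0")
  if (horizontal == 0 && vertical == 0)
    stop("null field: both components zero, inclination undefined")
  structure(
    list(
      horizontal_intensity = horizontal,
      vertical_intensity   = vertical,
      total_intensity      = sqrt(horizontal^2 + vertical^2),
      inclination          = rad2deg(atan2(vertical, horizontal)),
      declination          = declination
    ),
    class = "geomag_field"
  )
}

#' @export
print.geomag_field <- function(x, ...) {
  cat(sprintf(
    "Geomagnetic field: H = %.4g G, V = %.4g G, total = %.4g G, inclination = %.2f deg\n",
    x$horizontal_intensity, x$vertical_intensity, x$total_intensity,
    x$inclination))
  invisible(x)
}

#' Predicted optimal migration angles for vertical translation
#'
#' Given the local inclination, returns both mirror-image candidate headings
#' (relative to the field vector) whose vertical translation is maximally
#' upward, and their antipodes for downward translation. At inclination 0
#' (magnetic equator) the up and down candidate sets coincide at
#' \{90, 270\} and the prediction is flagged degenerate.
#'
#' @param inclination signed dip angle in degrees, in \[-90, 90\].
#' @return object of class `vertical_heading_prediction`: list with
#'   `up_candidates` (two degrees values), `down_candidates` (their
#'   antipodes, in matching order), `inclination_used`, and `degenerate`.
#' @examples
#' optimal_vertical_headings(66.3)$up_candidates   # 156.3, 203.7
#' optimal_vertical_headings(66.3)$down_candidates # 336.3,  23.7
#' @export
optimal_vertical_headings <- function(inclination) {
  stopifnot(is.numeric(inclination), length(inclination) == 1L)
  if (abs(inclination) > 90)
    stop("inclination must lie in [-90, 90] degrees")
  up <- norm_angle(c(90 + inclination, 270 - inclination))
  structure(
    list(
      up_candidates    = up,
      down_candidates  = norm_angle(up + 180),
      inclination_used = inclination,
      degenerate       = inclination == 0
    ),
    class = "vertical_heading_prediction"
  )
}

#' @export
print.vertical_heading_prediction <- function(x, ...) {
  cat(sprintf("Vertical-migration prediction (inclination %.1f deg)%s\n",
              x$inclination_used,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  up:   %.1f / %.1f deg\n", x$up_candidates[1], x$up_candidates[2]))
  cat(sprintf("  down: %.1f / %.1f deg\n", x$down_candidates[1], x$down_candidates[2]))
  invisible(x)
}

#' Resolve the mirror ambiguity against an observed mean heading
#'
#' A plate assay cannot distinguish the two mirror candidates geometrically;
#' data can. Returns the candidate (up or down sense) closest to the
#' observed mean direction in circular distance, breaking exact ties toward
#' the (90 + I)-branch candidate (the first listed).
#'
#' @param prediction a `vertical_heading_prediction`.
#' @param observed_mean observed mean heading, degrees.
#' @param sense `"up"` or `"down"`.
#' @return the selected candidate heading in degrees.
#' @examples
#' p <- optimal_vertical_headings(66.3)
#' select_candidate(p, observed_mean = 132, sense = "up")   # 156.3
#' @export
select_candidate <- function(prediction, observed_mean, sense = c("up", "down")) {
  stopifnot(inherits(prediction, "vertical_heading_prediction"),
            is.numeric(observed_mean), length(observed_mean) == 1L)
  sense <- match.arg(sense)
  if (prediction$degenerate)
    stop("degenerate prediction: up/down candidates coincide at inclination 0")
  cand <- if (sense == "up") prediction$up_candidates else prediction$down_candidates
  d <- circular_distance(cand, observed_mean)
  # ties break toward the first (90 + I branch) candidate: which.min does that
  cand[which.min(d)]
}
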