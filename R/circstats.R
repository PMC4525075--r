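#' Circular statistics for heading samples
#'
#' Descriptive and inferential statistics on per-worm migration angles:
#' the mean resultant vector, the Rayleigh test of uniformity and the
#' V test against an a-priori expected direction, plus the 18 x 20-degree
#' binned histogram used for circular plots.
#'
#' Population-level inference treats each worm as one observation (samples
#' are pooled across assay plates); [per_assay_summaries()] provides the
#' per-plate alternative for sensitivity checks.
#'
#' @name circstats
NULL

#' Construct a heading sample
#'
#' @param angles numeric vector of migration angles in degrees; normalized
#'   to \[0, 360).
#' @param strain,satiation,assay_id optional metadata labels; `satiation`
#'   is `"fed"` or `"starved"` when given.
#' @return object of class `heading_sample`.
#' @export
heading_sample <- function(angles, strain = NA_character_,
                           satiation = NA_character_,
                           assay_id = NA_character_) {
  stopifnot(is.numeric(angles), length(angles) >= 1L, all(is.finite(angles)))
  if (!is.na(satiation)) satiation <- match.arg(satiation, c("fed", "starved"))
  structure(
    list(angles = norm_angle(angles), strain = strain,
         satiation = satiation, assay_id = assay_id),
    class = "heading_sample"
  )
}

as_angles <- function(sample) {
  if (inherits(sample, "heading_sample")) sample$angles
  else if (is.numeric(sample)) norm_angle(sample)
  else stop("expected a heading_sample or a numeric vector of degrees")
}

#' Mean direction and resultant length of a heading sample
#'
#' The mean resultant vector is the vector average of unit headings; its
#' length R is 0 for a perfectly balanced sample and 1 when every worm
#' migrated in the same direction. The mean direction is undefined (NA)
#' when R is exactly 0.
#'
#' @param sample a [heading_sample()] or numeric vector of degrees.
#' @return object of class `circular_summary`: list with `mean_direction`
#'   (degrees in \[0, 360) or NA), `R` (in \[0, 1\]) and `n`.
#' @examples
#' circular_summary(c(10, 20, 30))  # mean 20, R ~ 0.99
#' @export
circular_summary <- function(sample) {
  a <- deg2rad(as_angles(sample))
  n <- length(a)
  C <- mean(cos(a))
  S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  # below ~1e-12 the resultant is numerically zero (e.g. exact antipodes)
  # and the mean direction carries no information
  mean_dir <- if (R < 1e-12) NA_real_ else norm_angle(rad2deg(atan2(S, C)))
  structure(list(mean_direction = mean_dir, R = R, n = n),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Circular summary: n = %d, mean = %s deg, R = %.4f\n",
              x$n,
              if (is.na(x$mean_direction)) "undefined"
              else sprintf("%.1f", x$mean_direction),
              x$R))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that headings are uniformly distributed around
#' the circle against a unimodal alternative, using z = n R^2 with Zar's
#' small-sample-corrected p approximation
#' p = exp(-z) \[1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288 n^2)\],
#' clamped to (0, 1].
#'
#' @param sample a [heading_sample()] or numeric vector of degrees (n >= 3).
#' @return list with `z`, `p`, `R`, `n`.
#' @export
rayleigh_test <- function(sample) {
  a <- as_angles(sample)
  n <- length(a)
  if (n < 3) stop("Rayleigh test requires n >= 3 headings")
  R <- circular_summary(a)$R
  z <- n * R^2
  p <- rayleigh_p(z, n)
  list(z = z, p = p, R = R, n = n)
}

# Zar's corrected Rayleigh p; vectorized over z (n scalar or same length)
rayleigh_p <- function(z, n) {
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' V test against an a-priori expected direction
#'
#' A modification of the Rayleigh test whose power is concentrated at a
#' direction fixed before seeing the data: V = R cos(mean - expected),
#' u = V sqrt(2n), with a one-tailed upper-tail standard-normal p-value.
#' Significance indicates non-uniform headings concentrated toward the
#' expected direction.
#'
#' @param sample a [heading_sample()] or numeric vector of degrees (n >= 3).
#' @param expected_direction degrees; must be chosen independently of the
#'   sample (here, from geomagnetic geometry).
#' @return list with `V`, `u`, `p`, `n`, `expected_direction`.
#' @export
v_test <- function(sample, expected_direction) {
  a <- as_angles(sample)
  n <- length(a)
  if (n < 3) stop("V test requires n >= 3 headings")
  stopifnot(is.numeric(expected_direction), length(expected_direction) == 1L)
  cs <- circular_summary(a)
  V <- if (is.na(cs$mean_direction)) 0
       else cs$R * cos(deg2rad(cs$mean_direction - expected_direction))
  u <- V * sqrt(2 * n)
  list(V = V, u = u, p = stats::pnorm(u, lower.tail = FALSE), n = n,
       expected_direction = norm_angle(expected_direction))
}

#' Bin headings into the standard 18 x 20-degree circular histogram
#'
#' Bins are half-open \[edge, edge + 20) and edge-aligned at 0 degrees;
#' counts are converted to percent of the sample, matching the circular
#' plots in which the plot radius marks 10% of the animals.
#'
#' @param sample a [heading_sample()] or numeric vector of degrees.
#' @param bin_width degrees per bin; must divide 360. Default 20.
#' @return object of class `circular_histogram`: list with `bin_edges`
#'   (length bins + 1: 0, 20, ..., 360), `bin_percent` (sums to 100) and
#'   `bin_count`.
#' @export
bin_headings <- function(sample, bin_width = 20) {
  a <- as_angles(sample)
  stopifnot(length(a) >= 1L, bin_width > 0, 360 %% bin_width == 0)
  edges <- seq(0, 360, by = bin_width)
  idx <- floor(a / bin_width) + 1L   # half-open [edge, edge + w)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(bin_edges = edges, bin_count = counts,
         bin_percent = 100 * counts / length(a)),
    class = "circular_histogram"
  )
}

#' Per-assay circular summaries
#'
#' The per-plate alternative to pooling: summarizes each assay's headings
#' separately so second-order analyses can treat plates as the unit.
#'
#' @param headings data frame with columns `assay_id` and `angle_deg`.
#' @return data frame with one row per assay: `assay_id`, `mean_deg`, `R`, `n`.
#' @export
per_assay_summaries <- function(headings) {
  stopifnot(is.data.frame(headings),
            all(c("assay_id", "angle_deg") %in% names(headings)))
  out <- lapply(split(headings$angle_deg, headings$assay_id), function(a) {
    cs <- circular_summary(a)
    data.frame(mean_deg = cs$mean_direction, R = cs$R, n = cs$n)
  })
  cbind(data.frame(assay_id = names(out)),
        do.call(rbind, unname(out)))
}
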