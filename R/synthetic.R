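#' Seeded synthetic-data generators
#'
#' Generators with the statistical structure the analysis assumes:
#' von Mises headings around a preferred direction, binomial two-choice
#' assay counts, linear index-vs-field-parameter isolate tables, and
#' fluorescence traces with exponential photobleaching plus stimulus-locked
#' transients. Every generator is deterministic under a fixed seed
#' (bit-identical re-runs) and leaves the caller's RNG state untouched.
#'
#' @name synthetic_data
NULL

# run code under a seed without disturbing the global RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw von Mises headings
#'
#' Samples `n` angles from a von Mises distribution with mean direction
#' `mean_direction` (degrees) and concentration `kappa`, by Best-Fisher
#' rejection sampling from a wrapped Cauchy envelope. `kappa = 0` yields
#' uniform headings; large `kappa` degenerates to the mean.
#'
#' @param n number of worms.
#' @param mean_direction preferred heading, degrees.
#' @param kappa concentration parameter (>= 0; dimensionless). The package
#'   default of 1 approximates the dispersion of unimodal worm-heading
#'   histograms.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param strain,satiation,assay_id metadata passed to [heading_sample()].
#' @return a [heading_sample()] of `n` angles in \[0, 360).
#' @examples
#' s <- sample_headings(200, mean_direction = 132, kappa = 1, seed = 1)
#' circular_summary(s)
#' @export
sample_headings <- function(n, mean_direction, kappa = 1, seed = NULL,
                            strain = NA_character_, satiation = NA_character_,
                            assay_id = NA_character_) {
  stopifnot(n >= 1, is.numeric(mean_direction), is.numeric(kappa))
  if (kappa < 0) stop("kappa must be >= 0")
  ang <- with_local_seed(seed, {
    if (kappa == 0) {
      stats::runif(n, 0, 360)
    } else {
      rad2deg(rvonmises(n, deg2rad(mean_direction), kappa))
    }
  })
  heading_sample(ang, strain = strain, satiation = satiation,
                 assay_id = assay_id)
}

# Best & Fisher (1979) rejection sampler; mu in radians, returns radians
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c <- kappa * (r - f)
    if (c * (2 - c) - u2 > 0 || log(c / u2) + 1 - c >= 0) {
      u3 <- stats::runif(1)
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

#' Simulate two-choice assay counts
#'
#' Per assay, the number of worms reaching either goal is binomial in the
#' plated worms (`arrival_fraction`), and each arrival independently
#' chooses side A with probability `choice_probability`.
#'
#' @param n_assays number of replicate assays.
#' @param choice_probability probability an arriving worm ends at side A
#'   (the magnet goal / end A).
#' @param worms_per_assay worms plated per assay. Default 48, the typical
#'   plate load.
#' @param arrival_fraction fraction of plated worms reaching either goal.
#'   Default 1.
#' @param seed integer seed or NULL.
#' @param strain,satiation,assay_type metadata labels recycled across rows.
#' @return data frame with columns `assay_id`, `strain`, `satiation`,
#'   `assay_type`, `side_a`, `side_b`.
#' @export
simulate_assay_counts <- function(n_assays, choice_probability,
                                  worms_per_assay = 48, arrival_fraction = 1,
                                  seed = NULL, strain = "N2",
                                  satiation = "fed", assay_type = "magnet") {
  stopifnot(n_assays >= 1, worms_per_assay >= 1)
  if (choice_probability < 0 || choice_probability > 1)
    stop("choice_probability must lie in [0, 1]")
  if (arrival_fraction < 0 || arrival_fraction > 1)
    stop("arrival_fraction must lie in [0, 1]")
  with_local_seed(seed, {
    arrivals <- stats::rbinom(n_assays, worms_per_assay, arrival_fraction)
    side_a <- stats::rbinom(n_assays, arrivals, choice_probability)
    data.frame(assay_id = sprintf("assay_%03d", seq_len(n_assays)),
               strain = strain, satiation = satiation,
               assay_type = assay_type,
               side_a = side_a, side_b = arrivals - side_a)
  })
}

#' Simulate a fluorescence trace with bleaching and stimulus transients
#'
#' intensity(t) = f0 exp(-t / bleach_tau) (1 + sum amplitude box(t)) plus
#' Gaussian noise with standard deviation `noise_sd` percent of the
#' (decaying) baseline. The boxcar transient spans exactly the stimulus
#' epoch, so window means round-trip exactly in the noiseless case; set
#' `kernel = "alpha"` for a smooth rise-and-decay transient when testing
#' robustness to non-square responses.
#'
#' @param epochs data frame with columns `onset_s`, `duration_s`,
#'   `amplitude_pct` (percent above baseline); must be non-overlapping and
#'   lie within the recording.
#' @param f0 initial brightness, arbitrary units. Default 100.
#' @param bleach_tau photobleaching time constant, seconds. Default 60.
#' @param noise_sd Gaussian noise, percent of baseline. Default 0.
#' @param sample_rate frames per second, in \[3.5, 8\]. Default 8.
#' @param total_duration recording length, seconds. Default 50 (the
#'   standard 12.5 s baseline + 6 s stimulus + 31.5 s recovery run).
#' @param kernel `"boxcar"` (default) or `"alpha"` transient shape.
#' @param seed integer seed or NULL.
#' @param worm_id,neuron,genotype metadata labels.
#' @return list with `trace` (data frame `worm_id`, `neuron`, `time_s`,
#'   `intensity`) and `epochs` (the annotations, with `worm_id`).
#' @export
simulate_trace <- function(epochs, f0 = 100, bleach_tau = 60, noise_sd = 0,
                           sample_rate = 8, total_duration = 50,
                           kernel = c("boxcar", "alpha"), seed = NULL,
                           worm_id = "worm_01", neuron = "AFD",
                           genotype = "wild-type") {
  kernel <- match.arg(kernel)
  stopifnot(is.data.frame(epochs),
            all(c("onset_s", "duration_s", "amplitude_pct") %in% names(epochs)),
            f0 > 0, bleach_tau > 0, noise_sd >= 0,
            sample_rate >= 3.5, sample_rate <= 8, total_duration > 0)
  ep <- epochs[order(epochs$onset_s), , drop = FALSE]
  ends <- ep$onset_s + ep$duration_s
  if (any(ep$onset_s < 0) || any(ends > total_duration))
    stop("stimulus epochs must lie within [0, total_duration]")
  if (nrow(ep) > 1 && any(ep$onset_s[-1] < ends[-nrow(ep)]))
    stop("stimulus epochs overlap")

  t <- seq(0, total_duration, by = 1 / sample_rate)
  transient <- rep(0, length(t))
  for (i in seq_len(nrow(ep))) {
    amp <- ep$amplitude_pct[i] / 100
    if (kernel == "boxcar") {
      on <- t >= ep$onset_s[i] & t <= ends[i]
      transient[on] <- transient[on] + amp
    } else {
      # alpha kernel peaking mid-stimulus, normalized to peak = amplitude
      tau_k <- ep$duration_s[i] / 2
      dt <- t - ep$onset_s[i]
      k <- ifelse(dt > 0, (dt / tau_k) * exp(1 - dt / tau_k), 0)
      transient <- transient + amp * k
    }
  }
  baseline <- f0 * exp(-t / bleach_tau)
  intensity <- with_local_seed(seed, {
    y <- baseline * (1 + transient) +
      stats::rnorm(length(t), 0, noise_sd / 100) * baseline
    pmax(y, .Machine$double.eps)
  })
  list(trace = data.frame(worm_id = worm_id, neuron = neuron,
                          time_s = t, intensity = intensity),
       epochs = data.frame(worm_id = worm_id, onset_s = ep$onset_s,
                           duration_s = ep$duration_s,
                           amplitude_pct = ep$amplitude_pct))
}

#' Synthetic per-isolate geomagnetic field table
#'
#' A plausible world sample of isolate origins spanning both hemispheres
#' and the magnetic equator. The strains and field values are synthetic
#' stand-ins shaped like real geomagnetic data (vertical component between
#' -0.6 and +0.6 Gauss, horizontal between 0.2 and 0.4); they are inputs
#' to the generators, not measurements.
#'
#' @param n number of isolates. Default 11 (ten training + one holdout).
#' @return data frame with columns `strain`, `inclination_deg`,
#'   `vertical_gauss`, `horizontal_gauss`.
#' @export
synthetic_isolate_fields <- function(n = 11) {
  stopifnot(n >= 4)
  # evenly spread vertical components across hemispheres; horizontal varies
  # smoothly, strongest near the magnetic equator as on the real globe
  v <- seq(-0.55, 0.55, length.out = n)
  h <- 0.40 - 0.18 * abs(v) / 0.55
  data.frame(strain = sprintf("SYN%02d", seq_len(n)),
             inclination_deg = rad2deg(atan2(v, h)),
             vertical_gauss = v,
             horizontal_gauss = h)
}

#' Simulate an isolate performance table
#'
#' Couples each isolate's mean magnetotaxis index linearly to one field
#' parameter: mi = slope * predictor + intercept + Gaussian noise, clipped
#' to \[-1, 1\], with one record flagged as the hold-out.
#'
#' @param fields data frame with columns `strain`, `inclination_deg`,
#'   `vertical_gauss`, `horizontal_gauss` (>= 4 rows); see
#'   [synthetic_isolate_fields()].
#' @param slope,intercept generating line on the predictor scale.
#' @param noise_sd Gaussian noise on the index. Default 0.05.
#' @param predictor which field parameter drives the index. Default
#'   `"vertical"`.
#' @param holdout_index row flagged as hold-out. Default last row.
#' @param seed integer seed or NULL.
#' @return isolate table: `fields` plus `mi_mean`, `mi_sem`, `holdout`.
#' @export
simulate_isolate_table <- function(fields, slope, intercept = 0,
                                   noise_sd = 0.05,
                                   predictor = c("vertical", "inclination",
                                                 "horizontal"),
                                   holdout_index = nrow(fields),
                                   seed = NULL) {
  stopifnot(is.data.frame(fields), nrow(fields) >= 4,
            all(c("strain", "inclination_deg", "vertical_gauss",
                  "horizontal_gauss") %in% names(fields)))
  if (holdout_index < 1 || holdout_index > nrow(fields))
    stop("holdout_index out of range")
  col <- predictor_column(predictor)
  x <- fields[[col]]
  mi <- with_local_seed(seed,
    pmin(pmax(slope * x + intercept +
                stats::rnorm(nrow(fields), 0, noise_sd), -1), 1))
  out <- fields
  out$mi_mean <- mi
  out$mi_sem <- noise_sd / 2   # nominal display SEM; fits are unweighted
  out$holdout <- seq_len(nrow(fields)) == holdout_index
  out
}
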