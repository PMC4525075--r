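#' Stimulus-evoked responses in calcium-indicator fluorescence traces
#'
#' GCaMP soma-brightness traces decay under illumination (photobleaching).
#' Responses are quantified on a bleach-corrected trace as the percent
#' change of the mean brightness over the final 4 s of a magnetic stimulus
#' relative to the mean over the 4 s immediately preceding stimulus onset.
#' Bleaching is modeled as a mono-exponential decay fitted to samples
#' outside the stimulus windows, so a stimulus-locked transient does not
#' drag the baseline; the corrected trace is raw / fitted and sits near 1
#' at baseline.
#'
#' Sampling is 3.5-8 Hz, so a 4-s window holds 14-32 frames; windows are
#' realized as the set of sample timestamps they contain (partial frames at
#' the edges are excluded). The standard protocol is a 50-s run: 12.5 s of
#' baseline, a 6-s stimulus, and a 31.5-s recovery; an 8-s stimulus variant
#' is supported by passing the epoch's actual duration.
#'
#' @name calcium
NULL

check_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "intensity") %in% names(trace)))
  if (nrow(trace) < 2) stop("trace needs >= 2 samples")
  if (any(diff(trace$time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (any(trace$intensity <= 0)) stop("intensities must be positive")
  trace
}

in_windows <- function(t, windows) {
  if (is.null(windows) || nrow(windows) == 0) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(windows)))
    hit <- hit | (t >= windows$start[i] & t <= windows$end[i])
  hit
}

#' Windows to protect from the bleach fit
#'
#' Converts stimulus epochs into \[onset, offset + pad\] windows excluded
#' from the photobleach fit.
#'
#' @param epochs data frame with columns `onset_s`, `duration_s`.
#' @param pad_after seconds of post-stimulus recovery also excluded.
#'   Default 0 (a boxcar transient ends at stimulus offset).
#' @return data frame with columns `start`, `end`.
#' @export
protect_epochs <- function(epochs, pad_after = 0) {
  stopifnot(is.data.frame(epochs),
            all(c("onset_s", "duration_s") %in% names(epochs)))
  data.frame(start = epochs$onset_s,
             end = epochs$onset_s + epochs$duration_s + pad_after)
}

#' Photobleach-correct a fluorescence trace
#'
#' Fits I(t) = f0 exp(-t / tau) to the samples outside `protected_windows`
#' and divides the raw trace by the fit, yielding a dimensionless trace
#' with baseline near 1. The fit is seeded by log-linear regression and
#' refined by nonlinear least squares; if the refinement does not converge
#' the function falls back to a linear detrend with a warning. A constant
#' trace (no decay) is normalized to 1 unchanged.
#'
#' @param trace data frame with columns `time_s` (strictly increasing
#'   seconds) and `intensity` (positive fluorescence units).
#' @param protected_windows data frame with columns `start`, `end` in
#'   seconds (see [protect_epochs()]), or NULL to fit on all samples.
#' @return object of class `corrected_trace`: list with `trace` (data frame
#'   `time_s`, `corrected`, `raw`, `fitted`), `f0`, `tau` (seconds; Inf for
#'   no decay), and `method` (`"exponential"` or `"linear_detrend"`).
#' @export
bleach_correct <- function(trace, protected_windows = NULL) {
  trace <- check_trace(trace)
  keep <- !in_windows(trace$time_s, protected_windows)
  if (sum(keep) < 10)
    stop("bleach fit needs >= 10 samples outside protected windows; have ",
         sum(keep))
  t_fit <- trace$time_s[keep]
  y_fit <- trace$intensity[keep]

  # log-linear seed: exact for a noiseless exponential
  ll <- stats::lm(log(y_fit) ~ t_fit)
  a0 <- exp(unname(stats::coef(ll)[1]))
  b0 <- -unname(stats::coef(ll)[2])
  seed_fit <- a0 * exp(-b0 * t_fit)
  method <- "exponential"

  if (max(abs(y_fit / seed_fit - 1)) < 1e-9) {
    a <- a0; b <- b0   # already exact; nls would fail on zero residuals
  } else {
    nl <- tryCatch(
      stats::nls(y ~ a * exp(-b * t), data = data.frame(t = t_fit, y = y_fit),
                 start = list(a = a0, b = b0)),
      error = function(e) NULL)
    if (is.null(nl)) {
      warning("exponential bleach fit did not converge; using linear detrend")
      method <- "linear_detrend"
      lf <- stats::lm(y ~ t, data = data.frame(t = t_fit, y = y_fit))
      fitted_all <- unname(stats::predict(lf, newdata = data.frame(t = trace$time_s)))
      if (any(fitted_all <= 0))
        stop("linear detrend produced non-positive fitted values")
      return(structure(
        list(trace = data.frame(time_s = trace$time_s,
                                corrected = trace$intensity / fitted_all,
                                raw = trace$intensity, fitted = fitted_all),
             f0 = unname(stats::coef(lf)[1]), tau = NA_real_, method = method),
        class = "corrected_trace"))
    }
    cf <- stats::coef(nl)
    a <- unname(cf["a"]); b <- unname(cf["b"])
  }
  fitted_all <- a * exp(-b * trace$time_s)
  structure(
    list(trace = data.frame(time_s = trace$time_s,
                            corrected = trace$intensity / fitted_all,
                            raw = trace$intensity, fitted = fitted_all),
         f0 = a, tau = if (b == 0) Inf else 1 / b, method = method),
    class = "corrected_trace"
  )
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf(
    "Bleach-corrected trace: %d samples over %.1f s, f0 = %.3g, tau = %.3g s [%s]\n",
    nrow(x$trace), diff(range(x$trace$time_s)), x$f0, x$tau, x$method))
  invisible(x)
}

corrected_values <- function(corrected) {
  if (inherits(corrected, "corrected_trace"))
    list(t = corrected$trace$time_s, y = corrected$trace$corrected)
  else {
    trace <- check_trace(corrected)
    list(t = trace$time_s, y = trace$intensity)
  }
}

#' Windowed response statistic for one stimulus epoch
#'
#' Percent change of the mean corrected brightness over the final `window`
#' seconds of the stimulus relative to the mean over the `window` seconds
#' immediately before stimulus onset:
#' 100 (mean\[offset - w, offset\] - mean\[onset - w, onset)) / mean\[onset - w, onset).
#'
#' @param corrected a `corrected_trace` (or a trace data frame already on a
#'   flat baseline).
#' @param onset_s stimulus onset, seconds.
#' @param duration_s stimulus duration, seconds; must be >= `window`.
#' @param window averaging window, seconds. Default 4.
#' @param stimulus_index ordinal position of this stimulus in the run.
#' @return object of class `response_stat`: list with `delta_percent`,
#'   `baseline_window`, `response_window`, `stimulus_index`, and the frame
#'   counts used.
#' @export
windowed_response <- function(corrected, onset_s, duration_s, window = 4,
                              stimulus_index = 1L) {
  v <- corrected_values(corrected)
  stopifnot(duration_s > 0, window > 0)
  if (duration_s < window)
    stop("stimulus duration (", duration_s, " s) shorter than window (",
         window, " s)")
  offset <- onset_s + duration_s
  base_lo <- onset_s - window
  if (base_lo < min(v$t) - 1e-9)
    stop("insufficient pre-stimulus data: baseline window starts at ",
         signif(base_lo, 4), " s but trace starts at ", signif(min(v$t), 4), " s")
  base <- v$y[v$t >= base_lo & v$t < onset_s]
  resp <- v$y[v$t >= offset - window & v$t <= offset]
  if (length(base) == 0) stop("no samples in baseline window")
  if (length(resp) == 0) stop("no samples in response window")
  mb <- mean(base)
  structure(
    list(delta_percent = 100 * (mean(resp) - mb) / mb,
         baseline_window = c(base_lo, onset_s),
         response_window = c(offset - window, offset),
         stimulus_index = as.integer(stimulus_index),
         n_baseline_frames = length(base), n_response_frames = length(resp)),
    class = "response_stat"
  )
}

#' @export
print.response_stat <- function(x, ...) {
  cat(sprintf("Stimulus %d response: %+.2f%% vs baseline (%d/%d frames)\n",
              x$stimulus_index, x$delta_percent,
              x$n_baseline_frames, x$n_response_frames))
  invisible(x)
}

#' Response amplitudes across repeated stimuli
#'
#' One windowed response per stimulus epoch, ordered by onset; adaptation
#' shows up as a decreasing profile (reported, never enforced).
#'
#' @param corrected a `corrected_trace`.
#' @param epochs data frame with columns `onset_s`, `duration_s`
#'   (non-overlapping).
#' @param window averaging window in seconds. Default 4.
#' @return data frame with columns `stimulus_index`, `onset_s`,
#'   `duration_s`, `delta_percent`.
#' @export
adaptation_profile <- function(corrected, epochs, window = 4) {
  stopifnot(is.data.frame(epochs),
            all(c("onset_s", "duration_s") %in% names(epochs)),
            nrow(epochs) >= 1)
  epochs <- epochs[order(epochs$onset_s), , drop = FALSE]
  ends <- epochs$onset_s + epochs$duration_s
  if (nrow(epochs) > 1 && any(epochs$onset_s[-1] < ends[-nrow(epochs)]))
    stop("stimulus epochs overlap")
  deltas <- vapply(seq_len(nrow(epochs)), function(i) {
    windowed_response(corrected, epochs$onset_s[i], epochs$duration_s[i],
                      window = window, stimulus_index = i)$delta_percent
  }, numeric(1))
  data.frame(stimulus_index = seq_len(nrow(epochs)),
             onset_s = epochs$onset_s, duration_s = epochs$duration_s,
             delta_percent = deltas)
}

#' Response statistic for the partially restrained 4-frame protocol
#'
#' In partially restrained animals, four frames are taken before, during,
#' and after magnet exposure. The response is the percent change of the
#' mean brightness during exposure relative to the mean of the eight
#' surrounding (before + after) frames.
#'
#' @param before,during,after numeric vectors of exactly 4 positive soma
#'   intensities each.
#' @return percent change (positive = brighter during exposure).
#' @examples
#' partial_restraint_response(rep(100, 4), rep(120, 4), rep(100, 4))  # 20
#' @export
partial_restraint_response <- function(before, during, after) {
  stopifnot(length(before) == 4L, length(during) == 4L, length(after) == 4L)
  if (any(c(before, during, after) <= 0))
    stop("intensities must be positive")
  ref <- mean(c(before, after))
  100 * (mean(during) - ref) / ref
}

#' Group-level test of stimulus-evoked brightness change
#'
#' Two-tailed paired test, across worms, of the response-window mean
#' against the baseline-window mean: Student's paired t when a
#' Shapiro-Wilk screen (alpha = 0.05) on the paired differences does not
#' reject normality, otherwise the Wilcoxon signed-rank test.
#'
#' @param baseline_means per-worm baseline-window mean brightness (n >= 3).
#' @param response_means per-worm response-window mean brightness, same
#'   worm order.
#' @return list with `p`, `test_used`, `n`, `mean_delta` (mean paired
#'   difference).
#' @export
group_response_test <- function(baseline_means, response_means) {
  stopifnot(is.numeric(baseline_means), is.numeric(response_means),
            length(baseline_means) == length(response_means))
  n <- length(baseline_means)
  if (n < 3) stop("group test requires >= 3 worms")
  d <- response_means - baseline_means
  if (stats::sd(d) == 0) {
    return(list(p = if (mean(d) == 0) 1 else 0, test_used = "degenerate",
                n = n, mean_delta = mean(d)))
  }
  sw_p <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (sw_p >= 0.05) {
    list(p = stats::t.test(response_means, baseline_means,
                           paired = TRUE)$p.value,
         test_used = "t", n = n, mean_delta = mean(d))
  } else {
    list(p = suppressWarnings(
           stats::wilcox.test(response_means, baseline_means,
                              paired = TRUE)$p.value),
         test_used = "mann_whitney", n = n, mean_delta = mean(d))
  }
}
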