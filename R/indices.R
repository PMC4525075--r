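#' Two-choice behavioral indices
#'
#' The magnetotaxis index MI = (M - C)/(M + C) compares worm counts at a
#' goal under a magnet (M) with a control goal (C); the burrowing index
#' BI = (A - B)/(A + B) compares counts at the two ends of an agar-filled
#' pipette. Both live in \[-1, 1\], are 0 under indifference, and count only
#' worms that reached a goal; non-arrivals are excluded by construction.
#'
#' @name indices
NULL

two_choice_index <- function(side_a, side_b, what) {
  stopifnot(is.numeric(side_a), is.numeric(side_b),
            length(side_a) == length(side_b))
  if (any(side_a < 0 | side_b < 0)) stop(what, ": counts must be non-negative")
  if (any(side_a %% 1 != 0 | side_b %% 1 != 0))
    stop(what, ": counts must be integers")
  total <- side_a + side_b
  if (any(total == 0))
    stop(what, " undefined: no worms reached either goal (zero total)")
  (side_a - side_b) / total
}

#' Magnetotaxis index MI = (M - C)/(M + C)
#'
#' @param magnet_count worms at the magnet goal (M); non-negative integer(s).
#' @param control_count worms at the control goal (C).
#' @return index value(s) in \[-1, 1\]; errors on a zero total.
#' @examples
#' magnetotaxis_index(20, 10)  # 1/3: two thirds of arrivals chose the magnet
#' @export
magnetotaxis_index <- function(magnet_count, control_count) {
  two_choice_index(magnet_count, control_count, "magnetotaxis index")
}

#' Burrowing index BI = (A - B)/(A + B)
#'
#' @param end_a_count worms at end A of the burrowing pipette.
#' @param end_b_count worms at end B.
#' @return index value(s) in \[-1, 1\]; errors on a zero total.
#' @export
burrowing_index <- function(end_a_count, end_b_count) {
  two_choice_index(end_a_count, end_b_count, "burrowing index")
}

#' Aggregate per-assay indices and test the mean against zero
#'
#' Computes each assay's index, then the replicate mean and SEM, and a
#' two-tailed one-sample test of mean index = 0. The test is Student's t
#' when a Shapiro-Wilk screen (alpha = 0.05) does not reject normality of
#' the per-assay indices, otherwise the Wilcoxon signed-rank test;
#' `test_used` records the choice. Assays in which no worm reached either
#' goal carry no information about choice and are dropped with a warning.
#'
#' @param counts data frame with columns `side_a` and `side_b` (one row per
#'   assay); extra columns are ignored.
#' @return object of class `index_summary`: list with `mean_index`, `sem`,
#'   `n_assays`, `p_vs_zero`, `test_used`, and the per-assay `indices`.
#' @examples
#' counts <- data.frame(side_a = c(30, 28, 35), side_b = c(15, 20, 13))
#' aggregate_indices(counts)
#' @export
aggregate_indices <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("side_a", "side_b") %in% names(counts)))
  total <- counts$side_a + counts$side_b
  if (any(total == 0)) {
    warning(sum(total == 0),
            " assay(s) with zero arrivals excluded from aggregation")
    counts <- counts[total > 0, , drop = FALSE]
  }
  if (nrow(counts) < 2)
    stop("aggregation requires >= 2 assays with defined indices")
  idx <- two_choice_index(counts$side_a, counts$side_b, "index")
  m <- mean(idx)
  sem <- stats::sd(idx) / sqrt(length(idx))

  if (stats::sd(idx) == 0) {
    # all replicates identical: no within-sample variance to test against
    test_used <- "degenerate"
    p <- if (m == 0) 1 else 0
  } else {
    sw_p <- tryCatch(stats::shapiro.test(idx)$p.value, error = function(e) 0)
    if (sw_p >= 0.05) {
      test_used <- "t"
      p <- stats::t.test(idx, mu = 0)$p.value
    } else {
      test_used <- "mann_whitney"
      p <- suppressWarnings(stats::wilcox.test(idx, mu = 0)$p.value)
    }
  }
  structure(
    list(mean_index = m, sem = sem, n_assays = length(idx),
         p_vs_zero = p, test_used = test_used, indices = idx),
    class = "index_summary"
  )
}

#' @export
print.index_summary <- function(x, ...) {
  cat(sprintf(
    "Index summary: mean = %.3f +/- %.3f SEM (%d assays), p vs 0 = %.3g [%s]\n",
    x$mean_index, x$sem, x$n_assays, x$p_vs_zero, x$test_used))
  invisible(x)
}
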