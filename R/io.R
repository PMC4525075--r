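#' Delimited-text readers and writers
#'
#' All interchange is comma-separated UTF-8 text with a header row and "."
#' decimals; angles are always degrees. Readers validate their schema and
#' report offending rows by number; writers round-trip (write then read
#' recovers the same table). Lines starting with `#` are metadata comments
#' (reports embed the seed there) and are skipped on read.
#'
#' @name io
NULL

read_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop(basename(path), ": no data rows")
  for (col in numeric_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(basename(path), ": non-numeric '", col, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read a worm-headings file
#'
#' Expects columns `assay_id`, `strain`, `satiation`, `angle_deg`; angles
#' must lie in \[0, 360).
#'
#' @param path CSV path.
#' @return data frame of validated headings.
#' @export
read_headings <- function(path) {
  df <- read_checked(path, c("assay_id", "strain", "satiation", "angle_deg"),
                     "angle_deg")
  bad <- which(df$angle_deg < 0 | df$angle_deg >= 360)
  if (length(bad))
    stop(basename(path), ": angle_deg outside [0, 360) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad_sat <- which(!df$satiation %in% c("fed", "starved"))
  if (length(bad_sat))
    stop(basename(path), ": satiation must be fed|starved at row(s) ",
         paste(utils::head(bad_sat, 5), collapse = ", "))
  df
}

#' Read a two-choice counts file
#'
#' Expects columns `assay_id`, `strain`, `satiation`, `assay_type`,
#' `side_a`, `side_b` with non-negative integer counts.
#'
#' @param path CSV path.
#' @return data frame of validated assay counts.
#' @export
read_counts <- function(path) {
  df <- read_checked(path, c("assay_id", "strain", "satiation", "assay_type",
                             "side_a", "side_b"), c("side_a", "side_b"))
  bad <- which(df$side_a < 0 | df$side_b < 0 |
                 df$side_a %% 1 != 0 | df$side_b %% 1 != 0)
  if (length(bad))
    stop(basename(path), ": counts must be non-negative integers at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' Read fluorescence traces and their stimulus epochs
#'
#' The trace file holds columns `worm_id`, `neuron`, `time_s`, `intensity`;
#' the epoch file holds `worm_id`, `onset_s`, `duration_s` (optionally
#' `gauss`, `rotation_hz`). Each worm's timestamps must be strictly
#' increasing and intensities positive.
#'
#' @param path trace CSV path.
#' @param epochs_path epoch CSV path.
#' @return list with `traces` and `epochs` data frames.
#' @export
read_traces <- function(path, epochs_path) {
  tr <- read_checked(path, c("worm_id", "neuron", "time_s", "intensity"),
                     c("time_s", "intensity"))
  for (w in unique(tr$worm_id)) {
    sub <- tr[tr$worm_id == w, ]
    if (any(diff(sub$time_s) <= 0))
      stop(basename(path), ": non-increasing time_s for worm ", w)
    if (any(sub$intensity <= 0))
      stop(basename(path), ": non-positive intensity for worm ", w)
  }
  ep <- read_checked(epochs_path, c("worm_id", "onset_s", "duration_s"),
                     c("onset_s", "duration_s"))
  if (any(ep$onset_s < 0) || any(ep$duration_s <= 0))
    stop(basename(epochs_path), ": epochs need onset_s >= 0 and duration_s > 0")
  list(traces = tr, epochs = ep)
}

#' Read a per-isolate table
#'
#' Expects at least `strain`, `inclination_deg`, `vertical_gauss`,
#' `horizontal_gauss`; performance columns `mi_mean`, `mi_sem` and the
#' `holdout` flag are validated when present.
#'
#' @param path CSV path.
#' @return data frame of validated isolate records.
#' @export
read_isolates <- function(path) {
  df <- read_checked(path, c("strain", "inclination_deg", "vertical_gauss",
                             "horizontal_gauss"),
                     c("inclination_deg", "vertical_gauss", "horizontal_gauss"))
  bad <- which(abs(df$inclination_deg) > 90 | df$horizontal_gauss < 0)
  if (length(bad))
    stop(basename(path), ": invalid field parameters at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if ("mi_mean" %in% names(df)) {
    df$mi_mean <- as.numeric(df$mi_mean)
    if (any(abs(df$mi_mean) > 1))
      stop(basename(path), ": mi_mean outside [-1, 1]")
  }
  if ("holdout" %in% names(df)) df$holdout <- as.logical(df$holdout)
  df
}

#' Write a report or data table as commented CSV
#'
#' Writes `df` as plain CSV, preceded by `#`-prefixed metadata lines
#' recording the package version, the seed in force, and any extra
#' parameters, so every output is self-describing. All readers in this
#' package skip `#` lines.
#'
#' @param df data frame to write.
#' @param path destination path (directories are created).
#' @param seed the seed used to produce `df`, or NA.
#' @param params optional named list of extra parameters to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, seed = NA, params = NULL) {
  stopifnot(is.data.frame(df))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# wormcompass %s | seed=%s | written=%s",
                     as.character(utils::packageVersion("wormcompass")),
                     as.character(seed), format(Sys.time(), "%Y-%m-%d")), con)
  if (length(params))
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(p) paste(format(p), collapse = ","),
                             character(1))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
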