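#' Day/night mask for minute timestamps
#'
#' Minutes whose clock time falls in `[day_start, night_start)` are
#' day; the remainder are night. A day window that wraps midnight
#' (e.g. day_start 22:00, night_start 06:00) is handled.
#'
#' @param timestamps POSIXct vector of minute marks (or an
#'   `actigraphy_pair`).
#' @param day_start,night_start Clock times `"HH:MM"` (defaults 06:00
#'   and 22:00).
#' @return Logical vector: TRUE for day minutes.
#' @export
split_day_night <- function(timestamps, day_start = "06:00",
                            night_start = "22:00") {
  if (inherits(timestamps, "actigraphy_pair")) {
    timestamps <- timestamps$timestamps
  }
  if (day_start == night_start) {
    stop("day_start and night_start must differ")
  }
  to_min <- function(s) {
    p <- as.integer(strsplit(s, ":")[[1]])
    p[1] * 60 + p[2]
  }
  d0 <- to_min(day_start); n0 <- to_min(night_start)
  lt <- as.POSIXlt(timestamps)
  mod <- lt$hour * 60 + lt$min
  if (d0 < n0) mod >= d0 & mod < n0 else mod >= d0 | mod < n0
}

#' Construct a bilateral actigraphy pair
#'
#' Aligned per-minute activity-count series for the affected and
#' unaffected arms, with a day/night tag per minute.
#'
#' @param timestamps POSIXct minute marks, strictly increasing at
#'   1-minute steps.
#' @param affected_counts,unaffected_counts Nonnegative per-minute
#'   counts.
#' @param day_start,night_start Day window bounds (defaults 06:00,
#'   22:00).
#' @param affected_side `"left"` or `"right"`.
#' @return An object of class `actigraphy_pair`.
#' @export
actigraphy_pair <- function(timestamps, affected_counts,
                            unaffected_counts, day_start = "06:00",
                            night_start = "22:00",
                            affected_side = "left") {
  n <- length(timestamps)
  stopifnot(length(affected_counts) == n,
            length(unaffected_counts) == n,
            all(affected_counts >= 0), all(unaffected_counts >= 0))
  steps <- diff(as.numeric(timestamps))
  if (n > 1 && any(abs(steps - 60) > 1e-6)) {
    stop("timestamps must be strictly increasing at 1-minute steps")
  }
  structure(list(timestamps = timestamps,
                 affected_counts = affected_counts,
                 unaffected_counts = unaffected_counts,
                 day_mask = split_day_night(timestamps, day_start,
                                            night_start),
                 affected_side = match.arg(affected_side,
                                           c("left", "right"))),
            class = "actigraphy_pair")
}

window_mask <- function(pair, window = c("all", "day", "night")) {
  window <- match.arg(window)
  switch(window,
         all = rep(TRUE, length(pair$timestamps)),
         day = pair$day_mask,
         night = !pair$day_mask)
}

#' Upper-limb activity ratio (ULAR)
#'
#' `ULAR = sum(affected counts) / sum(unaffected counts) x 100%` over
#' the minutes of the requested window. Computed on count sums, not as
#' a mean of per-minute ratios.
#'
#' @param pair An `actigraphy_pair`.
#' @param window `"all"`, `"day"`, or `"night"`.
#' @return ULAR in percent, or `NA` (with a warning) when the
#'   unaffected arm shows no activity in the window.
#' @export
compute_ular <- function(pair, window = c("all", "day", "night")) {
  stopifnot(inherits(pair, "actigraphy_pair"))
  m <- window_mask(pair, window)
  denom <- sum(pair$unaffected_counts[m])
  if (denom <= 0) {
    warning("ULAR undefined: no unaffected-arm activity in window")
    return(NA_real_)
  }
  100 * sum(pair$affected_counts[m]) / denom
}

#' Bimanual coordination index r
#'
#' Pearson correlation between the two arms' per-minute count series
#' within the requested window.
#'
#' @inheritParams compute_ular
#' @return Pearson r in `[-1, 1]`, or `NA` (with a warning) when the
#'   window has fewer than 3 minutes or a series has zero variance.
#' @export
compute_coordination_r <- function(pair,
                                   window = c("all", "day", "night")) {
  stopifnot(inherits(pair, "actigraphy_pair"))
  m <- window_mask(pair, window)
  a <- pair$affected_counts[m]; u <- pair$unaffected_counts[m]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(u) == 0) {
    warning("coordination r undefined: too few minutes or zero variance")
    return(NA_real_)
  }
  stats::cor(a, u)
}

#' Minutes above the moderate-activity threshold
#'
#' Counts minutes with activity strictly above `threshold` counts/min.
#'
#' @param pair An `actigraphy_pair`.
#' @param arm `"affected"` or `"unaffected"`.
#' @param threshold Counts/min cut (default 500).
#' @param window `"all"`, `"day"`, or `"night"`.
#' @return Number of minutes.
#' @export
moderate_activity_minutes <- function(pair,
                                      arm = c("affected", "unaffected"),
                                      threshold = 500,
                                      window = c("all", "day", "night")) {
  stopifnot(inherits(pair, "actigraphy_pair"))
  arm <- match.arg(arm)
  m <- window_mask(pair, window)
  x <- if (arm == "affected") pair$affected_counts else {
    pair$unaffected_counts
  }
  sum(x[m] > threshold)
}

#' Per-subject actigraphy metrics row
#'
#' Computes the full spontaneous-arm-movement metric set: ULAR and
#' coordination r over all minutes, day, and night, plus
#' moderate-activity minutes for both arms.
#'
#' @param pair An `actigraphy_pair`.
#' @param threshold Moderate-activity threshold in counts/min
#'   (default 500).
#' @param subject_id Optional identifier column.
#' @return One-row data frame: ular_all/day/night, r_all/day/night,
#'   moderate_minutes_affected/unaffected.
#' @export
activity_metrics <- function(pair, threshold = 500, subject_id = NULL) {
  out <- data.frame(
    ular_all = compute_ular(pair, "all"),
    ular_day = compute_ular(pair, "day"),
    ular_night = compute_ular(pair, "night"),
    r_all = compute_coordination_r(pair, "all"),
    r_day = compute_coordination_r(pair, "day"),
    r_night = compute_coordination_r(pair, "night"),
    moderate_minutes_affected =
      moderate_activity_minutes(pair, "affected", threshold),
    moderate_minutes_unaffected =
      moderate_activity_minutes(pair, "unaffected", threshold)
  )
  if (!is.null(subject_id)) out <- cbind(subject_id = subject_id, out)
  out
}

#' Write an actigraphy pair as a delimited table
#'
#' Columns: ISO-8601 minute timestamp, left_counts, right_counts. The
#' affected/unaffected series are mapped to left/right via the pair's
#' affected side.
#'
#' @param pair An `actigraphy_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_actigraphy <- function(pair, path) {
  left_is_affected <- pair$affected_side == "left"
  tab <- data.frame(
    timestamp = format(pair$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    left_counts = if (left_is_affected) pair$affected_counts else {
      pair$unaffected_counts
    },
    right_counts = if (left_is_affected) pair$unaffected_counts else {
      pair$affected_counts
    }
  )
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an actigraphy pair from a delimited table
#'
#' Expects columns `timestamp` (ISO-8601 minutes), `left_counts`,
#' `right_counts`; the affected side (from the subject sidecar) selects
#' which column is the affected arm.
#'
#' @param path Input path.
#' @param affected_side `"left"` or `"right"`.
#' @param day_start,night_start Day window bounds.
#' @return An `actigraphy_pair`.
#' @export
read_actigraphy <- function(path, affected_side,
                            day_start = "06:00", night_start = "22:00") {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  need <- c("timestamp", "left_counts", "right_counts")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("actigraphy table missing columns: ",
         paste(miss, collapse = ", "))
  }
  ts <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC")
  affected_side <- match.arg(affected_side, c("left", "right"))
  aff <- if (affected_side == "left") tab$left_counts else {
    tab$right_counts
  }
  una <- if (affected_side == "left") tab$right_counts else {
    tab$left_counts
  }
  actigraphy_pair(ts, aff, una, day_start, night_start, affected_side)
}
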