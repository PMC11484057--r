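#' Truncate a value at a display precision
#'
#' Reported percentages and rates in this package are truncated (floored
#' toward zero) at display precision rather than rounded; full precision is
#' always kept internally. Truncation is the convention under which the
#' derived detection statistics are self-consistent (51.72 reports as 51.7,
#' 1082.69 detections/s as 1082).
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep (default 1; use 0 for integers).
#' @return `x` truncated toward zero at `digits` decimals.
#' @examples
#' trunc_decimal(c(51.72, 84.87))      # 51.7 84.8
#' trunc_decimal(1082.69, digits = 0)  # 1082
#' @export
trunc_decimal <- function(x, digits = 1L) {
  s <- 10^digits
  trunc(x * s) / s
}

n_records_by_hand <- function(session) {
  h <- session$records$hand
  lm <- session$records$landmark_id
  c(right = sum(h == "right"), left = sum(h == "left"),
    null = sum(h == "none"))
}

#' Detection performance of a session
#'
#' The fraction of the maximum possible landmark records actually emitted:
#' `100 * n_records / (n_frames * 42)`, where 42 = 21 landmarks x 2 hands.
#' Null records count toward the numerator (they are detector emissions).
#' The value is returned at full precision; apply [trunc_decimal()] for
#' display.
#'
#' @param x An `hm_session`, or a single total record count (in which case
#'   `n_frames` is required).
#' @param n_frames Number of frames; only used when `x` is a count.
#' @return Detection performance in percent (full precision).
#' @examples
#' trunc_decimal(detection_performance(1948837, n_frames = 1800 * 30)) # 85.9
#' @export
detection_performance <- function(x, n_frames = NULL) {
  if (inherits(x, "hm_session")) {
    n_frames <- x$meta$n_frames
    x <- nrow(x$records)
  }
  if (is.null(n_frames) || any(n_frames <= 0))
    stop("`n_frames` must be a positive count", call. = FALSE)
  100 * x / (n_frames * 42)
}

#' Per-hand and null shares of landmark records
#'
#' Shares of the total record count attributable to the right hand, the left
#' hand and null (handedness-indeterminate) detections, each
#' `100 * count / n_total` at full precision.
#'
#' @param x An `hm_session`, or a named numeric vector of counts with
#'   elements `right`, `left`, `null`.
#' @return Named numeric vector `c(right=, left=, null=)` in percent.
#' @examples
#' trunc_decimal(hand_shares(c(right = 939540, left = 1007916, null = 1381)))
#' @export
hand_shares <- function(x) {
  counts <- if (inherits(x, "hm_session")) n_records_by_hand(x) else {
    stopifnot(all(c("right", "left", "null") %in% names(x)))
    x[c("right", "left", "null")]
  }
  n_total <- sum(counts)
  if (n_total == 0) stop("no records: shares undefined", call. = FALSE)
  100 * counts / n_total
}

#' Average landmark detections per second
#'
#' @param x An `hm_session`, or a total record count (then `duration_s` is
#'   required).
#' @param duration_s Session duration in seconds; only used when `x` is a
#'   count.
#' @return Records per second, full precision (truncate to integer for
#'   display).
#' @examples
#' trunc_decimal(detections_per_second(1948837, 1800), digits = 0) # 1082
#' @export
detections_per_second <- function(x, duration_s = NULL) {
  if (inherits(x, "hm_session")) {
    duration_s <- x$meta$duration_s
    x <- nrow(x$records)
  }
  if (is.null(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  x / duration_s
}

#' Detection-performance report for a session
#'
#' Bundles the record counts, per-hand shares, detection performance and
#' detection rate of one session. All percentages are stored at full
#' precision; the print method truncates at one decimal.
#'
#' @param session An `hm_session`.
#' @return An object of class `hm_performance`: a list with `procedure_id`,
#'   `n_total`, `n_right`, `n_left`, `n_null`, `performance_pct`,
#'   `right_pct`, `left_pct`, `null_pct`, `detections_per_second`.
#' @export
performance_report <- function(session) {
  stopifnot(inherits(session, "hm_session"))
  counts <- n_records_by_hand(session)
  n_total <- sum(counts)
  shares <- if (n_total > 0) hand_shares(session) else
    c(right = NA_real_, left = NA_real_, null = NA_real_)
  structure(
    list(procedure_id = session$meta$procedure_id,
         n_total = unname(n_total),
         n_right = unname(counts["right"]), n_left = unname(counts["left"]),
         n_null = unname(counts["null"]),
         performance_pct = detection_performance(session),
         right_pct = unname(shares["right"]),
         left_pct = unname(shares["left"]),
         null_pct = unname(shares["null"]),
         detections_per_second = if (session$meta$duration_s > 0)
           detections_per_second(session) else NA_real_),
    class = "hm_performance")
}

#' @export
print.hm_performance <- function(x, ...) {
  cat(sprintf("<hm_performance> procedure %s\n", x$procedure_id))
  cat(sprintf("  %d records: performance %.1f%%, %d/s\n", x$n_total,
              trunc_decimal(x$performance_pct),
              trunc_decimal(x$detections_per_second, 0L)))
  cat(sprintf("  right %.1f%% | left %.1f%% | null %.1f%%\n",
              trunc_decimal(x$right_pct), trunc_decimal(x$left_pct),
              trunc_decimal(x$null_pct)))
  invisible(x)
}

#' Per-cell dwell times of a session
#'
#' Seconds spent in each grid cell, summed over BOTH hands: frames of the
#' left series in cell c plus frames of the right series in cell c, divided
#' by fps. Undetected frames contribute to no cell, so per-cell totals can
#' sum to at most twice the session duration.
#'
#' @param series_left,series_right [cell_series()] objects for the two hands
#'   (must have equal length `n_frames`).
#' @param meta The session's [session_meta()].
#' @return A named numeric vector of class `hm_dwell` (names `"1"`-`"9"`,
#'   seconds) with attributes `frames` (per-cell frame counts),
#'   `undetected_frames` (named per-hand counts) and `fps`.
#' @export
dwell_times <- function(series_left, series_right, meta) {
  stopifnot(inherits(meta, "hm_meta"))
  if (length(series_left) != meta$n_frames ||
      length(series_right) != meta$n_frames)
    stop("series length must equal n_frames", call. = FALSE)
  frames <- tabulate(series_left, nbins = 9L) +
    tabulate(series_right, nbins = 9L)
  secs <- frames / meta$fps
  names(secs) <- as.character(1:9)
  structure(secs, class = "hm_dwell", frames = as.integer(frames),
            undetected_frames = c(left = sum(is.na(series_left)),
                                  right = sum(is.na(series_right))),
            fps = meta$fps)
}

#' @export
print.hm_dwell <- function(x, ...) {
  cat("<hm_dwell> seconds per cell (both hands):\n")
  print(matrix(round(unclass(x), 1L), 3L, 3L, byrow = TRUE,
               dimnames = list(NULL, NULL)))
  invisible(x)
}

#' Aggregate dwell tables across procedures
#'
#' Per-cell arithmetic mean and sample standard deviation (n-1 denominator)
#' of dwell seconds across repeated procedures.
#'
#' @param tables A list of at least two [dwell_times()] results (or named
#'   numeric vectors with cells `"1"`-`"9"`).
#' @return A tibble with columns `cell`, `mean_s`, `sd_s` (class
#'   `hm_dwell_agg`).
#' @export
aggregate_dwell <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least 2 procedures: SD is undefined otherwise",
         call. = FALSE)
  mat <- do.call(rbind, lapply(tables, function(t) {
    v <- unclass(t)
    stopifnot(length(v) == 9L)
    as.numeric(v[as.character(1:9)])
  }))
  out <- tibble::tibble(cell = 1:9,
                        mean_s = apply(mat, 2L, mean),
                        sd_s = apply(mat, 2L, stats::sd))
  class(out) <- c("hm_dwell_agg", class(out))
  out
}

#' Dwell heatmap matrix
#'
#' Arranges per-cell mean dwell seconds as the 3x3 grid: `matrix[r, c]` is
#' the mean of cell `3 * (r - 1) + c`.
#'
#' @param aggregate An [aggregate_dwell()] result, or a named numeric vector
#'   of per-cell values.
#' @return A 3x3 numeric matrix of mean seconds.
#' @export
heatmap_matrix <- function(aggregate) {
  vals <- if (inherits(aggregate, "hm_dwell_agg")) aggregate$mean_s
  else as.numeric(unclass(aggregate)[as.character(1:9)])
  stopifnot(length(vals) == 9L)
  matrix(vals, nrow = 3L, ncol = 3L, byrow = TRUE)
}
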