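EVENT_KINDS <- c("instrument_change", "microscope_adjust", "trash", "other")

#' Event segmentation configuration
#'
#' Tuning parameters for [detect_events()]. `gap_fill_s` bridges brief
#' tracking dropouts (e.g. microscope-light glare) so one excursion is not
#' split into many; `merge_gap_s` merges same-kind excursions separated by
#' only a brief return to the surgical field; `min_duration_s` suppresses
#' sub-half-second cell flickers that no deliberate reach could produce.
#'
#' @param gap_fill_s Undetected runs strictly shorter than this many seconds
#'   inherit the preceding cell (default 0.5).
#' @param merge_gap_s Maximum separation, in seconds, across which two
#'   same-kind excursions are merged (default 1.0).
#' @param min_duration_s Minimum event duration in seconds (default 0.5).
#' @return A list of class `hm_event_config`.
#' @export
event_config <- function(gap_fill_s = 0.5, merge_gap_s = 1.0,
                         min_duration_s = 0.5) {
  if (gap_fill_s < 0 || merge_gap_s < 0 || min_duration_s < 0)
    stop("event config values must be >= 0", call. = FALSE)
  structure(list(gap_fill_s = gap_fill_s, merge_gap_s = merge_gap_s,
                 min_duration_s = min_duration_s),
            class = "hm_event_config")
}

classify_cells <- function(cells) {
  # precedence for mixed excursions: reaching the microscope handles
  # necessarily sweeps other cells, so any top-row visit dominates
  if (any(cells %in% 1:3)) "microscope_adjust"
  else if (4L %in% cells) "instrument_change"
  else if (7L %in% cells) "trash"
  else "other"
}

fill_short_gaps <- function(cells, max_frames) {
  if (max_frames <= 0 || !anyNA(cells)) return(cells)
  r <- rle(is.na(cells))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] < max_frames && starts[k] > 1L)
      cells[starts[k]:ends[k]] <- cells[starts[k] - 1L]
  }
  cells
}

#' Segment workflow events from a cell-occupancy series
#'
#' Excursions of a hand away from the surgical-field cell (cell 5) are
#' segmented into workflow events and classified by the cells they visit:
#' cell 4 (instrument table) excursions are instrument changes, any visit to
#' the top row (cells 1-3, the microscope handles) marks a microscope
#' adjustment, cell 7 is the trash bin, and anything else is `other`.
#' These excursions appear as the large-amplitude "spikes" in horizontal
#' and vertical tracking plots of the hand.
#'
#' The algorithm: (1) undetected runs shorter than `gap_fill_s` inherit the
#' previous cell; (2) maximal runs of frames outside cell 5 become candidate
#' events; (3) consecutive same-kind candidates separated (by cell 5 or
#' undetected frames) by less than `merge_gap_s` are merged; (4) events
#' shorter than `min_duration_s` are dropped. Resulting events are disjoint
#' and time-ordered.
#'
#' @param series A [cell_series()] for one hand.
#' @param meta The session [session_meta()].
#' @param config An [event_config()].
#' @return A tibble of class `hm_events` with columns `kind`, `hand`,
#'   `start_frame`, `end_frame` (inclusive), `start_s`, `end_s` (half-open
#'   interval), `duration_s`, `cells_visited` (list of integer vectors).
#' @export
detect_events <- function(series, meta, config = event_config()) {
  stopifnot(inherits(meta, "hm_meta"), inherits(config, "hm_event_config"))
  if (length(series) != meta$n_frames)
    stop("series length must equal n_frames", call. = FALSE)
  fps <- meta$fps
  hand <- attr(series, "hand") %||% NA_character_
  cells <- fill_short_gaps(as.integer(series), config$gap_fill_s * fps)

  away <- !is.na(cells) & cells != 5L
  empty <- tibble::tibble(kind = character(), hand = character(),
                          start_frame = integer(), end_frame = integer(),
                          start_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), cells_visited = list())
  if (!any(away)) return(structure(empty, class = c("hm_events", class(empty))))

  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$kind <- vapply(seq_len(nrow(runs)), function(i)
    classify_cells(unique(cells[runs$start[i]:runs$end[i]])), character(1L))

  # merge same-kind neighbours separated by < merge_gap_s
  merged <- runs[1L, ]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      j <- nrow(merged)
      gap_frames <- runs$start[i] - merged$end[j] - 1L
      if (runs$kind[i] == merged$kind[j] &&
          gap_frames / fps < config$merge_gap_s) {
        merged$end[j] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }

  dur <- (merged$end - merged$start + 1L) / fps
  keep <- dur >= config$min_duration_s
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(structure(empty, class = c("hm_events", class(empty))))

  visited <- lapply(seq_len(nrow(merged)), function(i)
    sort(unique(cells[merged$start[i]:merged$end[i]])))
  visited <- lapply(visited, function(v) v[!is.na(v) & v != 5L])
  out <- tibble::tibble(
    kind = vapply(visited, classify_cells, character(1L)),
    hand = hand,
    start_frame = merged$start - 1L,        # back to 0-based
    end_frame = merged$end - 1L,
    start_s = (merged$start - 1L) / fps,
    end_s = merged$end / fps,
    duration_s = (merged$end - merged$start + 1L) / fps,
    cells_visited = visited)
  structure(out, class = c("hm_events", class(out)))
}

#' Summary statistics of detected events
#'
#' Count, mean duration and sample standard deviation (n-1) of event
#' durations per kind. Kinds with no events report count 0 and `NA`
#' mean/SD; a single event has defined mean but `NA` SD.
#'
#' @param events An [detect_events()] tibble.
#' @return A tibble with columns `kind`, `n`, `mean_s`, `sd_s`.
#' @export
event_stats <- function(events) {
  out <- tibble::tibble(kind = EVENT_KINDS, n = 0L, mean_s = NA_real_,
                        sd_s = NA_real_)
  if (!is.null(events) && nrow(events)) {
    agg <- dplyr::summarise(dplyr::group_by(events, .data$kind),
                            n = dplyr::n(),
                            mean_s = mean(.data$duration_s),
                            sd_s = stats::sd(.data$duration_s),
                            .groups = "drop")
    idx <- match(agg$kind, out$kind)
    out$n[idx] <- agg$n
    out$mean_s[idx] <- agg$mean_s
    out$sd_s[idx] <- agg$sd_s
  }
  out
}

#' Match detected events against simulator ground truth
#'
#' Greedy one-to-one matching of detected events to true scheduled
#' excursions of the same kind: truth events are taken in time order and
#' matched to the unmatched detected event of the same kind whose interval
#' overlaps the truth interval dilated by `tol_s`, preferring the largest
#' overlap. Used to validate the segmentation against the simulator.
#'
#' @param detected An [detect_events()] tibble.
#' @param truth A tibble of true events with columns `kind`, `start_s`,
#'   `end_s` (e.g. [truth_events()] of a simulated session).
#' @param tol_s Non-negative boundary tolerance in seconds.
#' @return A list with `precision` (matched / detected, `NA` when nothing
#'   was detected), `recall` (matched / truth, `NA` when truth is empty),
#'   `n_matched`, and `matches`: a tibble with per-match absolute boundary
#'   errors `start_err_s`, `end_err_s`.
#' @export
match_events <- function(detected, truth, tol_s = 1.0) {
  if (tol_s < 0) stop("`tol_s` must be >= 0", call. = FALSE)
  n_det <- if (is.null(detected)) 0L else nrow(detected)
  n_tru <- if (is.null(truth)) 0L else nrow(truth)
  matches <- tibble::tibble(truth_idx = integer(), detected_idx = integer(),
                            start_err_s = numeric(), end_err_s = numeric())
  if (n_det && n_tru) {
    truth <- truth[order(truth$start_s), ]
    used <- logical(n_det)
    for (i in seq_len(n_tru)) {
      lo <- truth$start_s[i] - tol_s
      hi <- truth$end_s[i] + tol_s
      ov <- pmin(detected$end_s, hi) - pmax(detected$start_s, lo)
      cand <- which(!used & detected$kind == truth$kind[i] & ov > 0)
      if (length(cand)) {
        j <- cand[which.max(ov[cand])]
        used[j] <- TRUE
        matches <- dplyr::bind_rows(matches, tibble::tibble(
          truth_idx = i, detected_idx = j,
          start_err_s = abs(detected$start_s[j] - truth$start_s[i]),
          end_err_s = abs(detected$end_s[j] - truth$end_s[i])))
      }
    }
  }
  n_match <- nrow(matches)
  list(precision = if (n_det) n_match / n_det else NA_real_,
       recall = if (n_tru) n_match / n_tru else NA_real_,
       n_matched = n_match, matches = matches)
}
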