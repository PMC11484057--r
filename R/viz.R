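#' Tracking plot of hand motion
#'
#' Time-versus-coordinate line plot of the occupancy landmark, one series
#' per hand, mirroring the horizontal/vertical tracking plots used to read
#' workflow off a session. Frames where a hand was undetected break the
#' line, so tracking loss stays visible rather than being interpolated.
#' Vertical plots invert the y axis so 0 px (the top of the image, where
#' the microscope handles sit) renders at the top and reaches appear as
#' upward spikes. Supplied events are shaded and coloured by kind.
#'
#' @param session An `hm_session`.
#' @param hands Hands to plot (default both).
#' @param axis `"horizontal"` (x coordinate) or `"vertical"` (y coordinate).
#' @param landmark_id Landmark to trace (default 12).
#' @param events Optional [detect_events()] tibble to annotate.
#' @param file Optional output path (PNG etc.); written via
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly if `file` is given.
#' @export
tracking_plot <- function(session, hands = c("left", "right"),
                          axis = c("horizontal", "vertical"),
                          landmark_id = 12L, events = NULL, file = NULL) {
  stopifnot(inherits(session, "hm_session"))
  axis <- match.arg(axis)
  hands <- match.arg(hands, c("left", "right"), several.ok = TRUE)
  m <- session$meta
  coord <- if (axis == "horizontal") "x_px" else "y_px"
  r <- session$records
  r <- r[r$hand %in% hands & !is.na(r$landmark_id) &
           r$landmark_id == as.integer(landmark_id), ]
  # explicit NA rows at undetected frames break the line
  full <- tidyr_like_grid(hands, m$n_frames)
  full <- dplyr::left_join(full, r[c("frame_index", "hand", coord)],
                           by = c("frame_index", "hand"))
  full$time_s <- full$frame_index / m$fps
  full$value <- full[[coord]]

  p <- ggplot2::ggplot(full, ggplot2::aes(x = .data$time_s, y = .data$value,
                                          colour = .data$hand)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s position (px)", axis),
                  colour = "hand",
                  title = sprintf("%s tracking, landmark %d (%s)",
                                  tools::toTitleCase(axis), landmark_id,
                                  m$procedure_id)) +
    ggplot2::theme_minimal()
  p <- if (axis == "vertical")
    p + ggplot2::scale_y_reverse(limits = c(m$height_px, 0)) else
      p + ggplot2::ylim(0, m$width_px)
  if (!is.null(events) && nrow(events)) {
    shade <- tibble::tibble(xmin = events$start_s, xmax = events$end_s,
                            kind = events$kind)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$kind),
      ymin = -Inf, ymax = Inf, alpha = 0.2, inherit.aes = FALSE) +
      ggplot2::labs(fill = "event")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 10, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

tidyr_like_grid <- function(hands, n_frames) {
  tibble::tibble(frame_index = rep(0:(n_frames - 1L), times = length(hands)),
                 hand = rep(hands, each = n_frames))
}

#' Dwell-time heatmap of the 3x3 grid
#'
#' Colour-mapped 3x3 grid of mean per-cell dwell seconds, annotated with
#' the values to one decimal. Annotations are taken directly from the
#' supplied matrix, never recomputed.
#'
#' @param matrix A 3x3 matrix of mean seconds (see [heatmap_matrix()]).
#' @param file Optional output path.
#' @return The ggplot object, invisibly if `file` is given.
#' @export
heatmap_plot <- function(matrix, file = NULL) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(3L, 3L)))
  df <- tibble::tibble(row = rep(1:3, each = 3L), col = rep(1:3, times = 3L),
                       cell = 1:9, value = as.numeric(t(matrix)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile(colour = "blue", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$value)), colour = "black") +
    ggplot2::scale_y_reverse(breaks = 1:3) +
    ggplot2::scale_x_continuous(breaks = 1:3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean s",
                  title = "Mean dwell time per grid cell (s)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Analyze one session end to end
#'
#' Runs the standard pipeline on a session: detection-performance report,
#' per-hand cell series, per-cell dwell times and workflow events of the
#' dominant hand.
#'
#' @param session An `hm_session`.
#' @param grid Optional [make_grid()]; defaults to equal thirds of the
#'   session frame.
#' @param config An [event_config()].
#' @param dominant Hand whose excursions define workflow events.
#' @param landmark_id Occupancy landmark (default 12).
#' @return A list of class `hm_analysis` with `procedure_id`, `performance`,
#'   `series` (per hand), `dwell`, `events`, `event_stats`.
#' @export
analyze_session <- function(session, grid = NULL, config = event_config(),
                            dominant = "right", landmark_id = 12L) {
  stopifnot(inherits(session, "hm_session"))
  m <- session$meta
  if (is.null(grid)) grid <- make_grid(m$width_px, m$height_px)
  series <- list(left = cell_series(session, grid, "left", landmark_id),
                 right = cell_series(session, grid, "right", landmark_id))
  dwell <- dwell_times(series$left, series$right, m)
  events <- detect_events(series[[dominant]], m, config)
  structure(list(procedure_id = m$procedure_id,
                 performance = performance_report(session),
                 series = series, dwell = dwell, events = events,
                 event_stats = event_stats(events)),
            class = "hm_analysis")
}

#' Consolidated multi-procedure report
#'
#' Bundles per-procedure performance, dwell and event statistics with the
#' cross-procedure dwell aggregate into one JSON-serialisable structure.
#'
#' @param analyses A non-empty list of [analyze_session()] results with
#'   distinct procedure ids.
#' @param file Optional path; the report is written as JSON.
#' @param plots Optional named list/vector of plot file paths to reference.
#' @return The report list, invisibly when `file` is given.
#' @export
build_report <- function(analyses, file = NULL, plots = NULL) {
  if (!is.list(analyses) || length(analyses) == 0L ||
      !all(vapply(analyses, inherits, logical(1L), "hm_analysis")))
    stop("`analyses` must be a non-empty list of hm_analysis objects",
         call. = FALSE)
  ids <- vapply(analyses, `[[`, character(1L), "procedure_id")
  if (anyDuplicated(ids))
    stop("inconsistent session ids: duplicated procedure_id", call. = FALSE)
  per_proc <- lapply(analyses, function(a) {
    perf <- a$performance
    list(procedure_id = a$procedure_id,
         performance = perf[setdiff(names(perf), "procedure_id")],
         dwell_s = as.list(unclass(a$dwell)),
         event_stats = a$event_stats)
  })
  names(per_proc) <- ids
  report <- list(procedures = per_proc)
  if (length(analyses) >= 2L) {
    agg <- aggregate_dwell(lapply(analyses, `[[`, "dwell"))
    report$aggregate <- list(
      dwell = agg,
      heatmap_mean_s = heatmap_matrix(agg),
      performance_mean_pct = mean(vapply(analyses, function(a)
        a$performance$performance_pct, numeric(1L))))
  }
  if (!is.null(plots)) report$plots <- as.list(plots)
  if (!is.null(file)) {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows", matrix = "rowmajor")
    return(invisible(report))
  }
  report
}
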