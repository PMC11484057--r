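#' Build a 3x3 calibration grid over the camera frame
#'
#' The grid partitions the frame into nine cells numbered 1-9 in row-major
#' order (1-3 top row, 4-6 middle, 7-9 bottom). In the intended camera setup
#' the surgical field sits in the centre cell 5, the instrument table in
#' cell 4, the microscope handles in the top row (cells 1-3), the trash bin
#' in cell 7 and a picture-in-picture microsurgical feed in cell 9. By
#' default the gridlines divide the frame into equal thirds; explicit edges
#' can be supplied for a calibration drawn to scene landmarks.
#'
#' @param width_px,height_px Frame dimensions in pixels (> 0).
#' @param x_edges,y_edges Optional length-4 strictly ascending pixel bounds
#'   overriding the equal-thirds edges; must start at 0 and end at the frame
#'   dimension.
#' @return An object of class `hm_grid` with fields `width_px`, `height_px`,
#'   `x_edges`, `y_edges`.
#' @examples
#' make_grid(1920, 1080)
#' @export
make_grid <- function(width_px, height_px, x_edges = NULL, y_edges = NULL) {
  if (!is.numeric(width_px) || width_px <= 0 ||
      !is.numeric(height_px) || height_px <= 0)
    stop("frame dimensions must be positive", call. = FALSE)
  if (is.null(x_edges)) x_edges <- width_px * (0:3) / 3
  if (is.null(y_edges)) y_edges <- height_px * (0:3) / 3
  check_edges <- function(e, lim, nm) {
    if (length(e) != 4L || any(diff(e) <= 0) || e[1L] != 0 || e[4L] != lim)
      stop("`", nm, "` must be 4 strictly ascending bounds from 0 to the ",
           "frame dimension", call. = FALSE)
  }
  check_edges(x_edges, width_px, "x_edges")
  check_edges(y_edges, height_px, "y_edges")
  structure(list(width_px = width_px, height_px = height_px,
                 x_edges = as.numeric(x_edges), y_edges = as.numeric(y_edges)),
            class = "hm_grid")
}

#' @export
print.hm_grid <- function(x, ...) {
  cat(sprintf("<hm_grid> %gx%g px; x edges %s; y edges %s\n", x$width_px,
              x$height_px, paste(round(x$x_edges, 1), collapse = "|"),
              paste(round(x$y_edges, 1), collapse = "|")))
  invisible(x)
}

#' Map pixel coordinates to grid cells
#'
#' Bins are half-open `[edge_i, edge_{i+1})`; points exactly on the right or
#' bottom frame edge belong to the last column/row, so every in-frame point
#' maps to exactly one cell. Points outside the frame return `NA` (treated
#' as undetected downstream).
#'
#' @param x_px,y_px Numeric vectors of pixel coordinates (origin top-left,
#'   y increasing downward).
#' @param grid An [make_grid()] object.
#' @return Integer vector of cell ids 1-9, `NA` for out-of-frame points.
#' @examples
#' g <- make_grid(1920, 1080)
#' assign_cell(960, 540, g)  # centre of frame -> cell 5
#' assign_cell(0, 0, g)      # top-left -> cell 1
#' @export
assign_cell <- function(x_px, y_px, grid) {
  stopifnot(inherits(grid, "hm_grid"))
  stopifnot(length(x_px) == length(y_px))
  col <- findInterval(x_px, grid$x_edges, rightmost.closed = TRUE)
  row <- findInterval(y_px, grid$y_edges, rightmost.closed = TRUE)
  out <- col < 1L | col > 3L | row < 1L | row > 3L | is.na(x_px) | is.na(y_px)
  cell <- (row - 1L) * 3L + col
  cell[out] <- NA_integer_
  as.integer(cell)
}

#' Per-frame cell occupancy of one hand
#'
#' Builds the occupancy series used for dwell-time and event analysis: for
#' every frame, the grid cell containing the hand's occupancy landmark
#' (landmark 12, the tip of the third digit, by default), or `NA` when the
#' hand was not detected in that frame (tracking loss) or the landmark lies
#' outside the frame.
#'
#' @param session An `hm_session`.
#' @param grid An `hm_grid`.
#' @param hand `"left"` or `"right"`.
#' @param landmark_id Landmark used as occupancy proxy (0-20, default 12).
#' @return An integer vector of class `hm_cell_series`, length `n_frames`,
#'   values in 1-9 or `NA`, with attributes `hand` and `fps`.
#' @export
cell_series <- function(session, grid, hand = c("right", "left"),
                        landmark_id = 12L) {
  stopifnot(inherits(session, "hm_session"), inherits(grid, "hm_grid"))
  hand <- match.arg(hand)
  if (!is.numeric(landmark_id) || landmark_id < 0 || landmark_id > 20)
    stop("`landmark_id` must be in 0-20", call. = FALSE)
  n <- session$meta$n_frames
  cells <- rep(NA_integer_, n)
  r <- session$records
  sel <- r$hand == hand & !is.na(r$landmark_id) &
    r$landmark_id == as.integer(landmark_id)
  if (any(sel)) {
    rr <- r[sel, ]
    cells[rr$frame_index + 1L] <- assign_cell(rr$x_px, rr$y_px, grid)
  }
  structure(cells, class = "hm_cell_series", hand = hand,
            fps = session$meta$fps)
}

#' @export
print.hm_cell_series <- function(x, ...) {
  cat(sprintf("<hm_cell_series> %s hand, %d frames, %d undetected (%.1f%%)\n",
              attr(x, "hand"), length(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}
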