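#' Session metadata
#'
#' Describes one recorded procedure: frame rate, frame geometry and duration.
#' The number of frames is derived as `round(duration_s * fps)`.
#'
#' @param procedure_id Character identifier for the procedure.
#' @param fps Frames per second of the recording (> 0). Defaults to 30, the
#'   common consumer-camera rate.
#' @param width_px,height_px Frame dimensions in pixels (> 0).
#' @param duration_s Recording duration in seconds (> 0).
#'
#' @return An object of class `hm_meta`: a list with fields `procedure_id`,
#'   `fps`, `width_px`, `height_px`, `duration_s` and the derived `n_frames`.
#' @examples
#' session_meta("proc-1", fps = 30, width_px = 1920, height_px = 1080,
#'              duration_s = 600)
#' @export
session_meta <- function(procedure_id, fps = 30, width_px = 1920,
                         height_px = 1080, duration_s) {
  stopifnot(is.character(procedure_id), length(procedure_id) == 1L)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (!is.numeric(width_px) || width_px <= 0 || !is.numeric(height_px) ||
      height_px <= 0)
    stop("frame dimensions must be positive", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  structure(
    list(procedure_id = procedure_id, fps = as.numeric(fps),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         duration_s = as.numeric(duration_s),
         n_frames = as.integer(round(duration_s * fps))),
    class = "hm_meta")
}

#' @export
print.hm_meta <- function(x, ...) {
  cat(sprintf("<hm_meta> procedure %s: %g s @ %g fps (%d frames), %dx%d px\n",
              x$procedure_id, x$duration_s, x$fps, x$n_frames,
              x$width_px, x$height_px))
  invisible(x)
}

HAND_LEVELS <- c("left", "right", "none")

empty_records <- function() {
  tibble::tibble(frame_index = integer(), hand = character(),
                 landmark_id = integer(), x_px = numeric(), y_px = numeric())
}

#' Construct a landmark session
#'
#' Bundles session metadata with the per-frame landmark records emitted by a
#' 21-landmark hand detector. Each detected hand in a frame carries exactly 21
#' records (landmark ids 0-20, wrist plus digit joints and tips); a hand that
#' the detector lost is simply absent from that frame. A *null detection* --
#' a detector output without a left/right handedness decision -- is a single
#' record with `hand == "none"` and `NA` landmark id and coordinates.
#'
#' Coordinates are pixels with the origin at the top-left corner and y
#' increasing downward, so "0 pixels" on the vertical axis is the top of the
#' image.
#'
#' @param meta A [session_meta()] object.
#' @param records A data frame with columns `frame_index` (0-based integer),
#'   `hand` (`"left"`, `"right"` or `"none"`), `landmark_id` (0-20, `NA` for
#'   null records), `x_px`, `y_px`. Rows are sorted on construction.
#' @param validate Run full invariant checks (default `TRUE`).
#'
#' @return An object of class `hm_session`: a list with elements `meta` and
#'   `records` (a tibble sorted by frame, hand, landmark id).
#' @seealso [read_session()], [write_session()], [validate_session()]
#' @export
new_session <- function(meta, records = empty_records(), validate = TRUE) {
  stopifnot(inherits(meta, "hm_meta"))
  records <- tibble::as_tibble(records)
  needed <- c("frame_index", "hand", "landmark_id", "x_px", "y_px")
  if (!all(needed %in% names(records)))
    stop("records must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  records <- records[needed]
  records$frame_index <- as.integer(records$frame_index)
  records$hand <- as.character(records$hand)
  records$landmark_id <- as.integer(records$landmark_id)
  records$x_px <- as.numeric(records$x_px)
  records$y_px <- as.numeric(records$y_px)
  records <- dplyr::arrange(records, .data$frame_index, .data$hand,
                            .data$landmark_id)
  sess <- structure(list(meta = meta, records = records),
                    class = "hm_session")
  if (validate) validate_session(sess)
  sess
}

#' Validate a session against the format invariants
#'
#' Checks that frame indices lie within the session, landmark ids are in
#' 0-20, every detected hand in a frame carries all 21 landmarks, null
#' records carry no landmark payload, and coordinates are finite.
#'
#' @param session An `hm_session`.
#' @return The session, invisibly; errors describe the first violation.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "hm_session"))
  r <- session$records
  m <- session$meta
  if (nrow(r) == 0L) return(invisible(session))
  if (!all(r$hand %in% HAND_LEVELS))
    stop("validation error: `hand` must be one of ",
         paste(HAND_LEVELS, collapse = "/"), call. = FALSE)
  if (any(r$frame_index < 0L) || any(r$frame_index >= m$n_frames))
    stop("validation error: frame_index outside [0, n_frames)", call. = FALSE)
  det <- r[r$hand != "none", ]
  nul <- r[r$hand == "none", ]
  if (nrow(det)) {
    if (anyNA(det$landmark_id) ||
        any(det$landmark_id < 0L | det$landmark_id > 20L))
      stop("validation error: landmark_id must be in 0-20", call. = FALSE)
    if (anyNA(det$x_px) || anyNA(det$y_px) ||
        any(!is.finite(det$x_px)) || any(!is.finite(det$y_px)))
      stop("validation error: non-numeric coordinates on detected landmarks",
           call. = FALSE)
    # records are sorted by (frame, hand, landmark): every detected
    # (frame, hand) group must be exactly the landmark run 0,1,...,20
    key <- det$frame_index * 2 + (det$hand == "right")
    grp <- rle(key)
    if (any(grp$lengths != 21L) ||
        !identical(det$landmark_id, rep(0:20, length(grp$lengths))))
      stop("validation error: a detected (frame, hand) must carry each of ",
           "the 21 landmarks exactly once", call. = FALSE)
  }
  if (nrow(nul) && (!all(is.na(nul$landmark_id)) || !all(is.na(nul$x_px)) ||
                    !all(is.na(nul$y_px))))
    stop("validation error: null records must not carry landmark payload",
         call. = FALSE)
  invisible(session)
}

#' @export
print.hm_session <- function(x, ...) {
  print(x$meta)
  n <- nrow(x$records)
  nn <- sum(x$records$hand == "none")
  cat(sprintf("  %d landmark records (%d null)\n", n, nn))
  invisible(x)
}

#' Time of a frame
#'
#' Maps a 0-based frame index to the start of its half-open time interval
#' `[i/fps, (i+1)/fps)`.
#'
#' @param frame_index Integer vector of 0-based frame indices.
#' @param meta A [session_meta()].
#' @return Time(s) in seconds.
#' @examples
#' m <- session_meta("p", fps = 30, duration_s = 600)
#' frame_time(c(0, 30, 17999), m)
#' @export
frame_time <- function(frame_index, meta) {
  stopifnot(inherits(meta, "hm_meta"))
  if (any(frame_index < 0 | frame_index >= meta$n_frames))
    stop("frame_index outside [0, n_frames)", call. = FALSE)
  frame_index / meta$fps
}

meta_header_keys <- c("procedure_id", "fps", "width_px", "height_px",
                      "duration_s")

#' Read a landmark session file
#'
#' Reads the session formats written by [write_session()]: a CSV with
#' `#key=value` metadata header lines followed by
#' `frame_index,hand,landmark_id,x_px,y_px` rows, or a JSON object with
#' `meta` and `records` members. The format is inferred from the file
#' extension unless given.
#'
#' @param path Path to the session file.
#' @param format `"auto"` (default, by extension), `"csv"` or `"json"`.
#' @return A validated `hm_session`.
#' @export
read_session <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") read_session_json(path) else read_session_csv(path)
}

read_session_csv <- function(path) {
  head_lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  kv <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#([a-z_]+)=(.*)$", ln))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  missing <- setdiff(meta_header_keys, names(kv))
  if (length(missing))
    stop("schema error: missing meta header(s): ",
         paste0("#", missing, collapse = ", "), call. = FALSE)
  meta <- session_meta(kv$procedure_id, fps = as.numeric(kv$fps),
                       width_px = as.numeric(kv$width_px),
                       height_px = as.numeric(kv$height_px),
                       duration_s = as.numeric(kv$duration_s))
  # readr warns on parse problems; they are re-raised as errors below
  records <- suppressWarnings(readr::read_csv(
    path, comment = "#",
    col_types = readr::cols(frame_index = readr::col_integer(),
                            hand = readr::col_character(),
                            landmark_id = readr::col_integer(),
                            x_px = readr::col_double(),
                            y_px = readr::col_double()),
    progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(records)
  if (nrow(probs))
    stop("parse error at line ", probs$row[1L] + length(meta_lines) + 1L,
         ": ", probs$expected[1L], " but got '", probs$actual[1L], "'",
         call. = FALSE)
  if (!setequal(names(records),
                c("frame_index", "hand", "landmark_id", "x_px", "y_px")))
    stop("schema error: unexpected CSV columns", call. = FALSE)
  new_session(meta, records)
}

read_session_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$meta) || is.null(obj$records))
    stop("schema error: JSON session must have `meta` and `records`",
         call. = FALSE)
  mk <- obj$meta
  missing <- setdiff(meta_header_keys, names(mk))
  if (length(missing))
    stop("schema error: missing meta field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  meta <- session_meta(mk$procedure_id, fps = mk$fps, width_px = mk$width_px,
                       height_px = mk$height_px, duration_s = mk$duration_s)
  rec <- obj$records
  if (length(rec) == 0L || (is.data.frame(rec) && nrow(rec) == 0L))
    return(new_session(meta))
  rec <- tibble::as_tibble(rec)
  new_session(meta, rec)
}

#' Write a landmark session file
#'
#' Emits a session as CSV (metadata in `#key=value` header lines) or JSON.
#' Coordinates are written with two decimal places -- sub-pixel precision
#' beyond detector jitter carries no information, and the fixed precision
#' makes write/read round-trips exact. Null records leave the landmark
#' fields empty.
#'
#' @param session An `hm_session`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  validate_session(session)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  m <- session$meta
  r <- session$records
  r$x_px <- round(r$x_px, 2L)
  r$y_px <- round(r$y_px, 2L)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#%s=%s", meta_header_keys,
                       c(m$procedure_id, format(m$fps), m$width_px,
                         m$height_px, format(m$duration_s))), con)
    writeLines("frame_index,hand,landmark_id,x_px,y_px", con)
    if (nrow(r)) {
      num <- function(v) ifelse(is.na(v), "", sprintf("%.2f", v))
      writeLines(paste(r$frame_index, r$hand,
                       ifelse(is.na(r$landmark_id), "", r$landmark_id),
                       num(r$x_px), num(r$y_px), sep = ","), con)
    }
  } else {
    obj <- list(meta = list(procedure_id = m$procedure_id, fps = m$fps,
                            width_px = m$width_px, height_px = m$height_px,
                            duration_s = m$duration_s),
                records = r)
    jsonlite::write_json(obj, path, dataframe = "columns", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
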