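# Fixtures are built in code: tiny sessions with hands parked at known
# pixel positions, and hand-made cell series.

# 21 landmark records per frame for one hand, all at (x, y)
hand_block <- function(frames, hand, x, y) {
  tibble::tibble(
    frame_index = rep(frames, each = 21L),
    hand = hand,
    landmark_id = rep(0:20, times = length(frames)),
    x_px = x, y_px = y)
}

null_block <- function(frames) {
  tibble::tibble(frame_index = frames, hand = "none",
                 landmark_id = NA_integer_, x_px = NA_real_, y_px = NA_real_)
}

# session with hands parked at fixed positions; positions is a list like
# list(right = c(x, y), left = c(x, y)); NULL hand -> absent
parked_session <- function(duration_s = 2, fps = 30, width_px = 1920,
                           height_px = 1080, positions = list(),
                           null_frames = integer(), id = "fix") {
  meta <- session_meta(id, fps = fps, width_px = width_px,
                       height_px = height_px, duration_s = duration_s)
  frames <- 0:(meta$n_frames - 1L)
  blocks <- lapply(names(positions), function(h)
    hand_block(frames, h, positions[[h]][1L], positions[[h]][2L]))
  if (length(null_frames)) blocks <- c(blocks, list(null_block(null_frames)))
  recs <- if (length(blocks)) dplyr::bind_rows(blocks) else
    tibble::tibble(frame_index = integer(), hand = character(),
                   landmark_id = integer(), x_px = numeric(),
                   y_px = numeric())
  new_session(meta, recs)
}

# a cell series straight from a vector of cells (NA = undetected)
as_series <- function(cells, hand = "right", fps = 30) {
  structure(as.integer(cells), class = "hm_cell_series", hand = hand,
            fps = fps)
}

meta_for <- function(cells, fps = 30, id = "fix") {
  session_meta(id, fps = fps, duration_s = length(cells) / fps)
}

# independent per-frame recount of cell occupancy straight from records,
# bypassing cell_series/dwell_times: arithmetic cell formula + explicit loop
brute_force_dwell_frames <- function(session, landmark_id = 12L) {
  m <- session$meta
  counts <- setNames(numeric(9L), as.character(1:9))
  r <- session$records
  r <- r[!is.na(r$landmark_id) & r$landmark_id == landmark_id, ]
  for (i in seq_len(nrow(r))) {
    cx <- floor(3 * r$x_px[i] / m$width_px)
    cy <- floor(3 * r$y_px[i] / m$height_px)
    cx <- min(max(cx, 0), 2)
    cy <- min(max(cy, 0), 2)
    if (r$x_px[i] >= 0 && r$x_px[i] <= m$width_px &&
        r$y_px[i] >= 0 && r$y_px[i] <= m$height_px) {
      cell <- as.character(cy * 3 + cx + 1)
      counts[cell] <- counts[cell] + 1
    }
  }
  counts
}

# small, fast simulator configuration used across tests
fast_config <- function(..., duration_s = 60) {
  sim_config(duration_s = duration_s,
             drill = list(cell = 5L, mean_s = 12, sd_s = 4, min_s = 4),
             excursions = list(
               instrument_change = list(cell = 4L, mean_s = 8, sd_s = 3,
                                        min_s = 2, prob = 0.4),
               microscope_adjust = list(cell = 2L, mean_s = 4.4, sd_s = 2,
                                        min_s = 2, prob = 0.4),
               trash = list(cell = 7L, mean_s = 5, sd_s = 2, min_s = 2,
                            prob = 0.2)),
             ...)
}
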