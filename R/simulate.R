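`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulator configuration
#'
#' Parameters of the behaviour simulator that stands in for recorded
#' sessions. A surgeon alternates long drilling dwells in the surgical-field
#' cell with excursions to semantic cells: the instrument table (cell 4),
#' the microscope handles (top row; the handle reached is sampled from
#' `microscope_cells`) and the trash bin (cell 7). Dwell durations are
#' lognormal (positive and right-skewed, matching the large spreads such
#' reaches show), with a physical floor `min_s` -- no deliberate reach
#' completes faster. The wrist follows an Ornstein-Uhlenbeck
#' (mean-reverting) walk toward the active cell's anchor; 21 landmarks are
#' a rigid hand template around the wrist with per-landmark jitter.
#' Tracking dropout removes whole hand-frames with probability `p0`, plus
#' `p1` when the wrist is within `radius_px` of the frame centre (microscope
#' glare); null-handedness records are injected per hand-frame at `p_null`.
#'
#' @param duration_s,fps,width_px,height_px Session geometry (defaults:
#'   600 s at 30 fps, 1920x1080).
#' @param drill List: `cell` anchor (5), lognormal `mean_s`/`sd_s` of
#'   drilling bouts, floor `min_s`.
#' @param excursions Named list of excursion kinds, each a list with `cell`
#'   anchor, lognormal `mean_s`/`sd_s`, floor `min_s` and transition
#'   probability `prob` out of drilling (probs must sum to <= 1; the
#'   remainder continues drilling).
#' @param microscope_cells Integer cells from which a microscope reach
#'   samples its anchor (default 1:3, centre handle most likely).
#' @param microscope_cell_probs Sampling weights for `microscope_cells`.
#' @param theta Mean-reversion rate of the wrist walk, 1/s.
#' @param sigma Diffusion of the wrist walk, px/sqrt(s).
#' @param hand_scale Hand template scale in px (wrist-to-fingertip ~ scale).
#' @param hand_sep_px Lateral offset of each wrist from its anchor, px
#'   (keeps the two hands side by side in the field).
#' @param dropout List with `p0`, `p1`, `radius_px`.
#' @param p_null Per-frame, per-hand probability of a null record.
#' @param dominant `"right"` or `"left"`: the hand performing excursions.
#' @return A list of class `hm_sim_config`.
#' @export
sim_config <- function(duration_s = 600, fps = 30, width_px = 1920,
                       height_px = 1080,
                       drill = list(cell = 5L, mean_s = 55, sd_s = 25,
                                    min_s = 5),
                       excursions = list(
                         instrument_change = list(cell = 4L, mean_s = 21.5,
                                                  sd_s = 12.4, min_s = 2,
                                                  prob = 0.4),
                         microscope_adjust = list(cell = 2L, mean_s = 4.4,
                                                  sd_s = 5.7, min_s = 2,
                                                  prob = 0.4),
                         trash = list(cell = 7L, mean_s = 5.5, sd_s = 9.1,
                                      min_s = 2, prob = 0.2)),
                       microscope_cells = 1:3,
                       microscope_cell_probs = c(0.25, 0.5, 0.25),
                       theta = 8, sigma = 30, hand_scale = 60,
                       hand_sep_px = 80,
                       dropout = list(p0 = 0.10, p1 = 0.05, radius_px = 150),
                       p_null = 0.02, dominant = c("right", "left")) {
  dominant <- match.arg(dominant)
  probs <- vapply(excursions, function(e) e$prob, numeric(1L))
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1 + 1e-12)
    stop("excursion probabilities must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  for (p in c(dropout$p0, dropout$p1, p_null))
    if (p < 0 || p > 1) stop("rates must lie in [0,1]", call. = FALSE)
  if (theta < 0 || sigma < 0 || dropout$radius_px < 0)
    stop("theta, sigma and radius_px must be >= 0", call. = FALSE)
  dwells <- c(list(drill), excursions)
  if (any(vapply(dwells, function(d) d$mean_s <= 0 || d$min_s < 0,
                 logical(1L))))
    stop("dwell durations must be positive", call. = FALSE)
  structure(list(duration_s = duration_s, fps = fps, width_px = width_px,
                 height_px = height_px, drill = drill,
                 excursions = excursions,
                 microscope_cells = microscope_cells,
                 microscope_cell_probs = microscope_cell_probs,
                 theta = theta, sigma = sigma, hand_scale = hand_scale,
                 hand_sep_px = hand_sep_px, dropout = dropout,
                 p_null = p_null, dominant = dominant),
            class = "hm_sim_config")
}

# lognormal with natural-scale mean m and sd s, resampled above a floor
rlnorm_ms <- function(n, mean_s, sd_s, min_s = 0) {
  sdlog2 <- log(1 + (sd_s / mean_s)^2)
  meanlog <- log(mean_s) - sdlog2 / 2
  x <- stats::rlnorm(n, meanlog, sqrt(sdlog2))
  while (any(bad <- x < min_s))
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sqrt(sdlog2))
  x
}

cell_center <- function(cell, config) {
  col <- (cell - 1L) %% 3L
  row <- (cell - 1L) %/% 3L
  c(x = (col + 0.5) * config$width_px / 3,
    y = (row + 0.5) * config$height_px / 3)
}

#' Draw the surgeon's state schedule
#'
#' Simulates the semi-Markov behaviour model: the dominant hand alternates
#' drilling bouts with excursions drawn by the configured transition
#' probabilities; the non-dominant hand drills throughout. Dwells are drawn
#' in seconds and quantised to whole frames; the schedule tiles the session
#' without overlap per hand. A final excursion that could not complete
#' before the session ends is replaced by drilling to the end (procedures
#' end mid-drilling).
#'
#' @param config An [sim_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `hm_truth` with element `schedule`: a tibble
#'   `(hand, kind, cell, start_frame, end_frame, start_s, end_s,
#'   duration_s)`. The dropout and null logs are filled in by
#'   [render_session()].
#' @export
state_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "hm_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  fps <- config$fps
  n_frames <- as.integer(round(config$duration_s * fps))
  kinds <- names(config$excursions)
  probs <- vapply(config$excursions, function(e) e$prob, numeric(1L))

  draw_frames <- function(d) max(1L, as.integer(round(
    rlnorm_ms(1L, d$mean_s, d$sd_s, d$min_s) * fps)))

  rows <- list()
  at <- 0L  # next free frame (0-based)
  repeat {
    if (at >= n_frames) break
    # drilling bout
    df <- draw_frames(config$drill)
    dr_end <- min(at + df - 1L, n_frames - 1L)
    rows[[length(rows) + 1L]] <- list(kind = "drill",
                                      cell = config$drill$cell,
                                      start = at, end = dr_end)
    at <- dr_end + 1L
    if (at >= n_frames) break
    u <- stats::runif(1L)
    k <- findInterval(u, cumsum(probs)) + 1L
    if (k > length(kinds)) next  # stayed drilling; extend with another bout
    exc <- config$excursions[[k]]
    ef <- draw_frames(exc)
    if (at + ef > n_frames) {
      # excursion would not complete: drill to the end instead
      rows[[length(rows) + 1L]] <- list(kind = "drill",
                                        cell = config$drill$cell,
                                        start = at, end = n_frames - 1L)
      at <- n_frames
      break
    }
    cell <- exc$cell
    if (kinds[k] == "microscope_adjust")
      cell <- sample(config$microscope_cells, 1L,
                     prob = config$microscope_cell_probs)
    rows[[length(rows) + 1L]] <- list(kind = kinds[k], cell = cell,
                                      start = at, end = at + ef - 1L)
    at <- at + ef
  }
  sch <- tibble::tibble(
    hand = config$dominant,
    kind = vapply(rows, `[[`, character(1L), "kind"),
    cell = as.integer(vapply(rows, `[[`, numeric(1L), "cell")),
    start_frame = as.integer(vapply(rows, `[[`, numeric(1L), "start")),
    end_frame = as.integer(vapply(rows, `[[`, numeric(1L), "end")))
  # collapse adjacent drill rows
  keep <- rep(TRUE, nrow(sch))
  prev <- 1L
  for (i in seq_len(nrow(sch))[-1L]) {
    if (sch$kind[i] == "drill" && sch$kind[prev] == "drill") {
      sch$end_frame[prev] <- sch$end_frame[i]
      keep[i] <- FALSE
    } else {
      prev <- i
    }
  }
  sch <- sch[keep, ]
  other <- setdiff(c("left", "right"), config$dominant)
  sch <- dplyr::bind_rows(sch, tibble::tibble(
    hand = other, kind = "drill", cell = config$drill$cell,
    start_frame = 0L, end_frame = n_frames - 1L))
  sch$start_s <- sch$start_frame / fps
  sch$end_s <- (sch$end_frame + 1L) / fps
  sch$duration_s <- sch$end_s - sch$start_s
  structure(list(schedule = sch, dropout = NULL, null_frames = NULL,
                 n_frames = n_frames, fps = fps),
            class = "hm_truth")
}

#' True excursion events of a simulated session
#'
#' @param truth An `hm_truth`.
#' @param hand Hand to extract (default the hand that has excursions).
#' @return Tibble of non-drill schedule rows with `kind`, `start_s`, `end_s`.
#' @export
truth_events <- function(truth, hand = NULL) {
  stopifnot(inherits(truth, "hm_truth"))
  ev <- truth$schedule[truth$schedule$kind != "drill", ]
  if (!is.null(hand)) ev <- ev[ev$hand == hand, ]
  ev[order(ev$start_s), ]
}

# stylised 21-landmark hand template, unit scale, wrist at origin,
# fingertips toward negative y (up); x mirrored for the left hand
hand_template <- function(hand) {
  off <- rbind(
    c(0, 0),                                                     # 0 wrist
    c(-0.25, -0.10), c(-0.45, -0.25), c(-0.60, -0.40), c(-0.70, -0.50), # thumb
    c(-0.30, -0.45), c(-0.35, -0.70), c(-0.38, -0.85), c(-0.40, -1.00), # index
    c(-0.10, -0.50), c(-0.12, -0.75), c(-0.13, -0.90), c(-0.15, -1.05), # middle
    c(0.10, -0.48), c(0.12, -0.72), c(0.13, -0.87), c(0.15, -1.00),     # ring
    c(0.30, -0.42), c(0.33, -0.60), c(0.35, -0.72), c(0.37, -0.85))     # pinky
  if (hand == "left") off[, 1L] <- -off[, 1L]
  off
}

#' Render a scheduled session into landmark records
#'
#' Realises a [state_schedule()] as a landmark stream. Each wrist follows a
#' discretised Ornstein-Uhlenbeck walk toward its active anchor,
#' `p[t+1] = p[t] + theta * (anchor - p[t]) * dt + sigma * sqrt(dt) * eps`;
#' the 21 landmarks are the hand template around the wrist with small
#' per-landmark jitter, clipped to the frame and rounded to 2 decimals.
#' Whole hand-frames are dropped with probability `p0`, plus `p1` inside
#' the central bright disc; null records are injected at `p_null`. The
#' returned truth carries the per-frame dropout and null logs.
#'
#' @param truth An `hm_truth` from [state_schedule()].
#' @param config The same [sim_config()].
#' @param seed Optional integer seed.
#' @param procedure_id Identifier for the session metadata.
#' @return A list with elements `session` (`hm_session`) and `truth`
#'   (`hm_truth` with `dropout` and `null_frames` filled in).
#' @export
render_session <- function(truth, config, seed = NULL,
                           procedure_id = "sim") {
  stopifnot(inherits(truth, "hm_truth"), inherits(config, "hm_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  fps <- config$fps
  n <- truth$n_frames
  dt <- 1 / fps
  meta <- session_meta(procedure_id, fps = fps, width_px = config$width_px,
                       height_px = config$height_px,
                       duration_s = config$duration_s)
  stopifnot(meta$n_frames == n)
  center <- c(config$width_px / 2, config$height_px / 2)

  rec_list <- list()
  drop_list <- list()
  null_list <- list()
  for (hand in c("left", "right")) {
    sch <- truth$schedule[truth$schedule$hand == hand, ]
    sch <- sch[order(sch$start_frame), ]
    sep <- if (hand == config$dominant) config$hand_sep_px else
      -config$hand_sep_px
    # anchor the wrist so that landmark 12 -- the occupancy proxy -- sits at
    # the target cell centre (plus the lateral hand offset)
    tip_off <- hand_template(hand)[13L, ] * config$hand_scale
    anchors <- matrix(NA_real_, n, 2L)
    for (i in seq_len(nrow(sch))) {
      idx <- (sch$start_frame[i]:sch$end_frame[i]) + 1L
      cc <- cell_center(sch$cell[i], config)
      anchors[idx, 1L] <- cc["x"] + sep - tip_off[1L]
      anchors[idx, 2L] <- cc["y"] - tip_off[2L]
    }
    # OU walk of the wrist
    pos <- matrix(NA_real_, n, 2L)
    p <- anchors[1L, ]
    noise <- matrix(stats::rnorm(2L * n, sd = config$sigma * sqrt(dt)), n, 2L)
    for (t in seq_len(n)) {
      p <- p + config$theta * (anchors[t, ] - p) * dt + noise[t, ]
      pos[t, ] <- p
    }
    dist_c <- sqrt((pos[, 1L] - center[1L])^2 + (pos[, 2L] - center[2L])^2)
    p_drop <- config$dropout$p0 +
      config$dropout$p1 * (dist_c < config$dropout$radius_px)
    detected <- stats::runif(n) >= p_drop
    drop_list[[hand]] <- tibble::tibble(frame_index = 0:(n - 1L),
                                        hand = hand, detected = detected)
    is_null <- stats::runif(n) < config$p_null
    null_list[[hand]] <- which(is_null) - 1L

    det_idx <- which(detected)
    if (length(det_idx)) {
      tmpl <- hand_template(hand) * config$hand_scale
      nf <- length(det_idx)
      fx <- rep(pos[det_idx, 1L], each = 21L) + rep(tmpl[, 1L], nf) +
        stats::rnorm(21L * nf, sd = 1.5)
      fy <- rep(pos[det_idx, 2L], each = 21L) + rep(tmpl[, 2L], nf) +
        stats::rnorm(21L * nf, sd = 1.5)
      rec_list[[hand]] <- tibble::tibble(
        frame_index = rep(det_idx - 1L, each = 21L),
        hand = hand,
        landmark_id = rep(0:20, nf),
        x_px = round(pmin(pmax(fx, 0), config$width_px), 2L),
        y_px = round(pmin(pmax(fy, 0), config$height_px), 2L))
    }
  }
  null_frames <- sort(unlist(null_list, use.names = FALSE))
  if (length(null_frames))
    rec_list[["null"]] <- tibble::tibble(
      frame_index = null_frames, hand = "none", landmark_id = NA_integer_,
      x_px = NA_real_, y_px = NA_real_)
  records <- if (length(rec_list)) dplyr::bind_rows(rec_list) else
    empty_records()
  session <- new_session(meta, records)
  truth$dropout <- dplyr::bind_rows(drop_list)
  truth$null_frames <- null_frames
  list(session = session, truth = truth)
}

#' Simulate one session end to end
#'
#' Convenience wrapper: draws a schedule and renders it.
#'
#' @inheritParams render_session
#' @param config An [sim_config()].
#' @param seed Integer seed (drives both schedule and rendering).
#' @return A list with `session` and `truth`.
#' @export
simulate_session <- function(config = sim_config(), seed = NULL,
                             procedure_id = "sim") {
  truth <- state_schedule(config, seed = seed)
  render_session(truth, config, seed = NULL, procedure_id = procedure_id)
}

#' Simulate a batch of procedures
#'
#' Independent sessions whose seeds are derived reproducibly from one
#' master seed, mirroring a repeated-procedure study design.
#'
#' @param config An [sim_config()].
#' @param n_procedures Number of sessions (>= 1).
#' @param seed Master integer seed.
#' @return A list with `sessions` (list of `hm_session`) and `truths`
#'   (list of `hm_truth`).
#' @export
simulate_batch <- function(config = sim_config(), n_procedures = 3L,
                           seed = NULL) {
  if (n_procedures < 1L) stop("`n_procedures` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_procedures)
  out <- lapply(seq_len(n_procedures), function(i)
    simulate_session(config, seed = child_seeds[i],
                     procedure_id = sprintf("sim-%03d", i)))
  list(sessions = lapply(out, `[[`, "session"),
       truths = lapply(out, `[[`, "truth"))
}
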