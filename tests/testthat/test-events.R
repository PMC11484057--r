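fps <- 30

test_that("a hand that never leaves the surgical field yields no events", {
  s <- as_series(rep(5L, 600))
  ev <- detect_events(s, meta_for(s))
  expect_s3_class(ev, "hm_events")
  expect_equal(nrow(ev), 0L)
})

test_that("a single instrument-table excursion is one event of that length", {
  cells <- rep(5L, 18000)
  cells[3001:3600] <- 4L  # 20 s in cell 4
  ev <- detect_events(as_series(cells), meta_for(cells))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "instrument_change")
  expect_lt(abs(ev$duration_s - 20), 1 / fps + 1e-9)
  expect_equal(ev$start_frame, 3000L)
  expect_equal(ev$cells_visited[[1]], 4L)
})

test_that("short tracking dropouts do not split an excursion", {
  cells <- rep(5L, 1200)
  cells[301:600] <- 4L
  cells[400:410] <- NA  # 0.37 s dropout inside the excursion
  ev <- detect_events(as_series(cells), meta_for(cells))
  expect_equal(nrow(ev), 1L)
  # a dropout longer than gap_fill_s splits it, and the 2 s separation
  # exceeds merge_gap_s, so two events remain
  cells[380:440] <- NA
  ev2 <- detect_events(as_series(cells), meta_for(cells))
  expect_equal(nrow(ev2), 2L)
})

test_that("same-kind excursions separated by a brief return are merged", {
  cells <- rep(5L, 1200)
  cells[301:360] <- 4L
  cells[376:450] <- 4L  # 0.5 s of cell 5 between: below merge_gap_s
  ev <- detect_events(as_series(cells), meta_for(cells))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 300L)
  expect_equal(ev$end_frame, 449L)
  # a 2 s separation stays two events
  cells2 <- rep(5L, 1200)
  cells2[301:360] <- 4L
  cells2[421:480] <- 4L
  expect_equal(nrow(detect_events(as_series(cells2), meta_for(cells2))), 2L)
})

test_that("sub-threshold flickers are dropped", {
  cells <- rep(5L, 600)
  cells[101:110] <- 4L  # 0.33 s < min_duration_s
  expect_equal(nrow(detect_events(as_series(cells), meta_for(cells))), 0L)
  cfg <- event_config(min_duration_s = 0.2)
  expect_equal(nrow(detect_events(as_series(cells), meta_for(cells), cfg)), 1L)
})

test_that("mixed-cell excursions classify by precedence", {
  mk <- function(path_cells) {
    cells <- rep(5L, 600)
    path <- rep(path_cells, each = ceiling(60 / length(path_cells)))
    cells[101:160] <- path[1:60]
    detect_events(as_series(cells), meta_for(cells))
  }
  expect_equal(mk(c(4L, 2L))$kind, "microscope_adjust")  # handle reach via 4
  expect_equal(mk(c(4L, 7L))$kind, "instrument_change")
  expect_equal(mk(c(8L, 7L))$kind, "trash")
  expect_equal(mk(6L)$kind, "other")
})

test_that("events are disjoint, ordered and deterministic on simulations", {
  for (seed in c(2L, 9L)) {
    sim <- simulate_session(fast_config(), seed = seed)
    m <- sim$session$meta
    g <- make_grid(m$width_px, m$height_px)
    sr <- cell_series(sim$session, g, "right")
    ev <- detect_events(sr, m)
    if (nrow(ev) > 1L) {
      expect_true(all(diff(ev$start_frame) > 0))
      expect_true(all(ev$start_frame[-1L] > ev$end_frame[-nrow(ev)]))
    }
    expect_identical(ev, detect_events(sr, m))
    # monotonicity in the filtering parameters
    n0 <- nrow(ev)
    expect_lte(nrow(detect_events(sr, m, event_config(min_duration_s = 2))),
               n0)
    expect_lte(nrow(detect_events(sr, m, event_config(merge_gap_s = 3))), n0)
  }
})

test_that("event_stats gives per-kind count, mean and sample SD", {
  ev <- tibble::tibble(kind = c("instrument_change", "instrument_change",
                                "trash"),
                       hand = "right", start_frame = c(0L, 1000L, 2000L),
                       end_frame = c(599L, 1689L, 2059L),
                       start_s = c(0, 33.3, 66.7), end_s = c(20, 56.3, 68.7),
                       duration_s = c(20, 23, 2),
                       cells_visited = list(4L, 4L, 7L))
  st <- event_stats(ev)
  ic <- st[st$kind == "instrument_change", ]
  expect_equal(ic$n, 2L)
  expect_equal(ic$mean_s, 21.5)
  expect_equal(ic$sd_s, abs(20 - 23) / sqrt(2))
  expect_true(is.na(st$sd_s[st$kind == "trash"]))  # single event
  empty <- event_stats(detect_events(as_series(rep(5L, 60)),
                                     meta_for(rep(5L, 60))))
  expect_equal(empty$n, rep(0L, 4L))
})

test_that("matching detected events against themselves is perfect", {
  cells <- rep(5L, 3000)
  cells[301:900] <- 4L
  cells[1501:1650] <- 2L
  ev <- detect_events(as_series(cells), meta_for(cells))
  truth <- ev[c("kind", "start_s", "end_s")]
  m <- match_events(ev, truth, tol_s = 0.5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(max(m$matches$start_err_s), 0)
  # nothing detected: recall 0, precision undefined
  none <- detect_events(as_series(rep(5L, 60)), meta_for(rep(5L, 60)))
  m0 <- match_events(none, truth)
  expect_equal(m0$recall, 0)
  expect_true(is.na(m0$precision))
  expect_error(match_events(ev, truth, tol_s = -1), "tol_s")
})
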