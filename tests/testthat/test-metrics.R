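# The printed study values these checks reproduce: per-procedure counts
# 621,898 / 641,625 / 685,314 over 600 s each, total 1,948,837 over 1800 s;
# fps 30 and 42 possible records per frame.
T1 <- list(
  counts = c(621898, 641625, 685314, 1948837),
  frames = c(18000, 18000, 18000, 54000),
  right = c(345786, 254583, 339171, 939540),
  left = c(275646, 386757, 345513, 1007916),
  null = c(466, 285, 630, 1381))

test_that("detection performance reproduces the printed per-procedure cells", {
  perf <- trunc_decimal(detection_performance(T1$counts, n_frames = T1$frames))
  expect_equal(perf, c(82.2, 84.8, 90.6, 85.9))
})

test_that("hand shares reproduce the printed percentages under truncation", {
  sh <- sapply(1:4, function(i)
    trunc_decimal(hand_shares(c(right = T1$right[i], left = T1$left[i],
                                null = T1$null[i]))))
  expect_equal(unname(sh["right", ]), c(55.6, 39.6, 49.4, 48.2))
  expect_equal(unname(sh["left", c(1, 3, 4)]), c(44.3, 50.4, 51.7))
  # row-2 left and total null are printed at coarser precision
  expect_equal(unname(trunc_decimal(sh["left", 2], 0L)), 60)
  expect_equal(round(unname(hand_shares(c(right = 939540, left = 1007916,
                                          null = 1381))["null"]), 1), 0.1)
})

test_that("detection rate truncates to whole records per second", {
  expect_equal(trunc_decimal(detections_per_second(1948837, 1800), 0L), 1082)
  # full detection at 30 fps: 42 records/frame
  s <- parked_session(duration_s = 1, positions =
                        list(left = c(800, 500), right = c(1100, 560)))
  expect_equal(detections_per_second(s), 1260)
  expect_equal(detection_performance(s), 100)
  s0 <- parked_session(duration_s = 1, positions = list())
  expect_equal(detection_performance(s0), 0)
  expect_equal(detections_per_second(s0), 0)
  expect_error(hand_shares(s0), "undefined")
})

test_that("performance_report on a full-detection session is exact", {
  s <- parked_session(duration_s = 2, positions =
                        list(left = c(800, 500), right = c(1100, 560)),
                      null_frames = c(3L, 10L))
  p <- performance_report(s)
  expect_equal(p$n_total, 60L * 42L + 2L)
  expect_equal(p$n_right + p$n_left + p$n_null, p$n_total)
  expect_equal(p$right_pct + p$left_pct + p$null_pct, 100)
})

test_that("dwell time sums both hands and is capped by twice the duration", {
  s <- parked_session(duration_s = 600, positions =
                        list(left = c(900, 540), right = c(1000, 560)))
  g <- make_grid(1920, 1080)
  d <- dwell_times(cell_series(s, g, "left"), cell_series(s, g, "right"),
                   s$meta)
  expect_equal(unname(unclass(d)["5"]), 1200)
  expect_equal(sum(d), 1200)
  # one hand absent: totals equal single-hand occupancy
  s1 <- parked_session(duration_s = 600,
                       positions = list(right = c(1000, 560)))
  d1 <- dwell_times(cell_series(s1, g, "left"), cell_series(s1, g, "right"),
                    s1$meta)
  expect_equal(sum(d1), 600)
  expect_error(dwell_times(as_series(rep(5, 10)), as_series(rep(5, 9)),
                           meta_for(rep(5, 10))), "length")
})

test_that("dwell conservation holds exactly on simulated sessions", {
  for (seed in 1:3) {
    sim <- simulate_session(fast_config(), seed = seed)
    m <- sim$session$meta
    g <- make_grid(m$width_px, m$height_px)
    sl <- cell_series(sim$session, g, "left")
    sr <- cell_series(sim$session, g, "right")
    d <- dwell_times(sl, sr, m)
    und <- attr(d, "undetected_frames")
    expect_identical(sum(attr(d, "frames")) + sum(und), 2L * m$n_frames)
    expect_equal(sum(d) + sum(und) / m$fps, 2 * m$duration_s)
  }
})

test_that("simulated dwell equals an independent per-record recount", {
  sim <- simulate_session(fast_config(duration_s = 20), seed = 5L)
  m <- sim$session$meta
  g <- make_grid(m$width_px, m$height_px)
  d <- dwell_times(cell_series(sim$session, g, "left"),
                   cell_series(sim$session, g, "right"), m)
  oracle <- brute_force_dwell_frames(sim$session)
  expect_equal(as.numeric(attr(d, "frames")), unname(oracle))
})

test_that("aggregate_dwell computes cross-procedure mean and sample SD", {
  base <- structure(setNames(c(0, 0, 0, 20, 900, 0, 5, 0, 0),
                             as.character(1:9)), class = "hm_dwell")
  agg <- aggregate_dwell(list(base, base, base))
  expect_equal(agg$sd_s, rep(0, 9))
  expect_equal(agg$mean_s[5], 900)
  # illustrative centre-cell values averaging to the study's magnitude
  t3 <- lapply(c(900, 1000, 1061.3), function(v) {
    x <- base; x["5"] <- v; x
  })
  agg3 <- aggregate_dwell(t3)
  expect_equal(agg3$mean_s[5], 987.1)
  expect_equal(agg3$sd_s[5], sd(c(900, 1000, 1061.3)))
  # two procedures: SD has the closed form |a-b|/sqrt(2)
  a <- base; b <- base; b["4"] <- 50
  agg2 <- aggregate_dwell(list(a, b))
  expect_equal(agg2$sd_s[4], abs(20 - 50) / sqrt(2))
  expect_error(aggregate_dwell(list(base)), "at least 2")
})

test_that("heatmap matrix lays cells out row-major and conserves totals", {
  vals <- setNames(c(9.7, 3.1, 0.6, 21.5, 987.1, 0.5, 5.5, 1.4, 1.7),
                   as.character(1:9))
  m <- heatmap_matrix(vals)
  expect_equal(m[1, 1], 9.7)
  expect_equal(m[2, 2], 987.1)
  expect_equal(m[2, 1], 21.5)
  expect_equal(m[3, 1], 5.5)
  expect_equal(sum(m), sum(vals))
  only5 <- setNames(c(0, 0, 0, 0, 100, 0, 0, 0, 0), as.character(1:9))
  m5 <- heatmap_matrix(only5)
  expect_equal(sum(m5 != 0), 1L)
  expect_equal(m5[2, 2], 100)
})

test_that("truncation convention floors toward the printed precision", {
  expect_equal(trunc_decimal(c(51.72, 49.49, 39.67, 84.87)),
               c(51.7, 49.4, 39.6, 84.8))
  expect_equal(trunc_decimal(1082.69, 0L), 1082)
})
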