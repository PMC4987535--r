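test_that("ROI assignment respects margins and leaves the centre empty", {
  geo <- screen_geometry()
  r <- geo$rois
  # symbol centres hit their ROIs
  cx <- (r$x0 + r$x1) / 2
  cy <- (r$y0 + r$y1) / 2
  expect_identical(assign_roi(cx, cy, geo), r$roi)

  # 49 px outside the symbol box edge is inside the 50 px margin;
  # 51 px outside is not
  box_right <- r$x1[r$roi == "left_symbol"] - geo$margin
  y_mid <- cy[r$roi == "left_symbol"]
  expect_identical(assign_roi(box_right + 49, y_mid, geo), "left_symbol")
  expect_true(is.na(assign_roi(box_right + 51, y_mid, geo)))

  # forced-fixation point (screen centre) lies outside all ROIs
  expect_true(is.na(assign_roi(geo$screen_w / 2, geo$screen_h / 2, geo)))
  # off-screen samples are never assigned
  expect_true(is.na(assign_roi(-5, y_mid, geo)))
})

test_that("samples collapse into run-length events", {
  geo <- screen_geometry()
  r <- geo$rois
  cx <- function(roi) mean(unlist(r[r$roi == roi, c("x0", "x1")]))
  cy <- function(roi) mean(unlist(r[r$roi == roi, c("y0", "y1")]))

  # 100 consecutive left-symbol samples at 1000 Hz: one 100 ms event
  s <- data.frame(subject_id = 1L, trial = 1L, t_ms = 0:99,
                  x_px = cx("left_symbol"), y_px = cy("left_symbol"))
  ev <- samples_to_events(s, geo)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$dwell_ms, 100)

  # empty input: empty event table
  expect_identical(nrow(samples_to_events(s[0, ], geo)), 0L)

  # alternating roi/none runs respect run boundaries (hand oracle)
  labs <- c("left_symbol", "left_symbol", "none", "right_symbol", "none",
            "none", "right_symbol", "right_symbol", "left_bar")
  xy <- t(vapply(labs, function(l) {
    if (l == "none") c(geo$screen_w / 2, geo$screen_h / 2)
    else c(cx(l), cy(l))
  }, numeric(2)))
  s2 <- data.frame(subject_id = 1L, trial = 1L, t_ms = seq_along(labs) - 1,
                   x_px = xy[, 1], y_px = xy[, 2])
  ev2 <- samples_to_events(s2, geo)
  expect_identical(ev2$roi, c("left_symbol", "right_symbol",
                              "right_symbol", "left_bar"))
  expect_equal(ev2$onset_ms, c(0, 3, 6, 8))
})

test_that("cleaning merges blink-split gazes and drops cross-ROI gaps", {
  e <- data.frame(subject_id = 1L, trial = 1L,
                  roi = c("left_symbol", "left_symbol"),
                  onset_ms = c(0, 150), offset_ms = c(100, 300),
                  dwell_ms = c(100, 150))
  m <- clean_events(e)
  expect_identical(nrow(m), 1L)
  expect_equal(m$dwell_ms, 250) # gap excluded from dwell
  expect_equal(m$offset_ms, 300)
  expect_equal(clean_events(e, gap_inclusive = TRUE)$dwell_ms, 300)

  # cross-ROI gap: both events unchanged
  e2 <- e
  e2$roi <- c("left_symbol", "right_symbol")
  expect_identical(nrow(clean_events(e2)), 2L)
  expect_equal(clean_events(e2)$dwell_ms, c(100, 150))

  # single event untouched
  expect_equal(clean_events(e[1, ]), e[1, ])
})

test_that("cleaning is idempotent and conserves dwell on fuzzed streams", {
  set.seed(61)
  for (i in 1:30) {
    ev <- random_events(sample(1:12, 1))
    cl <- clean_events(ev)
    expect_equal(clean_events(cl), cl) # idempotence
    expect_lte(nrow(cl), nrow(ev))
    expect_equal(sum(cl$dwell_ms), sum(ev$dwell_ms), tolerance = 1e-9)
    # consecutive cleaned events never share an ROI
    if (nrow(cl) > 1L) {
      expect_true(all(cl$roi[-1] != cl$roi[-nrow(cl)]))
    }
  }
})

test_that("blink insertion round-trips through cleaning", {
  set.seed(62)
  ev <- clean_events(random_events(8))
  blinked <- insert_blinks(ev, blink_ms = 80, min_dwell_ms = 150)
  expect_gte(nrow(blinked), nrow(ev))
  rec <- clean_events(blinked)
  expect_identical(rec$roi, ev$roi)
  expect_equal(rec$onset_ms, ev$onset_ms)
  expect_equal(rec$offset_ms, ev$offset_ms)
})

test_that("trials with no on-ROI gaze are excluded and counted", {
  trials <- make_trials(a1 = rep("A", 4), s2 = rep("blue", 4),
                        a2 = rep(0, 4), reward = rep(0, 4))
  ev <- rbind(random_events(2, trial = 1L), random_events(1, trial = 3L))
  flags <- exclude_trials(clean_events(ev), trials)
  expect_identical(flags$kept, c(TRUE, FALSE, TRUE, FALSE))
  excl <- attr(flags, "exclusions")
  expect_identical(excl$n_excluded, 2L)
})

test_that("per-trial gaze statistics follow the worked example", {
  # events A(200 ms), B(300 ms), A(150 ms); A on the left
  ev <- data.frame(subject_id = 1L, trial = 1L,
                   roi = c("left_symbol", "right_symbol", "left_symbol"),
                   onset_ms = c(0, 250, 600),
                   offset_ms = c(200, 550, 750),
                   dwell_ms = c(200, 300, 150))
  sm <- data.frame(subject_id = 1L, trial = 1L, left_symbol = "A")
  st <- gaze_statistics(ev, sm)
  expect_identical(st$n_gazes, 3L)
  expect_identical(st$first_symbol, "A")
  expect_identical(st$last_symbol, "A")
  expect_equal(st$dwell_A, 350)
  expect_equal(st$dwell_B, 300)
  expect_equal(st$dwell_advantage_last, 50)
  expect_identical(st$n_middle, 1L)
  expect_equal(st$middle_dwell_mean, 300)
  expect_identical(st$n_symbols_viewed, 2L)

  md <- middle_gaze_dwells(ev, sm)
  expect_equal(md$dwell_ms, 300)
  expect_identical(md$symbol, "B")

  # single gaze: first == last, no middle gazes
  st1 <- gaze_statistics(ev[1, ], sm)
  expect_identical(st1$first_symbol, st1$last_symbol)
  expect_identical(st1$n_middle, 0L)
  expect_identical(st1$n_symbols_viewed, 1L)

  # two equal dwells: zero dwell advantage
  ev2 <- ev[1:2, ]
  ev2$dwell_ms <- c(300, 300)
  expect_equal(gaze_statistics(ev2, sm)$dwell_advantage_last, 0)

  # an intervening bar gaze keeps symbol gazes separate
  ev3 <- ev
  ev3$roi[2] <- "left_bar"
  st3 <- gaze_statistics(ev3, sm)
  expect_identical(st3$n_gazes, 2L)
})

test_that("bar gaze share is the bar fraction of on-ROI dwell", {
  ev <- data.frame(subject_id = 1L, trial = c(1L, 1L, 2L, 3L),
                   roi = c("left_bar", "left_symbol", "right_bar",
                           "right_symbol"),
                   onset_ms = c(0, 400, 0, 0),
                   offset_ms = c(300, 1100, 500, 200),
                   dwell_ms = c(300, 700, 500, 200))
  bs <- bar_gaze_share(ev)
  expect_equal(bs$bar_share[bs$trial == 1L], 0.3)
  expect_equal(bs$bar_share[bs$trial == 2L], 1)
  expect_equal(bs$bar_share[bs$trial == 3L], 0)
  subj <- bar_gaze_share(ev, by = "subject")
  expect_equal(subj$bar_share, 800 / 1700)
})
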