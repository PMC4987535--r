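#' Screen and region-of-interest geometry
#'
#' Describes the stimulus layout used to map gaze coordinates to regions
#' of interest (ROIs). Defaults: 1920 x 1080 screen; 400 x 290 px symbol
#' boxes vertically centred at 33% of screen height, 460 px apart
#' edge-to-edge, each surrounded by a 50 px ROI margin; colour-bar ROIs
#' of the same size centred at 80% of screen height below each symbol.
#' The two symbol ROIs never overlap (their inner edges remain 360 px
#' apart under the defaults). All values are configurable; viewing
#' distance is metadata only.
#'
#' @param screen_w,screen_h Screen resolution in pixels.
#' @param symbol_w,symbol_h Symbol box size in pixels.
#' @param margin ROI margin around the symbol box, pixels.
#' @param symbol_y_frac Vertical centre of the symbols as a fraction of
#'   screen height from the top.
#' @param bar_y_frac Vertical centre of the bars as a fraction of screen
#'   height from the top.
#' @param symbol_gap Horizontal edge-to-edge distance between the two
#'   symbol boxes, pixels.
#' @param viewing_distance_cm Metadata only.
#' @return An object of class `screen_geometry`; `$rois` is a
#'   `data.frame(roi, x0, x1, y0, y1)` of ROI rectangles.
#' @export
screen_geometry <- function(screen_w = 1920, screen_h = 1080,
                            symbol_w = 400, symbol_h = 290, margin = 50,
                            symbol_y_frac = 0.33, bar_y_frac = 0.80,
                            symbol_gap = 460, viewing_distance_cm = 65) {
  half_w <- symbol_w / 2 + margin
  half_h <- symbol_h / 2 + margin
  offset <- (symbol_gap + symbol_w) / 2 # symbol centre offset from midline
  cx <- c(left = screen_w / 2 - offset, right = screen_w / 2 + offset)
  cy_sym <- symbol_y_frac * screen_h
  cy_bar <- bar_y_frac * screen_h
  rois <- data.frame(
    roi = c("left_symbol", "right_symbol", "left_bar", "right_bar"),
    x0 = c(cx - half_w, cx - half_w),
    x1 = c(cx + half_w, cx + half_w),
    y0 = c(rep(cy_sym - half_h, 2), rep(cy_bar - half_h, 2)),
    y1 = c(rep(cy_sym + half_h, 2), rep(cy_bar + half_h, 2)),
    stringsAsFactors = FALSE
  )
  if (rois$x1[1] >= rois$x0[2]) stop("symbol ROIs overlap; widen symbol_gap")
  structure(list(screen_w = screen_w, screen_h = screen_h,
                 symbol_w = symbol_w, symbol_h = symbol_h, margin = margin,
                 symbol_y_frac = symbol_y_frac, bar_y_frac = bar_y_frac,
                 symbol_gap = symbol_gap,
                 viewing_distance_cm = viewing_distance_cm, rois = rois),
            class = "screen_geometry")
}

#' Assign gaze samples to regions of interest
#'
#' Rectangle-membership test of gaze coordinates against the four ROIs
#' (symbol boxes plus margin, and bar boxes). Samples outside every ROI -
#' including the central fixation point - and samples off-screen return
#' `NA`.
#'
#' @param x,y Gaze coordinates in pixels (vectors).
#' @param geometry A [screen_geometry()].
#' @return Character vector of ROI names or `NA`.
#' @export
assign_roi <- function(x, y, geometry = screen_geometry()) {
  out <- rep(NA_character_, length(x))
  on_screen <- x >= 0 & x <= geometry$screen_w &
    y >= 0 & y <= geometry$screen_h & !is.na(x) & !is.na(y)
  r <- geometry$rois
  for (i in seq_len(nrow(r))) {
    hit <- on_screen & x >= r$x0[i] & x <= r$x1[i] &
      y >= r$y0[i] & y <= r$y1[i]
    out[hit] <- r$roi[i]
  }
  out
}

# Key columns identifying a trial within a gaze table; `condition` is
# included when present so that study-level tables (two conditions with
# repeating trial numbers) group correctly.
gaze_keys <- function(df) {
  intersect(c("subject_id", "condition", "trial"), names(df))
}

split_trials <- function(df) {
  split(df, df[gaze_keys(df)], drop = TRUE)
}

#' Run-length encode gaze samples into raw gaze events
#'
#' Maximal runs of consecutive samples in the same ROI become events;
#' runs outside all ROIs become gaps (no event). Event offsets extend one
#' sampling interval past the last sample, so 100 consecutive samples at
#' 1000 Hz yield a 100 ms dwell.
#'
#' @param samples `data.frame(subject_id, trial, t_ms, x_px, y_px)`,
#'   time-ordered within trial.
#' @param geometry A [screen_geometry()].
#' @return `data.frame(subject_id, trial, roi, onset_ms, offset_ms,
#'   dwell_ms)`.
#' @export
samples_to_events <- function(samples, geometry = screen_geometry()) {
  empty <- data.frame(subject_id = integer(0), trial = integer(0),
                      roi = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), dwell_ms = numeric(0))
  if (nrow(samples) == 0L) return(empty)
  rows <- lapply(split_trials(samples), function(df) {
    df <- df[order(df$t_ms), ]
    if (is.unsorted(df$t_ms)) stop("sample times must be non-decreasing")
    lab <- assign_roi(df$x_px, df$y_px, geometry)
    lab[is.na(lab)] <- "none"
    runs <- rle(lab)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    dt <- if (nrow(df) > 1L) median(diff(df$t_ms)) else 1
    keep <- runs$values != "none"
    if (!any(keep)) return(NULL)
    cbind(df[rep(1L, sum(keep)), gaze_keys(df), drop = FALSE],
          data.frame(roi = runs$values[keep],
                     onset_ms = df$t_ms[starts[keep]],
                     offset_ms = df$t_ms[ends[keep]] + dt,
                     dwell_ms = df$t_ms[ends[keep]] + dt -
                       df$t_ms[starts[keep]],
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) empty else out
}

#' Clean gaze events: merge blink-split gazes
#'
#' Gaps between two events on the *same* ROI are interpreted as blinks or
#' tracker dropouts and the two events are merged into one gaze; gaps
#' between events on *different* ROIs are simply discarded (the events
#' stay separate). By default the merged dwell excludes the gap (a blink
#' adds no evidence); with `gap_inclusive = TRUE` it is the full
#' onset-to-offset span. Cleaning is idempotent and never increases the
#' number of events or the total dwell.
#'
#' @param events Gaze-event table with `subject_id, trial, roi, onset_ms,
#'   offset_ms` (and optionally `dwell_ms`), time-ordered and
#'   non-overlapping within trial.
#' @param gap_inclusive Count gap time inside merged dwells.
#' @return Cleaned event table; consecutive events within a trial never
#'   share an ROI.
#' @export
clean_events <- function(events, gap_inclusive = FALSE) {
  if (nrow(events) == 0L) return(events)
  if (is.null(events$dwell_ms)) {
    events$dwell_ms <- events$offset_ms - events$onset_ms
  }
  rows <- lapply(split_trials(events), function(df) {
    df <- df[order(df$onset_ms), ]
    out <- df[0, ]
    for (i in seq_len(nrow(df))) {
      n_out <- nrow(out)
      if (n_out > 0L && out$roi[n_out] == df$roi[i]) {
        out$offset_ms[n_out] <- df$offset_ms[i]
        out$dwell_ms[n_out] <- if (gap_inclusive) {
          out$offset_ms[n_out] - out$onset_ms[n_out]
        } else {
          out$dwell_ms[n_out] + df$dwell_ms[i]
        }
      } else {
        out <- rbind(out, df[i, ])
      }
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Flag trials with no on-ROI gaze
#'
#' Trials without a single cleaned gaze event are excluded from all gaze
#' analyses. The full trial roster comes from the trial table, so trials
#' whose samples never hit an ROI are counted.
#'
#' @param events Cleaned gaze events.
#' @param trials Trial table giving the roster of
#'   `(subject_id, trial)` pairs.
#' @return `data.frame(subject_id, trial, n_events, kept)`; the attribute
#'   `exclusions` tabulates excluded-trial counts per subject.
#' @export
exclude_trials <- function(events, trials) {
  keys <- intersect(gaze_keys(trials), gaze_keys(events))
  if (length(keys) == 0L) keys <- gaze_keys(trials)
  roster <- unique(trials[, keys, drop = FALSE])
  if (nrow(events) > 0L) {
    counts <- aggregate(list(n_events = events$onset_ms),
                        by = events[, keys, drop = FALSE], FUN = length)
  } else {
    counts <- cbind(roster[0, , drop = FALSE], n_events = integer(0))
  }
  out <- merge(roster, counts, by = keys, all.x = TRUE)
  out$n_events[is.na(out$n_events)] <- 0L
  out$kept <- out$n_events > 0L
  out <- out[order(out$subject_id, out$trial), ]
  excl <- aggregate(list(n_excluded = !out$kept),
                    by = list(subject_id = out$subject_id), FUN = sum)
  attr(out, "exclusions") <- excl
  rownames(out) <- NULL
  out
}

# Map side-coded symbol ROIs to symbol identities using the per-trial
# left-symbol assignment.
symbol_of_roi <- function(roi, left_symbol) {
  side_left <- roi == "left_symbol" | roi == "left_bar"
  ifelse(side_left, left_symbol,
         ifelse(left_symbol == "A", "B", "A"))
}

#' Per-trial gaze statistics
#'
#' Computes, for every kept trial, the statistics used in the gaze
#' analyses: number of symbol gazes, first- and last-gaze symbol
#' identity, per-symbol total dwell, the last gaze's own dwell, the
#' dwell-time advantage of the last-seen symbol (its total dwell minus
#' the other symbol's), the number of middle gazes (neither first nor
#' last; only trials with >= 3 gazes have any) and their mean dwell, and
#' the number of distinct symbols viewed. Bar gazes are ignored here (see
#' [bar_gaze_share()]) but do not merge the symbol gazes they separate.
#'
#' @param events Cleaned gaze events.
#' @param side_map `data.frame(subject_id, trial, left_symbol)` giving
#'   which symbol was displayed on the left on each trial.
#' @return One row per trial present in `events` that has at least one
#'   symbol gaze.
#' @export
gaze_statistics <- function(events, side_map) {
  ev <- events[events$roi %in% c("left_symbol", "right_symbol"), ]
  if (nrow(ev) == 0L) {
    return(data.frame(subject_id = integer(0), trial = integer(0),
                      n_gazes = integer(0), first_symbol = character(0),
                      last_symbol = character(0), dwell_A = numeric(0),
                      dwell_B = numeric(0), last_dwell_ms = numeric(0),
                      dwell_advantage_last = numeric(0),
                      n_middle = integer(0), middle_dwell_mean = numeric(0),
                      n_symbols_viewed = integer(0)))
  }
  by_keys <- intersect(gaze_keys(ev), gaze_keys(side_map))
  ev <- merge(ev, side_map, by = by_keys)
  ev$symbol <- symbol_of_roi(ev$roi, ev$left_symbol)
  rows <- lapply(split_trials(ev), function(df) {
    df <- df[order(df$onset_ms), ]
    n <- nrow(df)
    dw_A <- sum(df$dwell_ms[df$symbol == "A"])
    dw_B <- sum(df$dwell_ms[df$symbol == "B"])
    last_sym <- df$symbol[n]
    mid <- if (n >= 3L) df$dwell_ms[2:(n - 1L)] else numeric(0)
    cbind(df[1L, gaze_keys(df), drop = FALSE], data.frame(
      n_gazes = n, first_symbol = df$symbol[1L], last_symbol = last_sym,
      dwell_A = dw_A, dwell_B = dw_B, last_dwell_ms = df$dwell_ms[n],
      dwell_advantage_last = if (last_sym == "A") dw_A - dw_B else dw_B - dw_A,
      n_middle = length(mid),
      middle_dwell_mean = if (length(mid)) mean(mid) else NA_real_,
      n_symbols_viewed = length(unique(df$symbol)),
      stringsAsFactors = FALSE
    ))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$subject_id, out$trial), ]
}

#' Middle-gaze dwells in long format
#'
#' One row per middle gaze (neither first nor last symbol gaze of its
#' trial; trials need >= 3 gazes to contribute), for dwell-time
#' regressions against choice difficulty or looked-at value.
#'
#' @inheritParams gaze_statistics
#' @return `data.frame(subject_id, trial, gaze_index, symbol, dwell_ms)`.
#' @export
middle_gaze_dwells <- function(events, side_map) {
  ev <- events[events$roi %in% c("left_symbol", "right_symbol"), ]
  by_keys <- intersect(gaze_keys(ev), gaze_keys(side_map))
  ev <- merge(ev, side_map, by = by_keys)
  ev$symbol <- symbol_of_roi(ev$roi, ev$left_symbol)
  rows <- lapply(split_trials(ev), function(df) {
    df <- df[order(df$onset_ms), ]
    n <- nrow(df)
    if (n < 3L) return(NULL)
    idx <- 2:(n - 1L)
    cbind(df[rep(1L, length(idx)), gaze_keys(df), drop = FALSE],
          data.frame(gaze_index = idx, symbol = df$symbol[idx],
                     dwell_ms = df$dwell_ms[idx], stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(subject_id = integer(0), trial = integer(0),
                      gaze_index = integer(0), symbol = character(0),
                      dwell_ms = numeric(0))
  }
  out
}

#' Share of dwell time on the transition-cue bars
#'
#' For cued-condition trials: dwell on the bar ROIs divided by total
#' on-ROI dwell (bars plus symbols). Trials with zero total dwell yield
#' `NA` (flagged missing).
#'
#' @param events Cleaned condition-2 gaze events.
#' @param by `"trial"` for one share per trial, `"subject"` for the
#'   per-subject share pooled over trials.
#' @return `data.frame` with `bar_share` per trial or per subject.
#' @export
bar_gaze_share <- function(events, by = c("trial", "subject")) {
  by <- match.arg(by)
  is_bar <- events$roi %in% c("left_bar", "right_bar")
  keys <- if (by == "trial") {
    events[, gaze_keys(events), drop = FALSE]
  } else {
    events[, intersect(c("subject_id", "condition"), names(events)),
           drop = FALSE]
  }
  bar <- aggregate(list(bar_dwell = events$dwell_ms * is_bar),
                   by = keys, FUN = sum)
  tot <- aggregate(list(total_dwell = events$dwell_ms), by = keys,
                   FUN = sum)
  out <- merge(bar, tot)
  out$bar_share <- ifelse(out$total_dwell > 0,
                          out$bar_dwell / out$total_dwell, NA_real_)
  out
}

#' Split gaze events with artificial blink gaps
#'
#' Testing utility: splits each sufficiently long event into two events
#' on the same ROI separated by a gap, emulating a blink or tracker
#' dropout. [clean_events()] merges the pieces back into a single event
#' with the original onset/offset span (the gap is excluded from dwell by
#' default).
#'
#' @param events Cleaned gaze events.
#' @param blink_ms Gap duration.
#' @param min_dwell_ms Only events at least this long are split.
#' @return Event table with blinks inserted.
#' @export
insert_blinks <- function(events, blink_ms = 80, min_dwell_ms = 200) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$offset_ms - e$onset_ms < min_dwell_ms + blink_ms) return(e)
    mid <- (e$onset_ms + e$offset_ms) / 2
    e1 <- e2 <- e
    e1$offset_ms <- mid - blink_ms / 2
    e1$dwell_ms <- e1$offset_ms - e1$onset_ms
    e2$onset_ms <- mid + blink_ms / 2
    e2$dwell_ms <- e2$offset_ms - e2$onset_ms
    rbind(e1, e2)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
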