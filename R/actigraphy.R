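# Physical activity, rest-interval and sleep estimation from minute-epoch
# actigraphy counts.

#' Epoch-level mobility flags
#'
#' An epoch is mobile when it records 4 or more activity counts per
#' minute and the device was worn. Off-wrist epochs are never mobile and
#' are excluded from downstream denominators.
#'
#' @param series An [epoch_series()].
#' @return Logical vector, one flag per epoch.
#' @export
score_mobile <- function(series) {
  if (length(series) == 0L) stop("empty epoch series", call. = FALSE)
  series$counts >= MOBILE_THRESHOLD & !series$off_wrist
}

#' Activity summary over a scope
#'
#' Average counts per minute and percentage of mobile time over a
#' selection of epochs (whole week, active period, or rest period).
#' Off-wrist epochs are removed from both numerator and denominator.
#'
#' @param series An [epoch_series()].
#' @param scope_mask Logical epoch selector; `NULL` selects all epochs.
#' @param scope Label stored with the summary.
#' @return List `avg_cpm`, `pct_mobile`, `n_epochs`, `scope`.
#' @export
summarize_activity <- function(series, scope_mask = NULL,
                               scope = "whole_week") {
  if (is.null(scope_mask)) scope_mask <- rep(TRUE, length(series))
  sel <- scope_mask & valid_epochs(series)
  if (!any(sel)) stop("no valid epochs in scope", call. = FALSE)
  mobile <- score_mobile(series)
  list(avg_cpm = mean(series$counts[sel]),
       pct_mobile = 100 * sum(mobile[sel]) / sum(sel),
       n_epochs = sum(sel), scope = scope)
}

#' Detect the nightly major rest interval
#'
#' For each complete noon-to-noon day, finds the longest block of epochs
#' whose centred 11-epoch rolling median of counts falls below
#' `frac_of_daily_median` times that day's median count, and keeps it if
#' it lasts at least `min_duration_min`. Brief above-threshold
#' interruptions up to `max_gap_min` (nocturnal arousals) are bridged
#' rather than allowed to split the night. Noon-to-noon attribution
#' avoids splitting nocturnal sleep across days. When `annotated`
#' intervals are supplied they bypass detection and are returned
#' verbatim.
#'
#' @param series An [epoch_series()] spanning at least 24 h.
#' @param frac_of_daily_median Relative threshold (default 0.2).
#' @param min_duration_min Minimum rest duration in minutes (default 240).
#' @param max_gap_min Longest above-threshold interruption bridged when
#'   assembling the rest block (default 20 minutes).
#' @param annotated Optional data.frame with POSIXct `start`, `end`
#'   columns of manually annotated rest intervals.
#' @return data.frame with `start`, `end` (POSIXct) and `source`
#'   (`"auto"` or `"annotated"`); days without a qualifying block are
#'   omitted with a warning.
#' @export
detect_rest_intervals <- function(series, frac_of_daily_median = 0.2,
                                  min_duration_min = 240,
                                  max_gap_min = 20,
                                  annotated = NULL) {
  if (!is.null(annotated)) {
    stopifnot(all(c("start", "end") %in% names(annotated)),
              all(annotated$start < annotated$end))
    return(data.frame(start = annotated$start, end = annotated$end,
                      source = "annotated"))
  }
  if (length(series) * series$epoch_s < 86400)
    stop("need at least 24 h of data", call. = FALSE)
  tt <- as.numeric(series$time)
  epoch_s <- series$epoch_s
  # complete noon-to-noon windows
  first_noon <- (floor((tt[1] - 43200) / 86400) + 1) * 86400 + 43200
  out <- list()
  w0 <- first_noon
  while (w0 + 86400 <= tt[length(tt)] + epoch_s) {
    idx <- which(tt >= w0 & tt < w0 + 86400)
    day_lab <- format(as.POSIXct(w0, origin = "1970-01-01", tz = "UTC"),
                      "%Y-%m-%d")
    v <- series$counts[idx]
    rm_ <- stats::runmed(v, 11)
    thr <- frac_of_daily_median * stats::median(v)
    below <- rm_ < thr
    # bridge short above-threshold interruptions (arousals)
    r <- rle(below)
    gap_epochs <- max_gap_min * 60 / epoch_s
    interior <- seq_along(r$values) > 1 &
      seq_along(r$values) < length(r$values)
    r$values[!r$values & r$lengths <= gap_epochs & interior] <- TRUE
    below <- inverse.rle(r)
    r <- rle(below)
    if (any(r$values)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]
      len_min <- r$lengths[best] * epoch_s / 60
      if (len_min >= min_duration_min) {
        i0 <- idx[starts[best]]
        i1 <- idx[ends[best]]
        out[[length(out) + 1L]] <- data.frame(
          start = series$time[i0],
          end = series$time[i1] + epoch_s,
          source = "auto")
      } else {
        warning("no qualifying rest block on ", day_lab, call. = FALSE)
      }
    } else {
      warning("no qualifying rest block on ", day_lab, call. = FALSE)
    }
    w0 <- w0 + 86400
  }
  if (length(out) == 0L)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      source = character()))
  do.call(rbind, out)
}

# Oakley-style weighted epoch score:
# D_i = 0.04 c_{i-2} + 0.2 c_{i-1} + c_i + 0.2 c_{i+1} + 0.04 c_{i+2}
# (series edges padded with zero counts).
oakley_scores <- function(counts) {
  n <- length(counts)
  pad <- c(0, 0, counts, 0, 0)
  0.04 * pad[seq_len(n)] + 0.2 * pad[seq_len(n) + 1L] + pad[seq_len(n) + 2L] +
    0.2 * pad[seq_len(n) + 3L] + 0.04 * pad[seq_len(n) + 4L]
}

#' Score sleep within a rest interval
#'
#' Implements a weighted-window actigraphy sleep scorer: each epoch's
#' score is a weighted sum of its count and its four neighbours
#' (`0.04, 0.2, 1, 0.2, 0.04`), and the epoch is scored sleep when the
#' score falls below `threshold` (medium sensitivity default 40). Sleep
#' onset is the start of the first run of at least `min_run` consecutive
#' sleep epochs inside the rest interval, offset the end of the last such
#' run. Sleep duration counts sleep epochs between onset and offset;
#' efficiency is sleep duration relative to the rest-interval duration
#' (time-in-bed analogue); the midpoint is the clock time halfway between
#' onset and offset.
#'
#' @param series An [epoch_series()].
#' @param interval One rest interval (list/row with POSIXct `start`,
#'   `end` within the series span).
#' @param threshold Wake threshold on the weighted score (default 40).
#' @param min_run Consecutive sleep epochs defining onset/offset
#'   (default 10).
#' @return List `onset`, `offset` (POSIXct), `sleep_duration_min`,
#'   `efficiency_pct`, `midpoint_dec_h`, `valid`. When no qualifying
#'   sleep run exists, `valid = FALSE` and the estimates are `NA`.
#' @export
score_sleep <- function(series, interval, threshold = 40, min_run = 10) {
  tt <- as.numeric(series$time)
  t0 <- as.numeric(interval$start)
  t1 <- as.numeric(interval$end)
  if (t0 < tt[1] || t1 > tt[length(tt)] + series$epoch_s)
    stop("interval outside series span", call. = FALSE)
  D <- oakley_scores(series$counts)
  idx <- which(tt >= t0 & tt < t1)
  asleep <- D[idx] < threshold
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  invalid <- list(onset = as.POSIXct(NA), offset = as.POSIXct(NA),
                  sleep_duration_min = NA_real_, efficiency_pct = NA_real_,
                  midpoint_dec_h = NA_real_, valid = FALSE)
  if (length(runs) == 0L) return(invalid)
  i_on <- idx[starts[runs[1]]]
  i_off <- idx[ends[runs[length(runs)]]]
  onset <- series$time[i_on]
  offset <- series$time[i_off] + series$epoch_s
  span <- idx[idx >= i_on & idx <= i_off]
  sleep_min <- sum(D[span] < threshold) * series$epoch_s / 60
  list(onset = onset, offset = offset,
       sleep_duration_min = sleep_min,
       efficiency_pct = 100 * sleep_min / ((t1 - t0) / 60),
       midpoint_dec_h = clock_hours(onset +
                                      as.numeric(offset - onset,
                                                 units = "secs") / 2),
       valid = TRUE)
}

#' Night-to-night intra-individual variability of sleep
#'
#' Sample SD across nights of (a) sleep duration, rescaled from minutes
#' to fractions of a day so the index is unitless, and (b) the sleep
#' midpoint in decimal hours. Midpoints are circular quantities and are
#' unwrapped around the subject's circular mean midpoint before taking
#' the SD, so midnight-straddling nights are handled correctly.
#'
#' @param nightly List of valid [score_sleep()] results (>= 2 nights).
#' @return List `iiv_duration` (unitless), `iiv_midpoint` (decimal
#'   hours).
#' @export
sleep_iiv <- function(nightly) {
  nightly <- Filter(function(x) isTRUE(x$valid), nightly)
  if (length(nightly) < 2)
    stop("need at least 2 valid nights", call. = FALSE)
  dur <- vapply(nightly, `[[`, numeric(1), "sleep_duration_min") / 1440
  mid <- vapply(nightly, `[[`, numeric(1), "midpoint_dec_h")
  ang <- mid * 2 * pi / 24
  mu <- (atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)) %% 24
  dev <- ((mid - mu + 12) %% 24) - 12
  list(iiv_duration = stats::sd(dur), iiv_midpoint = stats::sd(dev))
}

#' Full actigraphy feature vector for one subject
#'
#' Computes the standard per-subject actigraphy battery: whole-week,
#' active-period and rest-period activity summaries; nightly sleep
#' estimates averaged across valid nights with their intra-individual
#' variabilities; and the cosinor plus nonparametric circadian measures.
#'
#' @param series An [epoch_series()].
#' @param rest_intervals Optional annotated rest intervals (see
#'   [detect_rest_intervals()]).
#' @param sleep_threshold,min_run Passed to [score_sleep()].
#' @param bin_min Bin width for the circadian measures.
#' @return Named numeric vector of 22 features.
#' @export
actigraphy_features <- function(series, rest_intervals = NULL,
                                sleep_threshold = 40, min_run = 10,
                                bin_min = 60) {
  intervals <- if (is.null(rest_intervals))
    detect_rest_intervals(series) else
    detect_rest_intervals(series, annotated = rest_intervals)
  tt <- as.numeric(series$time)
  rest_mask <- rep(FALSE, length(series))
  for (i in seq_len(nrow(intervals)))
    rest_mask <- rest_mask | (tt >= as.numeric(intervals$start[i]) &
                                tt < as.numeric(intervals$end[i]))
  whole <- summarize_activity(series)
  active <- summarize_activity(series, !rest_mask, "active")
  rest <- if (any(rest_mask))
    summarize_activity(series, rest_mask, "rest")
  else list(avg_cpm = NA_real_, pct_mobile = NA_real_)
  rest_dur <- if (nrow(intervals))
    mean(as.numeric(intervals$end - intervals$start, units = "mins"))
  else NA_real_

  nights <- lapply(seq_len(nrow(intervals)), function(i)
    score_sleep(series, intervals[i, ], sleep_threshold, min_run))
  nights <- Filter(function(x) isTRUE(x$valid), nights)
  sl <- function(f) if (length(nights))
    mean(vapply(nights, `[[`, numeric(1), f)) else NA_real_
  mid <- if (length(nights)) {
    m <- vapply(nights, `[[`, numeric(1), "midpoint_dec_h")
    ang <- m * 2 * pi / 24
    (atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)) %% 24
  } else NA_real_
  iiv <- if (length(nights) >= 2) sleep_iiv(nights)
  else list(iiv_duration = NA_real_, iiv_midpoint = NA_real_)

  circ <- circadian_measures(series, bin_min)
  c(cpm_week = whole$avg_cpm, pct_mobile_week = whole$pct_mobile,
    cpm_active = active$avg_cpm, pct_mobile_active = active$pct_mobile,
    cpm_rest = rest$avg_cpm, pct_mobile_rest = rest$pct_mobile,
    rest_duration_min = rest_dur,
    sleep_duration_min = sl("sleep_duration_min"),
    sleep_efficiency = sl("efficiency_pct"),
    sleep_midpoint = mid,
    iiv_sleep_duration = iiv$iiv_duration,
    iiv_sleep_midpoint = iiv$iiv_midpoint,
    circ)
}
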