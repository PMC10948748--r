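test_that("mobility threshold flags epochs at 4+ counts", {
  es <- make_series(c(0, 3, 4, 10))
  expect_equal(score_mobile(es), c(FALSE, FALSE, TRUE, TRUE))
  zero <- make_series(rep(0, 10))
  expect_true(all(!score_mobile(zero)))
  expect_equal(summarize_activity(zero)$pct_mobile, 0)
})

test_that("mobility flags match a per-epoch oracle, off-wrist excluded", {
  set.seed(10)
  for (rep in 1:5) {
    counts <- rpois(200, 6)
    off <- runif(200) < 0.2
    es <- make_series(counts, off_wrist = off)
    expect_identical(score_mobile(es), mobile_oracle(counts, off))
  }
})

test_that("activity summaries compute cpm and %mobile over the scope", {
  es <- make_series(c(10, 10, 0, 0))
  s <- summarize_activity(es)
  expect_equal(s$avg_cpm, 5)
  expect_equal(s$pct_mobile, 50)
  # rest-scope mask on a toy 2-night fixture, hand-recomputed
  es2 <- make_series(c(100, 100, 2, 2, 6, 100))
  mask <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  r <- summarize_activity(es2, mask, "rest")
  expect_equal(r$avg_cpm, mean(c(2, 2, 6)))
  expect_equal(r$pct_mobile, 100 * 1 / 3)
})

test_that("off-wrist epochs leave rates unchanged but shrink denominators", {
  counts <- rep(c(10, 0), 50)
  off <- rep(c(FALSE, TRUE), each = 50)   # uniform pattern in both halves
  es_all <- make_series(counts)
  es_half <- make_series(counts, off_wrist = off)
  expect_equal(summarize_activity(es_half)$pct_mobile,
               summarize_activity(es_all)$pct_mobile)
  expect_equal(summarize_activity(es_half)$n_epochs, 50)
})

test_that("rest-interval detection recovers a clean nightly rest window", {
  es <- square_day_series(8, rest_start = 23, rest_end = 31)
  ints <- detect_rest_intervals(es)
  expect_equal(nrow(ints), 7)
  on_h <- (as.numeric(ints$start) / 3600) %% 24
  off_h <- (as.numeric(ints$end) / 3600) %% 24
  expect_true(all(abs(on_h - 23) <= 0.25))
  expect_true(all(abs(off_h - 7) <= 0.25))
})

test_that("annotated rest intervals bypass detection verbatim", {
  es <- square_day_series(2)
  ann <- data.frame(start = T0 + 23 * 3600, end = T0 + 31 * 3600)
  ints <- detect_rest_intervals(es, annotated = ann)
  expect_equal(ints$source, "annotated")
  expect_equal(ints$start, ann$start)
  expect_equal(ints$end, ann$end)
})

test_that("constant activity yields no rest interval and a warning", {
  es <- make_series(rep(100, 2 * 1440))
  expect_warning(ints <- detect_rest_intervals(es), "no qualifying")
  expect_equal(nrow(ints), 0)
})

test_that("weighted sleep scoring handles the canonical cases", {
  # all-zero counts in a 23:00-07:00 interval: full sleep (surrounding
  # activity low enough not to bleed a weighted wake score across the
  # boundary: 0.24 * 100 = 24 < 40)
  es <- square_day_series(2, rest_start = 23, rest_end = 31, active = 100)
  interval <- list(start = T0 + 23 * 3600, end = T0 + 31 * 3600)
  sl <- score_sleep(es, interval)
  expect_equal(sl$onset, T0 + 23 * 3600)
  expect_equal(sl$offset, T0 + 31 * 3600)
  expect_equal(sl$efficiency_pct, 100)
  expect_equal(sl$midpoint_dec_h, 3)
  # onset 23:30 / offset 07:30 gives midpoint 3.5 decimal hours
  es2 <- square_day_series(2, rest_start = 23.5, rest_end = 31.5,
                           active = 100)
  sl2 <- score_sleep(es2, list(start = T0 + 22 * 3600,
                               end = T0 + 33 * 3600))
  expect_equal(sl2$midpoint_dec_h, 3.5)
})

test_that("an isolated count spike scores its epoch awake", {
  counts <- rep(0, 120)
  counts[60] <- 100
  es <- make_series(counts)
  sl <- score_sleep(es, list(start = T0, end = T0 + 120 * 60))
  # weighted score at the spike is 100 >= 40: one wake epoch inside span
  expect_equal(sl$sleep_duration_min, 119)
  # neighbours get 0.2 * 100 = 20 < 40 and stay asleep
  expect_equal(sl$onset, T0)
})

test_that("raising counts never converts wake epochs to sleep", {
  set.seed(11)
  counts <- rexp(480, 1 / 30)
  es1 <- make_series(counts)
  es2 <- make_series(counts * 3)
  iv <- list(start = T0, end = T0 + 480 * 60)
  n_sleep <- function(es) {
    sl <- score_sleep(es, iv, min_run = 1)
    if (!sl$valid) 0 else sl$sleep_duration_min
  }
  expect_lte(n_sleep(es2), n_sleep(es1))
})

test_that("nightly IIV uses circular midpoints and day-rescaled durations", {
  night <- function(mid, dur) list(midpoint_dec_h = mid,
                                   sleep_duration_min = dur, valid = TRUE)
  same <- list(night(3.5, 420), night(3.5, 420))
  expect_equal(sleep_iiv(same), list(iiv_duration = 0, iiv_midpoint = 0))
  # midnight-straddling midpoints are unwrapped before the SD
  wrap <- list(night(23.5, 420), night(0.5, 420))
  expect_equal(sleep_iiv(wrap)$iiv_midpoint, sd(c(-0.5, 0.5)),
               tolerance = 1e-10)
  expect_equal(sleep_iiv(wrap)$iiv_midpoint, 0.7071, tolerance = 1e-4)
  dur <- list(night(3, 420), night(3, 480))
  expect_equal(sleep_iiv(dur)$iiv_duration, sd(c(420, 480) / 1440),
               tolerance = 1e-10)
  expect_equal(sleep_iiv(dur)$iiv_duration, 0.0295, tolerance = 1e-2)
  expect_error(sleep_iiv(list(night(3, 420))), "2 valid nights")
})

test_that("feature battery returns the full named 22-measure vector", {
  set.seed(12)
  es <- generate_epochs(preset_profiles()$control)
  f <- suppressWarnings(actigraphy_features(es))
  expect_length(f, 22)
  expect_true(all(c("pct_mobile_week", "sleep_midpoint", "mesor",
                    "acrophase", "IS", "IV", "RA") %in% names(f)))
  expect_true(f[["RA"]] <= 1 && f[["RA"]] >= 0)
  expect_true(f[["pct_mobile_week"]] >= 0 && f[["pct_mobile_week"]] <= 100)
  expect_true(f[["sleep_efficiency"]] >= 0 &&
                f[["sleep_efficiency"]] <= 100)
  expect_true(f[["L5"]] <= f[["M10"]])
})
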