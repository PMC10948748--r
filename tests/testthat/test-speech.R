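test_that("pause detection on constructed tracks", {
  # 1 s voiced, 0.5 s silent, 1 s voiced: one pause, phonation 2 s
  tr <- make_track(list(TRUE, 1), list(FALSE, 0.5), list(TRUE, 1))
  ps <- detect_pauses(tr)
  expect_equal(nrow(ps$pauses), 1)
  expect_equal(ps$pauses$end_s - ps$pauses$start_s, 0.5,
               tolerance = 1e-9)
  expect_equal(ps$phonation_s, 2, tolerance = 1e-9)
  # continuous voicing: no pause
  tr2 <- make_track(list(TRUE, 3))
  expect_equal(nrow(detect_pauses(tr2)$pauses), 0)
  # sub-threshold 0.2-s gap is not a pause and counts as phonation
  tr3 <- make_track(list(TRUE, 1), list(FALSE, 0.2), list(TRUE, 1))
  ps3 <- detect_pauses(tr3)
  expect_equal(nrow(ps3$pauses), 0)
  expect_equal(ps3$phonation_s, 2.2, tolerance = 1e-9)
  # all-silent track is an error
  tr4 <- make_track(list(FALSE, 1))
  expect_error(detect_pauses(tr4), "silent")
})

test_that("leading/trailing silence is trimmed and does not change the
          articulation rate", {
  base <- make_track(list(TRUE, 1), list(FALSE, 0.5), list(TRUE, 1))
  padded <- make_track(list(FALSE, 0.8), list(TRUE, 1), list(FALSE, 0.5),
                       list(TRUE, 1), list(FALSE, 1.2))
  f1 <- segment_features(speech_segment(base, 10))
  f2 <- segment_features(speech_segment(padded, 10))
  expect_equal(f2[["artic_rate"]], f1[["artic_rate"]], tolerance = 1e-9)
  expect_equal(f1[["artic_rate"]], 10 / 2, tolerance = 1e-9)
})

test_that("segment features compute the six prosodic measures", {
  # pauses 0.5, 1.0, 1.5 s in a 10-s segment
  tr <- make_track(list(TRUE, 2), list(FALSE, 0.5), list(TRUE, 2),
                   list(FALSE, 1), list(TRUE, 1.5), list(FALSE, 1.5),
                   list(TRUE, 1.5))
  seg <- speech_segment(tr, syllable_count = 28)
  f <- segment_features(seg)
  expect_equal(f[["pause_mean"]], 1, tolerance = 1e-9)
  expect_equal(f[["pause_sd"]], 0.5, tolerance = 1e-9)
  expect_equal(f[["pause_rate"]], 3 / 10, tolerance = 1e-9)
  expect_equal(f[["artic_rate"]], 28 / 7, tolerance = 1e-9)
})

test_that("segments without pause or in noisy environments are excluded", {
  tr <- make_track(list(TRUE, 3))
  expect_null(segment_features(speech_segment(tr, 10)))
  tr2 <- make_track(list(TRUE, 1), list(FALSE, 0.5), list(TRUE, 1))
  expect_null(segment_features(speech_segment(tr2, 10,
                                              valid_environment = FALSE)))
})

test_that("F0 statistics use voiced frames only", {
  voiced <- c(rep(TRUE, 100), rep(FALSE, 50), rep(TRUE, 100))
  n <- length(voiced)
  f0 <- ifelse(voiced, 120, 0)
  tr <- frame_track((0:(n - 1)) * 0.01, f0,
                    ifelse(voiced, 70, 40), voiced)
  f <- segment_features(speech_segment(tr, 5))
  expect_equal(f[["f0_mean"]], 120)
  expect_equal(f[["f0_sd"]], 0)
  # appending unvoiced frames leaves the F0 statistics unchanged
  tr2 <- frame_track((0:(n + 99)) * 0.01, c(f0, rep(0, 100)),
                     c(ifelse(voiced, 70, 40), rep(40, 100)),
                     c(voiced, rep(FALSE, 100)))
  f2 <- segment_features(speech_segment(tr2, 5))
  expect_equal(f2[["f0_mean"]], f[["f0_mean"]])
  expect_equal(f2[["f0_sd"]], f[["f0_sd"]])
})

test_that("pause detection matches the brute-force run scan on random
          tracks", {
  set.seed(30)
  for (rep in 1:30) {
    nruns <- sample(3:9, 1)
    args <- lapply(seq_len(nruns), function(i)
      list(i %% 2 == 1, runif(1, 0.1, 1.2)))
    tr <- do.call(make_track, args)
    got <- detect_pauses(tr)
    want <- pause_oracle(tr)
    expect_equal(nrow(got$pauses), want$n)
    expect_equal(got$phonation_s, want$phonation_s, tolerance = 1e-9)
    if (want$n > 0) {
      expect_equal(got$pauses$start_s, want$pauses[, 1],
                   tolerance = 1e-9)
      expect_equal(got$pauses$end_s, want$pauses[, 2], tolerance = 1e-9)
    }
  }
})

test_that("subject profile averages across valid segments only", {
  tr <- make_track(list(TRUE, 2.5), list(FALSE, 0.5), list(TRUE, 2.5))
  s1 <- speech_segment(tr, 20)   # artic 20 / 5 = 4.0
  s2 <- speech_segment(tr, 22)   # artic 22 / 5 = 4.4
  noisy <- speech_segment(tr, 100, valid_environment = FALSE)
  nopause <- speech_segment(make_track(list(TRUE, 3)), 10)
  prof <- subject_speech_profile(list(s1, noisy, s2, nopause), "F")
  expect_equal(prof$n_segments_used, 2)
  expect_equal(unname(prof$features[["artic_rate"]]), 4.2,
               tolerance = 1e-9)
  # single valid segment: profile equals that segment
  p1 <- subject_speech_profile(list(s1), "M")
  expect_equal(p1$features, segment_features(s1), tolerance = 1e-12)
  # no valid segment: subject missing for the voice modality
  expect_null(subject_speech_profile(list(noisy, nopause), "F"))
})

test_that("generated speech recovers the articulation-rate preset", {
  set.seed(31)
  p <- group_profile(artic_rate_sps = 3.97, quiet_prob = 1,
                     completion_prob = 1)
  segs <- lapply(1:30, function(i) digimood:::generate_speech_segment(p, "F", i))
  prof <- subject_speech_profile(segs, "F")
  expect_equal(unname(prof$features[["artic_rate"]]), 3.97,
               tolerance = 0.1)
})
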