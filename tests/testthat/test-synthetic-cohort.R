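test_that("cohort bookkeeping: sizes, groups and remission labels", {
  cfg <- cohort_config(n_control = 2, n_mdd = 2, seed = 7)
  co <- generate_cohort(cfg)
  expect_length(co, 4)
  subj <- cohort_subjects(co)
  expect_equal(sum(subj$group == "mdd"), 2)
  # remission is n/a exactly for controls, and labels follow the
  # Hamilton cutoff rule
  expect_true(all((subj$remission == "n/a") == (subj$group == "control")))
  expect_true(all(subj$hds17[subj$remission == "remitted"] <= 7))
  expect_true(all(subj$hds17[subj$remission == "non_remitted"] > 7))
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg1 <- cohort_config(n_control = 3, n_mdd = 3, seed = 11)
  cfg2 <- cohort_config(n_control = 3, n_mdd = 3, seed = 11)
  co1 <- generate_cohort(cfg1)
  co2 <- generate_cohort(cfg2)
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))
  co3 <- generate_cohort(cohort_config(n_control = 3, n_mdd = 3,
                                       seed = 12))
  expect_false(identical(serialize(co1, NULL), serialize(co3, NULL)))
})

test_that("config validation rejects invalid fields", {
  expect_error(cohort_config(0, 5), "n_control")
  expect_error(cohort_config(2, 2, days = 0), "days")
  expect_error(group_profile(mobile_prob_active = 1.2), "probabilit")
  expect_error(group_profile(amplitude = 200, mesor = 100), "amplitude")
  expect_error(group_profile(acrophase_h = 24), "acrophase")
})

test_that("degenerate profile with full mobility gives 100% mobile time", {
  p <- group_profile(amplitude = 0, mobile_prob_active = 1,
                     mobile_prob_rest = 1, noise_sd = 10)
  set.seed(1)
  es <- generate_epochs(p, days = 2)
  s <- summarize_activity(es)
  expect_equal(s$pct_mobile, 100)
})

test_that("jitter-free noise-free nights give exactly zero midpoint IIV", {
  p <- group_profile(night_jitter_sd_h = 0, duration_jitter_sd_min = 0,
                     noise_sd = 0, immobile_mean = 0,
                     mobile_prob_active = 1, mobile_prob_rest = 0)
  set.seed(2)
  es <- generate_epochs(p, days = 8)
  ints <- detect_rest_intervals(es)
  nights <- lapply(seq_len(nrow(ints)), function(i)
    score_sleep(es, ints[i, ]))
  iiv <- sleep_iiv(nights)
  expect_identical(iiv$iiv_midpoint, 0)
  expect_identical(iiv$iiv_duration, 0)
})

test_that("diary schedule has days x slots entries, all completed when
          completion_prob is 1", {
  p <- group_profile(completion_prob = 1)
  cfg <- cohort_config(1, 1, seed = 1)
  set.seed(3)
  app <- generate_app_streams(p, cfg)
  expect_equal(nrow(app$diary), 28)
  expect_equal(sum(app$diary$completed), 28)
  expect_true(all(!is.na(app$diary$happiness)))
  expect_true(all(app$diary$happiness >= 0 & app$diary$happiness <= 10))
})

test_that("a zero action-unit rate yields zero presence in every video", {
  rates <- c(AU1 = 0.3, AU4 = 0.3, AU6 = 0.3, AU12 = 0, AU15 = 0.3)
  p <- group_profile(au_rates = rates, completion_prob = 1,
                     mask_prob = 0)
  set.seed(4)
  app <- generate_app_streams(p, cohort_config(1, 1, seed = 1))
  expect_true(all(app$au_frames$AU12 == 0))
  prof <- subject_au_profile(app$au_frames)
  expect_equal(unname(prof$proportions[["AU12"]]), 0)
})

test_that("token category frequencies follow the generator probabilities", {
  p <- group_profile(p_negemo = 0.0092, p_selfref = 0.018,
                     completion_prob = 1, tokens_per_entry = 80)
  set.seed(5)
  app <- generate_app_streams(p, cohort_config(1, 1, seed = 1))
  n <- nrow(app$tokens)
  expect_gt(n, 2000)
  props <- category_proportions(app$tokens$token, builtin_lexicon())
  se <- 100 * sqrt(0.0092 * (1 - 0.0092) / n)
  expect_lt(abs(props[["negative_emotion"]] - 0.92), 3 * se)
})

test_that("simulated group contrasts have the documented directions", {
  # stochastic check on a 100-per-arm cohort with the shipped presets
  fe <- cached_features(100, 2024)
  grp <- fe$subjects$group
  acti <- fe$actigraphy
  app <- fe$app
  dm <- function(df, col) mean(df[[col]][grp == "mdd"], na.rm = TRUE) -
    mean(df[[col]][grp == "control"], na.rm = TRUE)
  expect_lt(dm(acti, "pct_mobile_week"), 0)   # less mobile time
  expect_gt(dm(acti, "acrophase"), 0)         # delayed acrophase
  expect_gt(dm(acti, "sleep_midpoint"), 0)    # delayed sleep midpoint
  expect_gt(dm(app, "AU4"), 0)                # more brow lowering
  expect_lt(dm(app, "AU12"), 0)               # less lip-corner pulling
  expect_lt(dm(app, "artic_rate"), 0)         # slower articulation
  expect_gt(dm(app, "pause_sd"), 0)           # more variable pauses
  expect_gt(dm(app, "selfref_pct"), 0)        # more self-reference
  expect_gt(dm(app, "negemo_pct"), 0)         # more negative emotion
  expect_lt(dm(app, "happiness"), 0)          # lower happiness
})

test_that("fitted acrophase contrast between arms tracks generator truth", {
  fe <- cached_features(100, 2024)
  keep <- fe$subjects$remission %in% c("n/a", "non_remitted")
  grp <- fe$subjects$group[keep]
  acro <- fe$actigraphy$acrophase[keep]
  diff <- mean(acro[grp == "mdd"]) - mean(acro[grp == "control"])
  # generator truth is +0.57 h; whole-series fits carry a small shared
  # rest-gating bias, so allow a generous stochastic band
  expect_gt(diff, 0.25)
  expect_lt(diff, 0.95)
})

test_that("cohort round-trips through the on-disk plain-text format", {
  cfg <- cohort_config(2, 2, seed = 21)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir, cfg)
  back <- read_cohort_dir(dir)
  expect_equal(names(back), names(co))
  expect_equal(back[["S001"]]$epochs$counts, co[["S001"]]$epochs$counts)
  expect_equal(back[["S003"]]$group, co[["S003"]]$group)
  expect_equal(nrow(back[["S002"]]$diary), nrow(co[["S002"]]$diary))
  # extracted features agree between the in-memory and re-read cohorts
  f1 <- suppressWarnings(extract_features(co))
  f2 <- suppressWarnings(extract_features(back))
  expect_equal(f2$app$selfref_pct, f1$app$selfref_pct, tolerance = 1e-10)
  expect_equal(f2$actigraphy$acrophase, f1$actigraphy$acrophase,
               tolerance = 1e-10)
  unlink(dir, recursive = TRUE)
})
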