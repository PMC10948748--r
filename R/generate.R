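# Synthetic cohort generation: raw modality streams with known group
# effects, so the whole extraction/statistics/classification pipeline can
# be exercised and calibrated without human data.

MOBILE_THRESHOLD <- 4   # counts/min at or above which an epoch is mobile
IMMOBILE_CAP <- 3.9     # immobile counts are capped strictly below it

# Zero-truncated normal via inverse CDF; exact, vectorised, and
# degenerate-safe (sd = 0 returns the mean).
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(pmax(mean, 0))
  lo <- stats::pnorm(0, mean, sd)
  q <- stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
  pmax(q, 0) # guard against qnorm rounding at the boundary
}

# Mean of min(Exp(mean), cap): the immobile-count expectation used to
# keep the marginal epoch mean on the cosinor curve.
capped_exp_mean <- function(mean, cap) {
  if (mean == 0) 0 else mean * (1 - exp(-cap / mean))
}

rcapped_exp <- function(n, mean, cap) {
  if (mean == 0) rep(0, n) else pmin(stats::rexp(n, 1 / mean), cap)
}

#' Simulate one subject's minute-epoch actigraphy counts
#'
#' Generates `days` of epoch counts following a 24-h cosinor rhythm
#' modulated by a nightly rest state. Nightly rest onset and duration are
#' jittered across nights by `night_jitter_sd_h` / `duration_jitter_sd_min`.
#' Outside rest, the marginal expectation of the counts equals
#' `mesor + amplitude * cos(2*pi*(t - acrophase_h)/24)` (mobility mixing
#' is mean-compensated), so cosinor fits of rest-free profiles recover
#' the generating parameters. Off-wrist flags are all `FALSE`.
#'
#' Uses the current RNG state; call `set.seed()` (or use
#' [generate_cohort()], which manages seeding) for reproducibility.
#'
#' @param profile A [group_profile()].
#' @param days Number of days (>= 1).
#' @param epoch_s Epoch length in seconds.
#' @param start Series start (POSIXct, midnight-aligned UTC).
#' @return An [epoch_series()].
#' @export
generate_epochs <- function(profile, days = 7, epoch_s = 60,
                            start = as.POSIXct("2023-01-02 00:00:00",
                                               tz = "UTC")) {
  validate_group_profile(profile)
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  n <- as.integer(days * 86400 / epoch_s)
  time <- start + (seq_len(n) - 1L) * epoch_s
  h <- abs_hours(time) - abs_hours(time)[1]    # hours since start
  clock <- clock_hours(time)
  mu <- profile$mesor +
    profile$amplitude * cos(2 * pi * (clock - profile$acrophase_h) / 24)

  # nightly rest windows in hours-since-start
  rest <- rep(FALSE, n)
  if (profile$rest_duration_min > 0) {
    for (k in seq_len(days) - 1L) {
      onset <- k * 24 + profile$rest_onset_h +
        stats::rnorm(1, 0, profile$night_jitter_sd_h)
      dur_h <- (profile$rest_duration_min +
                  stats::rnorm(1, 0, profile$duration_jitter_sd_min)) / 60
      dur_h <- max(dur_h, 0)
      rest <- rest | (h >= onset & h < onset + dur_h)
    }
  }

  counts <- numeric(n)
  imm_mean <- capped_exp_mean(profile$immobile_mean, IMMOBILE_CAP)

  act <- which(!rest)
  if (length(act)) {
    p <- profile$mobile_prob_active
    mobile <- stats::runif(length(act)) < p
    counts[act[!mobile]] <- rcapped_exp(sum(!mobile), profile$immobile_mean,
                                        IMMOBILE_CAP)
    if (any(mobile)) {
      # compensate the immobile mixture so E[count] stays on the curve
      mu_adj <- pmax((mu[act[mobile]] - (1 - p) * imm_mean) / p, 0)
      counts[act[mobile]] <- rtnorm0(sum(mobile), mu_adj, profile$noise_sd)
    }
  }

  rst <- which(rest)
  if (length(rst)) {
    mobile <- stats::runif(length(rst)) < profile$mobile_prob_rest
    counts[rst[!mobile]] <- rcapped_exp(sum(!mobile), profile$immobile_mean,
                                        IMMOBILE_CAP)
    if (any(mobile))
      counts[rst[mobile]] <- MOBILE_THRESHOLD +
        stats::rexp(sum(mobile), 1 / profile$rest_mobile_mean)
  }

  epoch_series(time, counts, epoch_s = epoch_s)
}

# Built-in neutral filler vocabulary for synthetic transcripts (words
# deliberately absent from the bundled lexicon categories).
FILLER_TOKENS <- c("今天", "天气", "吃饭",
                   "工作", "朋友", "看", "电视",
                   "散步", "休息", "公园",
                   "买东西", "煮饭", "家人",
                   "返工", "食飯", "睛覺")

#' Simulate app-derived streams for one subject
#'
#' Generates the post-extraction data the companion app pipeline would
#' produce for one subject over the monitoring week: a mood diary
#' (scheduled at `diary_slots_per_day` fixed slots starting 08:00,
#' completed independently with `completion_prob`), per-video facial
#' action-unit frame tables (Bernoulli presence at `au_rates`, with
#' face-confidence values and occasional mask-flagged videos), speech
#' segments as alternating phonation/pause frame tracks on a 10-ms grid
#' with transcript syllable counts consistent with `artic_rate_sps`, and
#' transcript token lists drawn with the profile's word-category
#' probabilities. One video + speech segment + transcript is produced per
#' completed diary entry. No raw audio or video is synthesised.
#'
#' @param profile A [group_profile()].
#' @param config A [cohort_config()] (days, slots, start time).
#' @param sex `"F"` or `"M"` (selects the F0 distribution).
#' @return List with elements `diary` (data.frame), `au_frames`
#'   (data.frame), `speech` (list of speech segments), `tokens`
#'   (data.frame).
#' @export
generate_app_streams <- function(profile, config, sex = "F") {
  validate_group_profile(profile)
  days <- config$days
  slots <- config$diary_slots_per_day
  slot_h <- (8 + 4 * (seq_len(slots) - 1L)) %% 24
  sched <- as.vector(vapply(seq_len(days) - 1L,
                            function(d) d * 24 + slot_h, numeric(slots)))
  scheduled_time <- config$start + sched * 3600
  completed <- stats::runif(length(sched)) < profile$completion_prob
  happiness <- ifelse(
    completed,
    pmin(pmax(round(stats::rnorm(length(sched), profile$happiness_mean,
                                 profile$happiness_sd)), 0), 10),
    NA_integer_)
  diary <- data.frame(entry_id = seq_along(sched),
                      scheduled_time = scheduled_time,
                      completed = completed,
                      happiness = as.integer(happiness))

  au_frames <- list()
  speech <- list()
  tokens <- list()
  lex <- builtin_lexicon()
  for (i in which(completed)) {
    # facial action-unit frames for this entry's video
    nf <- profile$frames_per_video
    au <- vapply(profile$au_rates[c("AU1", "AU4", "AU6", "AU12", "AU15")],
                 function(r) as.integer(stats::runif(nf) < r),
                 integer(nf))
    au_frames[[length(au_frames) + 1L]] <- data.frame(
      video_id = i, frame = seq_len(nf),
      face_confidence = round(stats::rbeta(nf, 18, 1.5), 4),
      mask_flag = stats::runif(1) < profile$mask_prob,
      au)

    speech[[length(speech) + 1L]] <- generate_speech_segment(profile, sex, i)

    ntok <- max(1L, stats::rpois(1, profile$tokens_per_entry))
    cat_draw <- stats::runif(ntok)
    word <- character(ntok)
    is_self <- cat_draw < profile$p_selfref
    is_neg <- !is_self & cat_draw < profile$p_selfref + profile$p_negemo
    word[is_self] <- sample(lex$self_reference, sum(is_self), replace = TRUE)
    word[is_neg] <- sample(lex$negative_emotion, sum(is_neg), replace = TRUE)
    word[!is_self & !is_neg] <- sample(FILLER_TOKENS,
                                       sum(!is_self & !is_neg),
                                       replace = TRUE)
    tokens[[length(tokens) + 1L]] <- data.frame(entry_id = i, token = word)
  }

  list(diary = diary,
       au_frames = if (length(au_frames)) do.call(rbind, au_frames)
                   else empty_au_frames(),
       speech = speech,
       tokens = if (length(tokens)) do.call(rbind, tokens)
                else data.frame(entry_id = integer(), token = character()))
}

empty_au_frames <- function() {
  data.frame(video_id = integer(), frame = integer(),
             face_confidence = numeric(), mask_flag = logical(),
             AU1 = integer(), AU4 = integer(), AU6 = integer(),
             AU12 = integer(), AU15 = integer())
}

# One speech segment: alternating phonation/pause intervals rendered as a
# 10-ms voicing/F0/intensity frame track, plus a transcript syllable
# count tied to the profile's articulation rate.
generate_speech_segment <- function(profile, sex, entry_id,
                                    frame_s = 0.01) {
  runs <- profile$phonation_runs
  phon <- pmax(stats::rnorm(runs, profile$phonation_mean_s,
                            profile$phonation_sd_s), 0.3)
  npause <- runs - 1L
  pause <- numeric(npause)
  if (npause > 0) {
    # gamma with the profile's mean/SD, resampled to respect the 0.3-s
    # pause definition used at extraction time
    shape <- (profile$pause_mean_s / profile$pause_sd_s)^2
    rate <- profile$pause_mean_s / profile$pause_sd_s^2
    for (j in seq_len(npause)) {
      repeat {
        d <- stats::rgamma(1, shape, rate)
        if (d >= 0.35) break
      }
      pause[j] <- d
    }
  }
  durs <- as.vector(rbind(phon, c(pause, NA)))
  durs <- durs[!is.na(durs)]
  voiced_runs <- rep(c(TRUE, FALSE), length.out = length(durs))
  nf <- pmax(1L, round(durs / frame_s))
  voiced <- rep(voiced_runs, nf)
  n <- length(voiced)
  f0m <- profile$f0_mean_hz[[sex]]
  f0s <- profile$f0_sd_hz[[sex]]
  f0 <- ifelse(voiced, pmax(stats::rnorm(n, f0m, f0s), 40), 0)
  intensity <- ifelse(voiced, stats::rnorm(n, 70, 2), stats::rnorm(n, 40, 2))
  track <- frame_track(times_s = (seq_len(n) - 1L) * frame_s,
                       f0_hz = f0, intensity_db = intensity,
                       voiced = voiced)
  speech_segment(track = track,
                 syllable_count = max(0L, round(profile$artic_rate_sps *
                                                  sum(phon))),
                 valid_environment = stats::runif(1) < profile$quiet_prob,
                 entry_id = entry_id)
}

#' Generate a complete synthetic study cohort
#'
#' Draws `n_control + n_mdd` subjects. MDD subjects are split into
#' remitted / non-remitted by `remitted_fraction`; each arm's raw streams
#' are generated from its [group_profile()]. Clinical scale scores are
#' drawn consistently with the remission rule (17-item Hamilton score <= 7
#' for remitted subjects, > 7 for non-remitted). Ages are drawn from the
#' same distribution in both groups (age-matched design); sex follows the
#' profile's `female_prob`.
#'
#' Reproducibility: the cohort is a pure function of the config. The
#' master seed drives one per-subject seed each, so a subject's data do
#' not depend on how many subjects precede it.
#'
#' @param config A [cohort_config()].
#' @return List of subject records (class `cohort`); each record has
#'   `subject_id`, `group`, `remission`, `age`, `sex`, `hds17`, `hadsd`,
#'   `epochs`, `diary`, `au_frames`, `speech`, `tokens`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config", call. = FALSE)
  n <- config$n_control + config$n_mdd
  n_rem <- round(config$n_mdd * config$remitted_fraction)
  group <- c(rep("control", config$n_control), rep("mdd", config$n_mdd))
  remission <- c(rep("n/a", config$n_control),
                 rep("remitted", n_rem),
                 rep("non_remitted", config$n_mdd - n_rem))

  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    profile <- switch(remission[i],
                      "n/a" = config$control_profile,
                      "remitted" = config$remitted_profile,
                      "non_remitted" = config$nonremitted_profile)
    set.seed(subject_seeds[i])
    sex <- if (stats::runif(1) < profile$female_prob) "F" else "M"
    age <- round(min(max(stats::rnorm(1, 50, 11.5), 18), 65))
    hds17 <- draw_hds17(remission[i], profile$hds17_mean)
    hadsd <- min(max(round(stats::rnorm(1, profile$hadsd_mean, 3)), 0), 21)
    epochs <- generate_epochs(profile, config$days, config$epoch_s,
                              config$start)
    app <- generate_app_streams(profile, config, sex)
    cohort[[i]] <- list(
      subject_id = sprintf("S%03d", i),
      group = group[i], remission = remission[i],
      age = age, sex = sex, hds17 = hds17, hadsd = hadsd,
      epochs = epochs, diary = app$diary, au_frames = app$au_frames,
      speech = app$speech, tokens = app$tokens)
  }
  names(cohort) <- vapply(cohort, `[[`, character(1), "subject_id")
  class(cohort) <- "cohort"
  cohort
}

# Hamilton scores drawn consistently with the remission label rule
# (<= 7 remitted, > 7 non-remitted; controls near zero).
draw_hds17 <- function(remission, mean) {
  repeat {
    x <- round(stats::rnorm(1, mean, if (remission == "n/a") 1.8 else 3))
    x <- max(x, 0)
    ok <- switch(remission,
                 "n/a" = x <= 7,
                 "remitted" = x <= 7,
                 "non_remitted" = x > 7 && x <= 52)
    if (ok) return(x)
  }
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(vapply(x, `[[`, character(1), "group"))
  cat(sprintf("<cohort> %d subjects (%s)\n", length(x),
              paste(names(grp), grp, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Subject-level covariate table of a cohort
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @return data.frame with one row per subject: id, group, remission,
#'   age, sex, 17-item Hamilton score, HADS-D score.
#' @export
cohort_subjects <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               remission = s$remission, age = s$age, sex = s$sex,
               hds17 = s$hds17, hadsd = s$hadsd,
               row.names = NULL)))
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits the on-disk interchange format consumed by the feature readers:
#' `subjects.csv`, `epochs.csv`, `diary.csv`, `au_frames.csv`,
#' `tokens.tsv`, `speech_segments.json`, and `config.json` (seed and
#' sizes, for provenance).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @param config Optional [cohort_config()] recorded in `config.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort_subjects(cohort), file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  write_epochs_csv(cohort, file.path(dir, "epochs.csv"))

  diary <- do.call(rbind, lapply(cohort, function(s)
    cbind(subject_id = s$subject_id,
          transform(s$diary,
                    scheduled_time = format(scheduled_time,
                                            "%Y-%m-%dT%H:%M:%S",
                                            tz = "UTC"),
                    completed = as.integer(completed)))))
  utils::write.csv(diary, file.path(dir, "diary.csv"), row.names = FALSE)

  au <- do.call(rbind, lapply(cohort, function(s) {
    if (nrow(s$au_frames) == 0) return(NULL)
    cbind(subject_id = s$subject_id,
          transform(s$au_frames, mask_flag = as.integer(mask_flag)))
  }))
  utils::write.csv(au %||% cbind(subject_id = character(),
                                 empty_au_frames()),
                   file.path(dir, "au_frames.csv"), row.names = FALSE)

  tok <- do.call(rbind, lapply(cohort, function(s) {
    if (nrow(s$tokens) == 0) return(NULL)
    cbind(subject_id = s$subject_id, s$tokens)
  }))
  utils::write.table(tok %||% data.frame(subject_id = character(),
                                         entry_id = integer(),
                                         token = character()),
                     file.path(dir, "tokens.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  speech <- lapply(cohort, function(s)
    lapply(s$speech, speech_segment_to_list))
  jsonlite::write_json(speech, file.path(dir, "speech_segments.json"),
                       auto_unbox = TRUE, digits = NA)

  if (!is.null(config)) {
    cfgmeta <- list(seed = config$seed, n_control = config$n_control,
                    n_mdd = config$n_mdd, days = config$days,
                    epoch_s = config$epoch_s,
                    diary_slots_per_day = config$diary_slots_per_day,
                    remitted_fraction = config$remitted_fraction,
                    start = format(config$start, "%Y-%m-%dT%H:%M:%S",
                                   tz = "UTC"))
    jsonlite::write_json(cfgmeta, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
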