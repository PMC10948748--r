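#' Group effect profile for the synthetic cohort generator
#'
#' A `group_profile` bundles every parameter that controls how raw data
#' streams are simulated for one diagnostic group: the 24-h cosinor
#' rest-activity rhythm (MESOR, amplitude, acrophase), the nightly rest
#' window and its night-to-night timing jitter, epoch-level mobility
#' probabilities, facial action-unit presence rates, prosodic speech timing,
#' word-category usage, mood-diary behaviour, and clinical scale locations.
#'
#' Activity counts are generated as a two-state (rest/active) process.
#' During the active state an epoch is "mobile" with probability
#' `mobile_prob_active`; mobile epochs draw a zero-truncated normal count
#' whose mean is adjusted so that the *marginal* epoch expectation equals
#' the cosinor curve `mesor + amplitude * cos(2*pi*(t - acrophase_h)/24)`,
#' which is what makes cosinor parameter recovery well defined. Immobile
#' epochs draw a small exponential count capped below the mobility
#' threshold. During the rest state, mobile epochs (probability
#' `mobile_prob_rest`) draw threshold-exceeding exponential counts with
#' mean `rest_mobile_mean`, emulating brief nocturnal arousals.
#'
#' @param mesor Mean level of the 24-h activity rhythm (counts/min).
#' @param amplitude Peak minus MESOR of the rhythm (counts/min); must not
#'   exceed `mesor` so expected counts stay nonnegative.
#' @param acrophase_h Clock time of peak activity, decimal hours in
#'   `[0, 24)`.
#' @param rest_onset_h Mean clock time at which the nightly rest interval
#'   starts (decimal hours; values near 0 mean around midnight).
#' @param rest_duration_min Mean nightly rest duration in minutes. Set to 0
#'   to disable the rest state entirely (pure cosinor process).
#' @param night_jitter_sd_h Night-to-night SD of rest onset (hours).
#' @param duration_jitter_sd_min Night-to-night SD of rest duration
#'   (minutes).
#' @param mobile_prob_active,mobile_prob_rest Probability that an epoch is
#'   mobile (counts at or above the mobility threshold) in the active and
#'   rest state respectively.
#' @param au_rates Named vector of facial action-unit presence
#'   probabilities, names `AU1, AU4, AU6, AU12, AU15`.
#' @param artic_rate_sps Articulation rate in syllables per second of
#'   phonation time.
#' @param pause_mean_s,pause_sd_s Mean and SD of within-segment pause
#'   durations (seconds).
#' @param f0_mean_hz,f0_sd_hz Named vectors (`F`, `M`) giving voiced-frame
#'   fundamental-frequency mean and variability by sex (Hz).
#' @param p_selfref,p_negemo Per-token probabilities of self-reference and
#'   negative-emotion words.
#' @param happiness_mean,happiness_sd Location and spread of the 0-10
#'   Likert happiness ratings.
#' @param completion_prob Probability that a scheduled diary entry is
#'   completed.
#' @param hds17_mean,hadsd_mean Locations of the 17-item Hamilton
#'   depression scale and the HADS depression subscale.
#' @param female_prob Probability that a simulated subject is female.
#' @param noise_sd SD of the zero-truncated normal count noise in the
#'   active state (counts). 0 gives a noise-free deterministic series.
#' @param immobile_mean Mean of the capped-exponential counts in immobile
#'   epochs (counts). 0 gives exact zeros.
#' @param rest_mobile_mean Mean excess (above the mobility threshold) of
#'   counts in mobile rest epochs.
#' @param mask_prob Probability that a video is recorded wearing a face
#'   mask (such videos are excluded from facial analysis).
#' @param quiet_prob Probability that a speech recording is made in a
#'   quiet environment (only those are analysed).
#' @param frames_per_video Facial frames per video recording.
#' @param tokens_per_entry Mean transcript length per diary entry (tokens).
#' @param phonation_runs Number of phonation intervals per speech segment.
#' @param phonation_mean_s,phonation_sd_s Duration distribution of each
#'   phonation interval (seconds).
#'
#' @return An object of class `group_profile` (a validated named list).
#' @seealso [preset_profiles()] for the shipped control / remitted /
#'   non-remitted presets, [generate_cohort()].
#' @export
group_profile <- function(mesor = 170,
                          amplitude = 129,
                          acrophase_h = 14.92,
                          rest_onset_h = 0.02,
                          rest_duration_min = 457,
                          night_jitter_sd_h = 0.6,
                          duration_jitter_sd_min = 30,
                          mobile_prob_active = 0.84,
                          mobile_prob_rest = 0.17,
                          au_rates = c(AU1 = 0.21, AU4 = 0.216, AU6 = 0.255,
                                       AU12 = 0.182, AU15 = 0.175),
                          artic_rate_sps = 4.38,
                          pause_mean_s = 0.72,
                          pause_sd_s = 0.31,
                          f0_mean_hz = c(F = 169.3, M = 110.3),
                          f0_sd_hz = c(F = 51.3, M = 36.9),
                          p_selfref = 0.0098,
                          p_negemo = 0.0026,
                          happiness_mean = 6.63,
                          happiness_sd = 1.43,
                          completion_prob = 0.8336,
                          hds17_mean = 1.6,
                          hadsd_mean = 3.4,
                          female_prob = 0.63,
                          noise_sd = 25,
                          immobile_mean = 1.5,
                          rest_mobile_mean = 105,
                          mask_prob = 0.05,
                          quiet_prob = 0.45,
                          frames_per_video = 300,
                          tokens_per_entry = 40,
                          phonation_runs = 5,
                          phonation_mean_s = 1.4,
                          phonation_sd_s = 0.5) {
  p <- as.list(environment())
  class(p) <- "group_profile"
  validate_group_profile(p)
  p
}

validate_group_profile <- function(p) {
  stopifnot(inherits(p, "group_profile"))
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  probs <- c(p$mobile_prob_active, p$mobile_prob_rest, p$au_rates,
             p$p_selfref, p$p_negemo, p$completion_prob, p$female_prob,
             p$mask_prob, p$quiet_prob)
  chk(all(is.finite(probs)) && all(probs >= 0) && all(probs <= 1),
      "all probabilities in a group_profile must lie in [0, 1]")
  chk(p$amplitude >= 0 && p$amplitude <= p$mesor,
      "amplitude must be in [0, mesor] so expected counts are nonnegative")
  chk(p$acrophase_h >= 0 && p$acrophase_h < 24,
      "acrophase_h must lie in [0, 24)")
  chk(p$rest_duration_min >= 0 && p$rest_duration_min < 1440,
      "rest_duration_min must lie in [0, 1440)")
  chk(all(c("AU1", "AU4", "AU6", "AU12", "AU15") %in% names(p$au_rates)),
      "au_rates must be named and include AU1, AU4, AU6, AU12, AU15")
  chk(all(c("F", "M") %in% names(p$f0_mean_hz)) &&
        all(c("F", "M") %in% names(p$f0_sd_hz)),
      "f0_mean_hz and f0_sd_hz must have entries named 'F' and 'M'")
  chk(p$p_selfref + p$p_negemo <= 1,
      "p_selfref + p_negemo must not exceed 1")
  chk(p$noise_sd >= 0 && p$immobile_mean >= 0 && p$rest_mobile_mean >= 0,
      "noise parameters must be nonnegative")
  chk(p$happiness_mean >= 0 && p$happiness_mean <= 10,
      "happiness_mean must lie on the 0-10 Likert scale")
  invisible(p)
}

#' Shipped group-profile presets
#'
#' Returns the three default [group_profile()]s used by
#' [cohort_config()]: healthy controls, remitted MDD, and non-remitted
#' MDD. The presets are seeded from published group means of a Chinese
#' case-control digital-phenotyping study of depression (activity rhythm,
#' sleep timing, facial action-unit, prosodic, linguistic, mood-diary and
#' clinical-scale locations). They are simulation presets that reproduce
#' the *direction and rough size* of the reported group contrasts, not
#' ground truth about depression.
#'
#' Directions encoded: patients show lower mobile time, a delayed
#' acrophase and sleep midpoint, longer and more variable rest, more brow
#' lowering (AU4), less lip-corner pulling (AU12), lower articulation
#' rate, larger and more variable pauses, more self-reference and
#' negative-emotion words, lower happiness, and lower diary completion.
#'
#' @return Named list with elements `control`, `remitted`, `non_remitted`.
#' @export
preset_profiles <- function() {
  control <- group_profile()
  mdd_common <- list(
    mesor = 160.3, amplitude = 120.8,
    rest_onset_h = 0.29, rest_duration_min = 478.6,
    mobile_prob_active = 0.83, mobile_prob_rest = 0.18,
    au_rates = c(AU1 = 0.230, AU4 = 0.297, AU6 = 0.155,
                 AU12 = 0.104, AU15 = 0.195),
    artic_rate_sps = 3.97, pause_mean_s = 0.82, pause_sd_s = 0.41,
    f0_mean_hz = c(F = 164.1, M = 107.0),
    f0_sd_hz = c(F = 51.2, M = 38.8),
    p_selfref = 0.0181, p_negemo = 0.0092,
    happiness_mean = 5.02, happiness_sd = 1.70,
    completion_prob = 0.7289, hadsd_mean = 8.0, female_prob = 0.72,
    rest_mobile_mean = 130
  )
  remitted <- do.call(group_profile, utils::modifyList(
    mdd_common,
    list(acrophase_h = 15.6, night_jitter_sd_h = 0.6,
         duration_jitter_sd_min = 30, hds17_mean = 4)))
  non_remitted <- do.call(group_profile, utils::modifyList(
    mdd_common,
    list(acrophase_h = 15.49, night_jitter_sd_h = 0.85,
         duration_jitter_sd_min = 60, hds17_mean = 12)))
  list(control = control, remitted = remitted, non_remitted = non_remitted)
}

#' Configuration for a synthetic study cohort
#'
#' @param n_control,n_mdd Number of control and MDD subjects (>= 1).
#' @param remitted_fraction Fraction of MDD subjects in remission.
#' @param days Days of monitoring (default one week).
#' @param epoch_s Actigraphy epoch length in seconds (default 60).
#' @param diary_slots_per_day Scheduled mood-diary prompts per day
#'   (default 4, i.e. 28 scheduled entries over a week).
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @param control_profile,remitted_profile,nonremitted_profile
#'   [group_profile()] objects; default to [preset_profiles()].
#' @param start Monitoring start time (POSIXct, midnight-aligned).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control,
                          n_mdd,
                          remitted_fraction = 0.5,
                          days = 7,
                          epoch_s = 60,
                          diary_slots_per_day = 4,
                          seed = 1L,
                          control_profile = NULL,
                          remitted_profile = NULL,
                          nonremitted_profile = NULL,
                          start = as.POSIXct("2023-01-02 00:00:00",
                                             tz = "UTC")) {
  presets <- preset_profiles()
  cfg <- list(
    n_control = as.integer(n_control),
    n_mdd = as.integer(n_mdd),
    remitted_fraction = remitted_fraction,
    days = as.integer(days),
    epoch_s = as.integer(epoch_s),
    diary_slots_per_day = as.integer(diary_slots_per_day),
    seed = as.integer(seed),
    control_profile = control_profile %||% presets$control,
    remitted_profile = remitted_profile %||% presets$remitted,
    nonremitted_profile = nonremitted_profile %||% presets$non_remitted,
    start = start
  )
  if (cfg$n_control < 1L || cfg$n_mdd < 1L)
    stop("n_control and n_mdd must both be >= 1", call. = FALSE)
  if (cfg$days < 1L) stop("days must be >= 1", call. = FALSE)
  if (cfg$diary_slots_per_day < 1L)
    stop("diary_slots_per_day must be >= 1", call. = FALSE)
  if (cfg$remitted_fraction < 0 || cfg$remitted_fraction > 1)
    stop("remitted_fraction must lie in [0, 1]", call. = FALSE)
  if (86400L %% cfg$epoch_s != 0L)
    stop("epoch_s must divide 86400", call. = FALSE)
  for (pr in list(cfg$control_profile, cfg$remitted_profile,
                  cfg$nonremitted_profile))
    validate_group_profile(pr)
  class(cfg) <- "cohort_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
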