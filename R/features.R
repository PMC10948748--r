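# Per-subject feature extraction across all modalities.

#' Extract per-subject feature tables from a cohort
#'
#' Runs the full extraction battery on every subject: the 22-measure
#' actigraphy battery ([actigraphy_features()]), the weekly facial
#' action-unit profile, the acoustic speech profile, pooled word-category
#' percentages, and the mood-diary summary. Subjects missing a modality
#' (e.g. no valid video or speech segment) get `NA` in that modality's
#' columns and are later removed by complete-case filtering in
#' [assemble_features()].
#'
#' @param cohort A `cohort` from [generate_cohort()], or an equivalent
#'   list of subject records read from disk.
#' @param lexicon Word-category lexicon (default [builtin_lexicon()]).
#' @param min_confidence Face-confidence threshold for AU frames.
#' @return List of data.frames: `subjects` (covariates and labels),
#'   `actigraphy` (22 feature columns), `app` (diary, facial, voice and
#'   NLP features).
#' @export
extract_features <- function(cohort, lexicon = builtin_lexicon(),
                             min_confidence = 0.75) {
  subjects <- cohort_subjects(cohort)

  acti <- do.call(rbind, lapply(cohort, function(s) {
    f <- suppressWarnings(actigraphy_features(s$epochs))
    cbind(data.frame(subject_id = s$subject_id), as.data.frame(t(f)))
  }))
  rownames(acti) <- NULL

  app <- do.call(rbind, lapply(cohort, function(s) {
    ds <- diary_summary(s$diary)
    au <- if (nrow(s$au_frames))
      subject_au_profile(s$au_frames, min_confidence) else NULL
    sp <- if (length(s$speech))
      subject_speech_profile(s$speech, s$sex) else NULL
    nl <- if (nrow(s$tokens))
      category_proportions(s$tokens$token, lexicon) else NULL
    data.frame(
      subject_id = s$subject_id,
      happiness = ds$mean_happiness,
      completion_rate = ds$completion_rate_pct,
      AU1 = if (is.null(au)) NA_real_ else 100 * au$proportions[["AU1"]],
      AU4 = if (is.null(au)) NA_real_ else 100 * au$proportions[["AU4"]],
      AU6 = if (is.null(au)) NA_real_ else 100 * au$proportions[["AU6"]],
      AU12 = if (is.null(au)) NA_real_ else 100 * au$proportions[["AU12"]],
      AU15 = if (is.null(au)) NA_real_ else 100 * au$proportions[["AU15"]],
      n_videos = if (is.null(au)) 0L else au$n_videos,
      artic_rate = feat_or_na(sp, "artic_rate"),
      pause_mean = feat_or_na(sp, "pause_mean"),
      pause_sd = feat_or_na(sp, "pause_sd"),
      pause_rate = feat_or_na(sp, "pause_rate"),
      f0_mean = feat_or_na(sp, "f0_mean"),
      f0_sd = feat_or_na(sp, "f0_sd"),
      n_segments = if (is.null(sp)) 0L else sp$n_segments_used,
      selfref_pct = if (is.null(nl)) NA_real_ else
        nl[["self_reference"]],
      negemo_pct = if (is.null(nl)) NA_real_ else
        nl[["negative_emotion"]])
  }))
  rownames(app) <- NULL
  list(subjects = subjects, actigraphy = acti, app = app)
}

feat_or_na <- function(sp, name) {
  if (is.null(sp)) NA_real_ else sp$features[[name]]
}

#' Feature columns belonging to each modality
#'
#' The actigraphy classification set keeps 17 of the 22 measures
#' (the L5/M10 window statistics and relative amplitude are dropped, as
#' they are largely redundant with the cosinor parameters).
#'
#' @return Named list mapping modality name to column names.
#' @export
modality_columns <- function() {
  list(
    happiness = "happiness",
    actigraphy = c("cpm_week", "pct_mobile_week", "cpm_active",
                   "pct_mobile_active", "cpm_rest", "pct_mobile_rest",
                   "rest_duration_min", "sleep_duration_min",
                   "sleep_efficiency", "sleep_midpoint",
                   "iiv_sleep_duration", "iiv_sleep_midpoint",
                   "mesor", "acrophase", "magnitude", "IS", "IV"),
    facial = c("AU1", "AU4", "AU6", "AU12", "AU15"),
    voice = c("artic_rate", "pause_mean", "pause_sd", "pause_rate"),
    nlp = c("selfref_pct", "negemo_pct"),
    hadsd = "hadsd")
}
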