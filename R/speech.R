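# Prosodic speech features from voicing/F0/intensity frame tracks.

#' Frame-level speech track
#'
#' Per-frame fundamental frequency, intensity, and voicing on a uniform
#' (10-ms by convention) time grid, as produced by standard prosody
#' extraction tools. F0 is 0 on unvoiced frames.
#'
#' @param times_s Strictly increasing frame times (s), uniform grid.
#' @param f0_hz Per-frame F0 in Hz (>= 0).
#' @param intensity_db Per-frame intensity in dB.
#' @param voiced Logical voicing flags.
#' @return Object of class `frame_track`.
#' @export
frame_track <- function(times_s, f0_hz, intensity_db, voiced) {
  n <- length(times_s)
  if (n == 0L) stop("empty frame track", call. = FALSE)
  if (length(f0_hz) != n || length(intensity_db) != n ||
        length(voiced) != n)
    stop("all frame track fields must have equal length", call. = FALSE)
  if (any(diff(times_s) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (any(f0_hz < 0)) stop("f0 must be nonnegative", call. = FALSE)
  structure(list(times_s = times_s, f0_hz = f0_hz,
                 intensity_db = intensity_db, voiced = as.logical(voiced)),
            class = "frame_track")
}

#' One recorded speech segment
#'
#' @param track A [frame_track()].
#' @param syllable_count Syllables in the transcript. For
#'   Cantonese/Chinese transcripts the character count is used as the
#'   syllable count (one character is one syllable).
#' @param valid_environment Whether the recording was made in a quiet
#'   environment; only quiet segments are analysed.
#' @param entry_id Optional diary entry the segment belongs to.
#' @return Object of class `speech_segment`.
#' @export
speech_segment <- function(track, syllable_count,
                           valid_environment = TRUE, entry_id = NA) {
  stopifnot(inherits(track, "frame_track"), syllable_count >= 0)
  structure(list(track = track,
                 syllable_count = as.integer(syllable_count),
                 valid_environment = isTRUE(valid_environment),
                 entry_id = entry_id),
            class = "speech_segment")
}

#' Detect pauses in a frame track
#'
#' A frame is silent when it is unvoiced *and* its intensity lies below
#' the segment's maximum intensity plus `silence_db_rel` (a relative
#' silence floor). Leading and trailing silence is trimmed first; a pause
#' is then any maximal internal silent run lasting at least
#' `min_pause_s`. Phonation time is the segment duration minus trimmed
#' silence minus pause time (sub-threshold gaps count as phonation).
#'
#' @param track A [frame_track()].
#' @param min_pause_s Minimum pause duration in seconds (default 0.3).
#' @param silence_db_rel Silence threshold relative to the segment's
#'   maximum intensity in dB (default -25).
#' @return List `pauses` (data.frame `start_s`, `end_s`),
#'   `phonation_s`, `total_s`.
#' @export
detect_pauses <- function(track, min_pause_s = 0.3, silence_db_rel = -25) {
  stopifnot(inherits(track, "frame_track"))
  n <- length(track$voiced)
  frame_s <- if (n > 1) track$times_s[2] - track$times_s[1] else 0.01
  if (!any(track$voiced))
    stop("all-silent track: no speech", call. = FALSE)
  silent <- !track$voiced &
    track$intensity_db < max(track$intensity_db) + silence_db_rel
  if (all(silent)) stop("all-silent track: no speech", call. = FALSE)
  first <- which(!silent)[1]
  last <- max(which(!silent))
  total_s <- n * frame_s
  trimmed_s <- ((first - 1) + (n - last)) * frame_s

  core <- silent[first:last]
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * frame_s >= min_pause_s)
  pauses <- data.frame(
    start_s = track$times_s[first + starts[keep] - 1L],
    end_s = track$times_s[first + ends[keep] - 1L] + frame_s)
  pause_s <- sum(pauses$end_s - pauses$start_s)
  list(pauses = pauses,
       phonation_s = total_s - trimmed_s - pause_s,
       total_s = total_s)
}

#' Acoustic features of one speech segment
#'
#' Computes the six standard prosodic features: articulation rate
#' (syllables per second of phonation time), pause duration mean and
#' variability (sample SD, seconds), pause rate (pauses per second of
#' total segment duration), and F0 mean and variability (sample SD, Hz)
#' over voiced frames only. Segments recorded in a noisy environment or
#' containing no pause are excluded (`NULL` is returned), matching the
#' segment-validity filters applied before group analysis.
#'
#' @param seg A [speech_segment()].
#' @param min_pause_s,silence_db_rel Passed to [detect_pauses()].
#' @return Named numeric vector of 6 features, or `NULL` when the
#'   segment fails a validity filter.
#' @export
segment_features <- function(seg, min_pause_s = 0.3, silence_db_rel = -25) {
  stopifnot(inherits(seg, "speech_segment"))
  if (!seg$valid_environment) return(NULL)
  ps <- detect_pauses(seg$track, min_pause_s, silence_db_rel)
  if (nrow(ps$pauses) < 1) return(NULL)   # no pause: segment excluded
  if (ps$phonation_s <= 0) stop("zero phonation time", call. = FALSE)
  durs <- ps$pauses$end_s - ps$pauses$start_s
  voiced <- seg$track$voiced
  f0 <- seg$track$f0_hz[voiced]
  c(artic_rate = seg$syllable_count / ps$phonation_s,
    pause_mean = mean(durs),
    pause_sd = if (length(durs) > 1) stats::sd(durs) else 0,
    pause_rate = nrow(ps$pauses) / ps$total_s,
    f0_mean = mean(f0),
    f0_sd = if (length(f0) > 1) stats::sd(f0) else 0)
}

#' Per-subject speech profile
#'
#' Unweighted mean of each acoustic feature across the subject's valid
#' segments (quiet environment, at least one pause). F0 features are
#' tagged with the subject's sex so group statistics can be stratified
#' (F0 distributions differ systematically between sexes).
#'
#' @param segments List of [speech_segment()]s.
#' @param sex `"F"` or `"M"`.
#' @param ... Passed to [segment_features()].
#' @return List `features` (named numeric vector), `sex`,
#'   `n_segments_used`; or `NULL` when no segment survives the filters
#'   (subject missing for the voice modality).
#' @export
subject_speech_profile <- function(segments, sex = "F", ...) {
  feats <- Filter(Negate(is.null),
                  lapply(segments, segment_features, ...))
  if (length(feats) == 0L) return(NULL)
  m <- colMeans(do.call(rbind, feats))
  list(features = m, sex = sex, n_segments_used = length(feats))
}

# JSON (de)serialisation of speech segments for the on-disk cohort format.
speech_segment_to_list <- function(seg) {
  list(entry_id = seg$entry_id,
       syllable_count = seg$syllable_count,
       valid_environment = seg$valid_environment,
       times_s = seg$track$times_s,
       f0_hz = round(seg$track$f0_hz, 2),
       intensity_db = round(seg$track$intensity_db, 2),
       voiced = seg$track$voiced)
}

speech_segment_from_list <- function(x) {
  speech_segment(
    frame_track(as.numeric(x$times_s), as.numeric(x$f0_hz),
                as.numeric(x$intensity_db), as.logical(x$voiced)),
    syllable_count = x$syllable_count,
    valid_environment = isTRUE(x$valid_environment),
    entry_id = x$entry_id)
}

#' Read per-subject speech segments from JSON
#'
#' @param path Path to a `speech_segments.json` written by
#'   [write_cohort()] (top level: subject id -> list of segments with
#'   frame arrays, syllable count and quiet flag).
#' @return Named list (by subject) of lists of [speech_segment()]s.
#' @export
read_speech_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(raw, function(subj) lapply(subj, speech_segment_from_list))
}
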