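# Facial action-unit proportions, word-category proportions and
# mood-diary summaries from app-derived streams.

AU_NAMES <- c("AU1", "AU4", "AU6", "AU12", "AU15")

#' Per-video facial action-unit proportions
#'
#' Proportion of retained frames on which each action unit is present
#' (presence is binary per frame). Frames with face-tracking confidence
#' below `min_confidence` are dropped; videos recorded with a face mask,
#' or with no retained frame, are invalid and return `NULL`.
#'
#' @param frames data.frame with columns `face_confidence`, `mask_flag`
#'   and one 0/1 column per action unit (`AU1`, `AU4`, `AU6`, `AU12`,
#'   `AU15`).
#' @param min_confidence Face-confidence retention threshold
#'   (default 0.75).
#' @return Named numeric vector of proportions in `[0, 1]`, or `NULL`
#'   for an invalid video.
#' @export
video_au_proportions <- function(frames, min_confidence = 0.75) {
  if (any(frames$mask_flag)) return(NULL)          # masked video excluded
  keep <- frames$face_confidence >= min_confidence
  if (!any(keep)) return(NULL)
  vapply(AU_NAMES, function(a) mean(frames[[a]][keep]), numeric(1))
}

#' Weekly per-subject action-unit profile
#'
#' Unweighted mean of per-video AU proportions over all the subject's
#' valid videos of the week.
#'
#' @param frames data.frame of AU frames for one subject, with a
#'   `video_id` column plus the columns of [video_au_proportions()].
#' @param min_confidence Passed to [video_au_proportions()].
#' @return List `proportions` (named vector) and `n_videos`, or `NULL`
#'   when no video is valid (subject missing for the facial modality).
#' @export
subject_au_profile <- function(frames, min_confidence = 0.75) {
  per_video <- Filter(Negate(is.null),
                      lapply(split(frames, frames$video_id),
                             video_au_proportions, min_confidence))
  if (length(per_video) == 0L) return(NULL)
  list(proportions = colMeans(do.call(rbind, per_video)),
       n_videos = length(per_video))
}

#' Word-category proportions of a token list
#'
#' Percentage of tokens belonging to each lexicon category relative to
#' text length. Matching is exact string match after whitespace
#' normalisation; a token may belong to several categories.
#'
#' @param tokens Character vector of segmented tokens.
#' @param lexicon Named list mapping category name to a character vector
#'   of member tokens (see [read_lexicon()], [builtin_lexicon()]).
#' @return Named numeric vector of percentages, one per category.
#' @export
category_proportions <- function(tokens, lexicon) {
  if (length(tokens) == 0L) stop("empty token list", call. = FALSE)
  tok <- trimws(tokens)
  vapply(lexicon, function(words) 100 * mean(tok %in% words), numeric(1))
}

#' Bundled toy word-category lexicon
#'
#' A small built-in Chinese (Standard/Cantonese) lexicon with
#' `self_reference` (first-person forms) and `negative_emotion`
#' categories. It is a minimal stand-in that makes the pipeline runnable
#' end to end; for real analyses supply a full psycholinguistic
#' dictionary via [read_lexicon()].
#'
#' @return Named list of character vectors.
#' @export
builtin_lexicon <- function() {
  path <- system.file("extdata", "lexicon_zh.json", package = "digimood")
  if (nzchar(path)) read_lexicon(path) else
    jsonlite::read_json("inst/extdata/lexicon_zh.json",
                        simplifyVector = TRUE)
}

#' Read a category lexicon from JSON
#'
#' Format: a JSON object mapping category names to arrays of tokens,
#' e.g. `{"self_reference": ["..."], "negative_emotion": ["..."]}`.
#'
#' @param path JSON file path.
#' @return Named list of character vectors.
#' @export
read_lexicon <- function(path) {
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(lex) || is.null(names(lex)))
    stop("lexicon must be a JSON object of category -> token arrays",
         call. = FALSE)
  lapply(lex, as.character)
}

#' Mood-diary summary
#'
#' @param diary data.frame with columns `completed` (logical) and
#'   `happiness` (0-10 integer, present iff completed), one row per
#'   scheduled entry.
#' @return List `mean_happiness` (`NA` when nothing was completed),
#'   `completion_rate_pct`, `n_scheduled`, `n_completed`.
#' @export
diary_summary <- function(diary) {
  n <- nrow(diary)
  if (n == 0L) stop("no scheduled diary entries", call. = FALSE)
  done <- diary$completed
  list(mean_happiness = if (any(done)) mean(diary$happiness[done])
       else NA_real_,
       completion_rate_pct = 100 * sum(done) / n,
       n_scheduled = n, n_completed = sum(done))
}
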