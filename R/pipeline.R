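# End-to-end orchestration: simulate -> extract -> compare -> classify,
# driven by a single config, with a manifest for reproducibility.

#' Read a cohort from a directory of plain-text files
#'
#' Inverse of [write_cohort()]: reads `subjects.csv`, `epochs.csv`,
#' `diary.csv`, `au_frames.csv`, `tokens.tsv` and
#' `speech_segments.json` into the in-memory cohort structure.
#'
#' @param dir Directory written by [write_cohort()] (or user-supplied
#'   files with the same schemas).
#' @param epoch_s Actigraphy epoch length in seconds.
#' @return A `cohort` list.
#' @export
read_cohort_dir <- function(dir, epoch_s = 60) {
  need <- c("subjects.csv", "epochs.csv", "diary.csv", "au_frames.csv",
            "tokens.tsv", "speech_segments.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input file: ", file.path(dir, missing[1]),
         call. = FALSE)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  epochs <- read_epochs_csv(file.path(dir, "epochs.csv"), epoch_s)
  diary <- utils::read.csv(file.path(dir, "diary.csv"),
                           stringsAsFactors = FALSE)
  diary$scheduled_time <- as.POSIXct(diary$scheduled_time, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%S")
  diary$completed <- as.logical(diary$completed)
  au <- utils::read.csv(file.path(dir, "au_frames.csv"),
                        stringsAsFactors = FALSE)
  if (nrow(au)) au$mask_flag <- as.logical(au$mask_flag)
  tok <- utils::read.table(file.path(dir, "tokens.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           quote = "")
  speech <- read_speech_json(file.path(dir, "speech_segments.json"))

  cohort <- lapply(seq_len(nrow(subjects)), function(i) {
    id <- subjects$subject_id[i]
    list(subject_id = id,
         group = subjects$group[i], remission = subjects$remission[i],
         age = subjects$age[i], sex = subjects$sex[i],
         hds17 = subjects$hds17[i], hadsd = subjects$hadsd[i],
         epochs = epochs[[id]],
         diary = diary[diary$subject_id == id,
                       setdiff(names(diary), "subject_id")],
         au_frames = if (nrow(au)) au[au$subject_id == id,
                                      setdiff(names(au), "subject_id")]
                     else empty_au_frames(),
         speech = speech[[id]] %||% list(),
         tokens = tok[tok$subject_id == id,
                      setdiff(names(tok), "subject_id")])
  })
  names(cohort) <- subjects$subject_id
  class(cohort) <- "cohort"
  cohort
}

#' Validate input files against the reader contracts
#'
#' Report-only schema check of a cohort input directory: required
#' columns, nonnegative counts, uniform epoch spacing, value ranges.
#'
#' @param dir Input directory.
#' @return data.frame with columns `file`, `row`, `issue`; zero rows
#'   when everything is well formed.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  add <- function(file, row, issue)
    issues[[length(issues) + 1L]] <<- data.frame(file = file, row = row,
                                                 issue = issue)
  ep_path <- file.path(dir, "epochs.csv")
  if (!file.exists(ep_path)) {
    add("epochs.csv", NA, "file missing")
  } else {
    df <- utils::read.csv(ep_path, stringsAsFactors = FALSE)
    need <- c("subject_id", "timestamp", "counts", "off_wrist")
    for (col in setdiff(need, names(df)))
      add("epochs.csv", NA, paste("missing column", col))
    if (all(need %in% names(df))) {
      bad <- which(!is.finite(df$counts) | df$counts < 0)
      for (r in bad) add("epochs.csv", r, "negative or non-finite counts")
      ts <- as.POSIXct(df$timestamp, tz = "UTC",
                       format = "%Y-%m-%dT%H:%M:%S")
      for (r in which(is.na(ts)))
        add("epochs.csv", r, "unparseable timestamp")
      for (id in unique(df$subject_id)) {
        tt <- sort(as.numeric(ts[df$subject_id == id]))
        dt <- diff(tt)
        if (length(dt) && length(unique(dt)) > 1)
          add("epochs.csv", NA,
              paste0("non-uniform epoch spacing for subject ", id))
      }
    }
  }
  di_path <- file.path(dir, "diary.csv")
  if (file.exists(di_path)) {
    df <- utils::read.csv(di_path, stringsAsFactors = FALSE)
    if ("happiness" %in% names(df)) {
      bad <- which(!is.na(df$happiness) &
                     (df$happiness < 0 | df$happiness > 10))
      for (r in bad) add("diary.csv", r, "happiness outside 0-10")
    }
  }
  au_path <- file.path(dir, "au_frames.csv")
  if (file.exists(au_path)) {
    df <- utils::read.csv(au_path, stringsAsFactors = FALSE)
    for (a in intersect(AU_NAMES, names(df))) {
      bad <- which(!df[[a]] %in% c(0, 1))
      for (r in bad) add("au_frames.csv", r,
                         paste("non-binary presence in", a))
    }
    if ("face_confidence" %in% names(df)) {
      bad <- which(df$face_confidence < 0 | df$face_confidence > 1)
      for (r in bad) add("au_frames.csv", r, "confidence outside [0,1]")
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(file = character(), row = integer(),
                  issue = character())
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> features -> compare -> classify into an
#' output directory, with a manifest recording the seed, configuration
#' hash and package version so a rerun with the same config reproduces
#' identical numbers.
#'
#' The config is a named list (or YAML file path) with fields:
#' \describe{
#'   \item{simulate}{List of [cohort_config()] arguments, *or*}
#'   \item{input_dir}{Directory of raw input files (exactly one of the
#'     two must be present).}
#'   \item{out_dir}{Output directory.}
#'   \item{seed}{Master seed for all stochastic stages.}
#'   \item{stages}{Subset of `c("features", "compare", "classify")`;
#'     later stages require earlier ones.}
#'   \item{tasks}{Classification tasks (default both).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required",
                                    call. = FALSE)
  has_sim <- !is.null(config$simulate)
  has_dir <- !is.null(config$input_dir)
  if (has_sim == has_dir)
    stop("exactly one of config$simulate / config$input_dir must be set",
         call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("features", "compare", "classify")
  if ("compare" %in% stages && !"features" %in% stages)
    stop("stage 'compare' requires stage 'features'", call. = FALSE)
  if ("classify" %in% stages && !"features" %in% stages)
    stop("stage 'classify' requires stage 'features'", call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (has_sim) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    cohort_cfg <- do.call(cohort_config, sim_args)
    cohort <- generate_cohort(cohort_cfg)
    write_cohort(cohort, file.path(out, "cohort"), cohort_cfg)
  } else {
    cohort <- read_cohort_dir(config$input_dir)
  }

  results <- list()
  if ("features" %in% stages) {
    feats <- extract_features(cohort)
    fdir <- file.path(out, "features")
    dir.create(fdir, showWarnings = FALSE)
    utils::write.csv(feats$subjects, file.path(fdir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(feats$actigraphy,
                     file.path(fdir, "actigraphy_features.csv"),
                     row.names = FALSE)
    utils::write.csv(feats$app, file.path(fdir, "app_features.csv"),
                     row.names = FALSE)
    results$features <- feats
  }

  if ("compare" %in% stages) {
    cdir <- file.path(out, "comparisons")
    dir.create(cdir, showWarnings = FALSE)
    feats <- results$features
    group <- feats$subjects$group
    acti_cmp <- compare_feature_table(
      feats$actigraphy[setdiff(names(feats$actigraphy), "subject_id")],
      group)
    app_cols <- setdiff(names(feats$app),
                        c("subject_id", "n_videos", "n_segments"))
    app_cmp <- compare_feature_table(feats$app[app_cols], group)
    utils::write.csv(acti_cmp,
                     file.path(cdir, "actigraphy_comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(app_cmp, file.path(cdir, "app_comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(actigraphy = acti_cmp, app = app_cmp),
                         file.path(cdir, "comparisons.json"),
                         dataframe = "rows", digits = NA)
    results$comparisons <- list(actigraphy = acti_cmp, app = app_cmp)
  }

  if ("classify" %in% stages) {
    kdir <- file.path(out, "classification")
    dir.create(kdir, showWarnings = FALSE)
    tasks <- config$tasks %||% c("lifetime_mdd", "non_remission")
    cls <- list()
    for (task in tasks) {
      fm <- assemble_features(results$features, task = task)
      tab <- compare_models(fm, seed = seed)
      utils::write.csv(tab,
                       file.path(kdir, paste0(task, "_models.csv")),
                       row.names = FALSE)
      cls[[task]] <- tab
    }
    jsonlite::write_json(cls, file.path(kdir, "classification.json"),
                         dataframe = "rows", digits = NA)
    results$classification <- cls
  }

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "digimood",
    version = as.character(utils::packageVersion("digimood")),
    seed = seed,
    stages = stages,
    config_hash = config_hash(cfg_for_hash),
    n_subjects = length(cohort))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

# stable config fingerprint: md5 of the canonical (sorted-name) JSON
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}
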