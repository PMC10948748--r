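#' Minute-epoch actigraphy series
#'
#' Container for one subject's epoch-by-epoch activity counts, the basic
#' currency of wrist actigraphy. Timestamps must be uniformly spaced at
#' `epoch_s` seconds and strictly increasing; counts are nonnegative;
#' `off_wrist` flags epochs where the device was not worn (these are
#' excluded from every downstream mean and denominator).
#'
#' @param time POSIXct vector of epoch start times.
#' @param counts Numeric vector of activity counts per epoch.
#' @param off_wrist Logical vector; defaults to all `FALSE`.
#' @param epoch_s Epoch length in seconds (default 60).
#'
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(time, counts, off_wrist = NULL, epoch_s = 60) {
  if (length(time) == 0L) stop("empty epoch series", call. = FALSE)
  if (is.null(off_wrist)) off_wrist <- rep(FALSE, length(time))
  if (length(counts) != length(time) || length(off_wrist) != length(time))
    stop("time, counts and off_wrist must have equal length", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  dt <- diff(as.numeric(time))
  if (length(dt) && (any(dt <= 0) || any(abs(dt - epoch_s) > 1e-6)))
    stop("timestamps must be strictly increasing with uniform spacing ",
         "equal to epoch_s", call. = FALSE)
  structure(
    list(time = time, counts = as.numeric(counts),
         off_wrist = as.logical(off_wrist), epoch_s = epoch_s),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %d epochs of %ds, %s to %s (%.1f days), %d off-wrist\n",
    length(x$counts), x$epoch_s,
    format(x$time[1], "%Y-%m-%d %H:%M", tz = "UTC"),
    format(x$time[length(x$time)], "%Y-%m-%d %H:%M", tz = "UTC"),
    length(x$counts) * x$epoch_s / 86400, sum(x$off_wrist)))
  invisible(x)
}

#' @export
as.data.frame.epoch_series <- function(x, ...) {
  data.frame(timestamp = x$time, counts = x$counts,
             off_wrist = x$off_wrist)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

# Clock time of each epoch in decimal hours [0, 24), UTC.
clock_hours <- function(time) (as.numeric(time) %% 86400) / 3600

# Absolute time in decimal hours (anchored so that h %% 24 is clock time).
abs_hours <- function(time) as.numeric(time) / 3600

valid_epochs <- function(series) !series$off_wrist

#' Read an epoch CSV into a list of epoch series
#'
#' Expects columns `subject_id`, `timestamp` (ISO-8601, UTC), `counts`
#' (nonnegative integer) and `off_wrist` (0/1).
#'
#' @param path CSV file path.
#' @param epoch_s Epoch length in seconds.
#' @return Named list of [epoch_series()], one per subject.
#' @export
read_epochs_csv <- function(path, epoch_s = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "counts", "off_wrist")
  if (!all(need %in% names(df)))
    stop("epochs CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%S")
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$timestamp), ]
    epoch_series(d$timestamp, d$counts, as.logical(d$off_wrist), epoch_s)
  })
  out[unique(df$subject_id)]
}

write_epochs_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id,
               timestamp = format(s$epochs$time, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               counts = s$epochs$counts,
               off_wrist = as.integer(s$epochs$off_wrist))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
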