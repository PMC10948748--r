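# Shared fixture builders and independent brute-force oracles.

T0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")

# epoch series from a plain counts vector
make_series <- function(counts, epoch_s = 60, start = T0,
                        off_wrist = NULL) {
  epoch_series(start + (seq_along(counts) - 1) * epoch_s, counts,
               off_wrist = off_wrist, epoch_s = epoch_s)
}

# hourly series over whole days from a function of clock hour
make_hourly <- function(days, f) {
  tm <- T0 + seq(0, days * 86400 - 3600, 3600)
  make_series(f((as.numeric(tm) / 3600) %% 24), epoch_s = 3600)
}

# deterministic day pattern: high counts except [rest_start, rest_end) h
square_day_series <- function(days, rest_start = 23, rest_end = 31,
                              active = 200, rest = 0, epoch_s = 60) {
  n <- days * 86400 / epoch_s
  tm <- T0 + (seq_len(n) - 1) * epoch_s
  h_abs <- (as.numeric(tm) - as.numeric(T0)) / 3600
  in_rest <- ((h_abs - rest_start) %% 24) < (rest_end - rest_start)
  make_series(ifelse(in_rest, rest, active), epoch_s = epoch_s)
}

# frame track from run-length (voiced?, seconds) pairs
make_track <- function(..., frame_s = 0.01, voiced_db = 70,
                       silent_db = 40) {
  runs <- list(...)
  voiced <- unlist(lapply(runs, function(r)
    rep(r[[1]], round(r[[2]] / frame_s))))
  n <- length(voiced)
  frame_track(times_s = (seq_len(n) - 1) * frame_s,
              f0_hz = ifelse(voiced, 150, 0),
              intensity_db = ifelse(voiced, voiced_db, silent_db),
              voiced = voiced)
}

# ---- independent oracles --------------------------------------------

mobile_oracle <- function(counts, off_wrist) {
  out <- logical(length(counts))
  for (i in seq_along(counts))
    out[i] <- counts[i] >= 4 && !off_wrist[i]
  out
}

is_oracle <- function(x, p) {
  N <- length(x)
  xbar <- mean(x)
  num <- 0
  for (h in 1:p) {
    xh <- mean(x[seq(h, N, by = p)])
    num <- num + (xh - xbar)^2
  }
  den <- 0
  for (i in 1:N) den <- den + (x[i] - xbar)^2
  N * num / (p * den)
}

l5m10_oracle <- function(x, len_h) {
  p <- length(x)
  bins_per_h <- p / 24
  w <- round(len_h * bins_per_h)
  means <- numeric(p)
  for (s in 0:(p - 1)) {
    acc <- 0
    for (j in 0:(w - 1)) acc <- acc + x[((s + j) %% p) + 1]
    means[s + 1] <- acc / w
  }
  list(min = min(means), max = max(means),
       min_mid = ((which.min(means) - 1) / bins_per_h + len_h / 2) %% 24,
       max_mid = ((which.max(means) - 1) / bins_per_h + len_h / 2) %% 24)
}

pause_oracle <- function(track, min_pause_s = 0.3, rel = -25) {
  frame_s <- track$times_s[2] - track$times_s[1]
  silent <- !track$voiced & track$intensity_db < max(track$intensity_db) + rel
  first <- which(!silent)[1]
  last <- max(which(!silent))
  pauses <- NULL
  i <- first
  while (i <= last) {
    if (silent[i]) {
      j <- i
      while (j <= last && silent[j]) j <- j + 1
      if ((j - i) * frame_s >= min_pause_s - 1e-9)
        pauses <- rbind(pauses, c(track$times_s[i],
                                  track$times_s[j - 1] + frame_s))
      i <- j
    } else i <- i + 1
  }
  total <- length(silent) * frame_s
  trimmed <- ((first - 1) + (length(silent) - last)) * frame_s
  pause_s <- if (is.null(pauses)) 0 else sum(pauses[, 2] - pauses[, 1])
  list(n = if (is.null(pauses)) 0L else nrow(pauses),
       pauses = pauses, phonation_s = total - trimmed - pause_s)
}

category_oracle <- function(tokens, lexicon) {
  out <- numeric(length(lexicon))
  names(out) <- names(lexicon)
  for (k in names(lexicon)) {
    hits <- 0
    for (tk in trimws(tokens))
      for (w in lexicon[[k]]) if (tk == w) { hits <- hits + 1; break }
    out[k] <- 100 * hits / length(tokens)
  }
  out
}

cutpoint_oracle <- function(values, labels, criterion) {
  u <- sort(unique(values))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  for (dir in c(">=", "<=")) {
    for (th in cand) {
      pred <- if (dir == ">=") as.integer(values >= th)
              else as.integer(values <= th)
      tp <- sum(pred & labels); fp <- sum(pred & !labels)
      tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
      sens <- if (tp + fn > 0) tp / (tp + fn) else NA
      spec <- if (tn + fp > 0) tn / (tn + fp) else NA
      ppv <- if (tp + fp > 0) tp / (tp + fp) else NA
      sc <- if (criterion == "balanced") sens + spec else sens + ppv
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  best
}

# two well-separated Gaussian clusters (all dimensions shifted) with
# subject ids
separable_fm <- function(n = 40, gap = 8, seed = 60, p = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + gap * y
  rownames(X) <- sprintf("S%03d", seq_len(n))
  list(X = X, y = y)
}

# cohort cache shared across test files (generated once per run)
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n_per_arm, seed, days = 7) {
  key <- paste(n_per_arm, seed, days, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- cohort_config(n_control = n_per_arm, n_mdd = n_per_arm,
                         days = days, seed = seed)
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

cached_features <- function(n_per_arm, seed, days = 7) {
  key <- paste("f", n_per_arm, seed, days, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- suppressWarnings(
      extract_features(cached_cohort(n_per_arm, seed, days)))
  .cohort_cache[[key]]
}
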