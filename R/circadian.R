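# Cosinor and nonparametric circadian rhythm analysis of epoch counts.

#' Single-component 24-h cosinor fit
#'
#' Fits `counts ~ MESOR + A*cos(2*pi*(t - phi)/24)` by ordinary least
#' squares on the linearised design `[1, cos(2*pi*t/24), sin(2*pi*t/24)]`
#' with `t` in decimal clock hours. The MESOR is the rhythm's mean level,
#' the magnitude the fitted peak minus the MESOR, and the acrophase the
#' clock time of the fitted peak. Off-wrist epochs are excluded.
#'
#' @param series An [epoch_series()].
#' @param period_h Rhythm period in hours (default 24).
#' @return Object of class `cosinor_fit`: `mesor`, `magnitude`,
#'   `acrophase_dec_h` (in `[0, 24)`; 0 with `acrophase_defined = FALSE`
#'   for a flat fit), `rss`, `n`.
#' @export
fit_cosinor <- function(series, period_h = 24) {
  keep <- valid_epochs(series)
  y <- series$counts[keep]
  t <- abs_hours(series$time)[keep]
  if (length(y) < 3) stop("need at least 3 valid epochs", call. = FALSE)
  if (diff(range(t)) < period_h)
    stop("series must span at least one period", call. = FALSE)
  w <- 2 * pi * t / period_h
  X <- cbind(1, cos(w), sin(w))
  qrX <- qr(X)
  if (qrX$rank < 3) stop("rank-deficient cosinor design", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  magnitude <- sqrt(beta[2]^2 + beta[3]^2)
  defined <- magnitude > 1e-8
  acro <- if (defined)
    (atan2(beta[3], beta[2]) * period_h / (2 * pi)) %% period_h else 0
  structure(list(mesor = unname(beta[1]), magnitude = unname(magnitude),
                 acrophase_dec_h = unname(acro),
                 acrophase_defined = defined,
                 rss = sum(res^2), n = length(y)),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> MESOR %.2f, magnitude %.2f, acrophase %s (n = %d)\n",
    x$mesor, x$magnitude,
    if (x$acrophase_defined) sprintf("%.2f h", x$acrophase_dec_h)
    else "undefined", x$n))
  invisible(x)
}

#' Average 24-h activity profile
#'
#' Mean counts per clock-time bin across all days; the substrate for the
#' L5/M10 window search. Off-wrist epochs are excluded; bins with no
#' valid epoch are `NA`.
#'
#' @param series An [epoch_series()].
#' @param bin_min Bin width in minutes; must divide 1440.
#' @return List with `bin_min`, `start_h` (bin starts, decimal hours),
#'   `mean_counts`, `n_epochs`.
#' @export
average_profile <- function(series, bin_min = 60) {
  if (1440 %% bin_min != 0)
    stop("bin_min must divide 1440", call. = FALSE)
  if (length(series) * series$epoch_s < 86400)
    stop("series must span at least 24 h", call. = FALSE)
  keep <- valid_epochs(series)
  p <- 1440 %/% bin_min
  bin <- floor(clock_hours(series$time) * 60 / bin_min) %% p
  m <- rep(NA_real_, p)
  cnt <- integer(p)
  agg <- tapply(series$counts[keep], factor(bin[keep], levels = 0:(p - 1)),
                mean)
  nn <- tapply(rep(1L, sum(keep)), factor(bin[keep], levels = 0:(p - 1)),
               sum)
  m[] <- as.numeric(agg)
  cnt[] <- ifelse(is.na(nn), 0L, as.integer(nn))
  list(bin_min = bin_min, start_h = (0:(p - 1)) * bin_min / 60,
       mean_counts = m, n_epochs = cnt)
}

# Sequential non-overlapping bin means plus each bin's clock slot;
# shared substrate for IS and IV.
sequential_bins <- function(series, bin_min) {
  if ((bin_min * 60) %% series$epoch_s != 0)
    stop("bin_min must be a whole number of epochs", call. = FALSE)
  keep <- valid_epochs(series)
  per <- (bin_min * 60) %/% series$epoch_s
  idx <- (seq_len(length(series)) - 1L) %/% per
  x <- tapply(ifelse(keep, series$counts, NA), idx,
              function(v) mean(v, na.rm = TRUE))
  x <- as.numeric(x)
  p <- 1440 %/% bin_min
  first <- tapply(clock_hours(series$time), idx, `[`, 1L)
  slot <- floor(as.numeric(first) * 60 / bin_min) %% p
  ok <- is.finite(x)
  list(x = x[ok], slot = slot[ok], p = p)
}

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average 24-h pattern to the total
#' variance of the binned series: `IS = N * sum_h (xbar_h - xbar)^2 /
#' (p * sum_i (x_i - xbar)^2)` with `p` bins per day and `N` total bins.
#' 1 means a perfectly day-stable rhythm; white noise tends to `1/days`.
#'
#' @param series An [epoch_series()].
#' @param bin_min Bin width in minutes (default 60, the classical
#'   convention).
#' @return IS, or `NA` with a warning for a constant signal.
#' @export
interdaily_stability <- function(series, bin_min = 60) {
  b <- sequential_bins(series, bin_min)
  if (length(b$x) < 2 * b$p)
    stop("need at least 2 days of binned data", call. = FALSE)
  x <- b$x
  N <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) {
    warning("constant signal: IS undefined")
    return(NA_real_)
  }
  hourly <- tapply(x, b$slot, mean)
  N * sum((hourly - xbar)^2) / (b$p * denom)
}

#' Intradaily variability (IV)
#'
#' Fragmentation index: normalised first-difference variance of the
#' binned series, `IV = N * sum (x_i - x_{i-1})^2 /
#' ((N - 1) * sum (x_i - xbar)^2)`. Around 2 for white noise; small for a
#' smooth rhythm; up to 4 for a perfectly alternating signal.
#'
#' @inheritParams interdaily_stability
#' @return IV, or `NA` with a warning for a constant signal.
#' @export
intradaily_variability <- function(series, bin_min = 60) {
  b <- sequential_bins(series, bin_min)
  x <- b$x
  N <- length(x)
  if (N < 2) stop("need at least 2 bins", call. = FALSE)
  denom <- sum((x - mean(x))^2)
  if (denom == 0) {
    warning("constant signal: IV undefined")
    return(NA_real_)
  }
  N * sum(diff(x)^2) / ((N - 1) * denom)
}

#' Least-active 5-h and most-active 10-h windows (L5, M10)
#'
#' Slides 5-h and 10-h windows circularly over the average 24-h profile
#' (1-bin step) and returns the extreme window means and their circular
#' midpoints. Ties are resolved deterministically: for L5 the earliest
#' starting window at or after 12:00 (night-anchored), for M10 the
#' earliest at or after 00:00.
#'
#' @param profile Result of [average_profile()].
#' @param l_h,m_h Window lengths in hours.
#' @return List `L5`, `L5_midpoint_dec_h`, `M10`, `M10_midpoint_dec_h`.
#' @export
l5_m10 <- function(profile, l_h = 5, m_h = 10) {
  x <- profile$mean_counts
  p <- length(x)
  bins_per_h <- p / 24
  pick <- function(len_h, which_extreme, anchor_h) {
    w <- as.integer(round(len_h * bins_per_h))
    means <- vapply(0:(p - 1), function(s) {
      idx <- ((s + 0:(w - 1)) %% p) + 1L
      v <- x[idx]
      if (anyNA(v)) NA_real_ else mean(v)
    }, numeric(1))
    if (all(is.na(means)))
      stop("missing bins inside every candidate window", call. = FALSE)
    target <- if (which_extreme == "min") min(means, na.rm = TRUE)
              else max(means, na.rm = TRUE)
    cand <- which(!is.na(means) & means == target) - 1L  # start bins
    # earliest start at or after the anchor, circularly
    anchor_bin <- anchor_h * bins_per_h
    key <- (cand - anchor_bin) %% p
    s <- cand[which.min(key)]
    mid <- ((s / bins_per_h) + len_h / 2) %% 24
    list(mean = target, mid = mid)
  }
  lo <- pick(l_h, "min", 12)
  hi <- pick(m_h, "max", 0)
  list(L5 = lo$mean, L5_midpoint_dec_h = lo$mid,
       M10 = hi$mean, M10_midpoint_dec_h = hi$mid)
}

#' Relative amplitude (RA)
#'
#' `RA = (M10 - L5) / (M10 + L5)`; lies in `[0, 1]` for nonnegative
#' activity profiles, with 1 meaning complete nocturnal quiescence.
#'
#' @param L5,M10 Window means from [l5_m10()].
#' @return RA, or `NA` with a warning when `M10 + L5 == 0`.
#' @export
relative_amplitude <- function(L5, M10) {
  if (L5 + M10 == 0) {
    warning("M10 + L5 = 0: RA undefined")
    return(NA_real_)
  }
  (M10 - L5) / (M10 + L5)
}

#' All circadian measures for one subject
#'
#' Convenience wrapper returning the cosinor (MESOR, acrophase,
#' magnitude) and nonparametric (IS, IV, L5, M10, their midpoints, RA)
#' measures as one named numeric vector.
#'
#' @param series An [epoch_series()].
#' @param bin_min Bin width for IS/IV and the L5/M10 profile.
#' @return Named numeric vector.
#' @export
circadian_measures <- function(series, bin_min = 60) {
  fit <- fit_cosinor(series)
  is_ <- interdaily_stability(series, bin_min)
  iv <- intradaily_variability(series, bin_min)
  prof <- average_profile(series, bin_min)
  lm10 <- l5_m10(prof)
  c(mesor = fit$mesor, acrophase = fit$acrophase_dec_h,
    magnitude = fit$magnitude, IS = is_, IV = iv,
    L5 = lm10$L5, L5_midpoint = lm10$L5_midpoint_dec_h,
    M10 = lm10$M10, M10_midpoint = lm10$M10_midpoint_dec_h,
    RA = relative_amplitude(lm10$L5, lm10$M10))
}
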