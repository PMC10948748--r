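test_that("cosinor fit recovers an exact sinusoid and matches normal
          equations", {
  es <- make_hourly(7, function(h) 10 + 5 * cos(2 * pi * (h - 15) / 24))
  fit <- fit_cosinor(es)
  expect_equal(fit$mesor, 10, tolerance = 1e-9)
  expect_equal(fit$magnitude, 5, tolerance = 1e-9)
  expect_equal(fit$acrophase_dec_h, 15, tolerance = 1e-9)
  # brute-force normal-equations solution on a noisy toy series
  set.seed(20)
  es2 <- make_hourly(3, function(h) 50 + 20 * cos(2 * pi * (h - 8) / 24))
  es2$counts <- es2$counts + abs(rnorm(length(es2$counts), 0, 5))
  t <- as.numeric(es2$time) / 3600
  X <- cbind(1, cos(2 * pi * t / 24), sin(2 * pi * t / 24))
  beta <- solve(crossprod(X), crossprod(X, es2$counts))
  fit2 <- fit_cosinor(es2)
  expect_equal(fit2$mesor, beta[1], tolerance = 1e-8)
  expect_equal(fit2$magnitude, sqrt(beta[2]^2 + beta[3]^2),
               tolerance = 1e-8)
})

test_that("constant series gives flat fit with undefined acrophase", {
  es <- make_hourly(2, function(h) rep(7, length(h)))
  fit <- fit_cosinor(es)
  expect_equal(fit$mesor, 7)
  expect_equal(fit$magnitude, 0, tolerance = 1e-9)
  expect_false(fit$acrophase_defined)
  expect_equal(fit$acrophase_dec_h, 0)
})

test_that("cosinor preconditions are enforced", {
  short <- make_series(c(1, 2, 3))
  expect_error(fit_cosinor(short), "period")
})

test_that("acrophase shifts with the clock and survives affine count
          changes", {
  f <- function(h) 30 + 10 * cos(2 * pi * (h - 14) / 24)
  es <- make_hourly(4, f)
  fit <- fit_cosinor(es)
  # shifting timestamps by 3 h shifts the acrophase by exactly 3 h
  es_shift <- epoch_series(es$time + 3 * 3600, es$counts, epoch_s = 3600)
  expect_equal(fit_cosinor(es_shift)$acrophase_dec_h,
               (fit$acrophase_dec_h + 3) %% 24, tolerance = 1e-9)
  # IS and IV are invariant to affine count rescaling
  set.seed(21)
  esr <- make_hourly(5, function(h) f(h) + 0)
  esr$counts <- esr$counts + rnorm(length(esr$counts), 0, 3)^2
  esr2 <- epoch_series(esr$time, 7 * esr$counts + 100, epoch_s = 3600)
  expect_equal(interdaily_stability(esr2), interdaily_stability(esr),
               tolerance = 1e-10)
  expect_equal(intradaily_variability(esr2),
               intradaily_variability(esr), tolerance = 1e-10)
})

test_that("average profile is idempotent over identical days and matches
          hand computation", {
  f <- function(h) 5 + h
  es <- make_hourly(3, f)
  prof <- average_profile(es, bin_min = 60)
  expect_equal(prof$mean_counts, f(0:23))
  # 2 days of 6-h epochs, 360-min bins, hand-computed means
  tm <- T0 + seq(0, 2 * 86400 - 21600, 21600)
  es2 <- epoch_series(tm, c(1, 2, 3, 4, 5, 6, 7, 8), epoch_s = 21600)
  prof2 <- average_profile(es2, bin_min = 360)
  expect_equal(prof2$mean_counts, c(3, 4, 5, 6))
  expect_error(average_profile(es, bin_min = 37), "divide")
})

test_that("bins that are entirely off-wrist are flagged missing", {
  off <- rep(FALSE, 48)
  off[seq(3, 48, by = 24)] <- TRUE    # clock hour 2 always off-wrist
  tm <- T0 + seq(0, 2 * 86400 - 3600, 3600)
  es <- epoch_series(tm, rep(10, 48), off_wrist = off, epoch_s = 3600)
  prof <- average_profile(es, bin_min = 60)
  expect_true(is.na(prof$mean_counts[3]))
  expect_equal(prof$n_epochs[3], 0)
})

test_that("IS equals 1 for day-periodic signals and matches a loop oracle", {
  es <- make_hourly(6, function(h) 10 + 8 * sin(2 * pi * h / 24))
  expect_equal(interdaily_stability(es), 1, tolerance = 1e-12)
  set.seed(22)
  x <- rexp(48, 1 / 20)
  es2 <- epoch_series(T0 + seq(0, 48 * 3600 - 3600, 3600), x,
                      epoch_s = 3600)
  expect_equal(interdaily_stability(es2), is_oracle(x, 24),
               tolerance = 1e-12)
})

test_that("IS of white noise concentrates near 1/days", {
  set.seed(23)
  vals <- replicate(60, {
    x <- rnorm(7 * 24, 100, 10)
    es <- epoch_series(T0 + seq(0, 7 * 86400 - 3600, 3600), abs(x),
                       epoch_s = 3600)
    interdaily_stability(es)
  })
  expect_lt(abs(mean(vals) - 1 / 7), 0.02)
})

test_that("IV closed forms: alternating 4, sinusoid 2(1-cos), noise
          2N/(N-1)", {
  alt <- make_hourly(4, function(h) rep(c(1, 9), length.out = length(h)))
  expect_equal(intradaily_variability(alt), 4, tolerance = 1e-12)
  sine <- make_hourly(7, function(h) 40 + 20 * cos(2 * pi * h / 24))
  expect_lt(abs(intradaily_variability(sine) -
                  2 * (1 - cos(2 * pi / 24))), 2e-3)
  set.seed(24)
  N <- 168
  vals <- replicate(200, {
    es <- epoch_series(T0 + seq(0, N * 3600 - 3600, 3600),
                       abs(rnorm(N, 50, 10)), epoch_s = 3600)
    intradaily_variability(es)
  })
  expect_equal(mean(vals), 2 * N / (N - 1), tolerance = 0.05)
})

test_that("constant signals flag IS and IV as undefined", {
  es <- make_hourly(2, function(h) rep(5, length(h)))
  expect_warning(v1 <- interdaily_stability(es), "constant")
  expect_warning(v2 <- intradaily_variability(es), "constant")
  expect_true(is.na(v1) && is.na(v2))
})

test_that("L5/M10 window search: step profile, constant profile, and
          exhaustive oracle", {
  # 100 counts 08:00-22:00, 0 counts 22:00-08:00
  es <- square_day_series(3, rest_start = 22, rest_end = 32, active = 100,
                          epoch_s = 3600)
  prof <- average_profile(es, bin_min = 60)
  w <- l5_m10(prof)
  expect_equal(w$L5, 0)
  expect_equal(w$M10, 100)
  expect_equal(relative_amplitude(w$L5, w$M10), 1)
  # constant profile: L5 = M10, RA = 0, night-anchored L5 tie-break
  profc <- list(bin_min = 60, start_h = 0:23,
                mean_counts = rep(50, 24), n_epochs = rep(10, 24))
  wc <- l5_m10(profc)
  expect_equal(wc$L5, wc$M10)
  expect_equal(relative_amplitude(wc$L5, wc$M10), 0)
  expect_equal(wc$L5_midpoint_dec_h, (12 + 2.5) %% 24)
  expect_equal(wc$M10_midpoint_dec_h, 5)
  # random profiles match the brute-force window oracle
  set.seed(25)
  for (rep in 1:20) {
    x <- runif(24, 0, 300)
    pr <- list(bin_min = 60, start_h = 0:23, mean_counts = x,
               n_epochs = rep(5, 24))
    got <- l5_m10(pr)
    o5 <- l5m10_oracle(x, 5)
    o10 <- l5m10_oracle(x, 10)
    expect_equal(got$L5, o5$min, tolerance = 1e-12)
    expect_equal(got$M10, o10$max, tolerance = 1e-12)
    expect_equal(got$L5_midpoint_dec_h, o5$min_mid, tolerance = 1e-12)
    expect_equal(got$M10_midpoint_dec_h, o10$max_mid, tolerance = 1e-12)
    expect_lte(got$L5, got$M10)
  }
})

test_that("relative amplitude formula and degenerate cases", {
  expect_equal(relative_amplitude(0, 100), 1)
  expect_equal(relative_amplitude(50, 50), 0)
  # magnitudes from a typical patient activity profile
  expect_equal(round(relative_amplitude(19.42, 252.09), 3), 0.857)
  expect_warning(ra <- relative_amplitude(0, 0), "undefined")
  expect_true(is.na(ra))
})
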