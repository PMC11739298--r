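# Signal preprocessing: clipping detection, smoothing/tapering, resampling,
# zero-phase filtering, outlier reconstruction.

test_that("clipping detection flags saturated runs and nothing else", {
  fs <- 200
  x <- sin(2 * pi * 2 * seq(0, 10, by = 1 / fs)) * 50
  rec <- raw_recording(x, fs, input_range_uV = 2e5)
  m0 <- detect_clipping(rec, threshold_frac = 0.999, min_run = 2)
  expect_identical(nrow(m0$events), 0L)

  x[1001:1200] <- 2e5          # 1 s at the positive rail
  rec <- raw_recording(x, fs, input_range_uV = 2e5)
  m <- detect_clipping(rec, threshold_frac = 0.999, min_run = 2)
  expect_identical(nrow(m$events), 1L)
  expect_identical(c(m$events$start, m$events$end), c(1001L, 1200L))
  expect_true(any(epoch_flags(m, 4)))
  expect_error(detect_clipping(raw_recording(numeric(0), fs)), "empty")
})

test_that("detected clipping count matches the generator log", {
  p <- quiet_params(hours = 2)
  p$clipping_rate_per_h <- 2
  h <- simulate_hypnogram(p, seed = 21)
  sr <- synthesize_recording(h, p, seed = 22)
  m <- detect_clipping(sr$recording)
  logged <- sr$truth$events[sr$truth$events$kind == "clipping", ]
  flag <- logical(length(sr$recording$samples))
  for (i in seq_len(nrow(logged))) flag[logged$start[i]:logged$end[i]] <- TRUE
  expect_identical(nrow(m$events), sum(rle(flag)$values))
})

test_that("three-point smoothing and Fermi taper behave as specified", {
  imp <- raw_recording(c(0, 0, 3, 0, 0), 200)
  out <- smooth_and_taper(imp, fermi_edge_frac = 0)
  expect_equal(out$samples, c(0, 1, 1, 1, 0))

  const <- raw_recording(rep(1, 1000), 200)
  tp <- smooth_and_taper(const, fermi_edge_frac = 0.05)$samples
  expect_lt(tp[1], 0.6)                       # edge attenuated toward 0
  expect_equal(tp[500], 1, tolerance = 1e-6)  # interior untouched
  expect_true(all(diff(tp[1:100]) > -1e-12))  # monotone rise
  expect_true(all(diff(tp[901:1000]) < 1e-12))

  set.seed(1)
  x <- rnorm(500)
  sm <- smooth_and_taper(raw_recording(x, 200), fermi_edge_frac = 0)$samples
  ora <- as.numeric(stats::filter(x, rep(1 / 3, 3)))   # convolution oracle
  expect_equal(sm[2:499], ora[2:499])
  expect_equal(sm[1], mean(x[1:2]))
})

test_that("resampling to 200 Hz preserves duration and tone frequency", {
  fs <- 198
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- raw_recording(sin(2 * pi * 5 * t), fs)
  out <- resample_to_200hz(rec)
  expect_identical(length(out$samples), 12000L)
  expect_identical(out$fs, 200)
  tt <- (seq_along(out$samples) - 1) / 200
  sse <- function(f) {
    X <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    sum(stats::lm.fit(X, out$samples)$residuals^2)
  }
  fhat <- stats::optimize(sse, c(4.98, 5.02), tol = 1e-10)$minimum
  expect_lt(abs(fhat - 5), 0.001)

  same <- resample_to_200hz(raw_recording(sin(2 * pi * 5 * (0:999) / 200), 200))
  expect_equal(same$samples, sin(2 * pi * 5 * (0:999) / 200), tolerance = 1e-12)
  expect_error(resample_to_200hz(raw_recording(rnorm(10), 100)), "150")
})

test_that("zero-phase band-pass keeps the pass band and kills both stop bands", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  amp_at <- function(y, f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    cf <- stats::lm.fit(X, y)$coefficients
    sqrt(sum(cf^2))
  }
  # pass band: amplitude within 1%, phase shift < 0.01 rad (measured on the
  # interior, away from the start-up transient of any FIR filter)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_zero_phase(raw_recording(x10, fs))$samples
  int <- t > 10 & t < 50
  cf <- stats::lm.fit(cbind(sin(2 * pi * 10 * t[int]),
                            cos(2 * pi * 10 * t[int])),
                      y10[int])$coefficients
  expect_lt(abs(sqrt(sum(cf^2)) - 1), 0.01)
  expect_lt(abs(atan2(cf[2], cf[1])), 0.01)

  # drift + stop bands attenuated >= 20 dB
  mix <- 5 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t)
  ymix <- bandpass_zero_phase(raw_recording(mix, fs))$samples
  expect_lt(amp_at(ymix, 0.1) / 5, 10^(-20 / 20))
  y45 <- bandpass_zero_phase(raw_recording(sin(2 * pi * 45 * t), fs))$samples
  expect_lt(amp_at(y45, 45), 10^(-20 / 20))

  # zero-phase property: cross-correlation peaks at lag 0
  cc <- stats::ccf(y10[2000:10000], x10[2000:10000], lag.max = 20,
                   plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_zero_phase(raw_recording(rnorm(100), fs),
                                   low_hz = 40, high_hz = 30), "low_hz")
})

test_that("brief NREM outliers are spline-reconstructed, long ones flagged", {
  set.seed(42)
  n_ep <- 30
  # band-limited Gaussian signal (9-point moving average of white noise),
  # matching the smoothness of a filtered EEG trace
  clean <- as.numeric(stats::filter(rnorm(n_ep * 800 + 8, sd = 30),
                                    rep(1 / 9, 9), sides = 2))
  clean <- clean[!is.na(clean)][1:(n_ep * 800)]
  hyp <- hypnogram(rep("NREM", n_ep))
  iqr <- IQR(clean)
  x <- clean
  spike_at <- 4000:4002                     # 3-sample spike at 20x IQR
  x[spike_at] <- 20 * iqr
  long_at <- 12000:12049                    # 50-sample excursion
  x[long_at] <- 15 * iqr
  rec <- clean_recording(raw_recording(x, 200))
  out <- reconstruct_nrem_outliers(rec, hyp)
  # spike repaired close to the pre-injection signal
  rmse <- sqrt(mean((out$recording$samples[spike_at] - clean[spike_at])^2))
  expect_lt(rmse, sd(clean))
  expect_true(all(abs(out$recording$samples[spike_at]) < 8 * iqr * 1.5))
  # long excursion untouched but flagged as a regional artifact
  expect_identical(out$recording$samples[long_at], x[long_at])
  expect_identical(nrow(out$mask$events), 1L)
  expect_identical(out$mask$events$kind, "regional")
  expect_true(epoch_flags(out$mask, 4)[15])  # epoch containing sample 12000

  # no-op when nothing exceeds the threshold
  rec2 <- clean_recording(raw_recording(clean, 200))
  out2 <- reconstruct_nrem_outliers(rec2, hyp)
  expect_identical(out2$recording$samples, clean)

  # idempotence: a second pass flags nothing new on its own output
  again <- reconstruct_nrem_outliers(out$recording, hyp)
  expect_identical(nrow(again$mask$events), 1L)
  expect_equal(again$recording$samples, out$recording$samples,
               tolerance = 1e-8)
})

test_that("the preprocessing stack records its provenance in order", {
  p <- quiet_params(hours = 0.2, fs_native = 198.7)
  h <- simulate_hypnogram(p, seed = 31)
  sr <- synthesize_recording(h, p, seed = 32)
  out <- preprocess_recording(sr$recording, h)
  steps <- vapply(out$recording$provenance, `[[`, "", "step")
  expect_identical(steps, c("smooth_and_taper", "resample_to_200hz",
                            "bandpass_zero_phase",
                            "reconstruct_nrem_outliers"))
  expect_identical(out$recording$fs, 200)
})
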