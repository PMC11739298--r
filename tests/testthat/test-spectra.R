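# Epoch spectra, band power, hourly aggregation, delta gain, NREM metrics.

make_clean <- function(x, zt0 = 0) clean_recording(raw_recording(x, 200,
                                                                 zt0_offset = zt0))

test_that("a pure 2 Hz tone concentrates its relative power at 2 Hz", {
  t <- (0:(800 * 10 - 1)) / 200
  rec <- make_clean(sin(2 * pi * 2 * t) * 40)
  hyp <- hypnogram(rep("NREM", 10))
  sp <- epoch_spectra(rec, hyp)
  expect_equal(dim(sp$power), c(10, 119))
  expect_equal(rowSums(sp$power), rep(100, 10), tolerance = 1e-9)
  near2 <- sp$freq >= 1.75 & sp$freq <= 2.25
  expect_true(all(rowSums(sp$power[, near2]) >= 95))
  expect_true(all(band_power(sp, c(0.5, 4)) >= 95))
})

test_that("white noise yields a flat relative spectrum", {
  set.seed(8)
  rec <- make_clean(rnorm(800 * 200))
  hyp <- hypnogram(rep("NREM", 200))
  sp <- epoch_spectra(rec, hyp)
  mu <- colMeans(sp$power)
  se <- apply(sp$power, 2, sd) / sqrt(nrow(sp$power))
  expect_true(all(abs(mu - 100 / 119) <= 5 * se))
})

test_that("band power is additive over a partition and totals 100%", {
  set.seed(9)
  rec <- make_clean(rnorm(800 * 5))
  hyp <- hypnogram(rep("NREM", 5))
  sp <- epoch_spectra(rec, hyp)
  expect_equal(band_power(sp, c(0.5, 30)), rep(100, 5), tolerance = 1e-9)
  expect_equal(band_power(sp, c(0.5, 4)) + band_power(sp, c(4.25, 30)),
               rep(100, 5), tolerance = 1e-9)
  expect_error(band_power(sp, c(0.6, 4)), "grid")
  expect_error(band_power(sp, c(0.5, 31)), "grid")
})

test_that("artifact epochs and flagged windows never contribute", {
  set.seed(10)
  x <- rnorm(800 * 6)
  hyp <- hypnogram(c("NREM", "NREM", "ARTIFACT", "NREM", "WAKE", "NREM"))
  mask <- artifact_mask(data.frame(start = 801L, end = 1600L,
                                   kind = "clipping"), length(x), 200)
  sp <- epoch_spectra(make_clean(x), hyp, mask)
  expect_true(sp$artifact[2])   # fully flagged epoch
  expect_true(sp$artifact[3])   # scorer artifact
  hb <- hourly_state_band_power(sp, min_epochs = 1)
  expect_identical(hb$n_epochs, 3L)  # epochs 1, 4, 6 only
})

test_that("hourly aggregation averages qualifying epochs and reports gaps", {
  # construct spectra object directly: constant 50% delta in NREM
  freq <- seq(0.5, 30, 0.25)
  pow <- matrix(rep(c(rep(50 / 15, 15), rep(50 / 104, 104)), 1800),
                1800, 119, byrow = TRUE)
  sp <- structure(list(power = pow, freq = freq,
                       state = rep(c("NREM", "WAKE"), 900),
                       zt = (seq_len(1800) - 0.5) * 4 / 3600,
                       artifact = rep(FALSE, 1800), epoch_len_s = 4),
                  class = "epoch_spectra")
  hb <- hourly_state_band_power(sp)
  expect_equal(hb$mean_rel_power, c(50, 50), tolerance = 1e-9)
  expect_identical(hb$n_epochs, c(450L, 450L))
  sp$state[sp$zt > 1] <- "WAKE"          # second hour has no NREM
  hb2 <- hourly_state_band_power(sp)
  expect_true(is.na(hb2$mean_rel_power[2]))
})

test_that("delta gain is the per-hour difference with the 9+10 summary", {
  hb <- function(vals, n = 450) data.frame(
    zt_hour = seq_along(vals) - 1, state = "NREM", low_hz = 0.5,
    high_hz = 4, mean_rel_power = vals, n_epochs = n)
  base <- hb(rep(45, 12))
  trt <- hb(rep(55, 12))
  g <- delta_gain(trt, base)
  expect_equal(g$gain_pp, rep(10, 12))
  expect_equal(gain_summary(g), 10)
  expect_equal(gain_summary(delta_gain(trt, base, summary_fun = "sum")), 20)
  g0 <- delta_gain(base, base)
  expect_equal(g0$gain_pp, rep(0, 12))
  # antisymmetry
  ga <- delta_gain(trt, base); gb <- delta_gain(base, trt)
  expect_equal(ga$gain_pp, -gb$gain_pp)
  # hours below the epoch minimum drop out
  base$n_epochs[3] <- 5
  g2 <- delta_gain(trt, base, min_epochs = 15)
  expect_false(2 %in% g2$zt_hour)
  expect_error(delta_gain(trt[0, ], base), "share no")
})

test_that("NREM time metrics difference and coverage checks", {
  h1 <- hypnogram(rep(c("NREM", "WAKE"), 50))
  expect_equal(nrem_time_metrics(h1, h1)$delta_nrem_pp, 0)
  h2 <- hypnogram(c(rep("NREM", 45), rep("WAKE", 55)))
  h3 <- hypnogram(c(rep("NREM", 40), rep("WAKE", 60)))
  m <- nrem_time_metrics(h3, h2)
  expect_equal(m$baseline_pct, 40)
  expect_equal(m$treatment_pct, 45)
  expect_equal(m$delta_nrem_pp, 5)
  expect_error(nrem_time_metrics(h1, hypnogram(rep("NREM", 10))), "duration")
  # artifact epochs excluded from the scored denominator
  h4 <- hypnogram(c(rep("NREM", 40), rep("WAKE", 40), rep("ARTIFACT", 20)))
  expect_equal(nrem_time_metrics(h4, h4)$baseline_pct, 50)
})

test_that("null cohorts keep the NREM-change ANOVA at its nominal level", {
  rejections <- vapply(1:20, function(s) {
    des <- cohort_design(c(3, 3, 3, 3))
    p <- quiet_params(hours = 24)
    d <- vapply(seq_len(nrow(des)), function(i) {
      hb <- simulate_hypnogram(p, seed = s * 1000 + i)
      ht <- simulate_hypnogram(p, seed = s * 1000 + 500 + i)
      nrem_time_metrics(hb, ht)$delta_nrem_pp
    }, 0)
    a <- two_way_anova(d, des$genotype, des$treatment)
    any(a$effects$p < 0.05)
  }, NA)
  # three tests per seed at alpha = .05 -> family rate ~ .14; 20 draws
  # should stay well under half rejecting
  expect_lt(mean(rejections), 0.45)
})

test_that("synthetic recordings reproduce their ground-truth hourly delta", {
  p <- quiet_params(hours = 2)
  h <- simulate_hypnogram(p, seed = 61)
  sr <- synthesize_recording(h, p, seed = 62)
  pp <- preprocess_recording(sr$recording, h)
  sp <- epoch_spectra(pp$recording, h, pp$mask)
  hb <- hourly_state_band_power(sp)
  expect_equal(hb$mean_rel_power, sr$truth$hourly$true_nrem_delta,
               tolerance = 0.05)  # within a few p.p. (relative tolerance)
  expect_true(all(abs(hb$mean_rel_power -
                        sr$truth$hourly$true_nrem_delta) < 4))
})
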