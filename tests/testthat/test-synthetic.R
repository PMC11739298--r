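# Synthetic-data generator: hypnograms, recordings, cohorts, masks.

test_that("simulated hypnogram matches the stationary state occupancy", {
  p <- quiet_params(hours = 24)
  h <- simulate_hypnogram(p, seed = 42)
  expect_length(h$labels, 21600)
  nrem_frac <- mean(h$labels == "NREM")
  expect_lt(abs(nrem_frac - stationary_nrem_fraction(p$state_dwell_means_s)),
            0.05)
  # REM entered only from NREM
  lab <- as.character(h$labels)
  entries <- which(lab[-1] == "REM" & lab[-length(lab)] != "REM")
  expect_true(all(lab[entries] == "NREM"))
})

test_that("hypnogram edge cases: empty recording, determinism, bad params", {
  p0 <- quiet_params(hours = 0)
  expect_length(simulate_hypnogram(p0, seed = 1)$labels, 0)
  p <- quiet_params(hours = 2)
  expect_identical(simulate_hypnogram(p, seed = 7)$labels,
                   simulate_hypnogram(p, seed = 7)$labels)
  expect_false(identical(simulate_hypnogram(p, seed = 7)$labels,
                         simulate_hypnogram(p, seed = 8)$labels))
  expect_error(sim_params(state_dwell_means_s = c(WAKE = -1, NREM = 240,
                                                  REM = 60)), "positive")
  expect_error(sim_params(fs_native = 100), "150")
})

test_that("injected clipping events are exactly recoverable by scanning", {
  p <- quiet_params(hours = 2)
  p$clipping_rate_per_h <- 2
  h <- simulate_hypnogram(p, seed = 3)
  sr <- synthesize_recording(h, p, seed = 4)
  logged <- sr$truth$events[sr$truth$events$kind == "clipping", ]
  x <- sr$recording$samples
  runs <- rle(abs(x) >= p$input_range_uV)
  found <- sum(runs$values & runs$lengths >= 2)
  # events may merge if two injections overlap; count distinct logged runs
  flag <- logical(length(x))
  for (i in seq_len(nrow(logged))) flag[logged$start[i]:logged$end[i]] <- TRUE
  expect_equal(found, sum(rle(flag)$values))
  expect_true(all(logged$end <= length(x)))
})

test_that("NREM epochs carry more relative delta power than wake", {
  p <- quiet_params(hours = 2)
  h <- simulate_hypnogram(p, seed = 5)
  sr <- synthesize_recording(h, p, seed = 6)
  spe <- round(4 * p$fs_native)
  lab <- as.character(h$labels)
  pick <- function(state) head(which(lab == state), 50)
  rel <- function(e) oracle_rel_delta(
    sr$recording$samples[((e - 1) * spe + 1):(e * spe)], p$fs_native)
  d_n <- vapply(pick("NREM"), rel, 0)
  d_w <- vapply(pick("WAKE"), rel, 0)
  expect_lt(t.test(d_w, d_n, alternative = "less")$p.value, 1e-6)
})

test_that("recording synthesis is deterministic and honours ground truth", {
  p <- quiet_params(hours = 1, effect = 8, admin = 0.25)
  h <- simulate_hypnogram(p, seed = 1)
  a <- synthesize_recording(h, p, seed = 9)
  b <- synthesize_recording(h, p, seed = 9)
  expect_identical(a$recording$samples, b$recording$samples)
  tr <- a$truth$epochs
  # effect decays from the administration time
  post <- tr$state == "NREM" & tr$zt > 0.25
  expect_true(all(tr$injected_gain_pp[post] > 0))
  expect_true(all(diff(tr$injected_gain_pp[post]) <= 1e-9))
  expect_true(all(tr$true_rel_delta[post] >
                    a$truth$baseline_nrem_delta - 1e-9))
})

test_that("cohort bundles are deterministic and reject empty cells", {
  des <- cohort_design(c(2, 2, 2, 2))
  p <- quiet_params(hours = 0.1)
  b1 <- simulate_cohort(des, p, seed = 11, modalities = c("tmaze", "elisa"))
  b2 <- simulate_cohort(des, p, seed = 11, modalities = c("tmaze", "elisa"))
  expect_identical(b1$tmaze, b2$tmaze)
  expect_identical(b1$elisa, b2$elisa)
  bad <- des[des$genotype == "WT" | des$treatment == "SO", ]
  expect_error(simulate_cohort(bad, p, seed = 1, modalities = "tmaze"),
               "cell")
})

test_that("behavioural draws regenerate the early-cohort group separation", {
  # groups drawn at the configured means/SDs should centre the Welch t on
  # its generating value
  des <- cohort_design(c(18, 2, 17, 2))  # placebo cells carry the printed ns
  ts <- vapply(1:200, function(s) {
    b <- simulate_cohort(des, quiet_params(hours = 0.1), seed = s,
                         modalities = "tmaze")
    tg <- b$tmaze$percent_baseline[b$tmaze$genotype == "Tg2576" &
                                     b$tmaze$treatment == "placebo"]
    wt <- b$tmaze$percent_baseline[b$tmaze$genotype == "WT" &
                                     b$tmaze$treatment == "placebo"]
    abs(independent_t(tg, wt, variant = "welch")$t)
  }, 0)
  expect_lt(abs(mean(ts) - 4.884), 0.2)
})

test_that("plaque mask simulation hits the target fraction with exact truth", {
  z <- simulate_plaque_mask(400, 400, um_per_pixel = 1, target_fraction = 0,
                            seed = 1)
  expect_identical(z$true_fraction, 0)
  expect_false(any(z$mask$plaque))
  m <- simulate_plaque_mask(2000, 2000, um_per_pixel = 1,
                            target_fraction = 0.10, n_plaques = 30, seed = 2)
  expect_lt(abs(m$true_fraction - 0.10), 0.02)
  expect_identical(m$true_fraction,
                   sum(m$mask$plaque & m$mask$roi) / sum(m$mask$roi))
  # determinism
  m2 <- simulate_plaque_mask(2000, 2000, um_per_pixel = 1,
                             target_fraction = 0.10, n_plaques = 30, seed = 2)
  expect_identical(m$mask$plaque, m2$mask$plaque)
})

test_that("null injected effect leaves no measurable mean delta gain", {
  gains <- vapply(1:10, function(s) {
    p <- quiet_params(hours = 1)
    h <- simulate_hypnogram(p, seed = 100 + s)
    tr <- synthesize_recording(h, p, seed = 200 + s)
    bl <- synthesize_recording(h, p, seed = 300 + s)
    f <- function(rec) {
      pp <- preprocess_recording(rec, h)
      hourly_state_band_power(epoch_spectra(pp$recording, h, pp$mask))
    }
    g <- delta_gain(f(tr$recording), f(bl$recording), summary_hours = 0,
                    min_epochs = 5)
    gain_summary(g)
  }, 0)
  se <- sd(gains) / sqrt(length(gains))
  expect_lt(abs(mean(gains)), 4 * se + 0.05)
})
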