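# Per-epoch relative power spectra (Hamming-window FFT, 2-s overlap,
# 0.25 Hz resolution), band power, hourly aggregation on the ZT axis,
# delta-activity gain versus baseline, and NREM time metrics.

#' Per-epoch normalised power spectra
#'
#' Computes, for every scored 4-s epoch, a power spectrum from 4-s
#' Hamming-windowed segments advanced by 2 s (each epoch averages the
#' segments whose centres fall inside it), restricted to 0.5-30 Hz at
#' 0.25 Hz resolution (119 bins) and normalised so each epoch's bins sum to
#' 100% of total 0.5-30 Hz power. Epochs labelled `ARTIFACT`, and segments
#' containing any sample flagged in `mask`, are excluded; an epoch with no
#' clean segment gets `NA` power and an artifact flag.
#'
#' @param rec A [clean_recording()] at 200 Hz.
#' @param hyp The aligned [hypnogram()].
#' @param mask Optional [artifact_mask()] at 200 Hz (e.g. from
#'   [preprocess_recording()]); flagged segments are dropped.
#' @return An object of class `epoch_spectra`: list with `power` (epochs x
#'   119 matrix, rows summing to 100), `freq` (0.5-30 Hz grid), `state`,
#'   `zt` (epoch midpoints, hours), and logical `artifact`.
#' @export
epoch_spectra <- function(rec, hyp, mask = NULL) {
  stopifnot(inherits(rec, "raw_recording"), inherits(hyp, "hypnogram"))
  if (abs(rec$fs - 200) > 1e-9) stop_user("epoch spectra require a 200 Hz recording")
  spe <- as.integer(hyp$epoch_len_s * rec$fs)        # 800
  step <- spe %/% 2                                  # 400 (2 s)
  n <- length(rec$samples)
  n_ep <- min(length(hyp), n %/% spe)
  if (n_ep < 1) stop_user("recording shorter than one epoch; misaligned hypnogram?")
  n_win <- 2L * n_ep - 1L
  win <- as.numeric(signal::hamming(spe))
  starts <- (seq_len(n_win) - 1L) * step
  seg <- matrix(rec$samples[outer(seq_len(spe), starts, `+`)], nrow = spe)
  P <- abs(stats::mvfft(seg * win))^2
  freq <- seq(0.5, 30, by = 0.25)
  bins <- 1L + seq(2L, 120L)                         # FFT rows for 0.5..30 Hz
  P <- P[bins, , drop = FALSE]

  win_ok <- rep(TRUE, n_win)
  if (!is.null(mask) && nrow(mask$events)) {
    bad <- sample_mask(mask)[seq_len(n)]
    bad_cum <- cumsum(bad)
    ends <- starts + spe
    win_ok <- (bad_cum[pmin(ends, n)] - c(0, bad_cum)[starts + 1L]) == 0
  }

  pow <- matrix(NA_real_, n_ep, length(freq))
  art <- as.character(hyp$labels[seq_len(n_ep)]) == "ARTIFACT"
  for (j in seq_len(n_ep)) {
    w <- c(2L * j - 2L, 2L * j - 1L)                 # windows centred in epoch j
    w <- w[w >= 1L & w <= n_win & win_ok[pmax(w, 1L)]]
    if (!length(w) || art[j]) next
    s <- rowMeans(P[, w, drop = FALSE])
    pow[j, ] <- 100 * s / sum(s)
  }
  art <- art | apply(pow, 1, function(r) all(is.na(r)))
  structure(list(power = pow, freq = freq,
                 state = as.character(hyp$labels[seq_len(n_ep)]),
                 zt = epoch_zt(hyp)[seq_len(n_ep)],
                 artifact = art,
                 epoch_len_s = hyp$epoch_len_s),
            class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat(sprintf("Epoch spectra: %d epochs x %d bins (%.2f-%.2f Hz), %d artifact\n",
              nrow(x$power), ncol(x$power), min(x$freq), max(x$freq),
              sum(x$artifact)))
  invisible(x)
}

#' Relative power in a frequency band
#'
#' Sums relative power over the 0.25 Hz bins falling in `[low, high]`
#' (both edges inclusive). Band edges must lie on the analysis grid.
#'
#' @param spec An [epoch_spectra()] object or a single 119-bin vector.
#' @param band Numeric length-2, band edges in Hz within 0.5-30.
#' @return Percentage per epoch (vector), or a scalar for a single spectrum.
#' @export
band_power <- function(spec, band = c(0.5, 4)) {
  freq <- if (inherits(spec, "epoch_spectra")) spec$freq else seq(0.5, 30, 0.25)
  if (length(band) != 2 || band[1] > band[2] ||
      band[1] < min(freq) || band[2] > max(freq) ||
      any(abs(band / 0.25 - round(band / 0.25)) > 1e-9)) {
    stop_user("band edges must lie on the 0.25 Hz grid within 0.5-30 Hz")
  }
  sel <- freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9
  if (inherits(spec, "epoch_spectra")) {
    rowSums(spec$power[, sel, drop = FALSE])
  } else {
    sum(spec[sel])
  }
}

#' Hourly mean band power per vigilance state
#'
#' Unweighted mean of per-epoch relative band power over non-artifact epochs
#' of the requested state, binned by ZT hour (hour `h` covers `[h, h+1)`).
#' Hours without qualifying epochs are reported as missing.
#'
#' @param spectra An [epoch_spectra()] object.
#' @param state Vigilance state to aggregate (default `"NREM"`).
#' @param band Frequency band in Hz (default delta, 0.5-4).
#' @param min_epochs Minimum qualifying epochs for an hour to be reported.
#' @return Data frame: `zt_hour`, `state`, `low_hz`, `high_hz`,
#'   `mean_rel_power`, `n_epochs`.
#' @export
hourly_state_band_power <- function(spectra, state = "NREM",
                                    band = c(0.5, 4), min_epochs = 1) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  bp <- band_power(spectra, band)
  hr <- floor(spectra$zt)
  ok <- spectra$state == state & !spectra$artifact & !is.na(bp)
  hours <- sort(unique(hr))
  mean_p <- vapply(hours, function(h) {
    i <- ok & hr == h
    if (sum(i) >= min_epochs) mean(bp[i]) else NA_real_
  }, 0)
  n_ep <- vapply(hours, function(h) sum(ok & hr == h), 0L)
  data.frame(zt_hour = hours, state = state,
             low_hz = band[1], high_hz = band[2],
             mean_rel_power = mean_p, n_epochs = n_ep)
}

#' Delta-activity gain versus baseline
#'
#' Per-ZT-hour difference (treatment minus baseline) in mean NREM relative
#' delta power, in percentage points, with a summary scalar over the hours
#' following the second administration (by default the mean of hours 9 and
#' 10 after lights-on). Hours missing, or with fewer than `min_epochs`
#' qualifying epochs on either day, are dropped.
#'
#' @param treatment,baseline Hourly tables from
#'   [hourly_state_band_power()] for the treatment and baseline day.
#' @param summary_hours ZT hours entering the summary (default `c(9, 10)`).
#' @param summary_fun `"mean"` (default) or `"sum"` over the summary hours.
#' @param min_epochs Minimum epochs per hour on both days (default 15,
#'   i.e. one minute of NREM).
#' @return Object of class `delta_gain_series`: data frame (`zt_hour`,
#'   `gain_pp`, `n_treatment`, `n_baseline`) with attribute `summary`.
#' @export
delta_gain <- function(treatment, baseline, summary_hours = c(9, 10),
                       summary_fun = c("mean", "sum"), min_epochs = 15) {
  summary_fun <- match.arg(summary_fun)
  m <- merge(treatment, baseline, by = "zt_hour",
             suffixes = c("_tr", "_bl"))
  if (!nrow(m)) stop_user("treatment and baseline days share no ZT hours")
  keep <- !is.na(m$mean_rel_power_tr) & !is.na(m$mean_rel_power_bl) &
    m$n_epochs_tr >= min_epochs & m$n_epochs_bl >= min_epochs
  out <- data.frame(zt_hour = m$zt_hour[keep],
                    gain_pp = m$mean_rel_power_tr[keep] -
                      m$mean_rel_power_bl[keep],
                    n_treatment = m$n_epochs_tr[keep],
                    n_baseline = m$n_epochs_bl[keep])
  sh <- out$gain_pp[out$zt_hour %in% summary_hours]
  summ <- if (length(sh) == length(summary_hours)) {
    if (summary_fun == "mean") mean(sh) else sum(sh)
  } else NA_real_
  structure(out, class = c("delta_gain_series", "data.frame"),
            summary = summ, summary_hours = summary_hours,
            summary_fun = summary_fun)
}

#' @export
print.delta_gain_series <- function(x, ...) {
  cat(sprintf("Delta-activity gain over %d ZT hours; summary (%s of ZT %s): %s p.p.\n",
              nrow(x), attr(x, "summary_fun"),
              paste(attr(x, "summary_hours"), collapse = ","),
              format(round(attr(x, "summary"), 2))))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname delta_gain
#' @param x A `delta_gain_series`.
#' @export
gain_summary <- function(x) attr(x, "summary")

#' NREM time metrics across recording days
#'
#' Time spent in NREM as a percentage of total scored (non-artifact) time
#' for the baseline and treatment day, and their difference in percentage
#' points.
#'
#' @param hyp_baseline,hyp_treatment Aligned [hypnogram()]s of equal
#'   coverage.
#' @return List: `baseline_pct`, `treatment_pct`, `delta_nrem_pp`.
#' @export
nrem_time_metrics <- function(hyp_baseline, hyp_treatment) {
  stopifnot(inherits(hyp_baseline, "hypnogram"),
            inherits(hyp_treatment, "hypnogram"))
  if (length(hyp_baseline) != length(hyp_treatment)) {
    stop_user("baseline and treatment hypnograms must cover the same duration")
  }
  pct <- function(h) {
    sc <- h$labels != "ARTIFACT"
    100 * sum(h$labels == "NREM") / sum(sc)
  }
  b <- pct(hyp_baseline); t <- pct(hyp_treatment)
  list(baseline_pct = b, treatment_pct = t, delta_nrem_pp = t - b)
}
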