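# EEG post-processing stack: clipping detection -> smoothing/taper ->
# resampling to 200 Hz -> zero-phase equiripple band-pass -> spline
# reconstruction of brief NREM outliers. Order is fixed; every step writes
# its parameters into the recording's provenance.

#' Artifact mask
#'
#' Event list (sample start/end, kind) over a recording, with helpers to
#' expand to a per-sample logical mask or per-epoch flags.
#'
#' @param events Data frame with integer columns `start`, `end` and a
#'   character `kind` (`"clipping"`, `"regional"` or `"spike"`).
#' @param n_samples Length of the masked signal.
#' @param fs Sampling rate the sample indices refer to.
#' @return An object of class `artifact_mask`.
#' @export
artifact_mask <- function(events, n_samples, fs) {
  if (nrow(events)) {
    if (any(events$start < 1 | events$end > n_samples | events$end < events$start)) {
      stop_user("artifact events must lie within the recording")
    }
  }
  structure(list(events = events, n_samples = n_samples, fs = fs),
            class = "artifact_mask")
}

#' @rdname artifact_mask
#' @param mask An `artifact_mask`.
#' @export
sample_mask <- function(mask) {
  m <- logical(mask$n_samples)
  for (i in seq_len(nrow(mask$events))) {
    m[mask$events$start[i]:mask$events$end[i]] <- TRUE
  }
  m
}

#' @rdname artifact_mask
#' @param epoch_len_s Epoch length in seconds.
#' @export
epoch_flags <- function(mask, epoch_len_s = 4) {
  n_ep <- ceiling(mask$n_samples / (epoch_len_s * mask$fs))
  fl <- logical(n_ep)
  for (i in seq_len(nrow(mask$events))) {
    e1 <- floor((mask$events$start[i] - 1) / (epoch_len_s * mask$fs)) + 1
    e2 <- floor((mask$events$end[i] - 1) / (epoch_len_s * mask$fs)) + 1
    fl[e1:min(e2, n_ep)] <- TRUE
  }
  fl
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("Artifact mask: %d events over %d samples @ %g Hz\n",
              nrow(x$events), x$n_samples, x$fs))
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}

#' Detect clipping (ADC saturation) events
#'
#' Flags maximal runs of at least `min_run` consecutive samples whose
#' magnitude reaches `threshold_frac` of the input range. Saturation at the
#' digitiser rails is the physical definition of a clipping artifact; epochs
#' containing any flagged sample are excluded from spectral analysis
#' downstream.
#'
#' @param rec A [raw_recording()].
#' @param threshold_frac Fraction of the input range treated as saturated
#'   (default 0.999).
#' @param min_run Minimum run length in samples (default 2).
#' @return An [artifact_mask()] with events of kind `"clipping"`.
#' @export
detect_clipping <- function(rec, threshold_frac = 0.999, min_run = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!length(rec$samples)) stop_user("empty signal")
  if (threshold_frac <= 0 || threshold_frac > 1) {
    stop_user("`threshold_frac` must be in (0, 1]")
  }
  if (min_run < 1) stop_user("`min_run` must be >= 1")
  thr <- threshold_frac * rec$input_range_uV
  runs <- true_runs(abs(rec$samples) >= thr)
  keep <- (runs[, "end"] - runs[, "start"] + 1) >= min_run
  events <- data.frame(start = runs[keep, "start"], end = runs[keep, "end"],
                       kind = rep("clipping", sum(keep)))
  artifact_mask(events, length(rec$samples), rec$fs)
}

# Fermi-Dirac taper for a segment of length L: ~0.5 at the segment boundary,
# rising to 1 over `edge_frac` of the segment at each end.
fermi_taper <- function(L, edge_frac) {
  if (edge_frac <= 0 || L < 2) return(rep(1, L))
  w <- max(1, edge_frac * L)
  temp <- w / 8
  d_left <- (seq_len(L) - 0.5)
  d_right <- (L - seq_len(L) + 0.5)
  1 / (1 + exp(-d_left / temp)) / (1 + exp(-d_right / temp))
}

#' Three-point smoothing and Fermi-window tapering
#'
#' Replaces each sample with the mean of itself and its two neighbours
#' (shrinking window at the ends), zeroes artifact samples, and applies a
#' Fermi-Dirac-shaped taper to each contiguous artifact-free segment so the
#' signal rolls smoothly to zero at segment edges. Tapering confines the
#' spectral footprint of excised artifacts before filtering.
#'
#' @param rec A [raw_recording()].
#' @param mask Optional [artifact_mask()]; flagged samples are zeroed and
#'   segment boundaries placed around them.
#' @param fermi_edge_frac Taper roll-off width as a fraction of segment
#'   length (default 0.01; 0 disables tapering).
#' @return A smoothed, tapered [raw_recording()].
#' @export
smooth_and_taper <- function(rec, mask = NULL, fermi_edge_frac = 0.01) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$samples
  n <- length(x)
  if (n < 3) stop_user("signal too short to smooth (need >= 3 samples)")
  bad <- if (is.null(mask)) logical(n) else sample_mask(mask)
  x[bad] <- 0
  sm <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(x[1:2])
  sm[n] <- mean(x[(n - 1):n])
  if (fermi_edge_frac > 0) {
    segs <- true_runs(!bad)
    for (i in seq_len(nrow(segs))) {
      a <- segs[i, "start"]; b <- segs[i, "end"]
      sm[a:b] <- sm[a:b] * fermi_taper(b - a + 1, fermi_edge_frac)
    }
  }
  rec$samples <- sm
  add_provenance(rec, "smooth_and_taper",
                 list(fermi_edge_frac = fermi_edge_frac,
                      n_artifact_samples = sum(bad)))
}

# FFT-based (trigonometric) resampling: exact for band-limited content.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nh <- min(floor(n / 2), floor(n_out / 2))
  Y[1] <- X[1]
  if (nh >= 1) {
    Y[2:(nh + 1)] <- X[2:(nh + 1)]
    Y[n_out - (1:nh) + 1] <- X[n - (1:nh) + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n)
}

#' Resample a recording to exactly 200 Hz
#'
#' Uses Fourier-domain (trigonometric) interpolation, which preserves the
#' amplitude and frequency of all components below the output Nyquist
#' exactly; sampling rates within [150, 250] Hz are accepted. The output
#' length is `round(n * 200 / fs)`, preserving duration.
#'
#' @param rec A [raw_recording()].
#' @return A [raw_recording()] with `fs = 200`.
#' @export
resample_to_200hz <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs < 150 || rec$fs > 250) {
    stop_user("sampling rate must lie within [150, 250] Hz")
  }
  if (abs(rec$fs - 200) > 1e-12) {
    n_out <- round(length(rec$samples) * 200 / rec$fs)
    rec$samples <- fft_resample(rec$samples, n_out)
  }
  fs_in <- rec$fs
  rec$fs <- 200
  add_provenance(rec, "resample_to_200hz", list(fs_in = fs_in))
}

# --- equiripple FIR design ---------------------------------------------------

.filter_cache <- new.env(parent = emptyenv())

#' Default equiripple FIR design parameters
#'
#' High-pass transition 0.25-0.5 Hz (1600 taps) and low-pass transition
#' 30-33 Hz (260 taps). Attenuation and ripple requirements apply to the
#' filter as used, i.e. the forward-backward (zero-phase) cascade, whose
#' response is the squared magnitude of the single-pass design; the defaults
#' achieve about 56 dB stop-band attenuation and 0.06 dB (< 1%) pass-band
#' ripple for the high-pass cascade. Achieved responses are verified at
#' design time and an error is raised when a requested spec cannot be met.
#'
#' @param hp_order,lp_order Filter orders (number of taps minus one).
#' @param hp_trans,lp_trans Transition bands in Hz.
#' @param hp_weight,lp_weight Remez band weights (stop/pass order as in the
#'   band specification).
#' @param min_stop_db Required stop-band attenuation of the zero-phase
#'   cascade (dB).
#' @param max_pass_ripple_db Allowed pass-band ripple of the zero-phase
#'   cascade (dB).
#' @return A named list of design parameters.
#' @export
fir_design_params <- function(hp_order = 1600, lp_order = 260,
                              hp_trans = c(0.25, 0.5), lp_trans = c(30, 33),
                              hp_weight = c(0.08, 1), lp_weight = c(1, 3),
                              min_stop_db = 40, max_pass_ripple_db = 0.5) {
  list(hp_order = hp_order, lp_order = lp_order, hp_trans = hp_trans,
       lp_trans = lp_trans, hp_weight = hp_weight, lp_weight = lp_weight,
       min_stop_db = min_stop_db, max_pass_ripple_db = max_pass_ripple_db)
}

# Design and verify one remez kernel. type "high" or "low"; trans in Hz.
design_fir <- function(type, order, trans, weight, fs, min_stop_db,
                       max_pass_ripple_db) {
  ny <- fs / 2
  bands <- if (type == "high") c(0, trans[1], trans[2], ny) / ny
           else c(0, trans[1], trans[2], ny) / ny
  amps <- if (type == "high") c(0, 0, 1, 1) else c(1, 1, 0, 0)
  b <- tryCatch(signal::remez(order, bands, amps, w = weight),
                error = function(e) stop_user(
                  sprintf("equiripple design failed (%s-pass, order %d): %s",
                          type, order, conditionMessage(e))))
  H <- signal::freqz(b, Fs = fs, n = 16384)
  mag <- abs(H$h); f <- H$f
  if (type == "high") {
    stop_db <- -20 * log10(max(mag[f <= trans[1]]))
    ripple <- max(abs(20 * log10(mag[f >= trans[2] & f <= ny * 0.99])))
  } else {
    stop_db <- -20 * log10(max(mag[f >= trans[2]]))
    ripple <- max(abs(20 * log10(mag[f <= trans[1] & f >= 0.01])))
  }
  stop_db <- 2 * stop_db          # forward-backward application
  ripple <- 2 * ripple
  if (stop_db < min_stop_db || ripple > max_pass_ripple_db) {
    stop_user(sprintf(
      "FIR design spec not met (%s-pass): %.1f dB stop (need %.1f), %.3f dB ripple (allow %.3f)",
      type, stop_db, min_stop_db, ripple, max_pass_ripple_db))
  }
  as.numeric(b)
}

# Cascade kernel for forward-backward high-pass + low-pass filtering:
# conv(b_hp, rev(b_hp)) convolved with conv(b_lp, rev(b_lp)). Symmetric,
# zero-phase when centred.
zero_phase_kernel <- function(low_hz, high_hz, fs, dp) {
  key <- paste(low_hz, high_hz, fs, dp$hp_order, dp$lp_order,
               paste(dp$hp_trans, collapse = "-"),
               paste(dp$lp_trans, collapse = "-"), sep = "|")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  bh <- design_fir("high", dp$hp_order, dp$hp_trans, dp$hp_weight, fs,
                   dp$min_stop_db, dp$max_pass_ripple_db)
  bl <- design_fir("low", dp$lp_order, dp$lp_trans, dp$lp_weight, fs,
                   dp$min_stop_db, dp$max_pass_ripple_db)
  g <- stats::convolve(bh, bh, type = "open")        # bh * rev(bh)
  gl <- stats::convolve(bl, bl, type = "open")
  k <- stats::convolve(g, rev(gl), type = "open")    # full cascade
  .filter_cache[[key]] <- k
  k
}

# Linear convolution with a symmetric odd-length kernel, output aligned to
# the kernel centre (zero phase), computed with one padded FFT.
zero_phase_conv <- function(x, kern) {
  n <- length(x); L <- length(kern); half <- (L - 1) / 2
  nfft <- stats::nextn(n + L - 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(kern, numeric(nfft - L)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  y[(half + 1):(half + n)]
}

#' Zero-phase equiripple band-pass filtering
#'
#' Applies equiripple (Parks-McClellan) FIR high-pass and low-pass filters,
#' each forward and backward, so the cascade has exactly zero phase. The
#' forward-backward cascade is computed as a single linear convolution with
#' the symmetric autocorrelation kernel of the designed filters, which is
#' mathematically identical to sequential bidirectional filtering away from
#' the (tapered) edges.
#'
#' @param rec A [raw_recording()] at 200 Hz.
#' @param low_hz,high_hz Band edges in Hz (defaults 0.5 and 30).
#' @param design_params See [fir_design_params()].
#' @return A [clean_recording()].
#' @export
bandpass_zero_phase <- function(rec, low_hz = 0.5, high_hz = 30,
                                design_params = fir_design_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2)) {
    stop_user("need 0 < low_hz < high_hz < fs/2")
  }
  dp <- design_params
  if (low_hz != 0.5) dp$hp_trans <- c(low_hz / 2, low_hz)
  if (high_hz != 30) dp$lp_trans <- c(high_hz, high_hz * 1.1)
  kern <- zero_phase_kernel(low_hz, high_hz, rec$fs, dp)
  rec$samples <- zero_phase_conv(rec$samples, kern)
  rec <- add_provenance(rec, "bandpass_zero_phase",
                        list(low_hz = low_hz, high_hz = high_hz,
                             hp_order = dp$hp_order, lp_order = dp$lp_order,
                             hp_trans = dp$hp_trans, lp_trans = dp$lp_trans))
  clean_recording(rec)
}

#' Spline reconstruction of brief NREM outliers
#'
#' Within scored NREM sleep, samples exceeding `iqr_mult` times the
#' interquartile range (IQR, computed once over all NREM samples of the
#' recording) in magnitude are treated as transient artifacts: runs shorter
#' than `max_run` samples are replaced by piecewise cubic spline
#' interpolation through the flanking unflagged samples; longer excursions
#' are flagged as regional artifacts and their epochs excluded instead.
#'
#' @param rec A [clean_recording()] at 200 Hz.
#' @param hyp The aligned [hypnogram()].
#' @param iqr_mult IQR multiplier for the outlier threshold (default 8).
#' @param max_run Minimum run length (samples) treated as regional rather
#'   than interpolable (default 7: runs of up to 6 samples are repaired).
#' @param n_flank Unflagged samples used on each side for the spline fit.
#' @return List with elements `recording` (repaired) and `mask`
#'   ([artifact_mask()] of kind `"regional"` events).
#' @export
reconstruct_nrem_outliers <- function(rec, hyp, iqr_mult = 8, max_run = 7,
                                      n_flank = 8) {
  stopifnot(inherits(rec, "clean_recording"), inherits(hyp, "hypnogram"))
  if (iqr_mult <= 0) stop_user("`iqr_mult` must be positive")
  x <- rec$samples
  spe <- hyp$epoch_len_s * rec$fs   # samples per epoch (800 at 4 s / 200 Hz)
  n_ep <- min(length(hyp), floor(length(x) / spe))
  nrem_ep <- which(as.character(hyp$labels[seq_len(n_ep)]) == "NREM")
  if (!length(nrem_ep)) {
    return(list(recording = rec,
                mask = artifact_mask(data.frame(start = integer(0),
                                                end = integer(0),
                                                kind = character(0)),
                                     length(x), rec$fs)))
  }
  nrem_idx <- unlist(lapply(nrem_ep, function(e) ((e - 1) * spe + 1):(e * spe)))
  iqr <- stats::IQR(x[nrem_idx])
  thr <- iqr_mult * iqr
  flag <- logical(length(x))
  flag[nrem_idx] <- abs(x[nrem_idx]) > thr
  if (all(flag[nrem_idx])) stop_user("all NREM samples exceed the threshold; degenerate input")
  runs <- true_runs(flag)
  regional <- data.frame(start = integer(0), end = integer(0),
                         kind = character(0))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, "start"]; b <- runs[i, "end"]
    if ((b - a + 1) < max_run) {
      lo <- max(1, a - n_flank); hi <- min(length(x), b + n_flank)
      sup <- setdiff(lo:hi, a:b)
      x[a:b] <- stats::spline(sup, x[sup], xout = a:b, method = "fmm")$y
    } else {
      regional <- rbind(regional,
                        data.frame(start = a, end = b, kind = "regional"))
    }
  }
  rec$samples <- x
  rec <- add_provenance(rec, "reconstruct_nrem_outliers",
                        list(iqr_mult = iqr_mult, max_run = max_run,
                             iqr = iqr, n_interpolated = sum(flag) -
                               sum(regional$end - regional$start + 1)))
  list(recording = rec, mask = artifact_mask(regional, length(x), rec$fs))
}

#' Run the full post-processing stack on a raw recording
#'
#' Fixed order: clipping detection, smoothing + Fermi tapering (with clipped
#' samples excised), resampling to 200 Hz, zero-phase equiripple band-pass
#' (0.5-30 Hz), and spline reconstruction of brief NREM outliers. Artifact
#' events from the clipping and reconstruction stages are merged into one
#' mask expressed at 200 Hz.
#'
#' @param rec A [raw_recording()].
#' @param hyp The aligned [hypnogram()].
#' @param low_hz,high_hz Band-pass edges in Hz.
#' @param clip_threshold_frac,clip_min_run See [detect_clipping()].
#' @param fermi_edge_frac See [smooth_and_taper()].
#' @param iqr_mult,max_run See [reconstruct_nrem_outliers()].
#' @param design_params See [fir_design_params()].
#' @return List with `recording` (a [clean_recording()]) and `mask` (an
#'   [artifact_mask()] at 200 Hz combining clipping and regional events).
#' @export
preprocess_recording <- function(rec, hyp, low_hz = 0.5, high_hz = 30,
                                 clip_threshold_frac = 0.999, clip_min_run = 2,
                                 fermi_edge_frac = 0.01, iqr_mult = 8,
                                 max_run = 7,
                                 design_params = fir_design_params()) {
  clip <- detect_clipping(rec, clip_threshold_frac, clip_min_run)
  rec2 <- smooth_and_taper(rec, clip, fermi_edge_frac)
  rec3 <- resample_to_200hz(rec2)
  rec4 <- bandpass_zero_phase(rec3, low_hz, high_hz, design_params)
  out <- reconstruct_nrem_outliers(rec4, hyp, iqr_mult, max_run)
  # re-express clipping events at 200 Hz and merge with regional events
  ratio <- 200 / rec$fs
  ev <- clip$events
  if (nrow(ev)) {
    ev$start <- pmax(1L, floor((ev$start - 1) * ratio) + 1L)
    ev$end <- pmin(length(out$recording$samples),
                   ceiling(ev$end * ratio))
  }
  events <- rbind(ev, out$mask$events)
  list(recording = out$recording,
       mask = artifact_mask(events, length(out$recording$samples), 200))
}
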