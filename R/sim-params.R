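#' Simulation parameters for the synthetic sleep-EEG generator
#'
#' Bundles the design constants of a simulated 24-h recording day: epoch
#' length (fixed at 4 s), native sampling rate, ADC input range, per-state
#' dwell-time means of the semi-Markov vigilance-state process, per-state
#' spectral shapes (1/f slope plus Gaussian band peaks), the treatment
#' administration times on the Zeitgeber-time (ZT) axis, the injected
#' delta-gain effect and its decay constant, and artifact rates.
#'
#' Defaults encode the study conditions the analysis pipeline assumes:
#' dosing at ZT1 and ZT9, nominal 200 Hz sampling, an input range of
#' +/-200 mV, 4-s scoring epochs, and state spectra tuned so that NREM
#' relative delta power sits in the 40-60% range typical of rodent EEG.
#'
#' @param epoch_len_s Scoring epoch length in seconds (fixed at 4).
#' @param fs_native Native sampling rate in Hz; must lie in [150, 250].
#'   Values other than 200 exercise the resampling stage.
#' @param input_range_mV Half-range of the ADC in millivolts; clipping
#'   artifacts saturate at this level (expressed internally in microvolts).
#' @param recording_hours Duration of one recording day in hours.
#' @param zt0_offset ZT hour of the first sample (lights-on = ZT0).
#' @param state_dwell_means_s Named numeric vector, mean dwell time in
#'   seconds for states `WAKE`, `NREM`, `REM`.
#' @param state_spectra Named list of per-state spectral shapes; see
#'   [default_state_spectra()].
#' @param treatment_admin_zt ZT hours of drug administration (default
#'   `c(1, 9)`, twice-daily dosing in the light period).
#' @param delta_gain_effect Peak injected gain in NREM relative delta power
#'   immediately after an administration, in percentage points (p.p.).
#' @param effect_decay_h Exponential decay constant of the injected effect,
#'   in hours.
#' @param clipping_rate_per_h Expected clipping (saturation) events per hour.
#' @param spike_rate_per_h Expected brief transient spikes per hour; spikes
#'   are 1-3 samples wide and exceed 8x the NREM interquartile range.
#' @param artifact_epoch_rate Fraction of epochs labelled ARTIFACT by the
#'   (emulated) scorer, independent of injected signal artifacts.
#'
#' @return An object of class `sim_params`.
#' @seealso [simulate_hypnogram()], [synthesize_recording()],
#'   [simulate_cohort()]
#' @export
#' @examples
#' p <- sim_params(recording_hours = 2)
#' p$treatment_admin_zt
sim_params <- function(epoch_len_s = 4,
                       fs_native = 200,
                       input_range_mV = 200,
                       recording_hours = 24,
                       zt0_offset = 0,
                       state_dwell_means_s = c(WAKE = 120, NREM = 240, REM = 60),
                       state_spectra = default_state_spectra(),
                       treatment_admin_zt = c(1, 9),
                       delta_gain_effect = 0,
                       effect_decay_h = 2,
                       clipping_rate_per_h = 1,
                       spike_rate_per_h = 3,
                       artifact_epoch_rate = 0) {
  if (epoch_len_s <= 0 || (3600 %% epoch_len_s) != 0) {
    stop_user("`epoch_len_s` must be a positive divisor of 3600 s")
  }
  if (fs_native < 150 || fs_native > 250) {
    stop_user("`fs_native` must lie within [150, 250] Hz")
  }
  if (input_range_mV <= 0) stop_user("`input_range_mV` must be positive")
  if (recording_hours < 0) stop_user("`recording_hours` must be >= 0")
  if (!all(c("WAKE", "NREM", "REM") %in% names(state_dwell_means_s)) ||
      any(state_dwell_means_s <= 0)) {
    stop_user("`state_dwell_means_s` needs positive WAKE, NREM, REM entries")
  }
  if (delta_gain_effect < 0) stop_user("`delta_gain_effect` must be >= 0")
  if (effect_decay_h < 0) stop_user("`effect_decay_h` must be >= 0")
  if (clipping_rate_per_h < 0 || spike_rate_per_h < 0) {
    stop_user("artifact rates must be >= 0")
  }
  structure(list(
    epoch_len_s = epoch_len_s,
    fs_native = fs_native,
    input_range_mV = input_range_mV,
    input_range_uV = input_range_mV * 1000,
    recording_hours = recording_hours,
    zt0_offset = zt0_offset,
    state_dwell_means_s = state_dwell_means_s[c("WAKE", "NREM", "REM")],
    state_spectra = state_spectra,
    treatment_admin_zt = treatment_admin_zt,
    delta_gain_effect = delta_gain_effect,
    effect_decay_h = effect_decay_h,
    clipping_rate_per_h = clipping_rate_per_h,
    spike_rate_per_h = spike_rate_per_h,
    artifact_epoch_rate = artifact_epoch_rate
  ), class = "sim_params")
}

#' Default per-state EEG spectral shapes
#'
#' Each state's target power spectral density is `amp^2 * (f^-alpha +
#' sum(bumps))` with Gaussian band bumps parameterised by centre frequency
#' (Hz), bandwidth (Hz, SD), and height (relative to the 1/f component at
#' 1 Hz). NREM carries a strong delta bump (slow-wave activity), REM a theta
#' bump at ~7 Hz, WAKE a low-amplitude mixed spectrum with a weak theta bump.
#' Amplitudes (`amp_uV`) are root-mean-square scale factors in microvolts.
#'
#' @return Named list (WAKE, NREM, REM) of lists with elements `alpha`,
#'   `amp_uV`, and `bumps` (data frame: `centre_hz`, `bw_hz`, `height`).
#' @export
default_state_spectra <- function() {
  list(
    WAKE = list(alpha = 0.3, amp_uV = 40,
                bumps = data.frame(centre_hz = 7, bw_hz = 1.5, height = 0.6)),
    NREM = list(alpha = 0.5, amp_uV = 80,
                bumps = data.frame(centre_hz = 1.5, bw_hz = 1.2, height = 1.5)),
    REM  = list(alpha = 0.3, amp_uV = 45,
                bumps = data.frame(centre_hz = 7, bw_hz = 1.0, height = 3.0))
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic sleep-EEG simulation parameters\n")
  cat(sprintf("  %g h recording @ %g Hz (ZT%g start), %g-s epochs, +/-%g mV\n",
              x$recording_hours, x$fs_native, x$zt0_offset, x$epoch_len_s,
              x$input_range_mV))
  cat(sprintf("  dosing at ZT %s; delta gain %g p.p. (decay %g h)\n",
              paste(x$treatment_admin_zt, collapse = ", "),
              x$delta_gain_effect, x$effect_decay_h))
  cat(sprintf("  artifacts: %g clip/h, %g spikes/h\n",
              x$clipping_rate_per_h, x$spike_rate_per_h))
  invisible(x)
}
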