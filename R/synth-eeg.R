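# Synthetic EEG: per-epoch frequency-domain synthesis of state-dependent
# coloured noise, with a closed-form treatment effect on relative delta power
# and logged artifact injection.

# Target one-sided power spectral density of a state at frequencies f (Hz).
state_psd <- function(f, spec) {
  s <- f^(-spec$alpha)
  if (!is.null(spec$bumps) && nrow(spec$bumps)) {
    for (i in seq_len(nrow(spec$bumps))) {
      b <- spec$bumps[i, ]
      s <- s + b$height * exp(-0.5 * ((f - b$centre_hz) / b$bw_hz)^2)
    }
  }
  spec$amp_uV^2 * s
}

# Squared magnitude response of the three-point moving average at fs.
ma3_response_sq <- function(f, fs) ((1 + 2 * cos(2 * pi * f / fs)) / 3)^2

# Relative delta power of a state *as the measurement pipeline sees it*:
# the target PSD weighted by the smoothing response, integrated on the
# 0.25 Hz analysis grid over 0.5-30 Hz.
state_rel_delta <- function(spec, fs, delta_band = c(0.5, 4)) {
  f <- seq(0.5, 30, by = 0.25)
  w <- state_psd(f, spec) * ma3_response_sq(f, fs)
  sum(w[f >= delta_band[1] & f <= delta_band[2]]) / sum(w)
}

# Injected gain (fraction of total band power) at ZT time t given admin times
# and an exponential decay constant (hours).
effect_at_zt <- function(zt, admin_zt, effect_pp, decay_h) {
  if (effect_pp <= 0 || decay_h <= 0) return(rep(0, length(zt)))
  e <- numeric(length(zt))
  for (ta in admin_zt) {
    dt <- zt - ta
    e <- e + ifelse(dt >= 0, effect_pp * exp(-dt / decay_h), 0)
  }
  e / 100
}

# Amplitude scale factor on the delta band turning baseline relative delta d0
# into d0 + e (closed-form renormalisation of a two-component spectrum).
delta_scale_factor <- function(d0, e) {
  d1 <- pmin(d0 + e, 0.999)
  sqrt(d1 * (1 - d0) / (d0 * (1 - d1)))
}

#' Synthesize a raw EEG recording from a hypnogram
#'
#' Each scored epoch is filled with coloured noise shaped to its state's
#' target spectrum (1/f plus Gaussian band peaks: a delta peak in NREM, a
#' theta peak in REM) by drawing independent complex-Gaussian Fourier
#' coefficients with the target magnitude and inverse-transforming. In NREM
#' epochs following a treatment administration, delta-band coefficients are
#' scaled so that the *measured* relative delta power (after the smoothing
#' stage of the analysis pipeline, on the 0.25 Hz grid over 0.5-30 Hz)
#' increases by the configured effect, decaying exponentially since the last
#' administration. Clipping events (saturation at the input range, 0.1-1 s)
#' and brief high-amplitude transients are injected at the configured rates
#' and logged sample-exactly in the returned ground truth.
#'
#' @param hyp A [hypnogram()].
#' @param params A [sim_params()]; `params$delta_gain_effect` in percentage
#'   points sets the injected effect (0 = baseline day).
#' @param seed Integer seed.
#' @return A list with elements `recording` (a [raw_recording()]) and
#'   `truth` (list: per-epoch table with true relative delta power, hourly
#'   NREM delta and gain profile, artifact event log).
#' @export
synthesize_recording <- function(hyp, params, seed = NULL) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(params, "sim_params"))
  n_epochs <- length(hyp)
  if (n_epochs == 0) stop_user("hypnogram is empty")
  fs <- params$fs_native
  ep_s <- hyp$epoch_len_s
  # epoch sample boundaries at the native rate (handles non-integer fs)
  bounds <- round((0:n_epochs) * ep_s * fs)
  lens <- diff(bounds)
  n_total <- bounds[n_epochs + 1]

  zt <- epoch_zt(hyp)
  labels <- as.character(hyp$labels)
  eff <- effect_at_zt(zt, params$treatment_admin_zt,
                      params$delta_gain_effect, params$effect_decay_h)
  d0 <- vapply(params$state_spectra, state_rel_delta, 0, fs = fs)
  true_rel_delta <- rep(NA_real_, n_epochs)

  with_seed(seed, {
    x <- numeric(n_total)
    for (st in c("WAKE", "NREM", "REM")) {
      idx <- which(labels == st)
      if (!length(idx)) next
      g2 <- rep(1, length(idx))
      if (st == "NREM") {
        g2 <- delta_scale_factor(d0[[st]], eff[idx])^2
        dd <- d0[[st]]
        true_rel_delta[idx] <- 100 * g2 * dd / (g2 * dd + (1 - dd))
      } else {
        true_rel_delta[idx] <- 100 * d0[[st]]
      }
      for (L in unique(lens[idx])) {
        sub <- idx[lens[idx] == L]
        blk <- synth_blocks(L, length(sub), fs, params$state_spectra[[st]],
                            g2 = g2[match(sub, idx)])
        for (k in seq_along(sub)) {
          e <- sub[k]
          x[(bounds[e] + 1):bounds[e + 1]] <- blk[, k]
        }
      }
    }
    # ARTIFACT-labelled epochs get wake-like filler (they are excluded anyway)
    idx <- which(labels == "ARTIFACT")
    for (e in idx) {
      L <- lens[e]
      x[(bounds[e] + 1):bounds[e + 1]] <-
        synth_blocks(L, 1, fs, params$state_spectra[["WAKE"]], g2 = 1)[, 1]
    }

    events <- inject_artifacts(x, params, labels, bounds, fs)
    x <- events$x

    rec <- raw_recording(x, fs = fs, input_range_uV = params$input_range_uV,
                         zt0_offset = hyp$zt0_offset,
                         subject_id = NA_character_)

    ep_tab <- data.frame(epoch = seq_len(n_epochs), state = labels, zt = zt,
                         true_rel_delta = true_rel_delta,
                         injected_gain_pp = 100 * eff)
    hourly <- hourly_truth(ep_tab, d0[["NREM"]])
    list(recording = rec,
         truth = list(epochs = ep_tab,
                      baseline_nrem_delta = 100 * d0[["NREM"]],
                      hourly = hourly,
                      events = events$log))
  })
}

# Draw n_blk independent coloured-noise blocks of length L at rate fs, with
# per-block delta-band power scale g2.
synth_blocks <- function(L, n_blk, fs, spec, g2 = rep(1, n_blk),
                         delta_band = c(0.5, 4)) {
  nf <- floor(L / 2)
  f <- (1:nf) * fs / L
  mag <- sqrt(state_psd(f, spec) / L)
  in_delta <- f >= delta_band[1] & f <= delta_band[2]
  Z <- matrix(stats::rnorm(nf * n_blk), nf, n_blk) +
    1i * matrix(stats::rnorm(nf * n_blk), nf, n_blk)
  X <- Z * mag
  if (any(g2 != 1)) {
    X[in_delta, ] <- X[in_delta, , drop = FALSE] *
      rep(sqrt(g2), each = sum(in_delta))
  }
  # assemble Hermitian spectrum: DC = 0, conjugate upper half
  full <- matrix(0 + 0i, L, n_blk)
  full[2:(nf + 1), ] <- X
  full[L:(L - nf + 1), ] <- Conj(X)
  if (L %% 2 == 0) full[nf + 1, ] <- Re(full[nf + 1, ]) * sqrt(2)
  Re(stats::mvfft(full, inverse = TRUE)) / sqrt(L)
}

# Hourly ground truth from the per-epoch table.
hourly_truth <- function(ep_tab, d0_nrem) {
  hr <- floor(ep_tab$zt)
  nrem <- ep_tab$state == "NREM"
  hours <- sort(unique(hr))
  out <- data.frame(
    zt_hour = hours,
    true_nrem_delta = vapply(hours, function(h) {
      i <- nrem & hr == h
      if (!any(i)) NA_real_ else mean(ep_tab$true_rel_delta[i])
    }, 0),
    n_nrem_epochs = vapply(hours, function(h) sum(nrem & hr == h), 0L)
  )
  out$true_gain_pp <- out$true_nrem_delta - 100 * d0_nrem
  out
}

# Saturate clipping runs and add brief transients; return modified signal and
# a sample-exact event log.
inject_artifacts <- function(x, params, labels, bounds, fs) {
  n <- length(x)
  hours <- n / fs / 3600
  log <- data.frame(start = integer(0), end = integer(0),
                    kind = character(0))
  n_clip <- stats::rpois(1, params$clipping_rate_per_h * hours)
  if (n_clip > 0) {
    for (i in seq_len(n_clip)) {
      len <- round(stats::runif(1, 0.1, 1) * fs)
      s <- sample.int(max(n - len, 1), 1)
      x[s:(s + len - 1)] <- sign(stats::rnorm(1)) * params$input_range_uV
      log <- rbind(log, data.frame(start = s, end = s + len - 1,
                                   kind = "clipping"))
    }
  }
  n_spk <- stats::rpois(1, params$spike_rate_per_h * hours)
  if (n_spk > 0) {
    nrem_ep <- which(labels == "NREM")
    if (length(nrem_ep)) {
      nrem_idx <- unlist(lapply(nrem_ep, function(e) (bounds[e] + 1):bounds[e + 1]))
      iqr <- stats::IQR(x[nrem_idx])
      for (i in seq_len(n_spk)) {
        w <- sample(1:3, 1)
        s <- sample(nrem_idx[nrem_idx <= n - w], 1)
        x[s:(s + w - 1)] <- x[s:(s + w - 1)] +
          sign(stats::rnorm(1)) * 25 * iqr
        log <- rbind(log, data.frame(start = s, end = s + w - 1,
                                     kind = "spike"))
      }
    }
  }
  list(x = x, log = log)
}
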