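# Shared fixtures: small, fast simulation settings used across test files.

quiet_params <- function(hours = 1, effect = 0, admin = c(1, 9), ...) {
  sim_params(recording_hours = hours, delta_gain_effect = effect,
             treatment_admin_zt = admin,
             clipping_rate_per_h = 0, spike_rate_per_h = 0, ...)
}

# Independent oracle: stationary NREM *time* fraction of the bout process.
# Builds the embedded transition matrix by hand and weights its stationary
# distribution by the mean dwell times.
stationary_nrem_fraction <- function(dwell_s) {
  states <- c("WAKE", "NREM", "REM")
  P <- matrix(0, 3, 3, dimnames = list(states, states))
  P["WAKE", "NREM"] <- 1
  P["NREM", "WAKE"] <- 0.65
  P["NREM", "REM"] <- 0.35
  P["REM", "WAKE"] <- 1
  pi <- rep(1 / 3, 3)
  for (i in 1:500) pi <- pi %*% P
  pi <- as.numeric(pi / sum(pi))
  tf <- pi * dwell_s[states]
  (tf / sum(tf))[[2]]
}

# Direct periodogram-based relative delta power of one signal block
# (independent of the package's spectral code path).
oracle_rel_delta <- function(x, fs = 200, band = c(0.5, 4)) {
  n <- length(x)
  P <- abs(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= 0.5 & f <= 30
  sum(P[sel & f <= band[2]]) / sum(P[sel])
}

# Tiny hand implementation of Benjamini-Hochberg, used as the oracle for
# the hourly FDR series.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
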