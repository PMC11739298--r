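#' Hypnogram: vigilance-state labels in 4-s epochs
#'
#' A hypnogram is the scored output of a sleep recording: one label per
#' scoring epoch, drawn from `WAKE`, `NREM`, `REM`, `ARTIFACT`. Scoring
#' itself (e.g. by an automated classifier) is upstream of this package;
#' hypnograms are inputs, aligned to the recording by epoch length and the
#' ZT hour of the first epoch.
#'
#' @param labels Character or factor vector of epoch labels.
#' @param epoch_len_s Epoch length in seconds (default 4).
#' @param zt0_offset ZT hour of the first epoch.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len_s = 4, zt0_offset = 0) {
  lv <- c("WAKE", "NREM", "REM", "ARTIFACT")
  labels <- as.character(labels)
  if (length(labels) && !all(labels %in% lv)) {
    stop_user("hypnogram labels must be WAKE, NREM, REM or ARTIFACT")
  }
  structure(list(
    labels = factor(labels, levels = lv),
    epoch_len_s = epoch_len_s,
    zt0_offset = zt0_offset
  ), class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x)
  cat(sprintf("Hypnogram: %d epochs of %g s (%.2f h), starting ZT%g\n",
              n, x$epoch_len_s, n * x$epoch_len_s / 3600, x$zt0_offset))
  if (n) print(round(100 * table(x$labels) / n, 1))
  invisible(x)
}

# ZT hour (fractional) at the midpoint of each epoch.
epoch_zt <- function(hyp) {
  n <- length(hyp)
  hyp$zt0_offset + ((seq_len(n) - 0.5) * hyp$epoch_len_s) / 3600
}

#' Simulate a scored hypnogram with a semi-Markov state process
#'
#' Draws vigilance-state bouts with geometrically distributed dwell times
#' (in epochs) around the configured per-state means. Transitions follow the
#' physiological skeleton of rodent sleep: REM is entered only from NREM;
#' wake transitions to NREM; NREM splits between brief awakenings and REM
#' entries; REM terminates in wake. A configurable fraction of epochs is
#' additionally relabelled `ARTIFACT`, emulating scorer rejections.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical seeds give identical label sequences.
#' @return A [hypnogram()] covering `params$recording_hours`.
#' @export
#' @examples
#' h <- simulate_hypnogram(sim_params(recording_hours = 1), seed = 1)
#' table(h$labels)
simulate_hypnogram <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n_epochs <- as.integer(round(params$recording_hours * 3600 / params$epoch_len_s))
  if (n_epochs == 0) {
    return(hypnogram(character(0), params$epoch_len_s, params$zt0_offset))
  }
  dwell_ep <- pmax(params$state_dwell_means_s / params$epoch_len_s, 1)
  with_seed(seed, {
    labels <- character(n_epochs)
    state <- "WAKE"
    i <- 1L
    while (i <= n_epochs) {
      # dwell ~ 1 + Geom(p), mean 1/p epochs
      d <- 1L + stats::rgeom(1, prob = 1 / dwell_ep[[state]])
      j <- min(i + d - 1L, n_epochs)
      labels[i:j] <- state
      i <- j + 1L
      state <- next_state(state)
    }
    if (params$artifact_epoch_rate > 0) {
      art <- stats::runif(n_epochs) < params$artifact_epoch_rate
      labels[art] <- "ARTIFACT"
    }
    hypnogram(labels, params$epoch_len_s, params$zt0_offset)
  })
}

# Embedded transition kernel of the bout process. REM is reachable only from
# NREM; REM bouts terminate in wake.
state_transitions <- function() {
  list(WAKE = c(NREM = 1),
       NREM = c(WAKE = 0.65, REM = 0.35),
       REM  = c(WAKE = 1))
}

next_state <- function(state) {
  tr <- state_transitions()[[state]]
  sample(names(tr), 1, prob = tr)
}
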