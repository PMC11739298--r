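# Cohort-level simulation: per-subject EEG days (baseline + treatment),
# behavioural percent-correct draws, ELISA tables, and plaque masks, all
# deterministic under a single seed with known ground truth.

#' Default cohort design table
#'
#' A genotype (WT / Tg2576) by treatment (placebo / SO) design with the
#' given cell sizes, one row per subject.
#'
#' @param n_per_cell Named or unnamed vector of four cell sizes in the
#'   order WT:placebo, WT:SO, Tg:placebo, Tg:SO.
#' @param cohort Cohort label (`"early"` or `"late"`).
#' @return Data frame: `subject`, `genotype`, `treatment`, `cohort`, `sex`.
#' @export
cohort_design <- function(n_per_cell = c(9, 9, 8, 6), cohort = "early") {
  cells <- data.frame(genotype = rep(c("WT", "Tg2576"), each = 2),
                      treatment = rep(c("placebo", "SO"), 2),
                      n = n_per_cell)
  rows <- cells[rep(seq_len(4), cells$n), c("genotype", "treatment")]
  data.frame(subject = sprintf("s%02d", seq_len(nrow(rows))),
             genotype = rows$genotype, treatment = rows$treatment,
             cohort = cohort,
             sex = rep_len(c("f", "m"), nrow(rows)),
             row.names = NULL)
}

#' Default group-level generating parameters for behaviour and ELISA
#'
#' Baseline T-maze percent-correct means/SDs per genotype and cohort, and
#' insoluble/soluble ELISA means/SDs (pg/mg) per treatment, used by
#' [simulate_cohort()] as the generating distributions.
#'
#' @return Nested list with `tmaze` and `elisa` components.
#' @export
cohort_effect_defaults <- function() {
  list(
    tmaze = list(
      early = list(Tg2576 = c(mean = 42.65, sd = 14.99),
                   WT = c(mean = 79.63, sd = 28.18)),
      late = list(Tg2576 = c(mean = 53.75, sd = 29.43),
                  WT = c(mean = 75.93, sd = 18.28))
    ),
    elisa = list(
      insoluble_ab40 = list(SO = c(mean = 4.982, sd = 0.379),
                            placebo = c(mean = 4.459, sd = 0.158)),
      insoluble_ab42 = list(SO = c(mean = 1.30, sd = 0.25),
                            placebo = c(mean = 1.40, sd = 0.25)),
      soluble_ab40 = list(SO = c(mean = 10.0, sd = 1.2),
                          placebo = c(mean = 9.8, sd = 1.2)),
      soluble_ab42 = list(SO = c(mean = 2.5, sd = 0.4),
                          placebo = c(mean = 2.45, sd = 0.4))
    ),
    burden = list(
      WT = c(fraction = 0.005), Tg2576_placebo = c(fraction = 0.10),
      Tg2576_SO = c(fraction = 0.05)
    )
  )
}

#' Simulate a full study cohort with known ground truth
#'
#' For each subject of the design: a baseline and a treatment EEG day
#' (hypnogram + raw recording; SO-treated subjects receive the configured
#' delta-gain effect on the treatment day, placebo subjects none),
#' behavioural percent-correct scores drawn from the cohort's group
#' distributions, an ELISA table whose pg/mg values are drawn from the
#' group distributions, and (optionally) plaque masks with known area
#' fraction. All draws are deterministic under `seed`.
#'
#' @param design Design table as from [cohort_design()]; needs >= 2
#'   subjects per genotype x treatment cell when EEG is simulated.
#' @param params A [sim_params()]; `delta_gain_effect` applies to
#'   SO-treated subjects' treatment day.
#' @param seed Integer seed.
#' @param modalities Subset of `c("eeg", "tmaze", "elisa", "masks")` to
#'   simulate; EEG synthesis dominates run time.
#' @param effects Group-level generating parameters, see
#'   [cohort_effect_defaults()].
#' @return Object of class `cohort_bundle`: list with `design`, `eeg`
#'   (per subject: baseline/treatment hypnograms, recordings, truths),
#'   `tmaze` (baseline/after percent-correct per subject), `elisa`
#'   (long-format table), `masks`, and `truth` (generating parameters).
#' @export
simulate_cohort <- function(design = cohort_design(),
                            params = sim_params(),
                            seed = NULL,
                            modalities = c("eeg", "tmaze", "elisa", "masks"),
                            effects = cohort_effect_defaults()) {
  tab <- table(design$genotype, design$treatment)
  if (any(tab == 0)) stop_user("empty genotype x treatment design cell")
  if ("eeg" %in% modalities && any(tab < 2)) {
    stop_user("need >= 2 subjects per cell")
  }
  n <- nrow(design)
  out <- list(design = design, truth = list(params = params,
                                            effects = effects))

  if ("eeg" %in% modalities) {
    out$eeg <- vector("list", n)
    names(out$eeg) <- design$subject
    for (i in seq_len(n)) {
      base_par <- params; base_par$delta_gain_effect <- 0
      tr_par <- params
      if (design$treatment[i] != "SO") tr_par$delta_gain_effect <- 0
      s1 <- child_seed(seed, 1000 + i)
      s2 <- child_seed(seed, 2000 + i)
      s3 <- child_seed(seed, 3000 + i)
      s4 <- child_seed(seed, 4000 + i)
      hyp_bl <- simulate_hypnogram(base_par, s1)
      hyp_tr <- simulate_hypnogram(tr_par, s2)
      bl <- synthesize_recording(hyp_bl, base_par, s3)
      tr <- synthesize_recording(hyp_tr, tr_par, s4)
      bl$recording$subject_id <- tr$recording$subject_id <- design$subject[i]
      out$eeg[[i]] <- list(baseline = list(hypnogram = hyp_bl,
                                           recording = bl$recording,
                                           truth = bl$truth),
                           treatment = list(hypnogram = hyp_tr,
                                            recording = tr$recording,
                                            truth = tr$truth))
    }
  }

  if ("tmaze" %in% modalities) {
    out$tmaze <- with_seed(child_seed(seed, 11), {
      co <- design$cohort[1]
      gp <- effects$tmaze[[co]] %||% effects$tmaze[["early"]]
      base <- vapply(seq_len(n), function(i) {
        p <- gp[[design$genotype[i]]]
        stats::rnorm(1, p["mean"], p["sd"])
      }, 0)
      data.frame(subject = design$subject, genotype = design$genotype,
                 treatment = design$treatment,
                 percent_baseline = base,
                 class_baseline = tmaze_class(base))
    })
  }

  if ("elisa" %in% modalities) {
    out$elisa <- with_seed(child_seed(seed, 12), {
      rows <- list()
      for (key in names(effects$elisa)) {
        parts <- strsplit(key, "_")[[1]]
        frac <- parts[1]; analyte <- parts[2]
        for (i in seq_len(n)) {
          p <- effects$elisa[[key]][[design$treatment[i]]]
          val <- stats::rnorm(1, p["mean"], p["sd"])
          mg <- stats::runif(1, 18, 22)
          rows[[length(rows) + 1]] <- data.frame(
            subject = design$subject[i], genotype = design$genotype[i],
            treatment = design$treatment[i], analyte = analyte,
            fraction = frac, raw_pg = val * mg, tissue_mg = mg)
        }
      }
      do.call(rbind, rows)
    })
  }

  if ("masks" %in% modalities) {
    out$masks <- with_seed(child_seed(seed, 13), {
      lapply(seq_len(n), function(i) {
        key <- if (design$genotype[i] == "WT") "WT"
               else paste0("Tg2576_", design$treatment[i])
        f <- effects$burden[[key]][["fraction"]]
        simulate_plaque_mask(600, 600, um_per_pixel = 2,
                             target_fraction = f, n_plaques = 12,
                             seed = child_seed(seed, 500 + i))
      })
    })
    names(out$masks) <- design$subject
  }

  class(out) <- "cohort_bundle"
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Cohort bundle: %d subjects (%s)\n", nrow(x$design),
              paste(names(x)[!names(x) %in% c("design", "truth")],
                    collapse = ", ")))
  print(table(x$design$genotype, x$design$treatment))
  invisible(x)
}
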