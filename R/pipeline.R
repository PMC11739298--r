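# End-to-end orchestration: simulate or ingest a cohort, preprocess, run the
# spectral quantification, the statistical battery and the tissue
# quantification, and write a results bundle with full provenance.

#' Pipeline run configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Unknown
#' keys are rejected; every value is echoed into the provenance record.
#'
#' @param simulation List of overrides for [sim_params()] plus optional
#'   `n_per_cell` and `cohort` for [cohort_design()]; `NULL` when real
#'   inputs are provided.
#' @param inputs Optional data frame of file paths (columns `subject`,
#'   `genotype`, `treatment`, `baseline_recording`, `baseline_hypnogram`,
#'   `treatment_recording`, `treatment_hypnogram`).
#' @param delta_band Delta band in Hz (default `c(0.5, 4)`).
#' @param summary_hours ZT hours summarised by [delta_gain()].
#' @param min_epochs_per_hour Minimum NREM epochs per reported hour.
#' @param d_variant Cohen's d denominator (only `"unweighted"` implemented).
#' @param fdr_method Multiplicity correction for hourly tests (`"BH"`).
#' @param t_variant Hourly t-test variant (`"welch"` or `"student"`).
#' @param fractionator Named list: `frame_um`, `grid_um`.
#' @param seed Integer master seed.
#' @param out_dir Output directory for tables, report and provenance.
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulation = list(), inputs = NULL,
                       delta_band = c(0.5, 4), summary_hours = c(9, 10),
                       min_epochs_per_hour = 15,
                       d_variant = "unweighted", fdr_method = "BH",
                       t_variant = "welch",
                       fractionator = list(frame_um = 150, grid_um = 150),
                       seed = 1, out_dir = tempfile("swaquant_run_")) {
  cfg <- list(simulation = simulation, inputs = inputs,
              delta_band = delta_band, summary_hours = summary_hours,
              min_epochs_per_hour = min_epochs_per_hour,
              d_variant = d_variant, fdr_method = fdr_method,
              t_variant = t_variant, fractionator = fractionator,
              seed = seed, out_dir = out_dir)
  if (!is.null(simulation)) {
    known <- c(names(formals(sim_params)), "n_per_cell", "cohort")
    bad <- setdiff(names(simulation), known)
    if (length(bad)) stop_user("unknown simulation keys: ",
                               paste(bad, collapse = ", "))
  }
  if (!fdr_method %in% "BH") stop_user("unsupported fdr_method: ", fdr_method)
  if (!d_variant %in% "unweighted") stop_user("unsupported d_variant")
  if (!t_variant %in% c("welch", "student")) stop_user("unsupported t_variant")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_user("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or ingestion of recording /
#' hypnogram files), signal preprocessing, per-epoch spectral
#' quantification, hourly delta-gain computation, the statistical battery
#' (hourly FDR-corrected gain tests per genotype, two-way ANOVA on the NREM
#' proportion change, baseline behavioural t-tests, ELISA comparisons,
#' plaque-burden ANOVA, gain correlations), and writes all tables plus a
#' provenance JSON to `config$out_dir`. A stage failure aborts with a
#' stage-labelled error and leaves a `FAILED` marker next to any partial
#' outputs.
#'
#' @param config A [run_config()].
#' @return Object of class `results_bundle`: list of result tables (see
#'   Details) with the configuration attached.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop_user(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  bundle <- list(config = config, log = character(0))
  note <- function(...) {
    bundle$log <<- c(bundle$log, sprintf(...))
  }

  # --- acquire cohort ------------------------------------------------------
  cohort <- stage("simulate", {
    if (!is.null(config$inputs)) {
      ingest_cohort(config$inputs)
    } else {
      sim <- config$simulation
      par_args <- sim[names(sim) %in% names(formals(sim_params))]
      params <- do.call(sim_params, par_args)
      design <- cohort_design(sim$n_per_cell %||% c(2, 2, 2, 2),
                              sim$cohort %||% "early")
      simulate_cohort(design, params, seed = config$seed)
    }
  })
  bundle$design <- cohort$design

  # --- preprocess + spectra + gain ----------------------------------------
  per_subject <- stage("spectra", {
    lapply(seq_len(nrow(cohort$design)), function(i) {
      sid <- cohort$design$subject[i]
      ee <- cohort$eeg[[sid]]
      days <- lapply(ee[c("baseline", "treatment")], function(day) {
        pp <- preprocess_recording(day$recording, day$hypnogram)
        sp <- epoch_spectra(pp$recording, day$hypnogram, pp$mask)
        hourly <- hourly_state_band_power(sp, state = "NREM",
                                          band = config$delta_band)
        list(hourly = hourly, hypnogram = day$hypnogram, mask = pp$mask)
      })
      gain <- delta_gain(days$treatment$hourly, days$baseline$hourly,
                         summary_hours = config$summary_hours,
                         min_epochs = config$min_epochs_per_hour)
      nrem <- nrem_time_metrics(days$baseline$hypnogram,
                                days$treatment$hypnogram)
      list(subject = sid, gain = gain, nrem = nrem)
    })
  })

  gain_tab <- do.call(rbind, lapply(per_subject, function(s) {
    cbind(subject = s$subject, as.data.frame(s$gain))
  }))
  bundle$delta_gain <- gain_tab
  bundle$subject_summary <- data.frame(
    subject = vapply(per_subject, `[[`, "", "subject"),
    gain_summary_pp = vapply(per_subject,
                             function(s) gain_summary(s$gain), 0),
    nrem_pct_baseline = vapply(per_subject,
                               function(s) s$nrem$baseline_pct, 0),
    nrem_pct_treatment = vapply(per_subject,
                                function(s) s$nrem$treatment_pct, 0),
    delta_nrem_pp = vapply(per_subject, function(s) s$nrem$delta_nrem_pp, 0)
  )

  # --- statistics ----------------------------------------------------------
  des <- cohort$design
  ss <- merge(bundle$subject_summary, des, by = "subject")
  bundle$stats <- list()

  bundle$stats$hourly_delta_gain <- stage("stats", {
    out <- list()
    for (gt in unique(des$genotype)) {
      so <- ss$subject[ss$genotype == gt & ss$treatment == "SO"]
      pl <- ss$subject[ss$genotype == gt & ss$treatment == "placebo"]
      if (length(so) >= 2 && length(pl) >= 2) {
        ga <- lapply(per_subject[match(so, sapply(per_subject, `[[`, "subject"))],
                     `[[`, "gain")
        gb <- lapply(per_subject[match(pl, sapply(per_subject, `[[`, "subject"))],
                     `[[`, "gain")
        out[[gt]] <- hourly_gain_tests_fdr(ga, gb, variant = config$t_variant)
      }
    }
    out
  })

  bundle$stats$anova_nrem <- stage("stats", {
    if (length(unique(des$genotype)) == 2 &&
        all(table(des$genotype, des$treatment) >= 2)) {
      two_way_anova(ss$delta_nrem_pp, ss$genotype, ss$treatment)
    } else NULL
  })

  if (!is.null(cohort$tmaze)) {
    bundle$tmaze <- cohort$tmaze
    bundle$stats$baseline_tmaze <- stage("stats", {
      tg <- cohort$tmaze$percent_baseline[cohort$tmaze$genotype == "Tg2576"]
      wt <- cohort$tmaze$percent_baseline[cohort$tmaze$genotype == "WT"]
      if (length(tg) >= 2 && length(wt) >= 2) independent_t(tg, wt) else NULL
    })
  }

  if (!is.null(cohort$elisa)) {
    bundle$stats$elisa <- stage("tissue", {
      en <- elisa_normalize(cohort$elisa)
      bundle$elisa <- en
      res <- list()
      tg <- en$normalized[en$normalized$genotype == "Tg2576", ]
      for (fr in unique(tg$fraction)) for (an in unique(tg$analyte)) {
        so <- tg$pg_per_mg[tg$fraction == fr & tg$analyte == an &
                             tg$treatment == "SO"]
        pl <- tg$pg_per_mg[tg$fraction == fr & tg$analyte == an &
                             tg$treatment == "placebo"]
        if (length(so) >= 2 && length(pl) >= 2) {
          res[[paste(fr, an, sep = "_")]] <-
            independent_t(so, pl, variant = "student")
        }
      }
      res
    })
  }

  if (!is.null(cohort$masks)) {
    bundle$burden <- stage("tissue", {
      cfg_f <- do.call(fractionator_config, config$fractionator)
      data.frame(
        subject = des$subject,
        burden = vapply(seq_len(nrow(des)), function(i) {
          area_fraction_fractionator(cohort$masks[[i]]$mask, cfg_f,
                                     seed = child_seed(config$seed, 600 + i))$burden
        }, 0))
    })
    bundle$stats$anova_burden <- stage("stats", {
      bb <- merge(bundle$burden, des, by = "subject")
      two_way_anova(bb$burden, bb$genotype, bb$treatment)
    })
  }

  bundle$stats$correlations <- stage("stats", {
    res <- list()
    tg <- ss[ss$genotype == "Tg2576", ]
    if (!is.null(bundle$tmaze) && nrow(tg) >= 4) {
      tm <- merge(tg, bundle$tmaze[, c("subject", "percent_baseline")],
                  by = "subject")
      succ <- tm$percent_baseline > 50
      if (any(succ) && !all(succ)) {
        res$gain_vs_performance <- biserial_from_point_biserial(
          point_biserial(tm$gain_summary_pp, succ))
      }
    }
    if (!is.null(bundle$burden) && nrow(tg) >= 3) {
      bb <- merge(tg, bundle$burden, by = "subject")
      if (nrow(bb) >= 3 && stats::var(bb$burden) > 0 &&
          stats::var(bb$gain_summary_pp) > 0) {
        res$gain_vs_burden <- pearson_corr(bb$gain_summary_pp, bb$burden)
      }
    }
    res
  })

  # --- outputs -------------------------------------------------------------
  stage("write", {
    wt <- function(d, f) utils::write.table(
      d, file.path(config$out_dir, f), sep = "\t", row.names = FALSE,
      quote = FALSE)
    wt(bundle$delta_gain, "delta_gain.tsv")
    wt(bundle$subject_summary, "subject_summary.tsv")
    if (!is.null(bundle$burden)) wt(bundle$burden, "burden.tsv")
    prov <- list(config = config[setdiff(names(config), "inputs")],
                 n_subjects = nrow(des),
                 package_version = as.character(utils::packageVersion("swaquant")))
    write_provenance_json(prov, file.path(config$out_dir, "provenance.json"))
  })

  class(bundle) <- "results_bundle"
  bundle
}

ingest_cohort <- function(inputs) {
  need <- c("subject", "genotype", "treatment", "baseline_recording",
            "baseline_hypnogram", "treatment_recording",
            "treatment_hypnogram")
  if (!all(need %in% names(inputs))) {
    stop_user("inputs table needs columns ", paste(need, collapse = ", "))
  }
  eeg <- lapply(seq_len(nrow(inputs)), function(i) {
    list(baseline = list(
           recording = read_recording_tsv(inputs$baseline_recording[i]),
           hypnogram = read_hypnogram_tsv(inputs$baseline_hypnogram[i])),
         treatment = list(
           recording = read_recording_tsv(inputs$treatment_recording[i]),
           hypnogram = read_hypnogram_tsv(inputs$treatment_hypnogram[i])))
  })
  names(eeg) <- inputs$subject
  design <- inputs[, c("subject", "genotype", "treatment")]
  design$cohort <- inputs$cohort %||% "unknown"
  list(design = design, eeg = eeg, tmaze = NULL, elisa = NULL, masks = NULL)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("Results bundle: %d subjects, outputs in %s\n",
              nrow(x$design), x$config$out_dir))
  cat("  analyses:", paste(names(x$stats), collapse = ", "), "\n")
  invisible(x)
}

#' Render a human-readable report from a results bundle
#'
#' Writes a markdown summary with sections mirroring the analysis flow
#' (delta-gain traces with administration markers, NREM-change ANOVA,
#' baseline behaviour, correlations, ELISA, plaque burden) plus PNG
#' figures. Sections whose tables are missing are skipped with a notice.
#'
#' @param bundle A [run_pipeline()] results bundle.
#' @param path Output markdown path (default `report.md` in the run's
#'   output directory); figures land alongside.
#' @return The report path, invisibly.
#' @export
make_report <- function(bundle, path = file.path(bundle$config$out_dir,
                                                 "report.md")) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- c("# Slow-wave activity intervention report", "")
  fig_dir <- dirname(path)

  lines <- c(lines, "## Hourly delta-activity gain", "")
  if (!is.null(bundle$delta_gain) && nrow(bundle$delta_gain)) {
    fig <- file.path(fig_dir, "delta_gain.png")
    grDevices::png(fig, width = 900, height = 500)
    plot_gain_traces(bundle)
    grDevices::dev.off()
    lines <- c(lines, "![hourly delta gain](delta_gain.png)", "",
               sprintf("Mean gain over summary hours (ZT %s): %.2f p.p.",
                       paste(bundle$config$summary_hours, collapse = ","),
                       mean(bundle$subject_summary$gain_summary_pp,
                            na.rm = TRUE)), "")
    for (gt in names(bundle$stats$hourly_delta_gain)) {
      ht <- bundle$stats$hourly_delta_gain[[gt]]
      nsig <- sum(ht$significant, na.rm = TRUE)
      lines <- c(lines, sprintf(
        "- %s: %d of %d hours significant after FDR correction", gt, nsig,
        nrow(ht)))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "_No gain table available._", "")

  lines <- c(lines, "## Time in NREM sleep", "")
  if (!is.null(bundle$stats$anova_nrem)) {
    eff <- bundle$stats$anova_nrem$effects
    lines <- c(lines, "Two-way ANOVA on the NREM-proportion change:", "",
               knit_effects(eff), "")
  } else lines <- c(lines, "_NREM ANOVA not available._", "")

  lines <- c(lines, "## Baseline cognitive performance", "")
  if (!is.null(bundle$stats$baseline_tmaze)) {
    tt <- bundle$stats$baseline_tmaze
    lines <- c(lines, sprintf(
      "Tg2576 vs WT percent correct: t(%.2f) = %.3f, p = %.4g, d = %.2f",
      tt$df, tt$t, tt$p, tt$d), "")
  } else lines <- c(lines, "_No behavioural table in this run._", "")

  lines <- c(lines, "## Correlations with delta gain", "")
  cr <- bundle$stats$correlations
  if (length(cr)) {
    if (!is.null(cr$gain_vs_performance)) {
      lines <- c(lines, sprintf(
        "- gain vs performance class: r_pb = %.3f, r_b = %.3f, p = %.3g",
        cr$gain_vs_performance$r_pb, cr$gain_vs_performance$r,
        cr$gain_vs_performance$p))
    }
    if (!is.null(cr$gain_vs_burden)) {
      fig <- file.path(fig_dir, "gain_vs_burden.png")
      grDevices::png(fig, width = 500, height = 500)
      plot_gain_burden(bundle)
      grDevices::dev.off()
      lines <- c(lines, sprintf(
        "- gain vs hippocampal burden: r = %.3f, p = %.3g",
        cr$gain_vs_burden$r, cr$gain_vs_burden$p),
        "", "![gain vs burden](gain_vs_burden.png)")
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "_No correlations computable._", "")

  lines <- c(lines, "## ELISA", "")
  if (!is.null(bundle$stats$elisa) && length(bundle$stats$elisa)) {
    for (nm in names(bundle$stats$elisa)) {
      tt <- bundle$stats$elisa[[nm]]
      lines <- c(lines, sprintf("- %s (SO vs placebo): t(%.2f) = %.3f, p = %.4g, d = %.2f",
                                nm, tt$df, tt$t, tt$p, tt$d))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "_No ELISA table in this run._", "")

  lines <- c(lines, "## Plaque burden", "")
  if (!is.null(bundle$stats$anova_burden)) {
    lines <- c(lines, knit_effects(bundle$stats$anova_burden$effects), "")
  } else lines <- c(lines, "_No plaque masks in this run._", "")

  writeLines(lines, path)
  invisible(path)
}

knit_effects <- function(eff) {
  c("| effect | F | df | p | partial eta sq |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %d, %d | %.4g | %.3f |",
            eff$effect, eff$F, eff$df1, eff$df2, eff$p,
            eff$partial_eta_sq))
}

plot_gain_traces <- function(bundle) {
  g <- merge(bundle$delta_gain, bundle$design, by = "subject")
  agg <- stats::aggregate(gain_pp ~ zt_hour + treatment, g, mean)
  graphics::plot(NA, xlim = range(agg$zt_hour), ylim = range(agg$gain_pp),
                 xlab = "ZT hour", ylab = "delta gain (p.p.)",
                 main = "Hourly NREM delta-activity gain")
  cols <- c(placebo = "grey50", SO = "firebrick")
  for (tr in unique(agg$treatment)) {
    a <- agg[agg$treatment == tr, ]
    graphics::lines(a$zt_hour, a$gain_pp, col = cols[[tr]], lwd = 2)
  }
  graphics::abline(v = bundle$config$simulation$treatment_admin_zt %||% c(1, 9),
                   col = "forestgreen", lty = 2)
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2)
}

plot_gain_burden <- function(bundle) {
  tg <- merge(bundle$subject_summary, bundle$design, by = "subject")
  tg <- merge(tg[tg$genotype == "Tg2576", ], bundle$burden, by = "subject")
  graphics::plot(tg$gain_summary_pp, tg$burden,
                 xlab = "delta gain (p.p.)", ylab = "plaque burden",
                 pch = 19, main = "Gain vs hippocampal burden")
  if (nrow(tg) >= 3) graphics::abline(stats::lm(burden ~ gain_summary_pp, tg),
                                      col = "firebrick")
}
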