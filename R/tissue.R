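# Amyloid plaque burden by the area-fraction fractionator, ELISA
# normalisation to tissue mass, and forced-alternation T-maze scoring.

#' Plaque label mask with region of interest
#'
#' @param plaque Logical (or 0/1) matrix of plaque-positive pixels.
#' @param roi Logical matrix of the same dimensions delimiting the region
#'   of interest.
#' @param um_per_pixel Isotropic pixel scale in micrometres.
#' @return An object of class `plaque_mask`.
#' @export
plaque_mask <- function(plaque, roi = NULL, um_per_pixel = 1) {
  plaque <- matrix(as.logical(plaque), nrow(plaque), ncol(plaque))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(plaque), ncol(plaque))
  roi <- matrix(as.logical(roi), nrow(roi), ncol(roi))
  if (!identical(dim(plaque), dim(roi))) {
    stop_user("plaque and ROI masks must share dimensions")
  }
  if (um_per_pixel <= 0) stop_user("`um_per_pixel` must be positive")
  structure(list(plaque = plaque, roi = roi, um_per_pixel = um_per_pixel),
            class = "plaque_mask")
}

#' @export
print.plaque_mask <- function(x, ...) {
  cat(sprintf("Plaque mask %d x %d px @ %g um/px; ROI %.1f%% of image, plaque %.2f%% of ROI\n",
              nrow(x$plaque), ncol(x$plaque), x$um_per_pixel,
              100 * mean(x$roi),
              100 * sum(x$plaque & x$roi) / max(sum(x$roi), 1)))
  invisible(x)
}

#' Fractionator sampling configuration
#'
#' Square counting frame and sampling grid sizes in micrometres. The study
#' defaults are a 150 um frame for the hippocampus and 200 um for the
#' cortex, with the grid equal to the frame so that the probe scans the
#' entire ROI.
#'
#' @param frame_um Counting-frame side length (um).
#' @param grid_um Sampling-grid pitch (um); must be >= `frame_um`.
#' @return An object of class `fractionator_config`.
#' @export
fractionator_config <- function(frame_um = 150, grid_um = frame_um) {
  if (frame_um <= 0) stop_user("`frame_um` must be positive")
  if (grid_um < frame_um) stop_user("grid must be at least as large as the frame")
  structure(list(frame_um = frame_um, grid_um = grid_um),
            class = "fractionator_config")
}

#' Area-fraction fractionator burden estimate
#'
#' Tiles the ROI bounding box with a square sampling grid from a seeded
#' random origin, counts plaque-positive and ROI pixels inside the counting
#' frame of each grid tile, and estimates the burden as total plaque area
#' over total ROI area within the sampled frames. Frames clipped by the ROI
#' boundary contribute their ROI-intersected pixels. With `grid = frame`
#' the frames tile the plane and the estimate equals the exhaustive pixel
#' ratio exactly.
#'
#' @param mask A [plaque_mask()].
#' @param cfg A [fractionator_config()].
#' @param seed Integer seed for the random grid origin.
#' @return Object of class `burden_estimate`: list with `burden`
#'   (dimensionless fraction), `plaque_um2`, `roi_um2`, `n_frames`, and the
#'   sampling parameters.
#' @export
area_fraction_fractionator <- function(mask, cfg = fractionator_config(),
                                       seed = NULL) {
  stopifnot(inherits(mask, "plaque_mask"), inherits(cfg, "fractionator_config"))
  if (!any(mask$roi)) stop_user("empty ROI")
  upp <- mask$um_per_pixel
  frame_px <- max(1L, round(cfg$frame_um / upp))
  grid_px <- max(frame_px, round(cfg$grid_um / upp))

  rr <- range(which(rowSums(mask$roi) > 0))
  cc <- range(which(colSums(mask$roi) > 0))

  with_seed(seed, {
    off_r <- sample.int(grid_px, 1) - grid_px   # origin in (-grid, 0]
    off_c <- sample.int(grid_px, 1) - grid_px
    r0 <- seq(rr[1] + off_r, rr[2], by = grid_px)
    c0 <- seq(cc[1] + off_c, cc[2], by = grid_px)
    plq <- 0; roi <- 0; n_frames <- 0L
    for (r in r0) for (c in c0) {
      ri <- max(r, 1):min(r + frame_px - 1, nrow(mask$roi))
      ci <- max(c, 1):min(c + frame_px - 1, ncol(mask$roi))
      if (ri[1] > ri[length(ri)] || ci[1] > ci[length(ci)]) next
      roi_px <- sum(mask$roi[ri, ci])
      if (roi_px == 0) next
      plq <- plq + sum(mask$plaque[ri, ci] & mask$roi[ri, ci])
      roi <- roi + roi_px
      n_frames <- n_frames + 1L
    }
    structure(list(burden = plq / roi,
                   plaque_um2 = plq * upp^2, roi_um2 = roi * upp^2,
                   n_frames = n_frames, frame_um = cfg$frame_um,
                   grid_um = cfg$grid_um, um_per_pixel = upp),
              class = "burden_estimate")
  })
}

#' @export
print.burden_estimate <- function(x, ...) {
  cat(sprintf("Burden %.4f (plaque %.0f um^2 / ROI %.0f um^2, %d frames of %g um, grid %g um)\n",
              x$burden, x$plaque_um2, x$roi_um2, x$n_frames, x$frame_um,
              x$grid_um))
  invisible(x)
}

#' Per-subject burden across sections
#'
#' Aggregates section-level fractionator estimates as the ratio of summed
#' plaque area to summed ROI area (total area covered with plaques over
#' total ROI area), not the mean of per-section ratios.
#'
#' @param sections List of [area_fraction_fractionator()] estimates
#'   (typically five sections per subject).
#' @return List: `burden`, `plaque_um2`, `roi_um2`, `n_sections`.
#' @export
subject_burden <- function(sections) {
  if (!length(sections)) stop_user("need >= 1 section")
  plq <- sum(vapply(sections, `[[`, 0, "plaque_um2"))
  roi <- sum(vapply(sections, `[[`, 0, "roi_um2"))
  list(burden = plq / roi, plaque_um2 = plq, roi_um2 = roi,
       n_sections = length(sections))
}

#' Normalise ELISA readouts to tissue mass
#'
#' Converts raw picogram readouts to pg per mg of brain tissue and computes
#' the Ab-42/Ab-40 ratio within each extraction fraction per subject.
#' Subjects missing one analyte of a pair get `NA` ratios and a flag.
#'
#' @param records Data frame with columns `subject`, `analyte`
#'   (`"ab40"`/`"ab42"`), `fraction` (`"soluble"`/`"insoluble"`),
#'   `raw_pg`, `tissue_mg`.
#' @return List with `normalized` (input plus `pg_per_mg`) and `ratios`
#'   (`subject`, `fraction`, `ratio_42_40`, `complete`).
#' @export
elisa_normalize <- function(records) {
  need <- c("subject", "analyte", "fraction", "raw_pg", "tissue_mg")
  if (!all(need %in% names(records))) {
    stop_user("ELISA table needs columns ", paste(need, collapse = ", "))
  }
  if (any(records$raw_pg <= 0) || any(records$tissue_mg <= 0)) {
    stop_user("raw pg and tissue mg must be positive")
  }
  records$pg_per_mg <- records$raw_pg / records$tissue_mg
  combos <- unique(records[, c("subject", "fraction")])
  ratios <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- records[records$subject == combos$subject[i] &
                     records$fraction == combos$fraction[i], ]
    a40 <- sub$pg_per_mg[sub$analyte == "ab40"]
    a42 <- sub$pg_per_mg[sub$analyte == "ab42"]
    ok <- length(a40) == 1 && length(a42) == 1
    data.frame(subject = combos$subject[i], fraction = combos$fraction[i],
               ratio_42_40 = if (ok) a42 / a40 else NA_real_,
               complete = ok)
  }))
  list(normalized = records, ratios = ratios)
}

#' Score a forced-alternation T-maze session
#'
#' Percent correct over the session's trials (four at test), classified as
#' `success` only when strictly above 50% (a 2-of-4 session is a `fail`).
#'
#' @param trials Character or logical vector of trial outcomes; `"correct"`
#'   / `TRUE` counts as correct.
#' @return Object of class `tmaze_result`: list with `correct`, `total`,
#'   `percent`, `class`.
#' @export
tmaze_score <- function(trials) {
  if (!length(trials)) stop_user("no trials")
  if (is.character(trials) || is.factor(trials)) {
    trials <- as.character(trials)
    bad <- !trials %in% c("correct", "incorrect")
    if (any(bad)) stop_user("trial outcomes must be 'correct' or 'incorrect'")
    correct <- trials == "correct"
  } else {
    correct <- as.logical(trials)
  }
  pct <- 100 * sum(correct) / length(correct)
  structure(list(correct = sum(correct), total = length(correct),
                 percent = pct,
                 class = if (pct > 50) "success" else "fail"),
            class = "tmaze_result")
}

#' Classify percent-correct scores as fail or success
#'
#' @param percent Numeric vector of percent-correct scores.
#' @return Character vector: `"success"` where strictly above 50,
#'   `"fail"` otherwise.
#' @export
tmaze_class <- function(percent) ifelse(percent > 50, "success", "fail")

#' @export
print.tmaze_result <- function(x, ...) {
  cat(sprintf("T-maze: %d/%d correct (%.0f%%) -> %s\n",
              x$correct, x$total, x$percent, x$class))
  invisible(x)
}
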