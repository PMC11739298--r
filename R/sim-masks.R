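# Synthetic plaque masks with known area fraction, plus plain-text PGM I/O
# for masks with a sidecar scale file.

#' Simulate a plaque label mask with known area fraction
#'
#' Places random non-overlapping disks inside the ROI until the plaque area
#' fraction reaches `target_fraction` (within what disk quantisation
#' allows), then reports the exact pixel-count fraction as ground truth.
#' Placement retries are bounded; an infeasible packing raises an error.
#'
#' @param width_um,height_um Image extent in micrometres.
#' @param um_per_pixel Pixel scale (um).
#' @param target_fraction Desired plaque area fraction of the ROI, in
#'   [0, 0.5].
#' @param n_plaques Number of disks to distribute (radii drawn log-normally
#'   and rescaled to meet the target area).
#' @param roi `"full"` for the whole image or `"inset"` for a centred
#'   rectangular ROI covering ~60% of the image.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per disk before giving up.
#' @return List: `mask` (a [plaque_mask()]) and `true_fraction` (exact
#'   plaque/ROI pixel ratio).
#' @export
simulate_plaque_mask <- function(width_um, height_um, um_per_pixel = 1,
                                 target_fraction = 0.1, n_plaques = 30,
                                 roi = c("full", "inset"), seed = NULL,
                                 max_tries = 200) {
  roi <- match.arg(roi)
  if (target_fraction < 0 || target_fraction > 0.5) {
    stop_user("`target_fraction` must lie in [0, 0.5]")
  }
  nr <- max(1L, round(height_um / um_per_pixel))
  nc <- max(1L, round(width_um / um_per_pixel))
  roi_m <- matrix(TRUE, nr, nc)
  if (roi == "inset") {
    roi_m[] <- FALSE
    ri <- max(1, round(nr * 0.2)):max(1, round(nr * 0.97))
    ci <- max(1, round(nc * 0.2)):max(1, round(nc * 0.97))
    roi_m[ri, ci] <- TRUE
  }
  plq <- matrix(FALSE, nr, nc)
  if (target_fraction > 0 && n_plaques > 0) {
    with_seed(seed, {
      target_px <- target_fraction * sum(roi_m)
      raw_r <- stats::rlnorm(n_plaques, 0, 0.35)
      radii <- raw_r * sqrt(target_px / sum(pi * raw_r^2))
      radii <- pmax(radii, 1)
      centres <- matrix(NA_real_, 0, 3)   # row, col, radius
      for (rad in sort(radii, decreasing = TRUE)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          r <- stats::runif(1, 1 + rad, nr - rad)
          c <- stats::runif(1, 1 + rad, nc - rad)
          if (!roi_m[round(r), round(c)]) next
          if (nrow(centres) == 0 ||
              all(sqrt((centres[, 1] - r)^2 + (centres[, 2] - c)^2) >
                  centres[, 3] + rad + 1)) {
            centres <- rbind(centres, c(r, c, rad))
            placed <- TRUE
            break
          }
        }
        if (!placed) stop_user("could not place plaque disks (infeasible packing)")
      }
      for (i in seq_len(nrow(centres))) {
        r <- centres[i, 1]; c <- centres[i, 2]; rad <- centres[i, 3]
        ri <- max(1, floor(r - rad)):min(nr, ceiling(r + rad))
        ci <- max(1, floor(c - rad)):min(nc, ceiling(c + rad))
        d2 <- outer((ri - r)^2, (ci - c)^2, `+`)
        plq[ri, ci] <- plq[ri, ci] | (d2 <= rad^2)
      }
    })
  }
  plq <- plq & roi_m
  mask <- plaque_mask(plq, roi_m, um_per_pixel)
  list(mask = mask, true_fraction = sum(plq) / sum(roi_m))
}

#' Read and write masks as plain-text PGM with a sidecar scale file
#'
#' Masks travel as ASCII PGM (P2) rasters with values 0/255 plus a sidecar
#' text file `<path>.scale` containing `um_per_pixel=<value>`. ROI masks
#' use the same carrier with suffix `_roi`.
#'
#' @param mask A [plaque_mask()].
#' @param path Output path of the plaque PGM (ROI written alongside).
#' @return `write_mask_pgm` returns `path` invisibly; `read_mask_pgm`
#'   returns a [plaque_mask()].
#' @export
write_mask_pgm <- function(mask, path) {
  write1 <- function(m, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    apply_rows <- apply(m, 1, function(r) paste(ifelse(r, 255L, 0L),
                                                collapse = " "))
    writeLines(apply_rows, con)
  }
  write1(mask$plaque, path)
  write1(mask$roi, sub("(\\.pgm)?$", "_roi.pgm", path))
  writeLines(sprintf("um_per_pixel=%g", mask$um_per_pixel),
             paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_mask_pgm
#' @export
read_mask_pgm <- function(path) {
  read1 <- function(p) {
    lines <- readLines(p)
    lines <- lines[!grepl("^#", lines)]
    if (lines[1] != "P2") stop_user("expected ASCII PGM (P2): ", p)
    dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
    matrix(vals > 0, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  }
  plq <- read1(path)
  roi_path <- sub("(\\.pgm)?$", "_roi.pgm", path)
  roi <- if (file.exists(roi_path)) read1(roi_path) else NULL
  upp <- 1
  sc <- paste0(path, ".scale")
  if (file.exists(sc)) {
    line <- grep("um_per_pixel=", readLines(sc), value = TRUE)[1]
    upp <- as.numeric(sub(".*=", "", line))
  }
  plaque_mask(plq, roi, upp)
}
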