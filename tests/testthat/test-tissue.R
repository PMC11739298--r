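# Fractionator stereology, ELISA normalisation, T-maze scoring, mask I/O.

test_that("fractionator saturation and zero cases", {
  full <- plaque_mask(matrix(TRUE, 50, 50), um_per_pixel = 2)
  expect_identical(area_fraction_fractionator(full,
                                              fractionator_config(20),
                                              seed = 1)$burden, 1)
  empty <- plaque_mask(matrix(FALSE, 50, 50), um_per_pixel = 2)
  expect_identical(area_fraction_fractionator(empty,
                                              fractionator_config(20),
                                              seed = 1)$burden, 0)
  no_roi <- plaque_mask(matrix(FALSE, 10, 10),
                        roi = matrix(FALSE, 10, 10))
  expect_error(area_fraction_fractionator(no_roi), "ROI")
  expect_error(fractionator_config(150, 100), "grid")
})

test_that("grid = frame equals exhaustive pixel counting exactly", {
  for (s in 1:10) {
    m <- simulate_plaque_mask(300, 260, um_per_pixel = 2,
                              target_fraction = runif(1, 0.02, 0.3),
                              n_plaques = 8, roi = "inset", seed = s)
    est <- area_fraction_fractionator(m$mask, fractionator_config(50),
                                      seed = 100 + s)
    expect_identical(est$burden, m$true_fraction)
  }
})

test_that("sparse grids are unbiased over random origins", {
  m <- simulate_plaque_mask(600, 600, um_per_pixel = 2,
                            target_fraction = 0.12, n_plaques = 25, seed = 3)
  cfg <- fractionator_config(frame_um = 60, grid_um = 120)
  ests <- vapply(1:100, function(s)
    area_fraction_fractionator(m$mask, cfg, seed = s)$burden, 0)
  expect_lt(abs(mean(ests) - m$true_fraction), 0.01)
  expect_gt(sd(ests), 0)    # genuinely subsampled
})

test_that("burden is invariant to joint rescaling of mask and ROI", {
  m <- simulate_plaque_mask(200, 200, um_per_pixel = 2,
                            target_fraction = 0.15, n_plaques = 6, seed = 4)
  # upscale 2x: every pixel becomes a 2x2 block at half the um/px scale
  up <- function(mm) mm[rep(seq_len(nrow(mm)), each = 2),
                        rep(seq_len(ncol(mm)), each = 2)]
  m2 <- plaque_mask(up(m$mask$plaque), up(m$mask$roi),
                    um_per_pixel = m$mask$um_per_pixel / 2)
  b1 <- area_fraction_fractionator(m$mask, fractionator_config(40), seed = 9)
  b2 <- area_fraction_fractionator(m2, fractionator_config(40), seed = 9)
  expect_equal(b1$burden, b2$burden, tolerance = 1e-12)
  expect_equal(b1$roi_um2, b2$roi_um2, tolerance = 1e-12)
})

test_that("subject burden is the ratio of sums and order-invariant", {
  sec <- function(p, r) structure(list(burden = p / r, plaque_um2 = p,
                                       roi_um2 = r),
                                  class = "burden_estimate")
  expect_equal(subject_burden(list(sec(10, 100), sec(30, 100)))$burden, 0.2)
  five <- replicate(5, sec(10, 100), simplify = FALSE)
  expect_equal(subject_burden(five)$burden, 0.1)
  expect_equal(subject_burden(list(sec(7, 50)))$burden, 0.14)
  expect_equal(subject_burden(list(sec(10, 100), sec(30, 100)))$burden,
               subject_burden(list(sec(30, 100), sec(10, 100)))$burden)
  expect_error(subject_burden(list()), "section")
})

test_that("ELISA normalisation and 42/40 ratios", {
  rec <- data.frame(subject = c("a", "a", "b"),
                    analyte = c("ab40", "ab42", "ab40"),
                    fraction = "insoluble",
                    raw_pg = c(100, 100, 60), tissue_mg = c(20, 20, 12))
  en <- elisa_normalize(rec)
  expect_equal(en$normalized$pg_per_mg, c(5, 5, 5))
  ra <- en$ratios
  expect_equal(ra$ratio_42_40[ra$subject == "a"], 1)
  expect_true(is.na(ra$ratio_42_40[ra$subject == "b"]))
  expect_false(ra$complete[ra$subject == "b"])
  expect_error(elisa_normalize(transform(rec, tissue_mg = 0)), "positive")
})

test_that("simulated insoluble groups regenerate the published separation", {
  ts <- vapply(1:200, function(s) {
    set.seed(s)
    so <- rnorm(5, 4.982, 0.379)
    pl <- rnorm(5, 4.459, 0.158)
    independent_t(so, pl, variant = "student")$t
  }, 0)
  # the mean of a noncentral t exceeds its noncentrality: correct by the
  # exact factor sqrt(df/2) * gamma((df-1)/2) / gamma(df/2) before comparing
  # with the t implied by the generating summaries
  ncp_target <- (4.982 - 4.459) / sqrt((0.379^2 + 0.158^2) / 5)
  corr <- sqrt(8 / 2) * gamma(3.5) / gamma(4)
  expect_lt(abs(mean(ts) / corr - ncp_target), 0.3)
  expect_equal(ncp_target, 2.846, tolerance = 0.002)
})

test_that("T-maze scoring applies the strict >50% success rule", {
  r <- tmaze_score(c("correct", "correct", "incorrect", "incorrect"))
  expect_equal(r$percent, 50)
  expect_identical(r$class, "fail")
  r3 <- tmaze_score(c("correct", "correct", "correct", "incorrect"))
  expect_equal(r3$percent, 75)
  expect_identical(r3$class, "success")
  expect_identical(tmaze_score(rep("incorrect", 4))$percent, 0)
  expect_identical(tmaze_score(rep("incorrect", 4))$class, "fail")
  expect_error(tmaze_score(character(0)), "trials")
  expect_error(tmaze_score(c("correct", "maybe")), "outcomes")
  expect_identical(tmaze_class(c(50, 50.1)), c("fail", "success"))
})

test_that("masks round-trip through ASCII PGM with their scale", {
  m <- simulate_plaque_mask(80, 60, um_per_pixel = 2, target_fraction = 0.1,
                            n_plaques = 3, roi = "inset", seed = 5)
  path <- file.path(tempdir(), "mask_test.pgm")
  write_mask_pgm(m$mask, path)
  back <- read_mask_pgm(path)
  expect_identical(back$plaque, m$mask$plaque)
  expect_identical(back$roi, m$mask$roi)
  expect_identical(back$um_per_pixel, m$mask$um_per_pixel)
})
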