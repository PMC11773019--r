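test_that("segmentation handles empty and degenerate images gracefully", {
  flat <- matrix(0.5, 64, 64)
  rec <- segment_nuclei(flat)
  expect_identical(nrow(rec), 0L)
  expect_identical(attr(rec, "flag"), "degenerate_image")
  set.seed(1)
  noise_only <- matrix(0.08 + rnorm(64^2, 0, 0.008), 64, 64)
  rec2 <- segment_nuclei(noise_only)
  expect_identical(nrow(rec2), 0L)
})

test_that("planted non-overlapping nuclei are recovered with sub-2px centroids", {
  tr <- ground_truth("m1", effects = 1)
  out <- render_well_image(list(well = "C05", role = "sample",
                                mirna_id = "m1"), tr,
                           imaging_params(nuclei_per_well = 50,
                                          fixed_count = TRUE), seed = 11)
  rec <- segment_nuclei(out$image)
  expect_identical(nrow(rec), 50L)
  idx <- match_planted(out$labels, rec, max_dist = 2)
  expect_false(anyNA(idx))
  expect_identical(sort(idx), 1:50)
})

test_that("touching nuclei are split by the watershed at an aggressive tolerance", {
  # one visible-radius apart: lobes merged into a dumbbell mask
  img <- two_blob_image(dist = 12, sigma = 4)
  merged <- segment_nuclei(img, seg_params(min_area = 10))
  split <- segment_nuclei(img, seg_params(min_area = 10,
                                          watershed_tolerance = 0.1))
  expect_identical(nrow(split), 2L)
  # far apart: two objects under any tolerance
  far <- two_blob_image(dist = 30, sigma = 4)
  expect_identical(nrow(segment_nuclei(far, seg_params(min_area = 10))), 2L)
})

test_that("two-threshold classifier follows the fitted robust criteria", {
  # healthy-template records: none dying
  healthy <- data.frame(mean_intensity = rep(0.27, 30) + (1:30) * 1e-4,
                        area = rep(150, 30) + (1:30) * 0.1)
  lab <- classify_nuclei(healthy,
                         clf_params(intensity_threshold = 0.35,
                                    area_threshold = 80))
  expect_true(all(lab$label == "healthy"))

  # a nucleus at +4 robust-z intensity and -3 robust-z area must be dying
  set.seed(21)
  ctrl <- data.frame(mean_intensity = rnorm(200, 0.27, 0.01),
                     area = rnorm(200, 150, 12))
  med_i <- median(ctrl$mean_intensity); mad_i <- mad(ctrl$mean_intensity)
  med_a <- median(ctrl$area); mad_a <- mad(ctrl$area)
  probe <- data.frame(mean_intensity = med_i + 4 * mad_i,
                      area = med_a - 3 * mad_a)
  lab2 <- classify_nuclei(probe, clf_params(k = 3), control_records = ctrl)
  expect_identical(lab2$label, "dying")

  expect_error(classify_nuclei(probe, clf_params()), "control")
})

test_that("estimated dying fraction tracks the planted fraction", {
  fx <- small_imaging()
  rec <- classify_nuclei(segment_nuclei(fx$well$image), clf_params(),
                         control_records = fx$control_records)
  est <- mean(rec$label == "dying")
  planted <- mean(fx$well$labels$dying)
  expect_lt(abs(est - planted), 0.03)
})

test_that("classification is monotone in the intensity criterion", {
  fx <- small_imaging()
  rec <- segment_nuclei(fx$well$image)
  counts <- sapply(seq(0.2, 0.6, by = 0.05), function(thr)
    sum(classify_nuclei(rec, clf_params(intensity_threshold = thr,
                                        area_threshold = 100))$label == "dying"))
  expect_true(all(diff(counts) <= 0))
})

test_that("well measurement computes percentages and applies the validity floor", {
  mk <- function(n, nd) data.frame(label = rep(c("dying", "healthy"),
                                               c(nd, n - nd)))
  expect_equal(measure_well(mk(100, 0), "P", "A01", "sample")$percent_dying, 0)
  expect_equal(measure_well(mk(80, 20), "P", "A01", "sample")$percent_dying, 25)
  expect_false(measure_well(mk(30, 3), "P", "A01", "sample")$valid)
  empty <- measure_well(mk(0, 0)[0, , drop = FALSE], "P", "A01", "sample")
  expect_false(empty$valid)
  expect_true(is.na(empty$percent_dying))
  # permutation invariance
  rec <- mk(80, 20)
  set.seed(3)
  shuf <- rec[sample.int(80), , drop = FALSE]
  expect_equal(measure_well(rec, "P", "A01", "sample")$percent_dying,
               measure_well(shuf, "P", "A01", "sample")$percent_dying)
})

test_that("transfection efficiency spans its trivial extremes and recovers 50%", {
  fx <- small_imaging()
  img <- fx$well$image
  # all-background red channel -> 0
  set.seed(5)
  bg_red <- matrix(0.05 + rnorm(length(img), 0, 0.005), nrow(img))
  expect_equal(as.numeric(estimate_transfection_efficiency(img, bg_red)), 0)
  # red blob over every nucleus -> 1 (reuse the stain channel as marker)
  expect_equal(as.numeric(estimate_transfection_efficiency(img, img)), 1)
  expect_error(estimate_transfection_efficiency(img, NULL), "red channel")
  expect_error(estimate_transfection_efficiency(img, bg_red[1:10, 1:10]),
               "dimensions")

  # generator at 50%: estimate within 0.05 over a few wells
  tr <- fx$truth
  well <- list(well = "P24", role = "transfection_control", mirna_id = NA)
  est <- sapply(1:4, function(s) {
    out <- render_well_image(well, tr, imaging_params(), seed = 600 + s)
    as.numeric(estimate_transfection_efficiency(out$image, out$red))
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})
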