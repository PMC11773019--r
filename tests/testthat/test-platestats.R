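# hand-rolled mean/SD oracle, independent of the implementation path
oracle_mean <- function(v) sum(v) / length(v)
oracle_sd <- function(v) {
  m <- oracle_mean(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

make_plate <- function(light, dark, samples, plate = "P1") {
  data.frame(plate_id = plate,
             well = sprintf("W%03d", seq_len(length(light) + length(dark) +
                                               length(samples))),
             role = rep(c("light_control", "dark_control", "sample"),
                        c(length(light), length(dark), length(samples))),
             mirna_id = c(rep(NA, length(light) + length(dark)),
                          sprintf("mir-%03d", seq_along(samples))),
             replicate = 1L,
             percent_dying = c(light, dark, samples),
             valid = TRUE, stringsAsFactors = FALSE)
}

test_that("plate QC statistics equal an independent mean/SD recomputation", {
  fx <- small_screen()
  wt <- fx$well_table[fx$well_table$plate_id == fx$well_table$plate_id[1], ]
  qc <- qc_plate(wt)
  light <- wt$percent_dying[wt$role == "light_control" & wt$valid]
  dark <- wt$percent_dying[wt$role == "dark_control" & wt$valid]
  expect_equal(qc$mu_light, oracle_mean(light), tolerance = 1e-12)
  expect_equal(qc$sigma_light, oracle_sd(light), tolerance = 1e-12)
  expect_equal(qc$mu_dark, oracle_mean(dark), tolerance = 1e-12)
  pooled <- sqrt(((length(light) - 1) * oracle_sd(light)^2 +
                    (length(dark) - 1) * oracle_sd(dark)^2) /
                   (length(light) + length(dark) - 2))
  expect_equal(qc$separation_stat,
               (oracle_mean(light) - oracle_mean(dark)) / pooled,
               tolerance = 1e-12)
  expect_true(qc$passed)  # dark ~5%, light ~40%: must separate
})

test_that("QC fails when light and dark controls are indistinguishable", {
  set.seed(8)
  wt <- make_plate(light = rnorm(16, 20, 3), dark = rnorm(16, 20, 3),
                   samples = rnorm(40, 20, 3))
  qc <- qc_plate(wt)
  expect_false(qc$passed)
  expect_error(zscore_wells(wt, qc), "failed QC")
  expect_silent(zscore_wells(wt, qc, override_qc = TRUE))
})

test_that("degenerate control sets are rejected or flagged", {
  wt <- make_plate(light = c(40, 41), dark = 5, samples = c(30, 35))
  expect_error(qc_plate(wt), ">= 2 valid")
  wt2 <- make_plate(light = c(40, 40, 40), dark = c(5, 6, 4),
                    samples = c(30, 35))
  qc2 <- qc_plate(wt2)
  expect_false(qc2$passed)
  expect_match(qc2$reason, "sigma_light")
  expect_error(zscore_wells(wt2, qc2, override_qc = TRUE), "Z undefined")
})

test_that("Z scores follow the formula exactly, per plate, for samples only", {
  fx <- small_screen()
  pid <- fx$well_table$plate_id[1]
  wt <- fx$well_table[fx$well_table$plate_id == pid, ]
  qc <- qc_plate(wt)
  z <- zscore_wells(wt, qc)
  # brute-force elementwise loop oracle
  for (i in seq_len(nrow(z))) {
    x <- wt$percent_dying[wt$well == z$well[i]]
    expect_equal(z$z[i], (x - qc$mu_light) / qc$sigma_light,
                 tolerance = 1e-12)
  }
  expect_setequal(z$well, wt$well[wt$role == "sample" & wt$valid])
  # formula identities
  expect_equal((qc$mu_light - qc$mu_light) / qc$sigma_light, 0)
  expect_identical((29.5 - 40) / 5, -2.1)
  # cross-plate scoring is refused
  other <- fx$well_table[fx$well_table$plate_id != pid, ]
  expect_error(zscore_wells(other, qc), "same single plate")
})

test_that("Z is equivariant under control-coupled shifts and monotone in x", {
  wt <- make_plate(light = c(38, 40, 42, 41, 39), dark = c(4, 5, 6, 5, 5),
                   samples = c(20, 30, 40, 50))
  qc <- qc_plate(wt)
  z0 <- zscore_wells(wt, qc)
  # shift everything (controls included): Z unchanged
  wt_all <- wt; wt_all$percent_dying <- wt_all$percent_dying + 7
  z1 <- zscore_wells(wt_all, qc_plate(wt_all))
  expect_equal(z1$z, z0$z, tolerance = 1e-12)
  # shift samples only: Z moves by c / sigma
  wt_s <- wt
  s_idx <- wt_s$role == "sample"
  wt_s$percent_dying[s_idx] <- wt_s$percent_dying[s_idx] + 7
  z2 <- zscore_wells(wt_s, qc_plate(wt_s))
  expect_equal(z2$z, z0$z + 7 / qc$sigma_light, tolerance = 1e-12)
  # strictly increasing in x
  expect_true(all(diff(z0$z[order(z0$x)]) > 0))
})

test_that("under the null the sample Z distribution is standard-normal-like", {
  ids <- sprintf("sim-mir-%04d", 1:320)
  lay <- generate_layout(320, replicate_count = 2, seed = 33)
  tr <- ground_truth(ids)
  wt <- simulate_well_table(lay, tr, seed = 34)
  sc <- score_screen(wt)
  z <- do.call(rbind, sc$zscores)$z
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.3)
})
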