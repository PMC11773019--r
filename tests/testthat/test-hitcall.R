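ztab <- function(ids, z, norm = 1 + z * 0.09, r = 1L)
  data.frame(plate_id = "P", well = sprintf("W%02d", seq_along(ids)),
             mirna_id = ids, replicate = r, x = 40 * norm, norm = norm,
             z = z, stringsAsFactors = FALSE)

test_that("replicate aggregation reproduces hand arithmetic", {
  zt <- lapply(1:3, function(r) ztab("a", -2.0, norm = 0.8, r = r))
  sc <- aggregate_replicates(zt)
  expect_equal(sc$mean_z, -2.0)
  expect_equal(sc$cv, 0)   # identical normalized fractions across replicates

  zt2 <- Map(function(z, r) ztab("b", z, r = r), c(-3.0, -2.5, -2.9), 1:3)
  sc2 <- aggregate_replicates(zt2)
  expect_equal(sc2$mean_z, -2.8)
  norms <- 1 + c(-3.0, -2.5, -2.9) * 0.09
  expect_equal(sc2$cv, sd(norms) / mean(norms), tolerance = 1e-12)
})

test_that("aggregation over a full screen equals brute-force recomputation", {
  fx <- small_screen()
  sc <- score_screen(fx$well_table)
  scores <- aggregate_replicates(sc$zscores)
  z_all <- do.call(rbind, sc$zscores)
  for (id in sample(scores$mirna_id, 10)) {
    expect_equal(scores$mean_z[scores$mirna_id == id],
                 mean(z_all$z[z_all$mirna_id == id]), tolerance = 1e-12)
    nv <- z_all$norm[z_all$mirna_id == id]
    expect_equal(scores$cv[scores$mirna_id == id], sd(nv) / mean(nv),
                 tolerance = 1e-12)
  }
  # ranking is a dense permutation ordered by mean Z
  expect_setequal(scores$rank, seq_len(nrow(scores)))
  expect_true(all(diff(scores$mean_z[order(scores$rank)]) >= 0))
})

test_that("duplicated miRNA within a replicate is rejected with context", {
  zt <- list(rbind(ztab("a", -1), ztab("a", -2)))
  expect_error(aggregate_replicates(zt), "more than once")
})

test_that("cutoffs define protective and deleterious membership", {
  zt <- lapply(1:3, function(r)
    ztab(c("A", "B", "C"), c(-2.2, -2.0, 2.5), r = r))
  scores <- aggregate_replicates(zt)
  hits <- suppressWarnings(rank_and_filter(scores, c("A", "B", "C")))
  expect_identical(hits$protective, "A")
  expect_identical(hits$deleterious, "C")
  expect_identical(hits$shortlist, "A")
})

test_that("the filter funnel is monotone and nested", {
  fx <- small_screen()
  sc <- aggregate_replicates(score_screen(fx$well_table)$zscores)
  annot <- sc$mirna_id[seq(1, nrow(sc), by = 2)]
  loose <- suppressWarnings(
    rank_and_filter(sc, annot, hit_config(z_cutoff_protective = -1.5,
                                          z_cutoff_deleterious = 1.5)))
  tight <- suppressWarnings(
    rank_and_filter(sc, annot, hit_config(z_cutoff_protective = -2.5,
                                          z_cutoff_deleterious = 2.5)))
  expect_true(all(tight$protective %in% loose$protective))
  expect_true(all(tight$deleterious %in% loose$deleterious))
  expect_true(all(loose$shortlist %in% loose$protective))
  cts <- loose$provenance$counts
  expect_true(cts[["shortlist"]] <= cts[["annotated"]])
  expect_true(cts[["annotated"]] <= cts[["below_protective_cutoff"]])
  expect_true(cts[["below_protective_cutoff"]] <= cts[["scored"]])
})

test_that("top_n beyond the survivor count warns and returns all survivors", {
  zt <- lapply(1:3, function(r) ztab(c("A", "B"), c(-2.5, -3), r = r))
  scores <- aggregate_replicates(zt)
  expect_warning(hits <- rank_and_filter(scores, c("A", "B"),
                                         hit_config(top_n = 6)),
                 "smaller than top_n")
  expect_setequal(hits$shortlist, c("A", "B"))
})

test_that("annotation matching strips species prefixes and case", {
  expect_identical(canonical_mirna_id(c("hsa-miR-429", "miR-429", "MIR-429")),
                   rep("mir-429", 3))
  zt <- lapply(1:3, function(r) ztab("hsa-miR-429", -3, r = r))
  hits <- suppressWarnings(rank_and_filter(aggregate_replicates(zt), "miR-429"))
  expect_identical(hits$shortlist, "hsa-miR-429")
  hits2 <- suppressWarnings(rank_and_filter(aggregate_replicates(zt), "miR-999"))
  expect_length(hits2$shortlist, 0)
  expect_error(rank_and_filter(aggregate_replicates(zt), character(0)),
               "annotation")
})

test_that("miRNAs missing a replicate are excluded unless relaxed", {
  zt <- list(ztab(c("A", "B"), c(-3, -3), r = 1),
             ztab(c("A", "B"), c(-3, -3), r = 2),
             ztab("A", -3, r = 3))
  scores <- aggregate_replicates(zt)
  hits <- suppressWarnings(rank_and_filter(scores, c("A", "B")))
  expect_false("B" %in% hits$protective)
  hits2 <- suppressWarnings(
    rank_and_filter(scores, c("A", "B"), hit_config(allow_partial = TRUE)))
  expect_true("B" %in% hits2$protective)
})

test_that("planted protectors are recovered in a small screen", {
  ids <- sprintf("sim-mir-%04d", 1:300)
  planted <- ids[1:5]
  eff <- setNames(rep(0.5, 5), planted)
  lay <- generate_layout(300, replicate_count = 3, seed = 55)
  tr <- ground_truth(ids, effects = eff)
  wt <- simulate_well_table(lay, tr, seed = 56)
  sc <- aggregate_replicates(score_screen(wt)$zscores)
  hits <- rank_and_filter(sc, ids, hit_config(top_n = 5))
  expect_true(all(planted %in% hits$protective))
  expect_setequal(hits$shortlist, planted)
})
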