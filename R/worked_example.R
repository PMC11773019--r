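#' Synthetic worked-example screen summary (1,268 miRNAs)
#'
#' Generates a fully synthetic per-miRNA screen summary emulating the scale
#' and outcome structure of a published-style 1,268-miRNA light-protection
#' screen: three replicate Z scores per miRNA, a small protective tail below
#' the -2.1 cutoff, a small deleterious tail above +2.1, and a curated
#' annotation set (MirGeneDB-style membership list). Six well-known
#' protective miRNAs — miR-150-3p, miR-346, miR-371a-5p, miR-429,
#' miR-514b-5p and miR-5010-5p — are planted as the annotated, reproducible
#' hits, with miR-429 carrying the lowest mean Z; additional planted entries
#' exercise every filter: annotated sub-cutoff miRNAs with excessive
#' replicate variability (removed by the CV selection) and unannotated
#' sub-cutoff miRNAs (removed by the annotation filter).
#'
#' This is synthetic data for demonstrations and end-to-end testing of the
#' hit-calling stage; the numbers are generated, not measured.
#'
#' @param seed integer seed for the null background draws; the planted
#'   entries are jittered but their ordering properties hold for any seed.
#' @param n_mirnas total number of distinct miRNAs (default 1268).
#' @return list with `zscores` — a list of three per-replicate data frames
#'   (`mirna_id`, `replicate`, `x`, `norm`, `z`) as produced by
#'   [zscore_wells()] — and `annotation`, the membership id list.
#' @examples
#' we <- synthetic_screen_summary(seed = 1)
#' sapply(we$zscores, nrow)
#' @export
synthetic_screen_summary <- function(seed = 1, n_mirnas = 1268) {
  if (n_mirnas < 40) stop("worked example needs at least 40 miRNAs")
  set.seed(seed)
  shortlist <- c("hsa-miR-429", "hsa-miR-150-3p", "hsa-miR-346",
                 "hsa-miR-371a-5p", "hsa-miR-514b-5p", "hsa-miR-5010-5p")
  n_cv_fail <- 4L   # annotated, Z < -2.1, but irreproducible across replicates
  n_unannot <- 3L   # strong Z but absent from the curated database
  n_delet <- 5L     # deleterious tail, Z > 2.1
  n_planted <- length(shortlist) + n_cv_fail + n_unannot + n_delet
  ids <- c(shortlist,
           sprintf("hsa-miR-cvfail-%d", seq_len(n_cv_fail)),
           sprintf("hsa-miR-novel-%d", seq_len(n_unannot)),
           sprintf("hsa-miR-delet-%d", seq_len(n_delet)),
           sprintf("hsa-miR-sim-%04d", seq_len(n_mirnas - n_planted)))

  # normalized dying fraction (x / mu_light) per replicate; z = (norm - 1)/s
  # with s the light-control CV typical of the simulated screen
  s <- 0.09
  m <- matrix(NA_real_, n_mirnas, 3, dimnames = list(ids, NULL))
  # planted shortlist: strong protection, tight replicates; miR-429 strongest
  target_mean <- c(-4.2, -3.1, -2.9, -2.7, -2.5, -2.3)
  for (i in seq_along(shortlist))
    m[shortlist[i], ] <- 1 + s * (target_mean[i] + c(-0.08, 0, 0.08) +
                                    stats::rnorm(3, 0, 0.03))
  # annotated but irreproducible: same mean pull, wildly spread replicates
  for (i in seq_len(n_cv_fail))
    m[length(shortlist) + i, ] <- 1 + s * (-2.6 + c(-1.8, 0, 1.8) +
                                             stats::rnorm(3, 0, 0.1))
  # strong but unannotated
  for (i in seq_len(n_unannot))
    m[length(shortlist) + n_cv_fail + i, ] <-
      1 + s * (-3.0 + stats::rnorm(3, 0, 0.15))
  # deleterious tail
  for (i in seq_len(n_delet))
    m[length(shortlist) + n_cv_fail + n_unannot + i, ] <-
      1 + s * (2.4 + i / 4 + stats::rnorm(3, 0, 0.15))
  # null background: replicate-mean Z ~ N(0, 1/sqrt(3)), clipped away from
  # the cutoffs so the planted structure is the only signal; per-replicate
  # deviations are mean-centred so the clip bounds the realized mean exactly
  nb <- n_mirnas - n_planted
  null_mean <- pmin(1.9, pmax(-1.9, stats::rnorm(nb, 0, 1 / sqrt(3))))
  dev <- matrix(stats::rnorm(3 * nb, 0, 0.55), nb, 3)
  dev <- dev - rowMeans(dev)
  m[n_planted + seq_len(nb), ] <- 1 + s * (null_mean + dev)

  zscores <- lapply(1:3, function(r)
    data.frame(plate_id = NA_character_, well = NA_character_,
               mirna_id = ids, replicate = r,
               x = 40 * m[, r], norm = m[, r], z = (m[, r] - 1) / s,
               stringsAsFactors = FALSE))

  # curated membership: planted hits and CV failures are bona fide entries,
  # plus roughly half of the unremarkable background
  annotation <- c(shortlist,
                  sprintf("hsa-miR-cvfail-%d", seq_len(n_cv_fail)),
                  sample(ids[n_planted + seq_len(nb)], size = round(nb * 0.45)))
  list(zscores = zscores, annotation = sort(annotation))
}
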