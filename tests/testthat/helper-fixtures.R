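# fixtures computed once per test run and shared across files
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small fast-mode screen: 50 miRNAs x 3 replicates, one planted protector
small_screen <- function() cached("small_screen", {
  ids <- sprintf("sim-mir-%04d", 1:50)
  layouts <- generate_layout(50, replicate_count = 3, seed = 101)
  truth <- ground_truth(ids, effects = c("sim-mir-0007" = 0.5))
  wt <- simulate_well_table(layouts, truth, seed = 202)
  list(ids = ids, layouts = layouts, truth = truth, well_table = wt)
})

# a rendered sample well plus dark-control nuclei for classifier fitting
small_imaging <- function() cached("small_imaging", {
  tr <- ground_truth("m1", effects = 0.5)  # sample dying prob 0.2
  ctrl <- NULL
  for (s in 1:3) {
    im <- render_well_image(list(well = "A01", role = "dark_control",
                                 mirna_id = NA), tr,
                            imaging_params(), seed = 400 + s)
    ctrl <- rbind(ctrl, segment_nuclei(im$image))
  }
  well <- render_well_image(list(well = "C05", role = "sample",
                                 mirna_id = "m1"), tr,
                            imaging_params(), seed = 7)
  list(truth = tr, control_records = ctrl, well = well)
})

# match detected centroids to planted ones; returns planted index per object
match_planted <- function(labels, records, max_dist = 3) {
  dd <- outer(labels$x, records$x, "-")^2 + outer(labels$y, records$y, "-")^2
  idx <- apply(dd, 2, which.min)
  idx[sqrt(dd[cbind(idx, seq_len(ncol(dd)))]) > max_dist] <- NA
  idx
}

# image with two Gaussian nuclei a given centre distance apart
two_blob_image <- function(dist, sigma = 4, size = 64, a = 0.3, bg = 0.08,
                           seed = 1) {
  img <- matrix(bg, size, size)
  for (cc in c(size / 2 - dist / 2, size / 2 + dist / 2))
    img <- img + a * outer(exp(-((1:size - cc)^2) / (2 * sigma^2)),
                           exp(-((1:size - size / 2)^2) / (2 * sigma^2)))
  set.seed(seed)
  pmin(img + matrix(stats::rnorm(size^2, 0, 0.008), size, size), 1)
}
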