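#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma in px (default 1).
#' @param min_area minimum object area in px^2; smaller objects are debris
#'   and discarded (default 20).
#' @param watershed_tolerance,watershed_ext tuning of the distance-transform
#'   watershed used to split touching nuclei. The default tolerance (0.5)
#'   avoids over-segmenting speckled apoptotic nuclei; for fields with many
#'   genuinely touching nuclei a lower tolerance (e.g. 0.1) splits more
#'   aggressively.
#' @param discard_edge drop objects touching the image border (default TRUE);
#'   truncated nuclei bias both area and intensity.
#' @return A `seg_params` list.
#' @export
seg_params <- function(smooth_sigma = 1, min_area = 20,
                       watershed_tolerance = 0.5, watershed_ext = 1,
                       discard_edge = TRUE) {
  structure(as.list(environment()), class = "seg_params")
}

#' Segment nuclei from a nuclear-stain image
#'
#' Standard operator chain for round fluorescent objects: Gaussian smoothing,
#' global Otsu threshold, morphological opening, distance-transform watershed
#' to split touching nuclei, then minimum-area and (optionally) edge filters.
#' Per nucleus it extracts the features the healthy/dying classifier uses:
#' area, mean and integrated intensity, circularity (`4 * pi * area /
#' perimeter^2`) and intensity dispersion (the CV of pixel intensities
#' within the mask, a chromatin-condensation proxy).
#'
#' @param image numeric matrix in \[0, 1\] (single channel).
#' @param params a [seg_params()].
#' @return data frame of unlabeled `NucleusRecord`s: `nucleus_id`, `x`, `y`
#'   (centroid, px), `area`, `mean_intensity`, `integrated_intensity`,
#'   `circularity`, `intensity_dispersion`, `label` (`NA`). A constant or
#'   saturated image yields zero rows with `attr(, "flag") =
#'   "degenerate_image"` rather than an error.
#' @examples
#' tr <- ground_truth("m1")
#' img <- render_well_image(list(well = "C03", role = "sample",
#'                               mirna_id = "m1"), tr,
#'                          imaging_params(nuclei_per_well = 15), seed = 4)
#' nrow(segment_nuclei(img$image))
#' @export
segment_nuclei <- function(image, params = seg_params()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  empty <- data.frame(nucleus_id = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), mean_intensity = numeric(0),
                      integrated_intensity = numeric(0),
                      circularity = numeric(0),
                      intensity_dispersion = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  rng <- range(image)
  if (diff(rng) < 1e-6) {  # constant or fully saturated frame
    attr(empty, "flag") <- "degenerate_image"
    return(empty)
  }
  img <- EBImage::Image(image)
  sm <- EBImage::gblur(img, sigma = params$smooth_sigma)
  th <- EBImage::otsu(sm, range = rng)
  mask <- sm > th
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, shape = "diamond"))
  # foreground must stand clear of the background noise floor, otherwise
  # Otsu is just bisecting noise (e.g. an empty well)
  bg_px <- image[!mask]
  contrast_ok <- sum(mask) > 0 &&
    mean(image[mask]) - mean(bg_px) > 6 * stats::mad(bg_px)
  if (!contrast_ok) {
    attr(empty, "flag") <- "no_foreground"
    return(empty)
  }
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = params$watershed_ext)
  n_obj <- max(lab)
  if (n_obj == 0) return(empty)

  shape <- EBImage::computeFeatures.shape(lab)
  basic <- EBImage::computeFeatures.basic(lab, img)
  mom <- EBImage::computeFeatures.moment(lab, img)
  area <- shape[, "s.area"]
  perim <- pmax(shape[, "s.perimeter"], 1)
  rec <- data.frame(nucleus_id = seq_len(nrow(shape)),
                    x = mom[, "m.cx"], y = mom[, "m.cy"],
                    area = area,
                    mean_intensity = basic[, "b.mean"],
                    integrated_intensity = basic[, "b.mean"] * area,
                    circularity = pmin(1, 4 * pi * area / perim^2),
                    intensity_dispersion = basic[, "b.sd"] /
                      pmax(basic[, "b.mean"], 1e-12),
                    label = NA_character_, stringsAsFactors = FALSE)
  keep <- rec$area >= params$min_area
  if (params$discard_edge) {
    edge_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- keep & !(rec$nucleus_id %in% edge_ids[edge_ids > 0])
  }
  rec <- rec[keep, ]
  rec$nucleus_id <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  rec
}

#' Classifier parameters
#'
#' @param method `"thresholds"` (default): a nucleus is dying iff its mean
#'   intensity is at or above the intensity criterion AND its area at or
#'   below the area criterion; `"cluster"`: 2-component k-means on scaled
#'   (intensity, area), the brighter/smaller cluster labeled dying.
#' @param intensity_threshold,area_threshold fixed criteria; leave `NULL` to
#'   fit them from control nuclei.
#' @param k robust-z multiplier when fitting from controls: criteria are
#'   `median + k * MAD` (intensity) and `median - k * MAD` (area) of the
#'   dark-control nucleus population (default 3).
#' @return A `clf_params` list.
#' @export
clf_params <- function(method = c("thresholds", "cluster"),
                       intensity_threshold = NULL, area_threshold = NULL,
                       k = 3) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "clf_params")
}

#' Classify segmented nuclei as healthy or dying
#'
#' Dying (apoptotic/pyknotic) nuclei are brighter and smaller than healthy
#' ones; the default rule labels a nucleus dying iff it exceeds the
#' intensity criterion and falls at or below the area criterion. Criteria
#' are either fixed in `params` or fit per plate from the dark-control
#' nucleus population as median +/- k * MAD — dark controls are the
#' overwhelmingly healthy reference, and robust statistics tolerate their
#' small dying minority.
#'
#' @param records nucleus records from [segment_nuclei()].
#' @param params a [clf_params()].
#' @param control_records dark-control nucleus records used to fit the
#'   criteria; required when thresholds are not fixed.
#' @return `records` with `label` filled (`"healthy"`/`"dying"`) and the
#'   criteria used attached as `attr(, "thresholds")`.
#' @export
classify_nuclei <- function(records, params = clf_params(),
                            control_records = NULL) {
  if (nrow(records) == 0) return(records)
  if (params$method == "cluster") {
    feats <- scale(cbind(records$mean_intensity, records$area))
    km <- stats::kmeans(feats, centers = 2, nstart = 5)
    cen <- km$centers
    dying_cl <- which.max(cen[, 1] - cen[, 2])  # brighter and smaller
    records$label <- ifelse(km$cluster == dying_cl, "dying", "healthy")
    return(records)
  }
  int_thr <- params$intensity_threshold
  area_thr <- params$area_threshold
  if (is.null(int_thr) || is.null(area_thr)) {
    if (is.null(control_records) || nrow(control_records) < 10)
      stop("threshold fitting needs >= 10 control nuclei; pass ",
           "control_records or fix the thresholds in clf_params")
    med_i <- stats::median(control_records$mean_intensity)
    mad_i <- stats::mad(control_records$mean_intensity)
    med_a <- stats::median(control_records$area)
    mad_a <- stats::mad(control_records$area)
    if (is.null(int_thr)) int_thr <- med_i + params$k * mad_i
    if (is.null(area_thr)) area_thr <- med_a - params$k * mad_a
  }
  records$label <- ifelse(records$mean_intensity >= int_thr &
                            records$area <= area_thr, "dying", "healthy")
  attr(records, "thresholds") <- c(intensity = int_thr, area = area_thr)
  records
}

#' Summarize one well's labeled nuclei
#'
#' @param records labeled nucleus records for a single well.
#' @param plate_id,well,role,mirna_id,replicate well context.
#' @param min_nuclei validity floor (default 50): wells with fewer nuclei
#'   give unstable percentages and are flagged invalid so they drop out of
#'   control statistics and Z scoring.
#' @return one-row data frame (`WellMeasurement`): context, `n_nuclei`,
#'   `n_dying`, `percent_dying`, `valid`.
#' @examples
#' rec <- data.frame(label = rep(c("dying", "healthy"), c(20, 60)))
#' measure_well(rec, "P1", "C03", "sample", "mir-a", 1)$percent_dying
#' @export
measure_well <- function(records, plate_id, well, role,
                         mirna_id = NA_character_, replicate = NA_integer_,
                         min_nuclei = 50) {
  n <- nrow(records)
  if (n > 0 && anyNA(records$label))
    stop("well ", well, ": classify nuclei before measuring")
  nd <- if (n == 0) 0L else sum(records$label == "dying")
  data.frame(plate_id = plate_id, well = well, role = role,
             mirna_id = mirna_id, replicate = replicate,
             n_nuclei = n, n_dying = nd,
             percent_dying = if (n > 0) 100 * nd / n else NA_real_,
             valid = n >= min_nuclei, stringsAsFactors = FALSE)
}

#' Measure a whole plate of rendered images
#'
#' The image-mode equivalent of [simulate_well_table()] for one plate:
#' segments every well, fits the classifier criteria from the plate's
#' dark-control nuclei, classifies, and assembles the well table.
#'
#' @param images named list of well images (matrices or
#'   [render_well_image()] results), names = well ids.
#' @param layout the plate's `plate_layout`.
#' @param seg a [seg_params()].
#' @param clf a [clf_params()].
#' @param min_nuclei validity floor passed to [measure_well()].
#' @return well table data frame, one row per imaged well.
#' @export
measure_plate <- function(images, layout, seg = seg_params(),
                          clf = clf_params(), min_nuclei = 50) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells
  getmat <- function(x) if (is.list(x)) x$image else x
  recs <- lapply(images, function(x) segment_nuclei(getmat(x), seg))
  roles <- w$role[match(names(images), w$well)]
  if (anyNA(roles)) stop("image wells not found in layout: ",
                         paste(names(images)[is.na(roles)], collapse = ", "))
  needs_fit <- clf$method == "thresholds" &&
    (is.null(clf$intensity_threshold) || is.null(clf$area_threshold))
  ctrl <- NULL
  if (needs_fit) {
    ctrl <- do.call(rbind, recs[roles == "dark_control"])
    if (is.null(ctrl) || nrow(ctrl) < 10)
      stop("plate ", layout$plate_id,
           ": threshold fitting needs dark-control wells among the images")
  }
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    lab <- classify_nuclei(recs[[i]], clf, control_records = ctrl)
    wi <- w[match(names(images)[i], w$well), ]
    rows[[i]] <- measure_well(lab, layout$plate_id, wi$well, wi$role,
                              wi$mirna_id, layout$replicate_index, min_nuclei)
  }
  do.call(rbind, rows)
}

#' Estimate transfection efficiency from a red-marker channel
#'
#' Segments nuclei on the nuclear-stain channel, then calls a nucleus
#' red-positive when the mean red signal in a disc around its centroid
#' exceeds a background-derived threshold (median + `k` * MAD of the red
#' channel outside all nucleus neighborhoods).
#'
#' @param nuclei_image nuclear-stain matrix.
#' @param red_image red-channel matrix, same size; required.
#' @param seg a [seg_params()].
#' @param k robust-z multiplier over red background (default 6).
#' @param radius sampling disc radius in px (default 4).
#' @return fraction of nuclei scored red-positive, with the per-nucleus
#'   calls as `attr(, "calls")`.
#' @export
estimate_transfection_efficiency <- function(nuclei_image, red_image,
                                             seg = seg_params(), k = 6,
                                             radius = 4) {
  if (is.null(red_image)) stop("red channel missing: cannot estimate ",
                               "transfection efficiency")
  if (!all(dim(nuclei_image) == dim(red_image)))
    stop("nuclear and red channels must have identical dimensions")
  rec <- segment_nuclei(nuclei_image, seg)
  if (nrow(rec) == 0) return(structure(NA_real_, calls = logical(0)))
  n <- nrow(red_image)
  # red background: pixels far from every nucleus centroid
  near <- matrix(FALSE, n, ncol(red_image))
  ij <- expand.grid(dx = -(3 * radius):(3 * radius),
                    dy = -(3 * radius):(3 * radius))
  ij <- ij[ij$dx^2 + ij$dy^2 <= (3 * radius)^2, ]
  for (i in seq_len(nrow(rec))) {
    xs <- round(rec$x[i]) + ij$dx; ys <- round(rec$y[i]) + ij$dy
    okp <- xs >= 1 & xs <= n & ys >= 1 & ys <= ncol(red_image)
    near[cbind(xs[okp], ys[okp])] <- TRUE
  }
  bg <- red_image[!near]
  thr <- stats::median(bg) + k * stats::mad(bg)
  disc <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  disc <- disc[disc$dx^2 + disc$dy^2 <= radius^2, ]
  calls <- vapply(seq_len(nrow(rec)), function(i) {
    xs <- round(rec$x[i]) + disc$dx; ys <- round(rec$y[i]) + disc$dy
    okp <- xs >= 1 & xs <= n & ys >= 1 & ys <= ncol(red_image)
    mean(red_image[cbind(xs[okp], ys[okp])]) > thr
  }, logical(1))
  structure(mean(calls), calls = calls)
}
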