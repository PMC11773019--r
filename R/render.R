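#' Imaging parameters for the synthetic nuclei renderer
#'
#' The renderer draws each nucleus as a 2-D anisotropic Gaussian blob over a
#' uniform background, with shot-like noise proportional to the square root
#' of the signal plus Gaussian read noise. Dying nuclei are rendered strictly
#' brighter and smaller than healthy ones (pyknotic, condensed chromatin),
#' with extra intra-nuclear intensity heterogeneity — the contrast the
#' downstream two-feature classifier exploits.
#'
#' @param image_size image side in pixels (square images, default 240).
#' @param nuclei_per_well expected nuclei per field; counts are Poisson with
#'   this mean unless `fixed_count = TRUE`.
#' @param fixed_count if TRUE, plant exactly `nuclei_per_well` nuclei.
#' @param healthy_intensity peak amplitude of a healthy nucleus above
#'   background, arbitrary units in \[0, 1\] (default 0.30).
#' @param intensity_cv cell-to-cell CV of peak amplitude (default 0.10).
#' @param healthy_radius Gaussian sigma of a healthy nucleus in px (default 5).
#' @param radius_cv cell-to-cell CV of the radius (default 0.06).
#' @param dying_intensity_mult amplitude multiplier for dying nuclei (> 1;
#'   default 2.2).
#' @param dying_radius_mult radius multiplier for dying nuclei (< 1;
#'   default 0.4).
#' @param dying_texture intra-nuclear heterogeneity of dying nuclei:
#'   multiplicative speckle SD (default 0.25).
#' @param background background level (default 0.08).
#' @param read_noise_sd Gaussian read-noise SD (default 0.008).
#' @param shot_noise_scale scale of signal-dependent noise,
#'   `sd = scale * sqrt(signal)` (default 0.015).
#' @param min_separation minimum centre-to-centre distance between planted
#'   nuclei, in units of the healthy radius (default 3.2: essentially
#'   non-overlapping).
#' @param transfected_fraction fraction of nuclei carrying the red
#'   transfection-marker signal in transfection-control wells (default 0.5,
#'   the typical reverse-transfection efficiency).
#' @param red_intensity,red_radius_mult amplitude and radius of the red
#'   channel blob around a transfected nucleus.
#' @return An `imaging_params` list, validated.
#' @export
imaging_params <- function(image_size = 240, nuclei_per_well = 80,
                           fixed_count = FALSE,
                           healthy_intensity = 0.30, intensity_cv = 0.10,
                           healthy_radius = 5, radius_cv = 0.06,
                           dying_intensity_mult = 2.2,
                           dying_radius_mult = 0.4,
                           dying_texture = 0.25,
                           background = 0.08, read_noise_sd = 0.008,
                           shot_noise_scale = 0.015,
                           min_separation = 3.2,
                           transfected_fraction = 0.5,
                           red_intensity = 0.40, red_radius_mult = 1.3) {
  if (dying_intensity_mult <= 1)
    stop("dying nuclei must be brighter than healthy ones (dying_intensity_mult > 1)")
  if (dying_radius_mult >= 1)
    stop("dying nuclei must be smaller than healthy ones (dying_radius_mult < 1)")
  if (transfected_fraction < 0 || transfected_fraction > 1)
    stop("transfected_fraction must be in [0, 1]")
  structure(as.list(environment()), class = "imaging_params")
}

# place n points in [margin, size-margin]^2 with pairwise min distance d,
# by seeded rejection sampling; errors out when the field cannot pack them
place_centres <- function(n, size, d, margin) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  max_pack <- floor(((size - 2 * margin) / d + 1)^2 * 1.2)
  if (n > max_pack)
    stop(sprintf(paste0("cannot place %d nuclei at minimum separation ",
                        "%.1f px in a %d px field (approx. capacity %d); ",
                        "reduce nuclei_per_well or min_separation"),
                 n, d, size, max_pack))
  xs <- numeric(n); ys <- numeric(n); placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop(sprintf("failed to pack %d nuclei after %d attempts (separation %.1f px)",
                   n, tries, d))
    x <- stats::runif(1, margin, size - margin)
    y <- stats::runif(1, margin, size - margin)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= d^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(xs, ys)
}

# add one anisotropic Gaussian blob (amplitude a, sigmas sx/sy, optional
# multiplicative speckle) into image matrix img at centre (cx, cy)
add_blob <- function(img, cx, cy, sx, sy, a, speckle_sd = 0) {
  n <- nrow(img)
  r <- ceiling(4 * max(sx, sy))
  xi <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
  yi <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  gx <- exp(-((xi - cx)^2) / (2 * sx^2))
  gy <- exp(-((yi - cy)^2) / (2 * sy^2))
  blob <- a * outer(gx, gy)
  if (speckle_sd > 0)
    blob <- blob * pmax(0, 1 + matrix(stats::rnorm(length(blob), 0, speckle_sd),
                                      nrow = length(xi)))
  img[xi, yi] <- img[xi, yi] + blob
  img
}

#' Render a synthetic well image with known per-nucleus truth
#'
#' Draws the number of dying nuclei binomially from the well's ground-truth
#' dying probability, places non-overlapping nuclei at random positions, and
#' renders the nuclear-stain channel (plus, for transfection-control wells or
#' on request, a red marker channel over the transfected subset). The
#' returned label table is the segmentation/classification oracle.
#'
#' @param layout_entry one row of a layout's `wells` data frame (or any list
#'   with `well`, `role`, `mirna_id`).
#' @param truth a [ground_truth()] object.
#' @param params an [imaging_params()] object.
#' @param seed integer seed.
#' @param with_red force rendering of the red channel (default: only for
#'   `transfection_control` wells).
#' @return list with `image` (matrix in \[0, 1\]), `red` (matrix or NULL),
#'   and `labels`: data frame of planted nuclei (`x`, `y`, `radius`,
#'   `intensity`, `dying`, `transfected`).
#' @examples
#' tr <- ground_truth("mir-a", effects = 1)
#' well <- list(well = "C05", role = "sample", mirna_id = "mir-a")
#' img <- render_well_image(well, tr, imaging_params(nuclei_per_well = 20),
#'                          seed = 2)
#' nrow(img$labels)
#' @export
render_well_image <- function(layout_entry, truth, params = imaging_params(),
                              seed = 1, with_red = NULL) {
  stopifnot(inherits(params, "imaging_params"))
  set.seed(seed)
  p_dying <- well_dying_prob(layout_entry$role, layout_entry$mirna_id, truth)
  n <- if (params$fixed_count) params$nuclei_per_well else
    stats::rpois(1, params$nuclei_per_well)
  size <- params$image_size
  img <- matrix(params$background, size, size)
  if (is.null(with_red)) with_red <- identical(layout_entry$role,
                                               "transfection_control")
  red <- if (with_red) matrix(params$background * 0.6, size, size) else NULL

  if (n > 0) {
    dmin <- params$min_separation * params$healthy_radius
    centres <- place_centres(n, size, dmin, margin = 3 * params$healthy_radius)
    dying <- stats::rbinom(n, 1, p_dying) == 1
    transfected <- if (with_red)
      stats::rbinom(n, 1, params$transfected_fraction) == 1 else rep(FALSE, n)
    amp <- params$healthy_intensity *
      pmax(0.2, 1 + stats::rnorm(n, 0, params$intensity_cv))
    rad <- params$healthy_radius *
      pmax(0.3, 1 + stats::rnorm(n, 0, params$radius_cv))
    amp[dying] <- amp[dying] * params$dying_intensity_mult
    rad[dying] <- rad[dying] * params$dying_radius_mult
    aniso <- stats::runif(n, 0.85, 1.15)
    for (i in seq_len(n)) {
      img <- add_blob(img, centres[i, 1], centres[i, 2],
                      rad[i] * aniso[i], rad[i] / aniso[i], amp[i],
                      speckle_sd = if (dying[i]) params$dying_texture else 0)
      if (with_red && transfected[i])
        red <- add_blob(red, centres[i, 1], centres[i, 2],
                        rad[i] * params$red_radius_mult,
                        rad[i] * params$red_radius_mult,
                        params$red_intensity)
    }
    labels <- data.frame(nucleus = seq_len(n),
                         x = centres[, 1], y = centres[, 2],
                         radius = rad, intensity = amp,
                         dying = dying, transfected = transfected)
  } else {
    labels <- data.frame(nucleus = integer(0), x = numeric(0), y = numeric(0),
                         radius = numeric(0), intensity = numeric(0),
                         dying = logical(0), transfected = logical(0))
  }

  noisify <- function(m) {
    m <- m + stats::rnorm(length(m), 0, params$shot_noise_scale * sqrt(pmax(m, 0)))
    m <- m + stats::rnorm(length(m), 0, params$read_noise_sd)
    matrix(pmin(1, pmax(0, m)), nrow(m), ncol(m))
  }
  list(image = noisify(img),
       red = if (with_red) noisify(red) else NULL,
       labels = labels)
}

#' Render all wells of a plate
#'
#' Convenience wrapper over [render_well_image()]: renders every non-empty
#' well of a plate layout with per-well seeds derived deterministically from
#' `seed`, and returns images alongside the planted truth.
#'
#' @inheritParams render_well_image
#' @param layout a `plate_layout`.
#' @return named list (by well) of [render_well_image()] results.
#' @export
render_plate_images <- function(layout, truth, params = imaging_params(),
                                seed = 1) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells[layout$wells$role != "empty", ]
  out <- vector("list", nrow(w))
  names(out) <- w$well
  for (i in seq_len(nrow(w)))
    out[[i]] <- render_well_image(w[i, ], truth, params, seed = seed + i)
  out
}
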