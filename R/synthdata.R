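#' Ground truth for a simulated light-stress screen
#'
#' Fixes the biological truth the generators draw from: the baseline dying
#' fractions of untransfected cells kept dark vs. exposed to light, and a
#' per-miRNA multiplicative effect on the dying probability under light
#' (1 = neutral, < 1 protective, > 1 deleterious). Dark wells are unaffected
#' by miRNA effects: the stressor is the light.
#'
#' @param mirna_ids character vector of miRNA identifiers.
#' @param effects multiplicative effect per miRNA; either a single value
#'   recycled to all, or a named vector (names matched to `mirna_ids`,
#'   unnamed miRNAs default to 1).
#' @param baseline_dying_dark dying fraction of dark controls (default 0.05).
#' @param baseline_dying_light dying fraction of light controls (default
#'   0.40); must exceed the dark baseline — an ineffective stressor would
#'   fail plate QC by design.
#' @return A `ground_truth` object (list with `effect_map`,
#'   `baseline_dying_dark`, `baseline_dying_light`).
#' @examples
#' tr <- ground_truth(c("mir-a", "mir-b"), effects = c("mir-a" = 0.5))
#' tr$effect_map
#' @export
ground_truth <- function(mirna_ids, effects = 1,
                         baseline_dying_dark = 0.05,
                         baseline_dying_light = 0.40) {
  stopifnot(length(mirna_ids) >= 1, !anyDuplicated(mirna_ids))
  if (baseline_dying_dark < 0 || baseline_dying_light > 1)
    stop("baselines must be fractions in [0, 1]")
  if (baseline_dying_light <= baseline_dying_dark)
    stop("baseline_dying_light must exceed baseline_dying_dark: ",
         "the light stress must increase cell death for QC to be meaningful")
  effect_map <- rep(1, length(mirna_ids))
  names(effect_map) <- mirna_ids
  if (is.null(names(effects))) {
    effect_map[] <- rep_len(effects, length(mirna_ids))
  } else {
    unknown <- setdiff(names(effects), mirna_ids)
    if (length(unknown))
      stop("effects named for miRNAs absent from mirna_ids: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    effect_map[names(effects)] <- effects
  }
  if (any(effect_map < 0) ||
      any(effect_map * baseline_dying_light > 1))
    stop("effect_map x baseline_dying_light must stay within [0, 1]")
  structure(list(effect_map = effect_map,
                 baseline_dying_dark = baseline_dying_dark,
                 baseline_dying_light = baseline_dying_light),
            class = "ground_truth")
}

# dying probability of one well given its role/miRNA, before well noise
well_dying_prob <- function(role, mirna_id, truth) {
  p <- ifelse(role == "dark_control", truth$baseline_dying_dark,
              truth$baseline_dying_light)
  is_sample <- role == "sample"
  if (any(is_sample)) {
    eff <- truth$effect_map[mirna_id[is_sample]]
    if (anyNA(eff)) stop("ground truth does not cover every miRNA in the layout")
    p[is_sample] <- truth$baseline_dying_light * eff
  }
  p
}

#' Simulate a well-level screen table (fast mode, no images)
#'
#' Draws the per-well percentage of dying cells directly, bypassing image
#' rendering. Each well's dying probability is its ground-truth value plus an
#' optional additive plate batch offset and Gaussian well-to-well noise; the
#' realized dying count is binomial over the cells seeded in the well. With
#' `noise_sd = 0` the table is fully deterministic: every well reports exactly
#' its ground-truth probability (no offsets, no binomial sampling), which is
#' useful as a degenerate check.
#'
#' @param layouts list of `plate_layout` objects.
#' @param truth a [ground_truth()] object covering every miRNA in the layouts.
#' @param noise_sd well-to-well Gaussian noise on the dying fraction
#'   (default 0.03, i.e. 3 percentage points).
#' @param cells_per_well cells seeded per well for the binomial draw
#'   (default 650, the typical 384-well seeding density).
#' @param plate_offset_sd SD of the additive per-plate batch offset on the
#'   dying fraction (default 0.02); plate-level shifts are what per-plate
#'   normalization exists to absorb. Set 0 to disable.
#' @param seed integer seed.
#' @return data frame with columns `plate_id`, `well`, `role`, `mirna_id`,
#'   `replicate`, `n_nuclei`, `n_dying`, `percent_dying`, `valid` — the same
#'   shape the imaging stage emits, so downstream stages cannot tell the
#'   modes apart.
#' @examples
#' lay <- generate_layout(10, replicate_count = 1, seed = 1)
#' tr <- ground_truth(sprintf("sim-mir-%04d", 1:10))
#' head(simulate_well_table(lay, tr, seed = 7))
#' @export
simulate_well_table <- function(layouts, truth, noise_sd = 0.03,
                                cells_per_well = 650,
                                plate_offset_sd = 0.02, seed = 1) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  if (!inherits(truth, "ground_truth")) stop("truth must be a ground_truth object")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  out <- lapply(layouts, function(l) {
    w <- l$wells[l$wells$role != "empty", ]
    p <- well_dying_prob(w$role, w$mirna_id, truth)
    if (noise_sd == 0) {
      pct <- 100 * p
      n <- rep(cells_per_well, nrow(w))
      nd <- round(n * p)
    } else {
      off <- stats::rnorm(1, 0, plate_offset_sd)
      p_well <- pmin(1, pmax(0, p + off + stats::rnorm(nrow(w), 0, noise_sd)))
      n <- rep(cells_per_well, nrow(w))
      nd <- stats::rbinom(nrow(w), n, p_well)
      pct <- 100 * nd / n
    }
    data.frame(plate_id = l$plate_id, well = w$well, role = w$role,
               mirna_id = w$mirna_id, replicate = l$replicate_index,
               n_nuclei = n, n_dying = nd, percent_dying = pct,
               valid = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a trypan-blue secondary viability assay
#'
#' Emulates the low-throughput validation assay: 12-well plates, matched
#' light and dark conditions, each miRNA mimic run next to a non-targeting
#' negative mimic, technical duplicates per condition, several biological
#' replicates. Dead counts are binomial over the cells seeded per well; a
#' Gaussian well-level jitter on the dead fraction models pipetting and
#' manual-counting variation. miRNA effects act only under light.
#'
#' @param effects named vector of multiplicative light-condition effects, one
#'   per miRNA to test.
#' @param baseline_dark,baseline_light dead fractions of negative-mimic wells
#'   in dark / light conditions (defaults 0.05 / 0.40).
#' @param cells_per_well cells counted per well (default 60000).
#' @param replicates biological replicates (default 3).
#' @param duplicates technical duplicates per condition (default 2).
#' @param noise_sd SD of the well-level jitter on the dead fraction
#'   (default 0.01).
#' @param seed integer seed.
#' @return data frame with columns `mirna_id`, `condition` (`light`/`dark`),
#'   `treatment` (`mimic`/`negative_mimic`), `replicate`, `duplicate`,
#'   `live`, `dead`.
#' @examples
#' cts <- simulate_secondary_assay(c("mir-x" = 0.5), seed = 3)
#' aggregate(dead / (live + dead) ~ condition + treatment, cts, mean)
#' @export
simulate_secondary_assay <- function(effects, baseline_dark = 0.05,
                                     baseline_light = 0.40,
                                     cells_per_well = 60000,
                                     replicates = 3, duplicates = 2,
                                     noise_sd = 0.01, seed = 1) {
  if (is.null(names(effects))) stop("effects must be a named vector of miRNA effects")
  if (baseline_dark < 0 || baseline_dark > 1 ||
      baseline_light < 0 || baseline_light > 1)
    stop("baselines must be fractions in [0, 1]")
  if (replicates < 1) stop("replicates must be >= 1")
  if (duplicates < 1) stop("duplicates must be >= 1")
  set.seed(seed)
  grid <- expand.grid(duplicate = seq_len(duplicates),
                      replicate = seq_len(replicates),
                      treatment = c("mimic", "negative_mimic"),
                      condition = c("light", "dark"),
                      mirna_id = names(effects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff <- ifelse(grid$treatment == "mimic" & grid$condition == "light",
                effects[grid$mirna_id], 1)
  base <- ifelse(grid$condition == "light", baseline_light, baseline_dark)
  p <- pmin(1, pmax(0, base * eff + stats::rnorm(nrow(grid), 0, noise_sd)))
  dead <- stats::rbinom(nrow(grid), cells_per_well, p)
  grid$live <- cells_per_well - dead
  grid$dead <- dead
  grid[, c("mirna_id", "condition", "treatment", "replicate", "duplicate",
           "live", "dead")]
}
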