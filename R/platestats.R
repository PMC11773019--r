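#' Per-plate quality control from control wells
#'
#' Summarizes the control wells of one plate and decides whether the light
#' stress was effective enough for scoring. The light-control mean and SD
#' (`mu_light`, `sigma_light`) are the reference location and scale for the
#' plate's Z scores; the QC criterion is that light controls died more than
#' dark controls, by a separation statistic above a configurable floor.
#'
#' @param well_table well measurements for exactly one plate (columns
#'   `plate_id`, `well`, `role`, `percent_dying`, `valid`).
#' @param separation_floor minimum separation for `passed` (default 2).
#' @param separation_stat `"pooled_sd"` (default): `(mu_light - mu_dark)`
#'   divided by the pooled control SD; or `"zprime"`: the Z'-factor
#'   `1 - 3(sd_light + sd_dark)/|mu_light - mu_dark|` (floor then typically
#'   0 or 0.5).
#' @return A `plate_qc` object: `plate_id`, `mu_light`, `sigma_light`,
#'   `mu_dark`, `n_light_controls`, `n_dark_controls`, `separation_stat`,
#'   `separation_method`, `passed`, `reason`.
#' @details `sigma_light` is the sample (n-1) standard deviation. A plate
#'   whose light controls have zero spread fails QC outright: its Z scores
#'   would be undefined. Wells flagged invalid (too few nuclei) are excluded
#'   from all control statistics.
#' @examples
#' lay <- generate_layout(320, 1, seed = 1)
#' tr <- ground_truth(sprintf("sim-mir-%04d", 1:320))
#' wt <- simulate_well_table(lay, tr, seed = 5)
#' qc_plate(wt)
#' @export
qc_plate <- function(well_table, separation_floor = 2,
                     separation_stat = c("pooled_sd", "zprime")) {
  separation_stat <- match.arg(separation_stat)
  plates <- unique(well_table$plate_id)
  if (length(plates) != 1)
    stop("qc_plate expects wells from exactly one plate, got: ",
         paste(plates, collapse = ", "))
  ok <- well_table$valid
  light <- well_table$percent_dying[ok & well_table$role == "light_control"]
  dark <- well_table$percent_dying[ok & well_table$role == "dark_control"]
  if (length(light) < 2 || length(dark) < 2)
    stop("plate ", plates, ": need >= 2 valid light-control and >= 2 valid ",
         "dark-control wells (have ", length(light), " light, ",
         length(dark), " dark)")
  mu_l <- mean(light); sd_l <- stats::sd(light)
  mu_d <- mean(dark); sd_d <- stats::sd(dark)
  sep <- switch(separation_stat,
    pooled_sd = {
      pooled <- sqrt(((length(light) - 1) * sd_l^2 +
                        (length(dark) - 1) * sd_d^2) /
                       (length(light) + length(dark) - 2))
      if (pooled == 0) Inf * sign(mu_l - mu_d) else (mu_l - mu_d) / pooled
    },
    zprime = if (mu_l == mu_d) -Inf else 1 - 3 * (sd_l + sd_d) / abs(mu_l - mu_d))
  reason <- NULL
  if (sd_l == 0) reason <- c(reason, "sigma_light = 0: Z scores undefined")
  if (mu_l <= mu_d) reason <- c(reason,
    "no light-induced death: mu_light <= mu_dark")
  if (is.finite(sep) && sep < separation_floor)
    reason <- c(reason, sprintf("separation %.2f below floor %.2f",
                                sep, separation_floor))
  structure(list(plate_id = plates, mu_light = mu_l, sigma_light = sd_l,
                 mu_dark = mu_d, n_light_controls = length(light),
                 n_dark_controls = length(dark), separation_stat = sep,
                 separation_method = separation_stat,
                 passed = is.null(reason),
                 reason = if (is.null(reason)) NA_character_ else
                   paste(reason, collapse = "; ")),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("<plate_qc> %s: mu_light = %.2f%%, sigma_light = %.2f, mu_dark = %.2f%%\n",
              x$plate_id, x$mu_light, x$sigma_light, x$mu_dark))
  cat(sprintf("  separation (%s) = %.2f -> %s\n", x$separation_method,
              x$separation_stat, if (x$passed) "PASS" else
                paste0("FAIL (", x$reason, ")")))
  invisible(x)
}

#' Z-score sample wells against a plate's light controls
#'
#' Applies `Z = (x - mu) / sigma`, where `x` is the percentage of dying cells
#' in a sample well and `mu`, `sigma` are the mean and standard deviation of
#' the dying percentage in the same plate's light-exposed control wells.
#' Normalization is strictly per plate; control wells receive no Z score.
#' Negative Z means fewer dying cells than light controls, i.e. protection.
#'
#' @param well_table well measurements for one plate.
#' @param qc the plate's [qc_plate()] result.
#' @param override_qc score the plate even if QC failed (default FALSE;
#'   scoring a failed plate is refused otherwise).
#' @return data frame with one row per valid sample well: `plate_id`, `well`,
#'   `mirna_id`, `replicate` (if present in the input), `x` (percent dying),
#'   `norm` (`x / mu_light`, the light-normalized dying fraction carried
#'   forward for replicate CV computation) and `z`.
#' @examples
#' lay <- generate_layout(320, 1, seed = 1)
#' tr <- ground_truth(sprintf("sim-mir-%04d", 1:320))
#' wt <- simulate_well_table(lay, tr, seed = 5)
#' z <- zscore_wells(wt, qc_plate(wt))
#' summary(z$z)
#' @export
zscore_wells <- function(well_table, qc, override_qc = FALSE) {
  stopifnot(inherits(qc, "plate_qc"))
  plates <- unique(well_table$plate_id)
  if (length(plates) != 1 || !identical(plates, qc$plate_id))
    stop("well table and QC must describe the same single plate (table: ",
         paste(plates, collapse = ", "), "; qc: ", qc$plate_id, ")")
  if (!qc$passed && !override_qc)
    stop("plate ", qc$plate_id, " failed QC (", qc$reason,
         "); pass override_qc = TRUE to score it anyway")
  if (qc$sigma_light <= 0)
    stop("plate ", qc$plate_id, ": sigma_light = 0, Z undefined")
  s <- well_table[well_table$role == "sample" & well_table$valid, ]
  data.frame(plate_id = s$plate_id, well = s$well, mirna_id = s$mirna_id,
             replicate = if ("replicate" %in% names(s)) s$replicate else NA,
             x = s$percent_dying,
             norm = s$percent_dying / qc$mu_light,
             z = (s$percent_dying - qc$mu_light) / qc$sigma_light,
             stringsAsFactors = FALSE)
}

#' QC and Z-score every plate of a screen
#'
#' Splits a multi-plate well table by plate, runs [qc_plate()] and
#' [zscore_wells()] on each, and collects the per-replicate Z tables the
#' hit-calling stage consumes. Plates failing QC are dropped from scoring
#' (with their reason recorded) unless `override_qc` is set.
#'
#' @inheritParams qc_plate
#' @inheritParams zscore_wells
#' @param well_table well measurements for any number of plates; must carry
#'   a `replicate` column.
#' @return list with `qc` (list of `plate_qc` by plate), `zscores` (list of
#'   per-replicate Z-score data frames, named by replicate index) and
#'   `failed_plates` (character).
#' @export
score_screen <- function(well_table, separation_floor = 2,
                         separation_stat = c("pooled_sd", "zprime"),
                         override_qc = FALSE) {
  separation_stat <- match.arg(separation_stat)
  stopifnot("replicate" %in% names(well_table))
  qcs <- list(); ztabs <- list(); failed <- character(0)
  for (pid in unique(well_table$plate_id)) {
    wt <- well_table[well_table$plate_id == pid, ]
    qc <- qc_plate(wt, separation_floor, separation_stat)
    qcs[[pid]] <- qc
    if (!qc$passed && !override_qc) {
      failed <- c(failed, pid)
      next
    }
    ztabs[[pid]] <- zscore_wells(wt, qc, override_qc = override_qc)
  }
  z_all <- do.call(rbind, ztabs)
  zscores <- if (is.null(z_all)) list() else
    split(z_all, z_all$replicate)
  list(qc = qcs, zscores = zscores, failed_plates = failed)
}
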