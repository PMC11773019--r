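#' Screen run configuration
#'
#' Bundles every stage's parameters plus the global seed. Each stochastic
#' stage derives its own seed deterministically from the global seed and the
#' stage name, so stages can be rerun independently and the whole run is
#' reproducible end to end.
#'
#' @param n_mirnas number of miRNAs to screen (default 1268).
#' @param replicate_count biological replicates (default 3).
#' @param effects per-miRNA multiplicative light effects (named vector;
#'   default all neutral).
#' @param mirna_ids optional explicit identifiers.
#' @param baseline_dying_dark,baseline_dying_light ground-truth baselines.
#' @param noise_sd,cells_per_well,plate_offset_sd fast-mode well noise model
#'   (see [simulate_well_table()]).
#' @param mode `"wells"` (fast, default) or `"images"` (render + segment;
#'   intended for reduced plate counts).
#' @param imaging an [imaging_params()] (image mode only).
#' @param seg,clf segmentation / classifier parameter lists (image mode).
#' @param min_nuclei well validity floor (image mode).
#' @param separation_floor plate-QC floor (see [qc_plate()]).
#' @param hit a [hit_config()].
#' @param annotation_set annotated miRNA ids; default: all screened ids
#'   (i.e. the annotation filter is neutral unless a real list is given).
#' @param run_secondary simulate + test the secondary assay on the shortlist
#'   (default TRUE).
#' @param secondary_design design passed to [two_way_test()].
#' @param outdir directory for persisted artifacts (NULL = in-memory only).
#' @param seed global seed (default 1).
#' @return A `run_config` list.
#' @export
run_config <- function(n_mirnas = 1268, replicate_count = 3, effects = 1,
                       mirna_ids = NULL,
                       baseline_dying_dark = 0.05, baseline_dying_light = 0.40,
                       noise_sd = 0.03, cells_per_well = 650,
                       plate_offset_sd = 0.02,
                       mode = c("wells", "images"),
                       imaging = imaging_params(), seg = seg_params(),
                       clf = clf_params(), min_nuclei = 50,
                       separation_floor = 2, hit = hit_config(),
                       annotation_set = NULL, run_secondary = TRUE,
                       secondary_design = "treatment_x_light",
                       outdir = NULL, seed = 1) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-stage seed: global seed mixed with the stage name,
# kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the screen end to end
#'
#' Orchestrates simulate -> (render/measure) -> per-plate QC and Z scoring ->
#' replicate aggregation -> hit calling -> secondary validation, and returns
#' a run report. Identical config and seed give identical reports. With
#' `outdir` set, every intermediate artifact (plate map, ground truth, well
#' table, Z scores, scored table, hit list, report) is persisted so any
#' downstream stage can be reproduced from files.
#'
#' @param config a [run_config()].
#' @return A `screen_report` list: `layouts`, `truth`, `well_table`, `qc`,
#'   `zscores`, `scores`, `hits`, `secondary` (if run) and `config`.
#' @examples
#' cfg <- run_config(n_mirnas = 50, effects = c("sim-mir-0001" = 0.5),
#'                   run_secondary = FALSE, seed = 11)
#' rep <- run_screen(cfg)
#' rep$hits$protective
#' @export
run_screen <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  layouts <- generate_layout(config$n_mirnas, config$replicate_count,
                             seed = stage_seed(config$seed, "layout"),
                             mirna_ids = config$mirna_ids)
  ids <- sort(unique(stats::na.omit(layout_table(layouts)$mirna_id)))
  truth <- ground_truth(ids, effects = config$effects,
                        baseline_dying_dark = config$baseline_dying_dark,
                        baseline_dying_light = config$baseline_dying_light)

  if (config$mode == "wells") {
    well_table <- simulate_well_table(layouts, truth,
                                      noise_sd = config$noise_sd,
                                      cells_per_well = config$cells_per_well,
                                      plate_offset_sd = config$plate_offset_sd,
                                      seed = stage_seed(config$seed, "wells"))
  } else {
    tabs <- vector("list", length(layouts))
    for (i in seq_along(layouts)) {
      imgs <- render_plate_images(layouts[[i]], truth, config$imaging,
                                  seed = stage_seed(config$seed,
                                                    layouts[[i]]$plate_id))
      tabs[[i]] <- measure_plate(imgs, layouts[[i]], config$seg, config$clf,
                                 min_nuclei = config$min_nuclei)
    }
    well_table <- do.call(rbind, tabs)
  }

  scored <- score_screen(well_table, separation_floor = config$separation_floor)
  if (length(scored$failed_plates))
    message("plates failing QC, excluded from scoring: ",
            paste(scored$failed_plates, collapse = ", "))
  scores <- aggregate_replicates(scored$zscores,
                                 cv_basis = config$hit$cv_basis)
  annot <- if (is.null(config$annotation_set)) ids else config$annotation_set
  hits <- rank_and_filter(scores, annot, config$hit)

  secondary <- NULL
  if (isTRUE(config$run_secondary) && length(hits$shortlist)) {
    eff <- truth$effect_map[hits$shortlist]
    cts <- simulate_secondary_assay(eff,
                                    baseline_dark = config$baseline_dying_dark,
                                    baseline_light = config$baseline_dying_light,
                                    seed = stage_seed(config$seed, "secondary"))
    secondary <- secondary_screen(cts, design = config$secondary_design)
  }

  report <- structure(list(layouts = layouts, truth = truth,
                           well_table = well_table, qc = scored$qc,
                           failed_plates = scored$failed_plates,
                           zscores = scored$zscores, scores = scores,
                           hits = hits, secondary = secondary,
                           config = config,
                           version = as.character(utils::packageVersion("hcsprotect"))),
                      class = "screen_report")
  if (!is.null(config$outdir)) persist_report(report, config$outdir)
  report
}

persist_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_plate_map(report$layouts, file.path(outdir, "plate_map.csv"))
  write_ground_truth(report$truth, file.path(outdir, "ground_truth.json"),
                     seed = report$config$seed)
  write_well_table(report$well_table, file.path(outdir, "well_table.csv"))
  zs <- do.call(rbind, report$zscores)
  utils::write.csv(zs, file.path(outdir, "zscores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$scores),
                   file.path(outdir, "scores.csv"), row.names = FALSE)
  qc <- lapply(report$qc, function(q) unclass(q))
  jsonlite::write_json(qc, file.path(outdir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(protective = report$hits$protective,
                            deleterious = report$hits$deleterious,
                            shortlist = report$hits$shortlist,
                            provenance = report$hits$provenance),
                       file.path(outdir, "hits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$secondary))
    utils::write.csv(report$secondary, file.path(outdir, "secondary.csv"),
                     row.names = FALSE)
  invisible(outdir)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", length(x$layouts), " plates, ",
      x$config$n_mirnas, " miRNAs x ", x$config$replicate_count,
      " replicates (", x$config$mode, " mode, seed ", x$config$seed, ")\n",
      sep = "")
  n_pass <- sum(vapply(x$qc, `[[`, logical(1), "passed"))
  cat(sprintf("  plate QC: %d/%d passed\n", n_pass, length(x$qc)))
  print(x$hits)
  if (!is.null(x$secondary)) {
    cat("  secondary validation:\n")
    print(x$secondary, row.names = FALSE)
  }
  invisible(x)
}
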