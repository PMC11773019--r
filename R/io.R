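#' Write rendered well images as 16-bit grayscale TIFFs
#'
#' Files are named `<plate>_<well>_<channel>.tif` with channels `nuclei`
#' and (when present) `red`.
#'
#' @param images named list of [render_well_image()] results (names = wells).
#' @param dir output directory (created if needed).
#' @param plate_id plate identifier used in file names.
#' @return invisibly, the written file paths.
#' @export
write_plate_images <- function(images, dir, plate_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (well in names(images)) {
    f <- file.path(dir, sprintf("%s_%s_nuclei.tif", plate_id, well))
    EBImage::writeImage(EBImage::Image(images[[well]]$image), f,
                        type = "tiff", bits.per.sample = 16L)
    paths <- c(paths, f)
    if (!is.null(images[[well]]$red)) {
      fr <- file.path(dir, sprintf("%s_%s_red.tif", plate_id, well))
      EBImage::writeImage(EBImage::Image(images[[well]]$red), fr,
                          type = "tiff", bits.per.sample = 16L)
      paths <- c(paths, fr)
    }
  }
  invisible(paths)
}

#' Read a single-channel well image
#'
#' @param path TIFF path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_well_image <- function(path) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  as.matrix(m)
}

#' Write / read the well-level measurement table
#'
#' @param well_table data frame as produced by [simulate_well_table()] or
#'   [measure_plate()].
#' @param path CSV path.
#' @return `read_well_table` returns the data frame.
#' @export
write_well_table <- function(well_table, path) {
  utils::write.csv(well_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a plate map CSV
#'
#' @param layouts list of `plate_layout`s.
#' @param path CSV path (columns `plate_id`, `well`, `role`, `mirna_id`,
#'   `replicate`).
#' @export
write_plate_map <- function(layouts, path) {
  utils::write.csv(layout_table(layouts), path, row.names = FALSE)
  invisible(path)
}

#' Persist ground truth as a JSON sidecar
#'
#' @param truth a [ground_truth()].
#' @param path JSON path.
#' @param seed the generator seed to record.
#' @export
write_ground_truth <- function(truth, path, seed = NA) {
  jsonlite::write_json(list(effect_map = as.list(truth$effect_map),
                            baseline_dying_dark = truth$baseline_dying_dark,
                            baseline_dying_light = truth$baseline_dying_light,
                            seed = seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
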