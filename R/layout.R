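#' 384-well screen plate layouts
#'
#' Builds the plate maps for an arrayed miRNA-mimic screen. Each plate follows
#' the standard layout for light-stress screening: untransfected dark-control
#' wells occupy the first two columns (covered to block light), untransfected
#' light-control wells the last two columns, and a small number of
#' transfection-control wells (cells transfected with a red-labelled
#' non-targeting mimic) sit in the bottom rows of the outermost control
#' columns. All remaining wells carry one miRNA mimic each. Every miRNA
#' appears exactly once per biological replicate; well positions are
#' randomized independently per replicate.
#'
#' @param n_mirnas number of distinct miRNAs to array (>= 1).
#' @param replicate_count number of biological replicates (>= 1); each
#'   replicate gets its own set of plates.
#' @param seed integer seed; identical inputs and seed give identical layouts.
#' @param mirna_ids optional character vector of miRNA identifiers of length
#'   `n_mirnas`; defaults to `sim-mir-0001` style names.
#' @param n_rows,n_cols plate dimensions; default 16 x 24 (384-well).
#' @param control_cols integer vector of columns reserved for controls;
#'   default `c(1, 2, 23, 24)`, the first two (dark) and last two (light).
#' @param n_transfection_controls number of transfection-control wells per
#'   plate, carved out of the outer control columns (default 4).
#'
#' @return A list of `plate_layout` objects, one per plate. Each holds
#'   `plate_id`, `replicate_index`, `n_rows`, `n_cols` and a `wells`
#'   data frame with columns `well` (A01 style), `row`, `col`, `role`
#'   (`dark_control`, `light_control`, `transfection_control`, `sample`,
#'   `empty`) and `mirna_id` (samples only, otherwise `NA`).
#' @examples
#' layouts <- generate_layout(320, replicate_count = 1, seed = 1)
#' table(layouts[[1]]$wells$role)
#' @export
generate_layout <- function(n_mirnas, replicate_count = 3, seed = 1,
                            mirna_ids = NULL, n_rows = 16, n_cols = 24,
                            control_cols = c(1L, 2L, 23L, 24L),
                            n_transfection_controls = 4) {
  if (length(n_mirnas) != 1 || is.na(n_mirnas) || n_mirnas < 1)
    stop("n_mirnas must be a positive integer (a screen with no miRNAs is empty)")
  if (replicate_count < 1) stop("replicate_count must be >= 1")
  if (n_rows > 26) stop("n_rows > 26 not supported by A01-style well names")
  control_cols <- sort(unique(as.integer(control_cols)))
  if (length(control_cols) < 4)
    stop("need at least 4 control columns (dark and light blocks)")
  if (is.null(mirna_ids)) {
    mirna_ids <- sprintf("sim-mir-%04d", seq_len(n_mirnas))
  } else if (length(mirna_ids) != n_mirnas || anyDuplicated(mirna_ids)) {
    stop("mirna_ids must be ", n_mirnas, " unique identifiers")
  }

  half <- length(control_cols) %/% 2
  dark_cols <- control_cols[seq_len(half)]
  light_cols <- control_cols[seq(half + 1, length(control_cols))]
  if (length(light_cols) == 0)
    stop("layout has no light-control columns; Z scoring would be impossible")

  sample_cols <- setdiff(seq_len(n_cols), control_cols)
  wells_per_plate <- n_rows * length(sample_cols)
  plates_per_rep <- ceiling(n_mirnas / wells_per_plate)

  base <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols),
                      KEEP.OUT.ATTRS = FALSE)
  base$well <- sprintf("%s%02d", LETTERS[base$row], base$col)
  base$role <- "sample"
  base$role[base$col %in% dark_cols] <- "dark_control"
  base$role[base$col %in% light_cols] <- "light_control"
  # transfection controls: bottom rows of the outermost control columns
  if (n_transfection_controls > 0) {
    outer_cols <- c(min(dark_cols), max(light_cols))
    per_col <- ceiling(n_transfection_controls / 2)
    tc_rows <- seq(n_rows - per_col + 1, n_rows)
    tc <- base$col %in% outer_cols & base$row %in% tc_rows
    tc_idx <- which(tc)[seq_len(min(n_transfection_controls, sum(tc)))]
    base$role[tc_idx] <- "transfection_control"
  }

  set.seed(seed)
  layouts <- vector("list", replicate_count * plates_per_rep)
  k <- 0L
  for (rep_i in seq_len(replicate_count)) {
    order_r <- sample.int(n_mirnas)  # fresh well assignment per replicate
    assigned <- 0L
    for (p in seq_len(plates_per_rep)) {
      wells <- base
      wells$mirna_id <- NA_character_
      n_here <- min(wells_per_plate, n_mirnas - assigned)
      slot <- which(wells$role == "sample")
      fill <- slot[seq_len(n_here)]
      wells$mirna_id[fill] <- mirna_ids[order_r[assigned + seq_len(n_here)]]
      wells$role[setdiff(slot, fill)] <- "empty"
      assigned <- assigned + n_here
      k <- k + 1L
      layouts[[k]] <- structure(
        list(plate_id = sprintf("R%d_P%d", rep_i, p),
             replicate_index = rep_i, n_rows = n_rows, n_cols = n_cols,
             wells = wells[order(wells$col, wells$row),
                           c("well", "row", "col", "role", "mirna_id")]),
        class = "plate_layout")
    }
  }
  layouts
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("<plate_layout> ", x$plate_id, " (replicate ", x$replicate_index,
      "), ", x$n_rows, "x", x$n_cols, " wells\n", sep = "")
  print(table(x$wells$role))
  invisible(x)
}

#' Flatten plate layouts into one plate-map table
#'
#' @param layouts list of `plate_layout` objects from [generate_layout()].
#' @return data frame with columns `plate_id`, `well`, `role`, `mirna_id`,
#'   `replicate` — the CSV plate-map interchange format.
#' @export
layout_table <- function(layouts) {
  if (inherits(layouts, "plate_layout")) layouts <- list(layouts)
  do.call(rbind, lapply(layouts, function(l) {
    data.frame(plate_id = l$plate_id, well = l$wells$well,
               role = l$wells$role, mirna_id = l$wells$mirna_id,
               replicate = l$replicate_index, stringsAsFactors = FALSE)
  }))
}
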