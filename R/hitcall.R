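#' Hit-calling configuration
#'
#' @param z_cutoff_protective protective cutoff on the replicate-averaged Z
#'   (default -2.1; must be negative).
#' @param z_cutoff_deleterious deleterious cutoff (default +2.1; positive).
#' @param cv_policy how the variability filter selects the shortlist:
#'   `"rank_and_keep_top_n"` (default) orders the annotated survivors by CV
#'   ascending and keeps `top_n`; `"cv_threshold"` keeps survivors with
#'   CV <= `cv_threshold`.
#' @param top_n shortlist size under the ranking policy (default 6).
#' @param cv_threshold CV ceiling under the threshold policy (default 0.1).
#' @param annotation_required drop protective candidates absent from the
#'   curated annotation set before CV selection (default TRUE).
#' @param min_replicates minimum replicate observations for a miRNA to be
#'   scored (default 3); miRNAs below it are excluded, not averaged over
#'   fewer replicates, unless `allow_partial`.
#' @param allow_partial average over however many replicates are available
#'   (default FALSE).
#' @param cv_basis `"norm"` (default): CV over the per-replicate
#'   light-normalized dying fractions (positive, scale-free); `"abs_z"`:
#'   CV over |Z| (unstable near 0; provided for comparison).
#' @return A validated `hit_config` list.
#' @export
hit_config <- function(z_cutoff_protective = -2.1, z_cutoff_deleterious = 2.1,
                       cv_policy = c("rank_and_keep_top_n", "cv_threshold"),
                       top_n = 6, cv_threshold = 0.1,
                       annotation_required = TRUE, min_replicates = 3,
                       allow_partial = FALSE, cv_basis = c("norm", "abs_z")) {
  cv_policy <- match.arg(cv_policy)
  cv_basis <- match.arg(cv_basis)
  if (!(z_cutoff_protective < 0 && z_cutoff_deleterious > 0))
    stop("need z_cutoff_protective < 0 < z_cutoff_deleterious")
  if (top_n < 1) stop("top_n must be >= 1")
  structure(as.list(environment()), class = "hit_config")
}

#' Aggregate per-replicate Z scores into per-miRNA scores
#'
#' Computes, for every miRNA, the average Z score across biological
#' replicates and the coefficient of variation used by the reproducibility
#' filter. The CV is taken over the per-replicate light-normalized dying
#' fractions (`norm = x / mu_light`), not over the signed Z scores: the
#' normalized fraction is positive and scale-free, so SD/mean is well
#' defined, whereas a CV of near-zero signed Z values is unstable
#' (`cv_basis = "abs_z"` is available for comparison). miRNAs are ranked
#' densely by mean Z ascending — rank 1 is the most protective — with ties
#' broken by lower CV, then lexicographic id.
#'
#' @param zscore_tables list of per-replicate data frames as returned by
#'   [zscore_wells()] (columns `mirna_id`, `x`, `norm`, `z`); one element
#'   per biological replicate.
#' @param cv_basis see [hit_config()].
#' @return A `mirna_scores` data frame: `mirna_id`, `z_rep<i>` columns,
#'   `mean_z`, `cv`, `n_reps`, `rank`.
#' @examples
#' zt <- lapply(1:3, function(r)
#'   data.frame(mirna_id = c("a", "b"), x = c(30, 42), norm = c(.75, 1.05),
#'              z = c(-2.5, 0.5) + r / 10))
#' aggregate_replicates(zt)
#' @export
aggregate_replicates <- function(zscore_tables, cv_basis = c("norm", "abs_z")) {
  cv_basis <- match.arg(cv_basis)
  stopifnot(is.list(zscore_tables), length(zscore_tables) >= 1)
  for (r in seq_along(zscore_tables)) {
    tab <- zscore_tables[[r]]
    dup <- tab$mirna_id[duplicated(tab$mirna_id)]
    if (length(dup)) {
      ctx <- tab[tab$mirna_id == dup[1],
                 intersect(c("plate_id", "well"), names(tab)), drop = FALSE]
      stop("replicate ", r, ": miRNA ", dup[1],
           " appears more than once (", paste(apply(ctx, 1, paste,
           collapse = "/"), collapse = ", "), ")")
    }
  }
  n_rep <- length(zscore_tables)
  ids <- sort(unique(unlist(lapply(zscore_tables, `[[`, "mirna_id"))))
  zm <- matrix(NA_real_, length(ids), n_rep,
               dimnames = list(ids, paste0("z_rep", seq_len(n_rep))))
  nm <- zm
  for (r in seq_len(n_rep)) {
    tab <- zscore_tables[[r]]
    zm[tab$mirna_id, r] <- tab$z
    nm[tab$mirna_id, r] <- tab$norm
  }
  n_obs <- rowSums(!is.na(zm))
  mean_z <- rowMeans(zm, na.rm = TRUE)
  basis <- if (cv_basis == "norm") nm else abs(zm)
  cv <- apply(basis, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  })
  out <- data.frame(mirna_id = ids, zm, mean_z = mean_z, cv = cv,
                    n_reps = n_obs, row.names = NULL,
                    stringsAsFactors = FALSE)
  ord <- order(out$mean_z, out$cv, out$mirna_id)
  out$rank[ord] <- seq_len(nrow(out))
  class(out) <- c("mirna_scores", "data.frame")
  out
}

#' Canonicalize miRNA identifiers
#'
#' Case-folds and strips a leading species prefix (`hsa-`, `mmu-`, ...) so
#' that `hsa-miR-429`, `miR-429` and `mir-429` all match. Matching is exact
#' after canonicalization; no fuzzy matching.
#'
#' @param ids character vector of miRNA names.
#' @return canonical ids.
#' @export
canonical_mirna_id <- function(ids) {
  ids <- tolower(trimws(ids))
  sub("^[a-z]{3,4}-(?=(mir|let)\\b|mir[0-9-]|let-)", "", ids, perl = TRUE)
}

#' Read an annotation membership list
#'
#' One miRNA id per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
read_annotation <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Rank, filter and shortlist screen hits
#'
#' The protective funnel is: (1) keep miRNAs with replicate-averaged
#' Z below the protective cutoff; (2) keep those present in the curated
#' annotation set; (3) apply the variability policy — by default, rank the
#' survivors by CV ascending and keep the `top_n` most reproducible. The
#' deleterious tail (mean Z above the positive cutoff) is reported as-is,
#' with no further filtering. Every stage's input and output counts are
#' recorded in the provenance.
#'
#' @param scores a `mirna_scores` table from [aggregate_replicates()].
#' @param annotation_set character vector of annotated miRNA ids (matched
#'   via [canonical_mirna_id()]); required when the config demands it.
#' @param config a [hit_config()].
#' @return A `hit_list`: `protective` (ids ordered by mean Z ascending),
#'   `deleterious` (descending), `shortlist` (CV-selected subset of
#'   `protective`), `scores` (the annotated score table) and `provenance`
#'   (config echo plus per-stage counts).
#' @examples
#' we <- synthetic_screen_summary(seed = 1)
#' sc <- aggregate_replicates(we$zscores)
#' hits <- rank_and_filter(sc, we$annotation)
#' hits$shortlist
#' @export
rank_and_filter <- function(scores, annotation_set = NULL,
                            config = hit_config()) {
  stopifnot(inherits(config, "hit_config"))
  if (config$annotation_required &&
      (is.null(annotation_set) || length(annotation_set) == 0))
    stop("annotation filtering requested but annotation_set is empty")
  sc <- as.data.frame(scores)
  n0 <- nrow(sc)
  if (!config$allow_partial) {
    sc <- sc[sc$n_reps >= config$min_replicates, ]
  }
  sc$annotated <- if (is.null(annotation_set)) NA else
    canonical_mirna_id(sc$mirna_id) %in% canonical_mirna_id(annotation_set)
  ord <- order(sc$mean_z, sc$cv, sc$mirna_id)
  sc <- sc[ord, ]

  prot <- sc[sc$mean_z < config$z_cutoff_protective, ]
  delet <- sc[sc$mean_z > config$z_cutoff_deleterious, ]
  annot <- if (config$annotation_required) prot[prot$annotated, ] else prot

  surv <- annot[!is.na(annot$cv), ]
  surv <- surv[order(surv$cv, surv$mirna_id), ]
  if (config$cv_policy == "rank_and_keep_top_n") {
    if (nrow(surv) < config$top_n)
      warning("only ", nrow(surv), " candidates survive filtering; ",
              "shortlist smaller than top_n = ", config$top_n)
    short <- utils::head(surv, config$top_n)
  } else {
    short <- surv[surv$cv <= config$cv_threshold, ]
  }
  short <- short[order(short$mean_z, short$cv, short$mirna_id), ]

  structure(list(
    protective = prot$mirna_id,
    deleterious = rev(delet$mirna_id),
    shortlist = short$mirna_id,
    scores = sc,
    provenance = list(
      config = unclass(config),
      counts = c(scored = n0, complete = nrow(sc),
                 below_protective_cutoff = nrow(prot),
                 annotated = nrow(annot),
                 shortlist = nrow(short),
                 above_deleterious_cutoff = nrow(delet)))),
    class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cts <- x$provenance$counts
  cat("<hit_list>\n")
  cat(sprintf("  scored %d miRNAs (%d with full replicates)\n",
              cts[["scored"]], cts[["complete"]]))
  cat(sprintf("  protective (Z < %.2f): %d; annotated: %d; shortlist: %d\n",
              x$provenance$config$z_cutoff_protective,
              cts[["below_protective_cutoff"]], cts[["annotated"]],
              cts[["shortlist"]]))
  cat(sprintf("  deleterious (Z > %.2f): %d\n",
              x$provenance$config$z_cutoff_deleterious,
              cts[["above_deleterious_cutoff"]]))
  if (length(x$shortlist))
    cat("  shortlist:", paste(x$shortlist, collapse = ", "), "\n")
  invisible(x)
}
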