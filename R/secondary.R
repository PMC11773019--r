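#' Light/dark fold changes from a trypan-blue count table
#'
#' For every (miRNA, treatment, biological replicate), the dead fraction
#' `dead / (live + dead)` is averaged over technical duplicates within each
#' condition, and the fold change is the light-condition fraction divided by
#' the matched dark-condition fraction. Dividing by the matched dark well
#' normalizes away transfection toxicity that acts regardless of light.
#' Replicates whose dark fraction is zero are flagged undefined and dropped
#' with a warning.
#'
#' @param counts data frame with columns `mirna_id`, `condition`
#'   (`light`/`dark`), `treatment`, `replicate`, `live`, `dead` (and
#'   optionally `duplicate`).
#' @return data frame with one row per (mirna_id, treatment, replicate):
#'   `frac_light`, `frac_dark`, `fc`.
#' @examples
#' cts <- simulate_secondary_assay(c("mir-x" = 0.5), seed = 1)
#' fold_change(cts)
#' @export
fold_change <- function(counts) {
  need <- c("mirna_id", "condition", "treatment", "replicate", "live", "dead")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  counts$frac <- counts$dead / (counts$live + counts$dead)
  agg <- stats::aggregate(frac ~ mirna_id + treatment + replicate + condition,
                          counts, mean)
  light <- agg[agg$condition == "light", ]
  dark <- agg[agg$condition == "dark", ]
  m <- merge(light[, c("mirna_id", "treatment", "replicate", "frac")],
             dark[, c("mirna_id", "treatment", "replicate", "frac")],
             by = c("mirna_id", "treatment", "replicate"),
             suffixes = c("_light", "_dark"))
  if (nrow(m) < nrow(light))
    stop("every light observation needs a matched dark observation ",
         "(same miRNA, treatment, replicate)")
  undef <- m$frac_dark == 0
  if (any(undef)) {
    warning(sum(undef), " replicate(s) with zero dark dead fraction: ",
            "fold change undefined, dropped")
    m <- m[!undef, ]
  }
  m$fc <- m$frac_light / m$frac_dark
  m[order(m$mirna_id, m$treatment, m$replicate), ]
}

#' Balanced two-way fixed-effects ANOVA by explicit sums of squares
#'
#' Classical two-factor decomposition for a balanced design with `r >= 2`
#' observations per cell, computed from the textbook sums-of-squares
#' formulas rather than a model-matrix fit, so every quantity is auditable:
#' `SS_A = rb * sum_i (Abar_i - gm)^2`, `SS_B = ra * sum_j (Bbar_j - gm)^2`,
#' `SS_AB = r * sum_ij (cell_ij - Abar_i - Bbar_j + gm)^2`,
#' `SS_E = sum (y - cell)^2`. F is the term mean square over the error mean
#' square; a term with zero sum of squares reports F = 0 and p = 1 (this
#' covers the fully degenerate case of identical observations, where the
#' error mean square is also zero).
#'
#' @param y numeric response.
#' @param a,b factors (or coercible) of the two crossed treatments.
#' @return data frame with rows for factor `a`, factor `b`, `a:b` and
#'   residuals: `term`, `df`, `sumsq`, `meansq`, `F`, `p`.
#' @examples
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"), r = 1:3)
#' d$y <- c(1, 2, 3, 4, 2, 3, 4, 5, 1, 3, 3, 5)
#' anova_two_way(d$y, d$a, d$b)
#' @export
anova_two_way <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  if (anyNA(y) || anyNA(a) || anyNA(b)) stop("missing values not supported")
  tab <- table(a, b)
  if (any(tab < 2))
    stop("every design cell needs >= 2 observations (no error df otherwise)")
  if (length(unique(as.vector(tab))) != 1)
    stop("design must be balanced (equal observations per cell)")
  r <- tab[1, 1]
  na <- nlevels(a); nb <- nlevels(b)
  gm <- mean(y)
  abar <- tapply(y, a, mean)
  bbar <- tapply(y, b, mean)
  cellbar <- tapply(y, list(a, b), mean)
  ss_a <- r * nb * sum((abar - gm)^2)
  ss_b <- r * na * sum((bbar - gm)^2)
  ss_ab <- r * sum((sweep(sweep(cellbar, 1, abar), 2, bbar) + gm)^2)
  ss_e <- sum((y - cellbar[cbind(a, b)])^2)
  df <- c(na - 1, nb - 1, (na - 1) * (nb - 1), na * nb * (r - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- ifelse(ss[1:3] == 0, 0, ms[1:3] / ms[4])
  p <- ifelse(ss[1:3] == 0, 1, stats::pf(f, df[1:3], df[4], lower.tail = FALSE))
  data.frame(term = c("a", "b", "a:b", "residuals"),
             df = df, sumsq = ss, meansq = ms,
             F = c(f, NA), p = c(p, NA), stringsAsFactors = FALSE)
}

#' Two-way test of one miRNA mimic against its negative mimic
#'
#' Default design (`"treatment_x_light"`): two crossed factors, treatment
#' (mimic vs. negative mimic) and illumination (light vs. dark), on the
#' per-replicate dead fractions (technical duplicates averaged first). The
#' treatment-by-illumination interaction is the protection term: a mimic
#' that rescues cells specifically under light shows up there, whereas a
#' light-independent toxicity loads on the treatment main effect.
#' The alternative design (`"treatment_x_replicate"`) tests treatment
#' against biological replicate on the duplicate-level light/dark fold
#' changes; there the treatment main effect is the protection term.
#'
#' @param counts secondary count table (see [fold_change()]) restricted to
#'   one miRNA and its negative mimic.
#' @param design `"treatment_x_light"` (default) or
#'   `"treatment_x_replicate"`.
#' @param alpha significance level (default 0.05).
#' @param transform `"none"` (default) or `"arcsine"`
#'   (`asin(sqrt(p))`, a variance-stabilizer for small-n proportions).
#' @return A `secondary_result`: `mirna_id`, `anova` (full table), `fc`
#'   (per-replicate fold changes), `fc_mimic`/`fc_negative` (means),
#'   `p_value` (protection term), `significant`, `effect_direction`
#'   (`protective`/`neutral`/`deleterious`), `design`, `alpha`.
#' @examples
#' cts <- simulate_secondary_assay(c("mir-x" = 0.5), seed = 1)
#' two_way_test(cts)
#' @export
two_way_test <- function(counts, design = c("treatment_x_light",
                                            "treatment_x_replicate"),
                         alpha = 0.05, transform = c("none", "arcsine")) {
  design <- match.arg(design)
  transform <- match.arg(transform)
  id <- unique(counts$mirna_id)
  if (length(id) != 1)
    stop("two_way_test analyzes one miRNA at a time; got: ",
         paste(id, collapse = ", "))
  if (!all(c("mimic", "negative_mimic") %in% counts$treatment))
    stop("counts must include both the mimic and its negative mimic")
  fc <- fold_change(counts)
  fc_mimic <- mean(fc$fc[fc$treatment == "mimic"])
  fc_negative <- mean(fc$fc[fc$treatment == "negative_mimic"])

  if (design == "treatment_x_light") {
    counts$frac <- counts$dead / (counts$live + counts$dead)
    d <- stats::aggregate(frac ~ treatment + condition + replicate, counts,
                          mean)
    y <- if (transform == "arcsine") asin(sqrt(d$frac)) else d$frac
    an <- anova_two_way(y, d$treatment, d$condition)
    an$term <- c("treatment", "illumination", "treatment:illumination",
                 "residuals")
    protection_term <- "treatment:illumination"
  } else {
    if (!"duplicate" %in% names(counts))
      stop("treatment_x_replicate design needs duplicate-level counts")
    counts$frac <- counts$dead / (counts$live + counts$dead)
    agg <- stats::aggregate(frac ~ mirna_id + treatment + replicate +
                              duplicate + condition, counts, mean)
    lg <- agg[agg$condition == "light", ]
    dk <- agg[agg$condition == "dark", ]
    m <- merge(lg, dk, by = c("mirna_id", "treatment", "replicate",
                              "duplicate"), suffixes = c("_l", "_d"))
    if (any(m$frac_d == 0)) stop("zero dark dead fraction: fold change undefined")
    fcv <- m$frac_l / m$frac_d
    an <- anova_two_way(fcv, m$treatment, m$replicate)
    an$term <- c("treatment", "replicate", "treatment:replicate", "residuals")
    protection_term <- "treatment"
  }
  p <- an$p[an$term == protection_term]
  sig <- is.finite(p) && p <= alpha
  direction <- if (!sig) "neutral" else
    if (fc_mimic < fc_negative) "protective" else "deleterious"
  structure(list(mirna_id = id, anova = an, fc = fc,
                 fc_mimic = fc_mimic, fc_negative = fc_negative,
                 protection_term = protection_term, p_value = p,
                 significant = sig, effect_direction = direction,
                 design = design, alpha = alpha),
            class = "secondary_result")
}

#' @export
print.secondary_result <- function(x, ...) {
  cat(sprintf("<secondary_result> %s (%s design)\n", x$mirna_id, x$design))
  cat(sprintf("  mean FC mimic = %.3f, negative mimic = %.3f\n",
              x$fc_mimic, x$fc_negative))
  cat(sprintf("  %s: p = %.4g -> %s at alpha = %g\n", x$protection_term,
              x$p_value, x$effect_direction, x$alpha))
  invisible(x)
}

#' Run the secondary test over several miRNAs
#'
#' Applies [two_way_test()] per miRNA. By default each miRNA is tested at
#' `alpha` with no multiple-testing correction (each mimic is compared only
#' to its own matched negative control); `correction = "sidak"` applies a
#' Sidak adjustment across the tested set.
#'
#' @inheritParams two_way_test
#' @param correction `"none"` (default) or `"sidak"`.
#' @return data frame with one row per miRNA: fold changes, p-value
#'   (adjusted if requested), significance and direction.
#' @export
secondary_screen <- function(counts, design = "treatment_x_light",
                             alpha = 0.05, transform = "none",
                             correction = c("none", "sidak")) {
  correction <- match.arg(correction)
  ids <- unique(counts$mirna_id)
  res <- lapply(ids, function(i)
    two_way_test(counts[counts$mirna_id == i, ], design = design,
                 alpha = alpha, transform = transform))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  if (correction == "sidak") p <- 1 - (1 - p)^length(p)
  sig <- p <= alpha
  fcm <- vapply(res, `[[`, numeric(1), "fc_mimic")
  fcn <- vapply(res, `[[`, numeric(1), "fc_negative")
  data.frame(mirna_id = ids, fc_mimic = fcm, fc_negative = fcn,
             p_value = p, significant = sig,
             effect_direction = ifelse(!sig, "neutral",
                                       ifelse(fcm < fcn, "protective",
                                              "deleterious")),
             stringsAsFactors = FALSE)
}
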