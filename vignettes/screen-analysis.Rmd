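---
title: "Analysis of arrayed miRNA-mimic light-protection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of arrayed miRNA-mimic light-protection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsprotect)
```

## The screening problem

Photoreceptor-like cell lines such as 661W die under intense light exposure,
which makes them a convenient in vitro model for photo-oxidative retinal
degeneration. An arrayed miRNA-mimic screen transfects each well of a
384-well plate with one synthetic miRNA mimic, stresses the plate with
bright light, stains nuclei with a DNA dye, and asks which miRNAs reduce
the fraction of dying cells. `hcsprotect` implements the complete analysis
for such a screen:

1. **Imaging** — segment nuclei, classify each as healthy or dying from
   intensity and morphology, and summarize each well as a percent-dying
   value.
2. **Plate statistics** — per-plate quality control and Z scoring of sample
   wells against the plate's light-exposed control wells.
3. **Hit calling** — replicate averaging, cutoff/annotation/variability
   filters, and ranked protective and deleterious hit lists.
4. **Secondary validation** — light/dark fold-change normalization of a
   trypan-blue viability assay and a per-miRNA two-way ANOVA against a
   non-targeting negative mimic.
5. **Synthetic data** — a seeded generator of all of the above inputs with
   known ground truth, so every stage can be tested against planted effects.

## Plate layout and controls

Each 16 x 24 plate reserves its first two columns for *dark controls*
(untransfected wells shielded from light) and its last two for *light
controls* (untransfected, exposed). A handful of wells in the outermost
control columns carry a red-labelled non-targeting mimic and act as
*transfection controls*. The remaining 320 wells carry one miRNA mimic
each. `generate_layout()` builds these maps, randomizing miRNA positions
independently per biological replicate so positional artifacts cannot
follow a miRNA across replicates.

Dark controls exist to prove the stressor worked: a plate where light
controls do not die more than dark controls carries no signal, and
`qc_plate()` fails it. The default separation statistic is the difference
of control means over the pooled control SD, with a floor of 2; a Z'-factor
mode is available. The floor is a configurable policy choice — effective
light stress in this model system typically yields separations far above
it, so the floor mainly guards against plates where the illumination or
seeding failed outright.

## The Z score

For a sample well with percent dying $x$ on a plate whose light controls
have mean $\mu$ and standard deviation $\sigma$,

$$Z = \frac{x - \mu}{\sigma}.$$

Negative Z means fewer dying cells than the light-stressed baseline, i.e.
protection. Normalization is strictly per plate: plates carry batch offsets
(the generator plants them by default), and scoring each plate against its
own controls absorbs them. $\sigma$ is the sample (n−1) standard deviation;
the convention matters at control counts around 30 wells and is pinned by
an oracle test. Wells with too few nuclei (default floor: 50) are excluded
from both the control statistics and the Z output rather than imputed.
Control wells never receive a Z. No additional normalization is applied
before the Z step, and no spatial (row/column/edge) correction is applied
at any point.

## Replicate aggregation and the CV filter

Per miRNA, the replicate Z scores are averaged (`mean_z`) and a coefficient
of variation quantifies irreproducibility. The CV is deliberately **not**
taken over the signed Z scores: Z values near zero make SD/mean explode and
the sign makes it meaningless. Instead the CV is computed over the
per-replicate *light-normalized dying fractions* $x/\mu$, which are
positive and scale-free; a `cv_basis = "abs_z"` mode exists for comparison.
This is the package's single most consequential convention and is therefore
carried in the Z-score tables themselves (`norm` column).

The protective funnel is: `mean_z` below the protective cutoff (default
−2.1) → membership in a curated annotation list (a MirGeneDB-style file,
one id per line; matching is exact after case-folding and species-prefix
stripping, never fuzzy) → rank survivors by CV ascending and keep the
`top_n` most reproducible (default 6). The deleterious tail (`mean_z` above
+2.1) is reported without further filtering. Ties on `mean_z` break by
lower CV, then lexicographic id, so ranking is always a permutation.
miRNAs that lost a replicate to a failed QC plate are excluded rather than
averaged over fewer replicates (`allow_partial` relaxes this). Every
filter stage logs its input and output counts in the hit list's provenance.

## Secondary assay analysis

The trypan-blue validation assay counts live and dead cells per well in
matched light and dark plates, with technical duplicates per condition and
three biological replicates. `fold_change()` averages duplicates within a
condition, then divides the light dead-fraction by the matched dark
dead-fraction per biological replicate — normalizing away light-independent
transfection toxicity. A zero dark fraction makes the ratio undefined; such
replicates are dropped with a warning rather than patched.

`two_way_test()` fits a classical balanced two-factor fixed-effects ANOVA
from explicit sums of squares (`anova_two_way()`), not an opaque formula
interface, so the arithmetic is auditable and testable against both hand
computation and `stats::aov`. The default design crosses *treatment* (mimic
vs. negative mimic) with *illumination* (light vs. dark) on the
replicate-averaged dead fractions; the treatment-by-illumination
interaction is the protection term, because a mimic that rescues cells
specifically under light loads there while uniform toxicity loads on the
treatment main effect. An alternative design (treatment crossed with
biological replicate on duplicate-level fold changes, protection read from
the treatment main effect) is selectable; the two designs answer subtly
different questions and can report different p values, which is why the
choice is explicit configuration. Dead fractions are analyzed untransformed
by default; an arcsine-square-root option exists for small-n proportions.
Each miRNA is tested against its own matched negative control at
α = 0.05 with no multiple-testing correction by default; a Sidak option
adjusts across the tested set.

Degenerate inputs are defined, not accidental: a term with zero sum of
squares reports F = 0 and p = 1 (covering the all-observations-equal case
where the error mean square is also zero), and any design cell with fewer
than two observations is rejected because there is no error df.

## The synthetic generator

The generator is the package's test bed and defines the conditions under
which the pipeline's statistical claims are verified.

**Well-level (fast) mode.** Ground truth fixes a dark baseline dying
fraction (default 0.05), a light baseline (default 0.40), and one
multiplicative effect per miRNA acting only under light (1 neutral,
< 1 protective, > 1 deleterious). A well's realized dying probability adds
a per-plate batch offset (Gaussian, SD 0.02 — the reason per-plate
normalization exists) and well-to-well Gaussian noise (SD 0.03), and the
dying count is binomial over the cells seeded per well (default 650, a
typical 384-well seeding density). The binomial choice makes closed-form
expectations available for tests. The 5%/40% baselines are configuration
choices that make QC separation non-trivial, not biological claims.
`noise_sd = 0` short-circuits to a fully deterministic table, which the
degenerate-case tests rely on.

**Image mode.** Each nucleus is a 2-D anisotropic Gaussian blob over a
uniform background with signal-proportional shot noise and Gaussian read
noise. Dying nuclei are rendered strictly brighter (amplitude × 2.2) and
smaller (radius × 0.4) than healthy ones, with multiplicative intra-nuclear
speckle — the pyknotic, condensed-chromatin phenotype that intensity- and
morphology-based classification exploits. The template contrast is chosen
so that the two populations are cleanly separable by robust per-plate
thresholds; nuclei-per-field (Poisson, mean 80 in a 240 px field) and
acquisition settings are free parameters with no empirical anchor, chosen
once for desk-scale runtimes. Nuclei are placed by rejection sampling with
a minimum separation of 3.2 radii (essentially non-overlapping); requesting
more nuclei than the field can pack is an error with a diagnostic, not a
silent density change. Transfection-control wells render a red marker
channel over a configurable fraction of nuclei (default 0.5, the typical
reverse-transfection efficiency).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatial gradients and edge effects within plates,
focus drift and illumination shading, debris and segmentation-confusing
clumps, real apoptotic morphology beyond the brighter/smaller/speckled
abstraction, cross-talk between channels, and any correlation between a
miRNA's identity and its well position beyond the layout itself. Results on
real screens depend on the upstream imaging matching the assumptions the
classifier encodes.

## Imaging operators and numerical choices

Segmentation is a fully specified standard chain: Gaussian smoothing
(σ = 1 px), global Otsu threshold, morphological opening,
distance-transform watershed, minimum-area filter (20 px²), and discard of
edge-touching objects (truncated nuclei bias both area and intensity). The
default watershed tolerance (0.5) does not over-segment speckled apoptotic
nuclei; fields with many genuinely touching nuclei should lower it
(e.g. 0.1), at the cost of occasional over-splitting — over-split control
nuclei inflate the fitted area MAD and bias the dying count down, which is
why conservative splitting is the default. A frame whose foreground does
not stand clear of the background noise floor (six background MADs) yields
zero nuclei with a flag rather than an error or Otsu noise-bisection
artifacts.

Classification defaults to a deterministic, auditable two-threshold rule:
dying iff mean intensity at or above the intensity criterion AND area at or
below the area criterion. Criteria are fit per plate from the dark-control
nucleus population as median ± k·MAD with k = 3 — dark controls are the
overwhelmingly healthy reference and robust statistics tolerate their small
dying minority, while per-plate fitting absorbs plate-level intensity
shifts. A 2-component k-means mode exists behind a flag for populations
where fixed rules fail. The exact features and thresholds a commercial
high-content analysis suite would use are not reproducible from the
outside; this rule is an explicit, documented stand-in driven by the same
intensity/morphology contrast.

Transfection efficiency is the fraction of segmented nuclei whose
surrounding red-channel disc exceeds the red background by six MADs.

## Problem sizes used in the checks

The test suite and the acceptance script verify the pipeline at the scale
each claim concerns: the null-calibration and planted-recovery checks run
the full screen geometry (1,268 miRNAs × 3 replicates × 4 plates per
replicate) in fast mode across multiple seeds; imaging concordance runs one
complete 384-well plate in image mode; ANOVA calibration uses 1,000 null
simulations. The worked-example dataset (`synthetic_screen_summary()`) is a
fully synthetic per-miRNA summary at the published screen's scale — 1,268
miRNAs with three replicate Z scores each, a planted six-member annotated
reproducible shortlist led by miR-429, planted high-CV and unannotated
decoys that exercise every filter, and a null background whose
replicate-mean is clipped away from the cutoffs so the planted structure is
the only signal at any seed. It demonstrates and tests the hit-calling
funnel; its numbers are generated, not measured.

## Known limitations

- The classifier is a two-feature rule; dim-but-fragmented or
  bright-but-large death phenotypes would be missed by construction.
- Fold changes are undefined for zero dark mortality; with very low seeded
  counts this occurs in practice and simply drops the replicate.
- The ANOVA assumes homoscedastic errors across design cells; dead
  fractions at very different baselines violate this mildly (the
  arcsine option mitigates it), and the type-I calibration check bounds
  the practical impact under the generator's noise model.
- No spatial normalization is implemented; screens with strong edge
  effects need upstream correction before Z scoring.

## A minimal run

```{r example, eval = FALSE}
library(hcsprotect)
eff <- c("sim-mir-0007" = 0.5)          # one planted protector
cfg <- run_config(n_mirnas = 100, effects = eff, seed = 1,
                  hit = hit_config(top_n = 1))
rep <- run_screen(cfg)
rep$hits$shortlist                       # "sim-mir-0007"
rep$secondary                            # its trypan-blue validation
```
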