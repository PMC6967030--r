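---
title: "Models, parameters and design choices in lchquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in lchquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lchquant)
```

# Scope

`lchquant` implements, as reusable and tested operations, the quantitative
chain used to ask whether BRAF V600E mutated Langerhans Cell Histiocytosis
(LCH) lesions differ in CD8⁺ T cell infiltration, whether HLA genotype is
associated with the disease, and whether a V600E-derived neopeptide is
presented by HLA class I. Because no patient-level raw data are publicly
deposited for this problem, every pipeline stage is exercised against a
synthetic-data module with known ground truth. This vignette records the
models, the tunable parameters with their defaults and units, the numerical
choices, and what the synthetic world does and does not establish.

# The synthetic world

## Lesion images

`generate_lesion_image()` renders three stained classes — CD1a⁺ LCH-cells
(green), CD3⁺CD8⁻ T cells (red), CD3⁺CD8⁺ T cells (purple) — as **opaque,
non-overlapping disks** placed by rejection sampling (at most 1000 retries
per cell, then an error naming the class). Opacity and non-overlap are a
deliberate simplification: they make the per-class pixel area an exact,
independently recomputable oracle, so the automated area quantification can
be tested for *exact* agreement rather than approximate similarity.
Autofluorescent blobs use a none-of-the-above colour (yellow) and are drawn
underneath the cells; photobleaching is a single multiplicative factor
`bleach_factor` in (0, 1]; background noise is Gaussian with standard
deviation `0.15 * background_level`, so `background_level = 0` is exactly
noiseless.

CD3⁺CD8⁺ cells are rendered in a distinct purple rather than an additive
red+blue mixture, matching the three display classes used when such slides
are scored; one pixel belongs to at most one class.

What the generator does **not** emulate: tissue texture, optical point-spread
functions, chromatic aberration, scanner tiling, partial-volume cell overlap
and out-of-focus regions. A green test on these images therefore establishes
that the colour-threshold area pipeline is *algorithmically* correct and
robust to uniform casts, bleaching and autofluorescent clutter — not that it
matches human annotation on real tissue.

## Cohorts

`generate_cohort()` states the world as: BRAF status Bernoulli
(`braf_pos_fraction`, default 48/93, the known-status fraction of the
studied cohort); CD8 ratio lognormal with group medians
`median_ratio_brafpos = 0.0316` and `median_ratio_brafwt = 0.0775` (the two
reported group medians) and a shared `ratio_log_sd`; HLA loci independent
with stated allele frequencies (residual mass pooled into `<locus>*other`);
event times exponential with hazard
`event_rate * exp(beta * (log ratio - mean log ratio))` and administrative
censoring at `admin_horizon_years = 15`; human counters with mean-1
lognormal multiplicative error of coefficient of variation `counter_cv`.

**The spread parameter.** `ratio_log_sd` is genuinely unconstrained by the
printed results. Two stated requirements pull in opposite directions: the
printed per-patient ratio range (0.00–4.96 at n = 101) would need
`ratio_log_sd ≈ 1.6`, while the required ≥ 80% Mann-Whitney power of the
two-median comparison at n ≈ 93 holds only up to about 1.2. We fix the
default at **1.1**, satisfying the explicit quantitative power property and
accepting that simulated cohorts are under-dispersed relative to the printed
extremes (observed n = 101 range ≈ 0.003–0.54). This is a documented free
parameter, not a fitted one.

Other defaults chosen once as field-realistic: `event_rate = 0.03`/year
(≈ one-third of patients with an event inside a 15-year horizon, the scale
of reactivation in long follow-up cohorts), counter CV 5% (trained observers
on the same images), demographics drawn from the marginal mix of the studied
cohort (84% pediatric, 52% male, 77% single-system).

## Binding curves and PRM reports

Titrations follow a four-parameter logistic (4PL) in concentration,
`y = bottom + (top - bottom) / (1 + (c / IC50)^h)`, with multiplicative
mean-1 lognormal noise; at `c = IC50` the noiseless signal is exactly the
midpoint. PRM reports pair light (endogenous) and heavy (spiked) rows per
transition with areas proportional to amount through a shared per-transition
response factor; an absent peptide produces light areas at a ~1e-5 noise
floor and a non-coeluting retention time, so all three detection checks fail
for it.

# The quantification pipeline

## Automated area quantification

The operation order is ROI → white balance → uniform thresholds → cumulative
areas → ratios.

- **ROI**: a simple polygon; pixels are in/out by their centre (0-based,
  origin top-left, half-open convention). Self-intersecting and zero-area
  polygons are rejected.
- **White balance** is per-image and per-channel affine. The gain is the
  through-origin least-squares slope of known class target colours on
  background-subtracted foreground means; the offset sends the background
  mean to 0. This maps an already-balanced image to itself and inverts any
  channel-wise affine cast (uniform offset, bleaching) exactly. Background
  and foreground references closer than 10/255 in RGB are rejected as
  insufficient contrast. Nonlinear sensor response is not modelled.
- **Classification** happens in HSV after balancing, because "green / red /
  purple" are hue statements: default hue windows 90–150° (green), 330–30°
  (red), 250–320° (purple), minimum saturation 0.3 and value 0.15. Windows
  must be pairwise disjoint; on hypothetical overlap the priority is purple
  > red > green (a CD3⁺CD8⁺ pixel is also CD3⁺ and must be counted once).
  Pixels within 0.15 RGB distance of the designated autofluorescence
  reference are voided first. Thresholds are global to a batch; calibration
  is per image; there is no shared mutable state between images.
- **Ratios**: `(red+purple)/green` and `purple/green`. A zero green area is
  an error, never a silent 0 — the patient must be flagged.

An automated surrogate for the by-eye exclusion of images with colour casts
or folded tissue (e.g. flagging high background variance) is deliberately
*not* claimed to reproduce expert judgement; only an ROI-level error path
exists.

## Manual counting and scoring

Counters' per-image counts are summed per patient; the two totals are
compared per class by `|A - B| / mean(A, B)`. At or below 10% the final
count is the half-up-rounded mean (the combination rule is not stated in the
source workflow; the mean is our choice, recorded as such). Above 10% a
referee selection is required, constrained to equal one counter's total per
class; in synthetic runs `referee_from_truth()` picks the counter closer to
ground truth. Semi-quantitative 1+–4+ scores from three scorers are averaged
(half-up) when the maximum pairwise difference is ≤ 1, otherwise a supplied
consensus value is required. Counting on masks uses 4-connected components
with `min_cell_area = 20` px (just under the smallest generated cell); a
cell split in two by the ROI boundary is counted twice — a documented
limitation forced by the definition.

# Statistical procedures

- **Fisher 2×2** is an exact enumeration over the hypergeometric support;
  two-sided by summing all tables with probability ≤ observed × (1 + 1e-7).
  The tie tolerance prevents floating-point order effects at symmetric
  tables.
- **Hardy-Weinberg** uses the exact conditional test; multi-allelic HLA loci
  are collapsed allele-vs-rest (the full multi-allelic exact test is out of
  scope).
- **Association scan**: carrier (dominant) coding; Šidák families are
  per-locus (the family definition is not stated in the source; per-locus is
  the conservative, conventional choice for HLA scans). Odds ratios are
  Woolf with Haldane's +0.5, so zero-carrier tables stay finite. Good's
  standardization is `min(0.5, p·√(n_actual/n_standard))` with
  `n_standard = 4·n_cases`; the cited method's exact formula is not printed
  in the source, so the form is isolated in `good_standardized_p()` for
  easy revision.
- **Cohort statistics**: the median split sends ties and the median itself
  to LOW (this reproduces a 50/51 split of 101 distinct values);
  Mann-Whitney is exact for two groups of ≤ 8 without ties and otherwise a
  tie-corrected normal approximation; Kaplan-Meier/log-rank and Cox (Efron
  ties) are delegated to the `survival` package behind the module
  interfaces. Zero ratios are replaced by half the smallest positive cohort
  ratio before the log transform — a documented knob, not a statement about
  the real data.

# Peptide screening

Mutation-spanning 8–12mers are enumerated with the substitution applied,
deduplicated by sequence and ordered by (length, start); an interior variant
yields exactly 8+9+10+11+12 = 50 windows. IC50 fitting is least-squares 4PL
on log10 concentration from multiple starts (Nelder-Mead, relative tolerance
1e-15), scale-invariant in signal units; curves whose fitted dynamic range
is under three residual standard deviations (or whose IC50 extrapolates
1000× beyond the dosed range) return an infinite-IC50 "no measurable
binding" sentinel instead of an uninterpretable number. Binder classes cut
at 50 nM (strong, inclusive) and 500 nM (intermediate, inclusive). Because a
peptide can exceed 500 nM while binding nearly as well as the strong
reference in the same assay run, `classify_binding()` accepts the
target/reference IC50 ratio and labels the (500, 1000] nM, ratio < 3 regime
`intermediate-by-ratio`.

PRM abundance is `heavy_spike × Σlight/Σheavy` over shared transitions.
Detection requires three independent checks: ≥ 3 light transitions
co-eluting with the heavy standard within 0.5 min, light/heavy intensity
rank correlation ≥ 0.9, and abundance ratio ≥ 0.001. These thresholds stand
in for expert review of extracted chromatograms and are package constructs.
Predicted binding/cleavage values from external neural-network tools are
accepted as pass-through annotation columns only and are never computed.

# What green tests establish

The acceptance suite verifies: exact reproduction of printed contingency
arithmetic (Fisher p-values, reciprocal ratios, carrier percentages); exact
oracle equivalence of the area pipeline on noiseless renders and ≤ 25%
relative error under default noise; IC50 recovery (median relative error
≤ 15% at 5% noise); Cox bias and coverage at stated n; Šidák family-wise
error control under the null; Mann-Whitney power at the stated medians; and
an exactly reproduced present/absent PRM panel. All of these are statements
about the stated synthetic world; none certifies performance on real slides
or spectra.
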