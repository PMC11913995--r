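---
title: "Evaluating dried-spot extraction protocols with spotEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating dried-spot extraction protocols with spotEval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(spotEval)
  library(SummarizedExperiment)
})
```

## The problem

Dried blood spots (DBS) and dried plasma spots (DPS) are card-based
microsamples: a drop of capillary blood is dried on a device such as a
Whatman 903 card, a Capitainer B (which meters an exact 10 µL volume
microfluidically), or a Telimmune DUO plasma-separation card. Before such
devices can carry untargeted metabolomics and lipidomics, three pre-analytic
questions have to be answered from pilot LC-MS data:

1. **Which extraction solvent?** Polar metabolites prefer aqueous methanol;
   lipids prefer pure organic solvents (methanol, isopropanol,
   butanol/methanol). A single spot analysed for both omics needs a
   compromise, or a two-step (consecutive) extraction.
2. **How reproducible is each protocol?** Replicate spots should agree;
   features with a CV above 30% are conventionally considered unreliable.
3. **How long does a spot survive at room temperature?** Remote sampling
   implies days without a cold chain.

`spotEval` turns the pilot-study analysis of these questions into a tested,
reusable pipeline operating on annotated feature tables (features × samples
with per-feature class annotations and per-sample design metadata). It does
not touch raw spectra: peak picking and annotation happen upstream.

## The data model

`SpotExperiment` extends `SummarizedExperiment`: the `"intensity"` assay
holds the feature × sample matrix, `rowData` the feature annotations
(`feature_id`, `assay` ∈ {polar, lipid}, `compound_class`), `colData` the
sample metadata (`device`, `solvent`, `replicate`, `day`,
`extraction_mode`), and two `metadata()` flags record whether the values
have been sum-normalized and/or log10-transformed. Polar features belong to
six classes (purine/pyrimidines, carboxylic acids, amino acids, sugars,
carnitines, phosphorylated compounds), lipids to eight (Cer, LPC, PC, PE,
PI, PS, SM, TG). An intensity of exactly 0 means "not detected"; there is
no separate missing-value state, and empty matrix cells are read as 0.
Because the sample key (device, solvent, replicate, day, extraction mode)
must be unique, one table holds one assay; polar and lipid data are
analysed as separate tables, which is also how the two LC-MS methods
produce them.

## The extraction score

For each feature the raw intensity of every in-scope sample is divided by
that feature's maximum over the in-scope samples and expressed as a
percentage; the percentage is binned into a score:

| relative intensity | score |
|---|---|
| not detected (intensity 0) | 0 |
| < 25% | 1 |
| 25% ≤ · < 50% | 2 |
| 50% ≤ · < 75% | 3 |
| ≥ 75% | 4 |

The per-sample **total score** is the sum over features, and each
extraction condition is reported as the mean ± SD of its replicate totals.
Class-level heatmaps average the per-feature scores over each
(class, solvent) cell within a device.

Choices worth making explicit:

* **Scope of the maximum.** The default anchors each feature's maximum
  within one device (and assay), across its solvents and replicates,
  because devices are evaluated and tabulated separately; cross-device
  pooling would let one device's strong ionisation depress every score of
  another. `scope = "all"`, or an arbitrary column grouping, widens this.
* **Boundary semantics** are lower-inclusive/upper-exclusive exactly as in
  the table above, with ≥ 75% closing the top bin. An exact tie at 25/50/75
  therefore lands in the upper bin, and the in-scope maximum itself always
  scores 4 (the "max-anchoring" property the tests assert).
* **Score 0 is keyed to non-detection**, not to a 0% rounded percentage: a
  detected but tiny signal scores 1.
* **SD over replicates** uses the n−1 sample convention; single-replicate
  conditions report sd = 0 and carry a warning flag.
* Scoring consumes **raw intensities**. Sum normalization rescales every
  sample column and would distort a statistic defined as
  intensity-relative-to-maximum; normalization belongs to the multivariate
  stages below.

## Preprocessing for the statistical stages

`normalizeSum()` divides each sample column by its total signal (each
column then sums to 1) — the usual correction for overall signal-intensity
differences between extracts before PCA or differential comparison. It is
per-column by construction, value-idempotent, and scale-invariant per
sample. `log10Transform()` then stabilises the heavy right tail; zeros are
replaced by half the smallest positive value in the table (`half_min`, the
common metabolomics default) or refused (`zero_policy = "error"`). The
half-minimum is global rather than per-feature so that the imputed value is
always below every observed signal.

## Reproducibility (CV%)

`cvPercent()` is 100 × SD(n−1) / mean over the replicate values of one
condition. It is undefined — flagged and excluded, never silently zero —
when the mean is not positive or fewer than two replicates detected the
feature. `cvProfile()` summarises each condition by the percentage of
defined-CV features with CV < 10%, between 10 and 30%, and > 30%. The
printed bucket labels leave CV = 10 and CV = 30 unassigned; the package
assigns both boundaries to the middle bucket ([0,10), [10,30], (30,∞)) so
that every value lands somewhere and "greater than 30%" keeps its strict
meaning. Bucket percentages always sum to 100 over defined-CV features.
CVs default to raw intensities: CV is scale-invariant within a sample, and
dividing each column by a different total (sum normalization) would add
between-replicate variation that is an artefact of the correction.

## Short-term stability

For a room-temperature storage series (days 0–5, day 0 = immediately
frozen), each feature's variation at day *d* is
100 × (mean_d − mean_0)/mean_0 over replicates, and a class's variation is
the mean over its features (`aggregation = "feature_mean"`). A class is
**stable** at day *d* while |variation| ≤ 20% (the `band` argument; sitting
exactly on the band edge counts as stable). Day-0 variation is identically
zero, noise or not, because day 0 is its own baseline. Features not
detected at baseline cannot contribute a finite ratio; they are excluded
and counted. The per-feature aggregation is deliberate: averaging the
class-summed signal instead (`"class_sum"`, available as an option) lets a
few high-abundance features mask degradation of the rest of the class. The
experimental horizon is what the series contains — the package never
extrapolates beyond the last observed day.

## Single versus consecutive extraction (volcano)

`volcanoCompare()` contrasts two groups of spots feature by feature: the
fold change is the ratio of group means on the linear, sum-normalized scale
(positive = higher in the consecutive group), the p-value a **two-sided
Welch t-test** on log10-transformed normalized values, and a feature is
significant when p < 0.05 and the fold change is at least 1.5-fold in
either direction. Welch rather than a paired test because single- and
two-step extractions consume different physical spots; no multiple-testing
correction by default (the conventional volcano display uses raw p-values;
`pAdjust` switches on any `p.adjust` method). The row-wise Welch test is
computed in closed form over all features at once and is cross-checked
against `stats::t.test` in the unit tests. One caveat the simulation makes
visible: because normalization is compositional, boosting one class's
recovery necessarily depresses every other class's normalized share — a
genuine property of sum-normalized data, not an artefact of the
implementation.

## PCA overview

`pcaOverview()` decomposes the samples of a normalized, log-transformed
table (features mean-centered; unit-variance autoscaling optional and off
by default, since log10 already compresses the dynamic range and autoscaling
would up-weight near-constant features). It reports per-PC variance
explained (summing to 100%) and the PC1+PC2 sum conventionally quoted as a
single clustering summary.

## BCA protein calibration

`bcaFit()` fits absorbance at 562 nm against the standard series
(conventionally 0–2000 µg/mL) by ordinary least squares and
`bcaConcentration()` inverts unknowns as
dilution_factor × (A − intercept)/slope, flagging values outside the
standards' range as extrapolation. A non-positive slope is treated as an
assay failure, not a usable fit. A quadratic option (`degree = 2`) covers
the mild top-of-range curvature BCA can show; inversion then takes the
quadratic root on the branch through the origin.

## The synthetic-data generator

The generator exists so that every stage can be tested against a known
truth. It emulates the study design — 3 devices × 5 solvents × 3 replicate
spots for the solvent screen, a 6-point day 0–5 series for stability, and
n = 3 paired single/consecutive samples — with this mechanism per cell:

> intensity = base_feature × yield(class, solvent, device) × LN(0, σ),

where base intensities are drawn log-uniformly (default 10^4–10^7 au,
a typical Q-TOF feature-intensity range), σ = √ln(1 + cv²) makes the
lognormal noise hit a target replicate CV exactly, storage multiplies the
expectation by (1 − decay_rate_class)^day (geometric per-day loss, the
simplest model producing the observed variation-to-baseline curves), the
consecutive mode multiplies by a per-class boost ≥ 1, and anything below
the detection limit (applied **after** noise, so low-yield conditions
produce realistic score-0 zeros) is set to 0. A single RNG stream per
table is consumed in a fixed documented order — base intensities over
features first, then the noise matrix in column-major order — so a fixed
config is bit-reproducible. The returned truth object (realized bases,
expected matrix, yield and decay maps, seed) suffices to recompute every
cell's expectation.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `noiseCv` | 0.15 | mid-range replicate CV for untargeted LC-MS; most features then sit in the 10–30% bucket |
| `baseLog10Range` | (4, 7) | three decades of feature abundance, typical for annotated Q-TOF tables |
| `detectionLimit` | 5 × 10³ au | just below the weakest base intensity, so only low-yield conditions censor |
| `nFeaturesPerClass` | 27 polar / 41 lipid | totals ≈ 162 polar and 328 lipid features, matching a realistic annotated data set |
| `decayRate` | 0 per class | no decay unless the user plants some; stability experiments set it explicitly |
| `nReplicates` | 3 | triplicate spots per condition, the standard pilot design |
| yield table | see `defaultClassYield()` | methanol-based solvents favour polar classes, with phosphorylated-compound yield rising with water fraction; lipid yields fall with water; pure organics strongest for lipids |

What the generator deliberately does **not** emulate: chromatographic drift
and batch effects, hematocrit-dependent spreading on non-volumetric cards,
inter-subject biological variance (the emulated design samples one
subject), correlation between features, and a "not measured" state distinct
from non-detection. Passing tests therefore demonstrate that the statistics
recover planted structure under multiplicative noise — not that any real
device or solvent behaves as the defaults do.

## Numerical choices and degenerate inputs

* Relative intensities are computed as (x / max) × 100 so the in-scope
  maximum is exactly 100 in floating point; an all-zero feature yields 0%
  everywhere rather than 0/0.
* Welch p-values for rows where both groups are constant are 1 when the
  means agree and 0 otherwise (the limit of the test).
* Fold changes where one group is entirely zero are ±∞ and can be
  significant; features zero in both groups are excluded.
* The BCA extrapolation flag carries a 10⁻⁹-relative slack so standards at
  the range limits are not spuriously flagged.
* Validation is total: malformed tables (duplicate ids, negative raw
  intensities, unknown devices/solvents/classes, broken cross-references)
  raise typed errors naming the offending value; nothing is silently
  coerced.

## Problem sizes used by the test and acceptance suites

The packaged checks run the solvent screen at 4–10 features per class,
CV calibration at 1000 replicates of 60 features, 100 seeds for
solvent-ranking recovery, 200 seeds × 504 features for the volcano
type-I-error simulation and 25 seeds for its power counterpart — sizes
chosen so the whole suite exercises every code path in about a minute on a
single core while keeping Monte-Carlo error well below the asserted
margins.

## A worked run

```{r example}
cfg <- syntheticConfig(seed = 11)
sim <- simulateExtractionExperiment(cfg)
sim$table

rep_ <- scoreReport(sim$table)
head(rep_$totals[rep_$totals$device == "Capitainer", c("solvent", "mean_score", "sd_score")])

round(rep_$heatmaps$Capitainer, 2)

prof <- cvProfile(sim$table)
head(prof$buckets[, c("device", "solvent", "cv_lt_10", "cv_10_30", "cv_gt_30")], 3)
```

## Known limitations

The score is an ordinal summary: it deliberately discards intensity
information within bins, so near-ties between solvents should be read
alongside the CV buckets rather than alone. Sum normalization makes the
volcano compositional (see above). The stability call treats the class mean
as the unit of decision; single diverging features inside a stable class
are visible in the per-feature CV output, not in the class call. And the
generator's yield defaults encode qualitative solvent-chemistry trends,
not measurements of any particular device.
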