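---
title: "Methods: an integrative NPC organoid pharmacogenomics pipeline on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrative NPC organoid pharmacogenomics pipeline on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcpgx)
```

## What the package computes

Nasopharyngeal carcinoma (NPC) cohorts can be stratified into histological
subtypes — epithelial (EC), sarcomatoid (SC), mixed (MSEC) and squamous
(SCC) — that differ in drug response. A precision-oncology pipeline built
around patient-derived organoids (PDOs) ties together: (1) viability-based
drug screens summarized by IC50; (2) chemoradiotherapy (CRT) synergy calls
against a Bliss-independence additive prediction; (3) somatic variant
discovery by multi-caller consensus with a hard annotation filter cascade,
summarized as mutation burden and 96-context mutational catalogs refit
against reference signatures; (4) subtype-differential expression reduced
to pathway gene signatures; and (5) per-sample ssGSEA signature scores
evaluated as predictors of drug sensitivity by ROC/AUC against a
random-signature null.

`npcpgx` implements each of these computations as a tested function, plus
synthetic-data generators that reproduce the statistical structure each
stage assumes, so the whole pipeline runs and is validated without any
external sequencing data. Every generator records its ground truth
(`SimTruth`), which is what the parameter-recovery and calibration tests
consume. The `analysis/` scripts in the repository run the stages in order
on one synthetic study; `run_demo()` composes the same stages in-process.

## Dose–response and IC50 censoring

Viability is normalized well-by-well against the mean of control wells and
expressed in percent. The screen design is six concentrations spanning
0.08–20 µM at 3-fold dilutions with 3 replicates per dose; replicates are
averaged per dose before fitting, matching how such screens report mean
viability per concentration.

The curve family is the four-parameter log-logistic (Hill) model

$$v(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (d/\mathrm{IC}_{50})^{h}},$$

with `bottom ≥ 0` and `top ≤ 120` (readings modestly above control are
biologically plausible; unbounded tops are not). Fitting is
box-constrained Levenberg–Marquardt least squares on log-dose. Two
numerical choices matter:

* **Initialization.** The primary start linearizes the model: with
  provisional asymptotes placed just outside the data range,
  $\log\!\big((\mathrm{top}_0 - v)/(v - \mathrm{bottom}_0)\big)$ is linear
  in log-dose, and its regression slope/intercept give starting values for
  the Hill slope and IC50. Four fallback starts (IC50 at the geometric
  mean, minimum and maximum dose; Hill slope ±1) guard against poor
  linearization; the lowest-SSE solution wins.
* **Exact fits.** The raw `nls.lm` optimizer is used rather than a
  model-object wrapper because noiseless series fit with zero residual,
  where wrapper interfaces fail on the singular gradient; the tests
  require noiseless recovery to 10⁻⁶ relative error.

A fit is declared non-converged when the optimizer fails everywhere or the
fitted dynamic range (`top − bottom`) is under 5 percentage points — a
flat curve carries no dose information. Series where viability rises with
dose fit naturally with a negative Hill slope.

IC50s are then censored to the tested range: raw values above 20 µM are
reported as 20 (`clipped_high`), below 0.08 µM as 0.08 (`clipped_low`).
Non-converged fits take the maximally *resistant* proxy (20 µM,
`nonconverged`): a flat viability curve at screen doses is
indistinguishable from resistance beyond the tested range, and this
mirrors the same ">20 → 20" proxy logic. The censoring status travels
with the estimate so downstream consumers can tell a measured 20 from a
proxy 20.

## Bliss additivity and synergy calling

For a drug at dose $d$ with inhibition $E_2(d)$ combined with ionizing
radiation at the screen dose (4 Gy) with inhibition $E_1$, the additive
prediction is $E_\mathrm{total} = E_1 + E_2 - E_1 E_2$ — the Bliss
independence model. Inhibition is defined as $1 - v/100$, clipped to
[0, 1] before the formula.

A pair is called **synergistic** when the combination curve lies below the
additive curve: at least `min_points` doses more than `tol` viability
percentage points below it. No numeric criterion exists for "lower than"
in the source protocol, so the defaults — `tol = 2` percentage points and
`min_points = 3` of 6 doses — are this package's calibration, both
configurable and echoed in every output. Whether synergy should be
required at *all* doses or *any* dose was genuinely open; the `min_points`
parameter exposes the whole spectrum rather than hard-coding one reading.

`evaluate_crt_pair()` compares the **fitted** curves of the two arms
rather than raw per-dose replicate means. The screens this emulates
present fitted dose–response curves, and fitting pools information across
doses: with replicate noise of 3 percentage points, raw-mean comparison
miscalls ~6% of truly additive pairs as synergistic, while fitted-curve
comparison keeps false calls at ~3.5% with undiminished (100%) detection
of a 0.15 inhibition offset. When an arm's fit does not converge the
replicate-mean curve is used for that arm.

Combination strength is additionally scored by fold change =
IC50(drug alone) / IC50(drug + IR), both censored first; "over 3" is read
strictly, so a boundary fold change of exactly 3.0 is not flagged as a
good combination.

## Variant consensus and filtering

Variants are keyed by (chromosome, 1-based position, ref, alt). The
consensus rule keeps keys reported by at least two of the three callers;
annotations for a kept variant come from the caller reporting the highest
tumor depth, with ties broken by caller name order (a deterministic,
auditable provenance rule).

The filter cascade retains a variant only if population allele frequency
< 0.0004, tumor depth > 20, tumor alt reads > 3, normal-sample alternate
reads < 1, and VAF > 5% — all strict comparisons, applied as a
conjunction of independent predicates (hence idempotent and
order-independent). One clause required interpretation: "support reads
for the reference less than 1" would, read literally, discard essentially
every real call (reference-supporting reads are almost never zero in a
diploid tumor). It is implemented as *alternate-supporting reads in the
matched normal* < 1 — i.e. a clean normal — which is the standard intent
of such a filter; the literal reading remains available via
`filter_config(normal_clause = "ref_reads")`. Low-mappability masking is
applied only when a BED mask is supplied, using the genomic convention
that a 0-based half-open interval [start, end) covers 1-based positions
start+1 … end. Rejected variants are returned with their first failing
reason so filter behavior is auditable.

Burden summaries report the per-sample mean rounded half-up to one
decimal (2662 variants over 88 samples reports as 30.3), the convention
used in the descriptive figures this package reproduces; R's default
round-half-even would print 30.2.

SNVs are classified into the 96 pyrimidine-centered trinucleotide classes
(purine-centered substitutions reverse-complemented), and the catalog is
refit against reference signature columns by nonnegative least squares on
the normalized catalog, with exposures rescaled to sum ≤ 1 and the
reconstruction scored by cosine similarity. The optional `exome2genome`
normalization multiplies each context by a supplied genome/exome
trinucleotide frequency ratio before fitting. The package bundles a
*synthetic* 96×5 reference matrix (sparse random probability columns,
fixed seed) for tests and demonstrations; real reference catalogs load
through the same `read_signature_ref()` path.

## Differential expression and signature assembly

Counts are normalized by median-of-ratios size factors (computed over
genes nonzero in every sample, falling back to total-count scaling with a
warning) and log2-transformed with pseudocount 1. Genes with zero counts
across all samples are excluded by construction of the generators and by
the all-nonzero reference-gene rule.

The published analysis defined significant genes as the overlap of two
independent tools' survivor sets. Re-implementing those tools' internals
is out of scope; the two-method *overlap-and-threshold* logic is the
contribution reproduced here, backed by two self-contained tests sharing
one effect estimate (difference of group means on the normalized log2
scale):

* a **moderated location test**: gene-wise pooled variances shrunk toward
  the across-gene median with `d0 = 4` prior degrees of freedom, the
  statistic referred to a t distribution with `df + d0` degrees of
  freedom (small fixed shrinkage — enough to stabilize small-sample
  variances at n = 7 vs 7 without distorting the null, which the
  Kolmogorov–Smirnov calibration test checks);
* a **rank-sum test** (Wilcoxon, exact where sample sizes permit).

Genes pass with |log2FC| > 1, p < 0.05 and BH-adjusted p < 0.05 in
*both* methods, with sign agreement; direction (up in EC-like group A vs
up in SC-like group B) follows the shared fold-change sign. Pathway
signatures are the intersections of the survivor list with curated
pathway sets, and the combined signature is their union — in the emulated
study, 105 genes across five drug-mechanism pathways.

## ssGSEA scoring, labeling and ROC

The per-sample enrichment score ranks genes by expression (descending)
and accumulates the difference between the weighted in-set empirical CDF
and the uniform out-of-set ECDF over all rank positions; in-set steps are
weighted by rank^α with α = 0.25, the conventional weighting. Using
*ranks* as weights (not raw expression) makes scores exactly invariant
under any strictly increasing transform of the expression values, which
the property tests assert on random matrices. Raw (unnormalized) scores
feed the ROC analysis — AUC is rank-invariant to the optional min–max
rescaling, which exists only for plotting parity.

Samples are labeled from IC50 quantiles: the bottom `floor(q·n)` are
sensitive, the top `floor(q·n)` resistant, q = 0.10 by default (880
cell lines give 88 per class). Boundary ties are broken by stable input
order, making labels deterministic. AUC uses the midrank Mann–Whitney
statistic — exactly the tie-corrected probability that a random positive
outranks a random negative, verified against brute-force pair counting.
The positive class is *sensitive* and the orientation is recorded in the
result, so a 1 − AUC confusion cannot go unnoticed. Score–response
association uses the point-biserial correlation (Pearson with response
coded 1 = sensitive); the statistic behind the published correlation
heatmap is unnamed, so this documented stand-in was chosen for
interpretability, with zero-variance scores reported as missing rather
than zero.

The random-signature null draws `n_iter` gene sets of the signature's
size uniformly without replacement, scores and evaluates each identically
to the real signature, and summarizes the AUC distribution. On
label-independent expression it centers at 0.5 — the reference value the
acceptance analysis recomputes (2000 genes × 200 samples, 200 random
105-gene signatures).

## What the generators emulate — and what they do not

* **Cohort**: subtype counts are the largest-remainder rounding of
  n × fraction (sums exactly to n, matches requested fractions to within
  rounding), defaults 57/26/20/3 of 106; organoid establishment is
  Bernoulli at 40/43.
* **Plates**: 4PL expectation plus additive Gaussian noise on the percent
  scale, truncated at 0; default noise SD 5 percentage points and 3
  replicates per dose (the replicate count stated in figure legends; no
  noise model is stated anywhere, so truncated-Gaussian is the simplest
  model matching replicate scatter).
* **Combination arms**: expected inhibition is Bliss-additive plus a
  synergy offset, clipped to [0, 1]; offset 0 satisfies additivity at
  machine precision.
* **Call sets**: every true variant appears in ≥ 2 callers and every
  false positive is private to one caller, so consensus precision is
  exactly 1 by construction and recall is computable from truth; true
  variants draw deep/clean annotations, false positives shallow/noisy
  ones. Consequence classes follow the 2306:191:47:51:31:23:8:5 mix.
* **Expression**: negative-binomial counts with gene-wise dispersions
  log-uniform on [0.05, 0.4], signature blocks shifted by the group
  log2FC, library sizes spanning ≥ 2-fold by construction, and an IC50
  phenotype that is a noisy monotone function of true signature activity.

What passing tests on these data do **not** show: robustness to
alignment or sequencing artifacts, batch effects, tumor purity variation,
correlated gene-gene structure within pathways, plate position effects,
or real mutational-process catalogs. The generators produce independent
noise around clean parametric structure; conclusions about real-data
performance require real data.

## Reproducibility and problem sizes

A single global seed fans out to per-stage child seeds by a stable
polynomial hash of the stage name (`stage_seed()`), so any stage can be
rerun in isolation and all seeds stay below 2³¹. The test suite and
acceptance analysis use deliberately modest problem sizes — 200-plate
recovery batches, 200-pair synergy calibrations, a 2000 × 200 null
matrix with 200 random signatures, 50-cohort end-to-end recovery — chosen
as the smallest sizes at which the Monte-Carlo tolerances quoted in the
tests are stable.

## Known limitations

* The 4PL bottom/top constraints (0 ≤ bottom, top ≤ 120) are a modeling
  choice; assays with strong over-control growth would need a wider top.
* The moderated test's fixed `d0 = 4` is a simplification of empirical-
  Bayes variance shrinkage with estimated prior df; it is calibrated for
  the simulated dispersions, not optimized per-dataset.
* `refit_signatures` assumes the reference columns are probability
  vectors on the same 96-class ordering as `context_classes()`.
* Real published gene counts from the deposited organoid data
  (3853/2791/2506 DE genes) depend on the deposited reads and are not
  reproducible here; the pipeline reproduces the *procedure* and its
  calibration, not those numbers.
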