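# npcpgx

An R implementation of the bespoke computations behind an integrative
pharmacogenomics pipeline for nasopharyngeal carcinoma (NPC)
patient-derived organoids (PDOs), exercisable end to end on synthetic
cohorts. It is aimed at computational biologists who want the pipeline's
statistical machinery — not its wet-lab or read-level preprocessing — as
tested, reusable functions.

The pipeline stratifies an NPC cohort into histological subtypes (EC,
MSEC, SC, SCC) and ties together five analysis stages:

1. **Dose–response screens.** Percent viability is fit with a
   four-parameter log-logistic curve
   `v(d) = bottom + (top − bottom) / (1 + (d/IC50)^h)` over six doses
   (0.08–20 µM, 3-fold dilutions); IC50s outside the tested range are
   censored to its limits (>20 → 20 µM, <0.08 → 0.08 µM), and
   non-converging (flat, resistant) fits take the 20 µM proxy.
2. **Chemoradiotherapy (CRT) synergy.** The additive prediction for drug
   + 4 Gy ionizing radiation follows Bliss independence,
   `E_total = E1 + E2 − E1·E2`; a pair is synergistic when the observed
   combination curve lies below the additive curve, and a combination
   with IC50 fold change (mono/combo, both censored) strictly over 3 is
   flagged as a good candidate.
3. **Somatic variant consensus.** Per-caller call sets are merged with
   the ≥2-caller rule and filtered by a strict cascade (population AF
   < 0.0004, tumor depth > 20, alt reads > 3, normal alt reads < 1,
   VAF > 5%), then summarized as per-sample burden, consequence-class
   counts, per-gene frequencies, and a 96-trinucleotide-context catalog
   refit against reference mutational signatures by nonnegative least
   squares.
4. **Differential expression.** Median-of-ratios normalization, two
   independent tests (a moderated location test and a rank-sum test)
   with Benjamini–Hochberg correction; signature genes must pass
   |log2FC| > 1, p < 0.05 and padj < 0.05 in **both** methods, and are
   intersected with five drug-mechanism pathway sets into a combined
   response signature.
5. **Signature scoring and prediction.** Per-sample ssGSEA scores
   (rank-weighted ECDF difference, α = 0.25), sensitive/resistant labels
   from bottom/top-10% IC50 quantiles, midrank ROC/AUC evaluation, and a
   random-signature null whose AUC centers at 0.5.

Synthetic-data generators reproduce the statistical structure each stage
assumes (subtype mix 57/26/20/3 of 106, six-dose plates with truncated
Gaussian noise, caller-private false positives, negative-binomial
expression with signature blocks linked to an IC50 phenotype) and record
their ground truth, so every stage is tested by parameter recovery and
calibration rather than against fixtures.

## Worked example

Simulate one drug screen with a matched drug + 4 Gy IR arm, extract the
censored IC50 and call synergy:

```r
library(npcpgx)

mono  <- gen_dose_response(list(ic50 = 2, hill = 1.2), n_reps = 3, noise_sd = 5,
                           seed = 11, sample = "PDO01", drug = "docetaxel")
combo <- gen_combo_screen(list(ic50 = 2, hill = 1.2), ir_inhibition = 0.25,
                          synergy_offset = 0.2, n_reps = 3, noise_sd = 5,
                          seed = 12, sample = "PDO01", drug = "docetaxel")

fit <- fit_4pl(mono)
fit
#> 4PL fit: top 94.0, bottom 5.7, IC50 1.874 uM, hill 1.76 (converged)

est <- ic50_with_proxy(fit)
sprintf("censored IC50: %.2f uM (%s)", est$value, est$censoring)
#> "censored IC50: 1.87 uM (none)"

ev <- evaluate_crt_pair(mono, combo, ir_inhibition = 0.25)
ev$verdict
#> "synergistic"
ev$fold$fold_change
#> 1.60  (good combination: FALSE — the fold-change cutoff is a strict 3)
```

The fitted IC50 (1.87 µM) recovers the simulated truth (2 µM) within the
replicate noise; the combination curve sits below the Bliss additive
prediction at all six doses, so the pair is called synergistic even
though its IC50 fold change alone would not flag it.

The `analysis/` directory runs the whole study in order on one synthetic
cohort — `01_simulate.R` through `06_signature_scoring.R` — writing
tables under `results/` and printing what each stage found (cohort
percentages 53.77 / 24.53 / 18.87 / 2.83; consensus precision on
caller-private false positives; 100% recovery of the true signature
genes at log2FC 3; signature AUC 1.0 versus a random-signature null mean
of 0.48 on the validation cohort).

## Layout

```
R/                  package functions (generators, dose-response, synergy,
                    variant consensus, differential expression, scoring, IO)
analysis/           numbered driver scripts for the synthetic study
scripts/acceptance.R   reference-quantity recomputation (JSON output)
tests/testthat/     unit, property and acceptance tests
inst/extdata/       synthetic 96x5 reference signature matrix (TSV)
vignettes/          methods vignette
```
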