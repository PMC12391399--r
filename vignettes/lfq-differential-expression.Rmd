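---
title: "Differential expression of label-free proteomes with MNAR imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential expression of label-free proteomes with MNAR imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqpipe)
```

## The problem

Label-free quantification (LFQ) estimates relative protein abundance from MS
signal intensity. Two features dominate the statistics of the resulting
protein-groups table. First, intensities span orders of magnitude and differ
systematically between runs, so per-sample normalization is required before
any cross-sample comparison. Second, missing values are not missing at
random: a protein near the detection limit drops out preferentially, so a
zero in the table usually means "too low to see", not "absent at random".
`lfqpipe` implements a complete treated-vs-control workflow for such tables,
organised around a multi-isolate herbicide-exposure design in
*Chlamydomonas reinhardtii* (3 isolates x 2 conditions x 3 biological
replicates), and a synthetic generator that reproduces exactly these two
features so every stage can be validated against known truth.

## The model and procedure

### Normalization

Raw intensities are log-transformed (base 2 by default — all downstream
fold-change thresholds are stated in log2 units, and the volcano axis
cut-off 4.32 equals $-\log_2 0.05$). Then, per sample:

1. **Centering**: subtract the mean of the sample's measured log values
   ("scale each value relative to the sample average"). The mean is the
   default statistic; a median option exists for heavy-tailed runs.
2. **Width scaling**: divide by the SD of the sample's measured values,
   equalizing acquisition dynamic range across runs. SD is the default
   width; an IQR-based option (IQR/1.349) is provided. After this step every
   sample's measured values have mean 0 and SD 1.

Both statistics are computed over *measured* values only; missing cells are
untouched until imputation. The two normalizations are per-sample by
construction, which is also the scope we give the imputation reference
distribution below.

### Validity filtering

A two-sample test needs a variance in at least one group, so the default
filter keeps a protein only if it has at least 2 measured values in at least
one group of *each* treated-vs-control pair in the design. This is the
weakest rule under which the F-gate and t-test are defined for every
contrast; it also removes proteins that are entirely below the detection
limit in some isolate, which would otherwise be "tested" purely on imputed
values against imputed values.

### Probabilistic minimum imputation

Each missing cell in sample $s$ is replaced by an independent draw from

$$\mathcal{N}\!\left(\mu_s - d\,\sigma_s,\ (w\,\sigma_s)^2\right),
\qquad d = 2,\ w = 0.3,$$

with $\mu_s, \sigma_s$ the mean and SD of the sample's measured values: the
missing value is resampled from the low-abundance tail, $d$ SD below the
bulk, with resampling variability $w$. Defaults $d = 2$, $w = 0.3$ are the
study settings. Because imputation follows centering and scaling, the
imputed cells are *not* re-centered — re-centering would silently shift the
down-shifted draws back toward the bulk and break the stated semantics.
Under the default chain $\sigma_s = 1$ after scaling, so the question of
whether the down-shift SD is computed before or after width scaling is moot;
we compute it on the matrix as given to the imputation step. A seed is
mandatory whenever missing cells exist; draws go through a private RNG
stream, so user-level `set.seed()` state is neither consumed nor clobbered,
and the full transform chain (with parameters and seed) is recorded in an
append-only provenance that `replay_provenance()` can re-execute to
reproduce the normalized matrix exactly.

### Variance-gated testing and volcano classification

Per protein, an F-test (larger sample variance over smaller, two-sided p,
gate level $\alpha_F = 0.05$) decides whether the two groups are
homoscedastic — pooled-variance t-test, $df = n_1 + n_2 - 2$ — or
heteroscedastic — Welch t-test with Welch–Satterthwaite df. A protein with
zero variance in exactly one group is routed to the Welch branch (a pooled
df would overstate the information); zero variance in both groups is
degenerate and the protein is excluded with a logged reason. The log2 fold
change is the difference of group means, treated minus control — the only
reading of "ratio of normalized abundances" consistent with a log2
fold-change axis — so "up-regulated" means higher under treatment.

Classification: up if $\mathrm{log2FC} > \theta$ and $p < 0.05$, down if
$\mathrm{log2FC} < -\theta$ and $p < 0.05$, default $\theta = 1$. The
boundary is strict by default (a protein exactly at $\pm\theta$ is not
significant); an inclusive `strict = FALSE` variant exists because the two
conventions both circulate. No multiple-testing correction is applied to the
classification — the criteria are stated on raw p-values — but a
Benjamini–Hochberg column can be annotated (`adjust_p = TRUE`) without ever
altering the class. The significance axis is $-\log_2 p$ by default: the
conventional label for this axis is $-\log_{10}$, but the printed cut-off
4.32 for p = 0.05 is a base-2 quantity ($-\log_{10} 0.05 \approx 1.30$), and
we follow the numeric equivalence while exposing `p_axis_base`.

### Sets, GO, ordination

Per-isolate up/down accession sets are partitioned into all $2^k - 1$ Venn
regions by exact membership (accession string equality; no isoform
collapsing). GO summarization is *descriptive categorization*: direct
annotations from a user-supplied map are counted per term, with unannotated
proteins reported separately; no DAG propagation, no live database, and
enrichment (`enrich_go()`, hypergeometric) is an off-path extension. PCA is
computed by SVD on feature-centered data (samples as observations). No
per-feature variance scaling is applied — sample-level normalization has
already equalized dynamic range, and feature autoscaling would inflate the
influence of quiet proteins. Components carry a deterministic sign
(largest-magnitude loading positive) so results are platform-reproducible.
A supervised projection (PLS-DA) is deliberately out of scope; the
treatment-separation claim is checked on the unsupervised scores with a
silhouette statistic.

### Physiology

Evans blue mortality is the sample A600 as a percentage of a matched
heat-killed control (≈100% mortality); raw values above 100% are QC-flagged
and viability is clipped to [0, 100]. Pigments use the standard 80%-acetone
equations (`pigment_coefficients()` exposes the set, since published
coefficient tables vary):
chl a $= 12.21 A_{663}' - 2.81 A_{646}'$,
chl b $= 20.13 A_{646}' - 5.03 A_{663}'$,
carotenoids $= (1000 A_{470}' - 3.27\,\mathrm{chl}_a - 104\,\mathrm{chl}_b)/198$,
where each $A'$ is the reading minus the 720 nm baseline — subtraction is
the conventional turbidity correction and makes the results exactly
invariant to a uniform absorbance offset. Negative corrected absorbances are
QC-flagged rather than rejected. Fv/Fm is consumed as instrument-reported
values; no fluorescence-trace computation is attempted.

## The synthetic generator

`generate_lfq()` draws per-protein baselines $\log_2 A \sim N(20, 2)$ (a
fixture convention mimicking LFQ dynamic range), adds planted treatment
effects of $\pm 2$ log2 units to a minority of proteins — each DE protein
assigned to a random or user-specified non-empty subset of isolates, so
shared/exclusive Venn structure is planted explicitly — plus within-group
noise (SD 0.3 by default, optionally unequal between conditions to exercise
the F-gate). Intensity is $2^{\text{abundance}}$ and each cell drops out
with probability $\mathrm{logistic}(-(x - m))$: missingness is logistic in
true abundance (MNAR), matching the assumption behind the down-shifted
imputation model. The everyday default midpoint $m = 16$ (2 SD below the
baseline mean) yields ≈7% missingness concentrated in the low tail.

What the generator does **not** emulate: peptide-to-protein roll-up,
correlated (batch/retention-time) structure, intensity-dependent
measurement noise, contaminants. Tests passing on this fixture therefore
validate the statistical chain under its stated assumptions — they do not
certify performance on any particular instrument's data.

## Numerical and design choices

* **Recovery test settings (calibrated once, then frozen).** Width scaling
  standardizes every sample to unit SD, so with a baseline spread of 2 log2
  units a planted effect of 2.0 appears as ≈1.0 *normalized* units. The
  end-to-end recovery checks therefore classify at `fc_threshold = 0.5` —
  half the expected normalized effect — with p < 0.05. They use dropout
  midpoint 14 (≈1.5% overall missingness, ≈12% on planted "down" cells):
  at the everyday default midpoint 16, a −2 effect pushes treated abundances
  onto the detection boundary and recovery is limited by censoring
  (sensitivity ≈0.83–0.93 across seeds) rather than by the statistical
  method, which is the thing the check is meant to measure. Under the frozen
  settings sensitivity is ≥0.92 across seeds with ≤1.3% false calls.
* **Problem sizes.** Simulation-based checks use 1,000–2,000 proteins with
  3 replicates per group, 10,000 draws for the imputation moments, and
  1,000 random instances for the set-logic enumeration — sizes at which the
  Monte-Carlo error of each assertion is far below its tolerance.
* **Degenerate inputs.** Samples with fewer than 2 measured values error at
  centering; zero sample SD errors at scaling; an empty post-filter matrix
  is allowed with a warning; p = 0 is impossible by construction (p-values
  are floored at the smallest positive double before the axis transform).
* **Determinism.** Every stochastic stage takes an explicit seed; the
  pipeline derives per-stage sub-seeds from the single run seed so adding a
  stage never perturbs another stage's draws.
* **Contaminant filtering.** Whether contaminant/decoy rows were removed
  upstream is unknowable from the table itself; the reader applies no
  default filter but exposes a `drop` hook.

## Limitations

Raw p-values with 3 replicates have limited power and no FDR control — that
is the method being implemented, not a recommendation; the BH column is
there for users who want it. The imputation model is a single down-shifted
Gaussian per sample; left-censored regression or kNN alternatives are out of
scope. GO counting without hierarchy propagation undercounts general terms
relative to DAG-aware tools. PCA assumes the imputed matrix; with heavy
missingness the ordination partially reflects the imputation model.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_lfq(n_proteins = 2000, seed = 7)
nm <- normalize_lfq(sim$matrix, seed = 8)
de <- run_de_table(nm, "CC-1009")
summary(de)
plot(de)                        # volcano
sets <- extract_sets(sapply(unique(sim$design$isolate), function(i)
  run_de_table(nm, i), simplify = FALSE))
sets$regions$up
plot(pca_lfq(nm))
```
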