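---
title: "ProxiStress: models, parameters and design choices"
author: "ProxiStress authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ProxiStress: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProxiStress)
```

## Overview

ProxiStress implements the downstream analysis of a ratiometric
proximity-labeling study: a biotin ligase fused to a chaperone bait labels
the bait's neighbourhood in body-wall muscle, and label-free quantification
(LFQ) intensities are compared across five sample roles — bait-ligase
proximity (i), free-ligase cytosol (ii), no-ligase negative control (iii),
and stress-condition proximity with (iv) or without (v) the optogenetic
cofactor. This vignette is the package's own account of the statistical
models, the tunable parameters, what the synthetic-data generator does and
does not emulate, and the choices made where the design was genuinely open.

## Preprocessing model

All statistics operate on the log2 scale, so a "2-fold" change is a log2
difference of 1.

* **Missingness encoding.** MaxQuant writes an LFQ intensity of 0 when it
  cannot quantify a protein in a run; `readProteinGroups()` therefore maps
  0, empty cells and `NaN` to missing. Rows flagged `Reverse`,
  `Potential contaminant` or `Only identified by site` are removed by
  default.
* **Normalization.** `medianNormalize()` centers each sample's observed
  values at median 0. The median is robust to the planted differential
  fraction (a few percent of proteins) and makes the operation idempotent.
* **Valid-value filter.** `filterValidValues()` keeps proteins with at
  least `minValid` observed values per group, in at least one group or in
  every group. The default `minValid = 3` guarantees a defined Student
  t-statistic with positive degrees of freedom even when one of four
  replicates is missing.
* **Imputation.** `imputeDownshift()` draws each missing cell from
  `Normal(m − downshift·s, (width·s)²)` with `m`, `s` the observed mean
  and SD of the imputation unit (each sample by default). The defaults
  `downshift = 1.8`, `width = 0.3` are the canonical left-censored
  imputation settings for LFQ data: missing values are predominantly
  low-abundance, so they are imputed into the lower tail. Imputed cells
  are flagged in a separate assay and never confused with observed ones;
  observed cells are never altered.

## The statistical kernel

The kernel is implemented in the package (not delegated) so that every
pipeline stage is a known, oracle-tested quantity; the test suite
cross-checks it against independent implementations (`t.test`,
`p.adjust`, `phyper`, `prcomp`, `fgsea`) on the same inputs.

* **Two-sample t.** Student's pooled-variance form is the default,
  matching the two-tailed Student's t-test used throughout the analysis;
  Welch is available by flag. Zero-variance inputs raise an error at the
  scalar level; the row-wise pipelines map that error to a missing p-value
  with a logged reason. No S0 variance moderation is applied — a
  deliberate divergence from Perseus's optional moderated test, chosen so
  the statistic is exactly the textbook quantity.
* **FDR.** Benjamini–Hochberg step-up with monotonicity enforcement,
  applied per comparison. Permutation-based FDR (the Perseus alternative)
  was rejected because BH is deterministic, testable against `p.adjust`,
  and the standard reading of "FDR-adjusted p-value".
* **Hypergeometric tail.** `P(X ≥ k)` summed in log space (`lchoose` with
  a max-shift), stable for universes of thousands of proteins; verified
  against exhaustive enumeration for every parameter combination with
  N ≤ 12.
* **Preranked GSEA.** Weighted running-sum enrichment score: member hits
  step up by `|metric|^p / Σ|metric|^p`, misses step down by `1/(N−N_H)`;
  the ES is the extreme deviation. The null is gene permutation (random
  same-size member sets), the only null available in preranked mode; one
  null pool is shared per set size. NES divides the ES by the mean
  magnitude of same-sign null scores; the permutation p uses the
  `(1 + r)/(1 + n)` estimator within the same-sign pool, and the FDR q is
  the classic ratio of null-to-observed NES tail fractions, clipped to
  [0, 1]. Ties in the metric keep stable input order; an exact tie between
  the positive and negative extreme deviation (within 1e−12) resolves to
  the positive one.
* **PCA.** Sample scores from the SVD of the protein-centered matrix;
  requires complete data, so it runs after imputation. Explained-variance
  fractions are `d_i²/Σd²`.

## Ratiometric enrichment (non-stress analysis)

Both comparisons — (i) vs (iii) and (i) vs (ii) — are computed for every
protein with enough valid values; BH is applied **separately per
comparison** over the tested proteins, mirroring the per-comparison hit
counts of the original design. Flags require `q ≤ α` *and* a positive
log2 fold change: "enriched in bait proximity" is directional, while the
p-value stays two-sided. A protein failing the valid-value criterion in
any required group is excluded from both comparisons (not tested
one-sidedly) so the tested denominator is single-valued, and it carries an
`exclusionReason`.

## Stress-shift analysis

* **Detection and overlap.** Detection means surviving the experiment's
  own valid-value filter. The overlap percentage is
  `100·n_shared/n_stress` — the stress-experiment denominator is the only
  definition consistent with the published 1512/1862 → 81.2% arithmetic,
  which `combineExperiments()` reproduces exactly.
* **Gate.** The muscle-expression gate uses group-mean differences only
  (no significance test), per the "at least 2-fold positively enriched"
  wording: `mean(i) − mean(iii) ≥ 1` or `mean(ii) − mean(iii) ≥ 1` in
  log2 units. The main-text wording says "or"; the corresponding figure
  legend says "both". The default is `mode = "either"`, with `"both"`
  available as a flag — the discrepancy is real and surfaced rather than
  resolved silently. The gate is computed on the non-stress arm of the
  combined matrix, since the gate precedes the volcano in the published
  workflow.
* **Volcano.** For gated proteins only: `log2Ratio = mean(iv) − mean(v)`,
  Student's t, BH **within the gated set**. Significant proteins partition
  exhaustively into `toward` (ratio > 0) and `away` (ratio < 0).

## Transcript/protein integration

Pairs are an inner join on feature identifier (optionally through an
explicit id map; many-to-many maps are rejected with a listing). Quadrants
come from the signs of the two log2 fold changes; a fold change of exactly
zero leaves the feature unassigned and out of the proportions, keeping the
sign rule well-defined — the source design never addresses ties.
Inclusion uses one assay's p-value only (transcript- or protein-side
filter), regardless of the other assay's significance; proportions are
percentages of included, assigned features and sum to 100. Per-quadrant
ORA uses all paired features as the default universe
(detection-conditioned and symmetric across quadrants); the reported rows
are filtered at q ≤ 0.01 for transcript-side runs and q ≤ 0.05 for
protein-side runs. Transcript differential statistics are accepted as a
precomputed table (`id`, `log2fc`, `pvalue`) so that real count-model
output (e.g. DESeq2) can be dropped in; the synthetic path generates them
with the package's own t-test as a documented stand-in — shrinkage
estimators and count-level modelling are out of scope.

## Co-IP GSEA workflow

`runCoipGsea()` ranks an interactor table by signed log2 fold change (the
default; `sign(fc)·−log10 p` by flag) and reports sets passing the NES
cutoff (default 0.5), ranked by NES. The cutoff is applied to positive
NES by default ("higher is better"), with a symmetric `direction = "both"`
option since depletion is equally interpretable.

## The synthetic-data generator

The generator's defaults are the study conditions: 1709 protein groups,
four replicates per condition, log2 baselines `Normal(26, 2)`, replicate
noise SD 0.5 — typical LFQ scales — a 3 log2 proximity effect, 2 log2
muscle and stress effects, a +1 log2 batch offset for the stress
experiment, and logistic missingness
`P(missing) = plogis(slope·(midpoint − intensity))` with slope 1 and
midpoint two baseline SDs below the mean (≈ 5–7% missing, concentrated at
low abundance). Class fractions default to 2% bait-proximal, 5% muscle
cytosol, 10% endogenous background and 0.5% stress shifts each way.
Classes are a deterministic function of the configuration and baselines
are drawn from the seed alone, so the proximity and stress experiments of
one configuration share identifiers, baselines and ground truth; noise
and dropout are drawn from documented per-experiment offsets of the seed,
making each generator call bit-reproducible. Stress-shift proteins carry
the proximity effect in the non-stress experiment — they are bait-proximal
proteins whose proximity changes — so the 2-fold gate can see them, which
is the only self-consistent reading of planting stress shifts inside the
gated set.

What the generator does **not** emulate: peptide-level rollup,
match-between-runs artifacts, correlated protein covariance (co-regulated
complexes), heavy-tailed or protein-specific variance, and
intensity-dependent fold-change compression. Passing tests therefore show
that the statistical machinery recovers planted structure under an
idealized Gaussian LFQ model — not that any particular real dataset's hit
list is reproduced.

## Numerical choices and degenerate inputs

* `dropoutSlope = 0` disables missingness entirely (the degenerate limit
  used by tests that need complete data).
* BH with fewer than two tested proteins degrades to pass-through with a
  warning; `NA` p-values propagate without affecting the others.
* Zero-variance t-tests: error at the scalar level, reasoned `NA` in
  row-wise pipelines.
* PCA refuses missing values rather than silently imputing.
* Round-trips: proteinGroups files are written with 10 significant digits
  (raw scale), preserving log2 values to well below 1e−6; GMT and RNK
  writers emit byte-stable output for identical inputs.

## Problem sizes used by the test suite

Unit tests run at 50–500 proteins; calibration and recovery checks use
the full 1709-protein scale with 20 seeds (null calibration), 5 seeds
(spike-in recovery), and 10 seeds at 2000 features (quadrant recovery) —
sizes chosen so the whole suite completes in a few minutes on one CPU
while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* With four replicates and replicate SD 0.5, the Student t-statistic has
  only six degrees of freedom; after BH correction at study scale, the
  per-protein power for a 3 log2 effect is in the 0.8–0.9 range, not
  higher — variance-moderated tests (limma/S0) would exceed it, but are
  intentionally out of scope. Recovery expectations should be set by the
  noncentral-t calculation, not the normal approximation.
* The `either`/`both` gate ambiguity is unresolved upstream; results at
  the gate boundary depend on the flag.
* ORA treats gene sets as flat; no ontology-graph deduplication
  (REVIGO-style reduction) is applied — the full filtered table is
  reported, sorted by q.
* Whether the published stress-arm t-test used imputed or observed-only
  values is not stated; this package tests imputed matrices, and the
  observed-only alternative can be had by skipping `imputeDownshift()`
  (rows then need valid values in both stress roles).
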