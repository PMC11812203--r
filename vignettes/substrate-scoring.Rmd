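---
title: "Predicting SLC substrates from multi-omics panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SLC substrates from multi-omics panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcscore)
```

## The problem

Roughly a quarter of human solute carrier (SLC) transporters have no
experimentally determined substrate, and substrates cannot be inferred from
sequence or structure alone: closely related family members transport
chemically unrelated molecules. `slcscore` implements an expression-based
alternative. If a transporter moves a metabolite across a membrane, cell
lines expressing more of the transporter should show systematically shifted
intracellular concentrations of the substrate — in either direction,
depending on whether the carrier mostly imports or exports it. Across
hundreds of cell lines profiled for both transcriptome and metabolome, that
shift appears as a rank correlation between transporter expression and
metabolite level.

The package turns this observation into a scoring pipeline with three
evidence sources:

1. **Cell-panel correlations.** Spearman correlations between normalized SLC
   expression and metabolite levels, computed per panel.
2. **CRISPR gene dependency.** If knockout of an SLC slows growth in a
   subset of cell lines, metabolites that differ between the most- and
   least-dependent lines are candidate substrates.
3. **Metabolite adjacency.** Substrates dissipate into downstream
   derivatives; correlation of the SLC to metabolites *near* the candidate
   in the reaction network reinforces the prediction.

## The model

### Transformed correlation

Metabolites differ widely in how strongly they correlate with *any* gene,
so raw correlation coefficients are not comparable between metabolites. For
SLC $a$ and metabolite $z$ the package standardizes the absolute
correlation within each (metabolite, dataset):

$$\tilde\rho_{(a,z)} = \frac{|\rho_{(a,z)}| - \overline{|\rho_{(z)}|}}
{\sigma_{|\rho_{(z)}|}},$$

with mean and sample standard deviation taken over all SLCs correlated with
$z$ in that dataset. A transformed value of 0 means "as correlated as the
average gene is with this metabolite"; 1 means one standard deviation above
that. The sign of $\rho$ is retained in the output table but only $|\rho|$
enters the transform: import and export produce opposite signs yet equally
strong evidence.

### Decile sub-scores and thresholds of discovery

Each evidence value $V_i$ is converted to an integer sub-score in $0..11$
by comparing it to the distribution of values observed for *known*
SLC–substrate pairs. Eleven quantiles $Q_k = \{q_{k0},\dots,q_{k10}\}$
(0th to 100th percentile in 10% steps) are computed from the known-pair
values, $q_{k0}$ is overridden by a per-dataset *threshold of discovery*
(ToD), and the sub-score is the index of the interval containing $V_i$:
0 below the ToD, 1–10 inside the decile intervals, and 11 at or above the
known maximum (values outside the known set are capped there).

The confidence score of a pair combines the sources as

$$\mathrm{Confidence}_i = a\,( \mathrm{CCLE2019}_i + \mathrm{NCI60}_i +
\mathrm{CCL180}_i) + b\,\mathrm{GeneDep}_i + c\,\mathrm{Adjacency}_i.$$

The gene-dependency value is $-\log_{10}$ of the BH-adjusted Wilcoxon p
from the dependency contrast, scored against the known pairs'
$-\log_{10}(p_{adj})$ distribution with $-\log_{10}$ of the CRISPR p-cutoff
as its threshold, and only when $p_{adj}$ is below that cutoff. The
adjacency term sums, over datasets and over all metabolites within the
adjacency radius of the candidate that are measured in that dataset, a
piecewise sub-score of the SLC–neighbor correlation: 0 up to a lower
threshold ToD′, 0.5 in the band between ToD′ and ToD, and the decile index
above ToD. The candidate itself (distance 0) never contributes to its own
adjacency term.

`default_score_params()` carries the tuned values for the three public
panels: ToD 0.0 (NCI60), 0.0 (CCLE2019), 1.0 (CCL180); ToD′ 0.1, 0.1, 0.2;
CRISPR cutoff 0.16; weights $a = 3$, $b = 1$, $c = 1$; radius 2 conversion
steps. All are dimensionless: ToD/ToD′ live on the transformed-rho (z)
scale, the cutoff is an adjusted p-value, the radius counts reaction edges.

Two consequences of the definitions deserve emphasis:

* **ToD′ may exceed ToD.** The two thresholds are tuned independently, and
  for NCI60/CCLE2019 the tuned ToD′ (0.1) is above ToD (0.0). The zero
  branch takes precedence, so the half-point band is simply empty there.
* **The quantile array is clamped at the ToD.** Setting $q_{k0}$ to the ToD
  can place interior deciles below it (CCL180's ToD of 1.0 is above several
  known-pair deciles). Those deciles are raised to the ToD, which keeps the
  array non-decreasing without changing any reachable interval: values
  below the ToD score 0 before the array is consulted. A ToD above the
  known maximum leaves no valid interval and is rejected.

### Threshold optimization and benchmarking

Thresholds are chosen to maximize the *mean fractional difference*: for
each candidate ToD, score the known pairs and each of the simulated random
tables, record at every integer score cutoff 1–100 the fraction of pairs
strictly exceeding it, and average (known fraction − mean random fraction)
over the cutoffs (`optimize_tod()`). Simulated random tables keep the SLC
column fixed and shuffle the metabolite column, redrawing any row that
would recreate a known pair, so the null preserves the per-SLC pair counts
while destroying the pairing. "Better than cutoff" is read as strictly
greater throughout.

Benchmarks use bootstrap means, per-SLC rank percentiles among
non-zero-score metabolites, hypergeometric pathway over-representation, and
ROC / precision–recall areas computed by the trapezoidal rule with tied
scores entering simultaneously (which makes the ROC area exactly the
normalized Mann–Whitney U; the test suite verifies this identity by
enumeration). Train/test cycles partition the known pairs 70/30
(`floor(0.7 n)` training pairs), re-optimize thresholds on the training
pairs only, and report test-set recovery, top-fraction membership and AUCs
against size-matched random sets.

### Drug associations

The parallel drug arm asks whether SLC expression shifts a cytotoxic
drug's dose–response curve. Cell lines treated with a drug are split into
high- and low-expression fifths (`floor(0.2 n)` each, ranked on normalized
expression, ties broken by cell-line id), a locally weighted quadratic
smoother (span 0.75) is fitted to each group's (log10 dose, log-fold
viability) points, and the two curves are evaluated on the fixed grid from
−3.21 to 1.00 in 0.01 steps — 422 points with both endpoints included; the
constant is asserted in the tests. The curves are compared with a paired
t-test (p and mean difference) and the dose dependence of their difference
is measured with a Spearman correlation against dose.

Because the paired t-test across an oversampled smooth grid is extremely
sensitive, significance is calibrated per drug: 100 random draws of two
disjoint groups of the same size yield null distributions of
$-\log_{10}(p)$ and of the absolute mean difference, and a pair is
*predicted* only when both its statistics exceed the null mean by at least
two null standard deviations. The shortlist orders predicted pairs by the
sum of the descending ranks of absolute mean difference and absolute
dose-effect correlation.

A practical caveat the synthetic experiments make visible: pairs that
merely share a drug with a genuinely affected SLC can inherit part of the
effect, because their expression extremes overlap the affected lines by
chance. The drug-specific null absorbs the average of this heterogeneity
but not its tail, so false-positive calibration is assessed on drugs with
no planted effect.

## What the synthetic generator emulates

`synth_panel()` produces every input the pipeline consumes, with the
statistical structure the method assumes:

* negative-binomial counts (dispersion 0.15) around log-normal gene means
  with per-sample library factors drawn from 0.5–2, so median-ratio
  normalization is non-trivial;
* for each planted (SLC, substrate) pair, a latent metabolite level that is
  a monotone function of the SLC's expression driver plus Gaussian noise.
  The latent correlation is calibrated by bisection (via `uniroot` on the
  bivariate-normal rank link $\rho_s = \frac{6}{\pi}\arcsin(r/2)$) against
  an attenuation budget covering count noise, measurement reliability
  (0.95) and tissue offsets, so the *realized* Spearman correlation hits
  the target (default 0.6). A target beyond what the noise budget admits is
  rejected with a diagnostic. Planted signs are random: import-like and
  export-like pairs both occur;
* derivatives chained to each substrate along the reaction graph, with
  latent correlation decaying by 0.7 per conversion step; background
  metabolites independent of everything;
* three panel copies drawn from the shared latent levels with independent
  measurement noise and partially overlapping 85% cell-line subsets,
  emulating inter-panel discordance;
* tissue structure as per-(tissue, metabolite) offsets, standardized per
  metabolite to an exact spread of 0.3 so the attenuation entering the
  calibration is identical for every pair;
* gene-effect scores that are negative for essentially all lines of planted
  SLCs, with magnitude tracking the expression driver, so the top-dependent
  fifth is enriched for substrate-rich lines;
* a drug screen (`synth_drug_panel()`) with four-parameter-logistic
  log-fold viability at the eight assay doses. A planted shift displaces
  the curve vertically by ±δ/2 for the top/bottom expression fifths, so
  the high-vs-low mean curve difference recovers δ directly; the shift is
  planted on *normalized* expression ranks, matching what the prediction
  stage stratifies on.

The defaults — 200 cell lines, 4 tissues, 30 SLCs with 20 planted pairs,
two derivatives per substrate, 50 background metabolites, target |ρ| 0.6 —
are the study conditions used by the test suite and are deliberately small
enough that the full pipeline runs in well under a minute.

What the generator does *not* emulate: cancer-type-specific metabolic
rewiring, correlated SLC co-expression, metabolite covariance beyond the
planted derivative chains, missing-value structure of real LC–MS panels,
and dose–response heterogeneity beyond the planted vertical shift. Passing
tests therefore demonstrate that the implementation recovers planted
structure under the stated assumptions, not that the method's real-data
performance is reproduced; the published real-panel metrics require the
original datasets, which are inputs, not package contents.

## Numerical choices

* **Quantiles** use linear interpolation between order statistics (R's
  default type 7); interval indices depend on this choice, so it is fixed.
* **Standard deviations** are sample SDs (n−1) everywhere the transform or
  z-scoring divides by a spread.
* **Spearman p-values** come from the large-sample t approximation
  (`cor.test(..., exact = FALSE)`); exact permutation is impractical at
  panel scale. Ties get average ranks.
* **Wilcoxon contrasts** use the exact distribution for small tie-free
  groups and the normal approximation with tie correction otherwise (the
  `wilcox.test` defaults); the suite checks small cases against full
  enumeration. Constant metabolites score p = 1 rather than erroring.
* **BH families**: correlation p-values are adjusted within each
  (SLC, dataset) across metabolites; dependency p-values within each SLC.
* **Group sizes** are `floor(frac * n)` with ties broken by id, making
  every split deterministic.
* **Median-ratio normalization** delegates factor estimation to the
  DESeq2 implementation (log-space geometric means; genes containing a
  zero are excluded from the median but kept in the output); genes with
  total counts below 10 are dropped first. The per-gene-total reading of
  the filter is a deliberate choice where the filter's unit was ambiguous.
* **Missing values** are never imputed: correlations use pairwise-complete
  observations and pairs with fewer than 10 complete shared lines are
  dropped, not zero-filled.
* **The reaction graph is undirected**: one conversion edge is one unit of
  adjacency in both directions, since substrate–derivative similarity is
  symmetric. Currency-metabolite hubs can be pruned by a degree cap or an
  explicit exclusion list; no automatic rule is inferred.
* **The dose grid** includes both endpoints (422 points). Counting the
  steps instead of the points gives 421; the inclusive grid is used and the
  constant is tested.
* **Randomness** flows from a single root seed; the CLI derives a fixed
  per-stage substream so stages are individually reproducible.

## Limitations

Correlation is not transport: co-expression with other SLCs,
post-translational regulation, compartmentalization and redundancy can all
decouple expression from substrate levels, and the cancer cell-line context
may produce cancer-specific associations. Predictions are hypotheses for
in-vitro validation, best read at the level of a metabolite neighborhood
rather than a single compound — which is exactly why the adjacency term
exists. The drug arm can flag associations that reflect the cellular
context of expression rather than transport of the drug itself.
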