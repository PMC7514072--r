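---
title: "Methods: RNL-dependency classification of ETI transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNL-dependency classification of ETI transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnleti)
options(rnleti.quiet = TRUE)
```

## The experimental design and the statistical model

The package analyses a four-way factorial RNA-seq design: genotypes
(`col0`, `adr1_triple`, `nrg1_double`, `helperless`) × treatments (empty
vector `EV`, effectors `AvrRps4`, `AvrRpt2`, `AvrRpm1`) × times (0, 0.5, 4,
8 hours post infiltration) × replication (by default 2 samples within each
of 3 independent experiments, i.e. 6 replicates per condition). Time-0
samples are collected before treatment, which is why the metadata validator
enforces `treatment == "none"` exactly at `time_hpi == 0`.

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $\mu_{gj}$ and dispersion $\alpha_g$, variance $\mu + \alpha\mu^2$.
Two biological layers sit on top of a per-gene baseline:

* **PTI** (pattern-triggered immunity): bacterial infiltration of any kind
  induces (or represses) a shared gene programme in *all four genotypes*
  from the gene's onset time.
* **ETI** (effector-triggered immunity): an additional log2 effect in the
  samples carrying one of the gene's triggering effectors, expressed only in
  the genotypes implied by the gene's RNL-dependency category.

The category → genotype map (`category_genotypes()`) is the single shared
definition used by both the simulator and the classifier:

| category | effect present in |
|---|---|
| RNL independent | all four genotypes |
| synergistic | Col-0 only |
| redundant | Col-0, *adr1 triple*, *nrg1.1 nrg1.2* |
| ADR1s specific | Col-0, *nrg1.1 nrg1.2* |
| NRG1s specific | Col-0, *adr1 triple* |

## The pipeline, stage by stage

**Normalization.** `size_factors()` is the median-of-ratios estimator:
reference genes are those with nonzero counts in every sample; each sample's
factor is the median ratio of its counts to the per-gene geometric means.
Factors are defined relative to the geometric-mean reference, so the
meaningful invariant is in factor *ratios* (scaling one library by 10
multiplies its factor tenfold relative to the others). When no all-nonzero
gene exists, an explicit `pseudo_reference = TRUE` fallback relaxes the
reference set to genes nonzero in at least half the samples.

**Dispersion.** `estimate_dispersion()` pools the method-of-moments
estimate $\hat\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)$ across all
conditions with at least two replicates (weights $n_c - 1$), fits the
mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ across genes by least
squares (coefficients clipped at zero), and shrinks the raw estimates
halfway toward the trend (`shrink_weight = 0.5` by default). Per-gene
moment estimates at 6 replicates are extremely noisy; the trend borrows
strength across genes, and the 50/50 blend keeps genuine per-gene signal
while stabilising the tails. `shrink_weight = 0` exposes the raw estimator
(used in the recovery test against simulated truth).

**Testing.** `nb_wald_test()` compares two sample groups within one
genotype: a treatment at a time against either the same-time EV control
(`EV_same_time`) or the genotype's untreated time-0 samples (`time_zero`).
Group means are estimated on normalized counts with +0.5 moderation per
group (no fold change is ever infinite; the shift is negligible for
expressed genes), the standard error propagates the NB variance through the
log ratio, and the two-sided p-value uses the normal reference. Batch
(experiment) is handled by design — contrasts always compare matched
conditions that span the same experiments — rather than by a covariate in
the GLM. A Wald test was chosen over a likelihood-ratio test to keep the
per-gene fit closed-form; at very small counts the LRT is sharper, and the
test suite checks that the two agree in direction and significance on a toy
where both can be computed.

**Independent filtering.** Genes whose mean normalized count across the
contrast's samples is below `min_count_filter` (default 5) are flagged
untested, carry no p-values, and are excluded from the BH family. The
threshold is deliberately explicit and configurable rather than hidden.

**DEG calling.** `call_degs()` applies strict inequalities:
`p_adjusted < alpha_fdr` (default 0.05, Benjamini–Hochberg) and
`|log2_fc| > log2(fc_threshold)` (default 2). A gene at exactly the
threshold is not called. The fold change is the estimated one — no
posterior shrinkage — because the calling rule is defined on the estimate.

**Classification.** `eti_regulated()` takes the effector-vs-EV DEG set at a
matched time (4 or 8 hpi; earlier times are refused because NLR activation
effects on expression are not yet visible). `classify_eti_genes()` builds
each Col-0 ETI gene's DE-status vector across the four genotypes and
applies the decision table above. Two conventions matter:

* "Not DE in a mutant" means absence from that genotype's DEG set at the
  same thresholds — there is no separate equivalence test, so a gene
  hovering near the threshold in a mutant can flip category. This matches
  the set-membership logic of the original analysis and is the main caveat
  when interpreting category counts.
* A gene DE in a mutant with the *opposite* sign to Col-0 is treated as not
  DE for the direction under analysis (and counted in a log message). Up-
  and down-regulated genes are classified separately and never merged.

An alternative ETI definition (`eti_mode = "set_difference"`: the
effector-vs-time0 set minus the EV-vs-time0 set) is available behind the
config switch; the direct contrast is the default because it tests the
effector's effect against the concurrent control in one statistically
clean comparison.

**Fraction accounting.** `fraction_report()` counts categories and derives
percentages on three bases: the RNL-dependent fraction of all ETI genes;
synergistic, redundant, shared (= synergistic + redundant) and specific
fractions of the RNL-dependent count; and the ADR1s/NRG1s split of the
specific count. Percentages are rounded half-up to one decimal (matching
how such tables are printed; base R's round-half-even would differ at ties)
and are `NA` — rendered as a dash, not 0.0% — whenever the denominator is
zero. `table1_report()` formats cells as `pct%(num/den)` with thousands
separators.

**Enrichment.** `hypergeom_enrich()` scores over-representation with the
upper hypergeometric tail $P(X \ge k)$ (equivalently one-sided Fisher),
BH-corrected across terms passing the size filters (defaults 3–500; tiny
terms would otherwise dominate the top-k report). The annotation is taken
as already propagated — no ontology-graph ancestor inheritance is
performed. The universe defaults to all annotated genes and, in the
pipeline, to all genes in the counts table; both are configurable because
the choice (all genes vs expressed genes) is a genuine analysis decision.
Ties in `top_terms()` (default k = 25) break by larger fold enrichment,
then lexicographic term id, so reports are deterministic.

## The synthetic-data generator

`sim_params()` defaults are the study conditions: the full design is 27,206
nuclear protein-coding genes over 312 samples; the desk-scale default used
throughout the tests and the acceptance script is 2,000 genes over the same
312-sample design — large enough for stable fraction estimates, small
enough that the whole pipeline runs in seconds. Planted RNL-category
proportions echo the observed accounting of the fully RNL-dependent ETI at
8 hpi (3.1% independent, 35.4% synergistic, 22.8% redundant, 28.1%
ADR1-specific, 10.6% NRG1-specific). Other defaults, chosen once as
realistic for bulk plant RNA-seq and reported in the fixture's
`params.json`:

* planted |log2 effects| uniform on [2, 4] — clearly above the fold-change-2
  calling threshold, as expected for strongly immune-responsive genes;
* signal-gene baselines log-uniform on [50, 500] counts, background on
  [0.5, 1000];
* dispersion trend $\alpha(\mu) = 0.01 + 1/\mu$ (low-count genes are
  noisier), per-sample library factors uniform on [0.7, 1.3], per-experiment
  log-normal batch factors with sd 0.1 on the log scale;
* 60% of planted effects are inductions; half the ETI genes respond to all
  three effectors (ETI programmes overlap extensively), half to one; onset
  is 4 or 8 hpi with equal probability;
* PTI genes are additionally over-induced by 0.5 log2 units during effector
  infections — RNL-dependently for AvrRps4 (the fully RNL-dependent ETI),
  RNL-independently otherwise. The boost is kept below the fold-change
  threshold so it does not leak PTI genes into ETI sets.

What the generator does **not** emulate: gene–gene correlation, count
outliers and sample swaps, partial (quantitative rather than all-or-none)
loss of induction in mutants, 3'-bias or mappability artefacts, and genes
whose mutant behaviour differs between effectors sharing its scope.
Passing the recovery tests therefore demonstrates that the pipeline's
logic and statistics are correct under the declared model, not that real
data would classify with the same accuracy — in real data the binary
DE/not-DE convention near thresholds is the dominant source of category
noise.

## Numerical choices and degenerate inputs

* Dispersion estimates are floored at $10^{-8}$; a dispersion of exactly
  zero (Poisson) is handled in the simulator by `rpois`.
* Constant genes have zero variance: `vst_zscore()` maps them to all-zero
  rows instead of dividing by zero.
* `fraction_report()` on an empty assignment set returns zero counts with
  undefined (NA) percentages.
* `venn_counts()` accepts empty sets; region counts are validated against
  set cardinalities in the tests.
* The compact letter display uses the insert-and-absorb algorithm on the
  significant Tukey pairs; letters are assigned in order of each group's
  first appearance so relabelling groups permutes letters consistently.
* The disease index is computed on the percentage scale (range 100–600) as
  the formula defines it; `scale = "fraction"` gives the 1–6 variant some
  figures use.
* cfu conversion constants (plated/extract volumes, disc area) are required
  arguments with no hidden defaults, because they vary between assays.

## Problem sizes and runtime

The test suite simulates at 2,000 genes × 312 samples (plus one
14,490-gene single-genotype dataset for the set-size scaling check and a
5,000-gene null for calibration); the full suite runs in well under two
minutes on one CPU. The acceptance script uses the same sizes. Full-scale
runs (27,206 genes) use the same code paths and scale linearly in genes.

## Known limitations

* The GLM has no covariates: batch is absorbed by matched contrasts, which
  is exact for the balanced design but would not be for unbalanced data.
* No shrinkage of fold changes; near-threshold genes are called on noisy
  estimates (mitigated by the strict inequality and the FDR gate).
* Classification is binary per genotype; a "weaker regulation" quantitative
  analysis is limited to exporting the normalized-expression matrices.
* Two-way ANOVA for disease-index time courses is out of scope; the package
  offers one-way ANOVA per time point.
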