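---
title: "Intrinsic and acquired sex-biased expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic and acquired sex-biased expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbiasDE)
```

## The scientific problem

Sex differences in endothelial gene expression can be *intrinsic* — driven by
sex chromosomes and present from birth onwards — or *acquired* over life, for
example through sex-steroid exposure. Separating the two requires expression
data at two stages of life with very different designs:

* **birth**: RNA-seq of umbilical-vein endothelial cells from twins. Opposite-sex
  (boy–girl) twins share the maternal/intra-uterine environment, so a paired
  analysis can subtract it; same-sex twin pairs provide the weaker unpaired
  contrast for comparison.
* **adult**: aortic endothelial cell expression from unrelated donors with
  strongly unbalanced sexes, analysed unpaired.

This package implements that two-stage analysis end to end, together with the
downstream machinery used to characterize the resulting gene sets
(hypergeometric and Fisher set tests, promoter/gene-body conservation
summaries, random-gene permutation nulls, GWAS-catalog annotation), and a
synthetic-data generator that plants known truth so the whole pipeline can be
validated without access to the original cohorts.

## Differential-expression models

Both stages use per-gene ordinary linear models on log2-scale expression:

* **Paired birth model**: `log2CPM ~ sex + pair (+ activation)`. The pair
  indicators absorb anything shared by co-twins — in particular the maternal
  environment — and the optional activation covariate (FOS counts per million)
  adjusts for the endothelial activation state of individual isolates. With the
  covariate disabled, the model is algebraically a paired t-test, which gives
  an exact closed-form oracle for testing.
* **Unpaired adult model**: a two-sided equal-variance t-test of female versus
  male (equivalently `expression ~ sex`).

These are deliberate simplifications of count-based (negative-binomial GLM)
and moderated-t approaches: the inferential content — the paired,
mother-corrected, covariate-adjusted sex contrast, and the plain unpaired sex
contrast — is preserved, while every p-value remains checkable against a
closed form. Variance moderation and count-model shrinkage are out of scope.

Conventions: the log2 fold change is always female-over-male (positive =
higher in females). Counts are normalized to `log2(1e6*(count+0.5)/(libsize+1))`;
the 0.5 pseudo-count is the common default and keeps zeros finite. Genes with
zero residual variance are never dropped; they get the degenerate convention
`lfc = 0, p = 1` and a `degenerate` flag, so the gene universe stays aligned
across stages. Multiple testing uses Benjamini–Hochberg throughout.

## Classification rules

After restricting both tables to their shared gene universe (mirroring an
analysis limited to genes probed on both platforms):

* **intrinsic**: birth FDR < 0.1, adult p < 0.05, and the same non-zero sign
  of the fold change at both stages ("concordant"). A zero fold change at
  either stage fails concordance.
* **acquired**: birth p > 0.5 (explicitly *no* signal at birth), adult
  p < 0.05, and |adult lfc| strictly greater than the median |adult lfc| of
  all adult-significant genes — a stringency filter against marginal calls.
  The median is computed over all adult-significant genes *before* the birth
  filter; "more extreme than" is read as a strict inequality, so exact ties
  fail.

The classes are disjoint analytically (FDR ≥ p, so birth FDR < 0.1 implies
birth p < 0.1 ≤ 0.5). Direction is taken from the adult fold change.
Percentages in summaries use half-up rounding to one decimal.

## Set statistics

Gene-set enrichment uses the upper-tail hypergeometric probability with a
population size of 20,000 (the convention for genome-scale collections), BH
adjustment across the collection, and the gene ratio `k/q` for reporting.
The overlap test between two gene lists is the same tail with the universe as
an explicit, required argument — the shared tested-gene universe is the
sensible choice, and no silent default is provided.

The hormonal-target contrast (are acquired genes richer in
estrogen/androgen/progestin-response genes than intrinsic ones?) is a
two-sided Fisher exact test using the point-probability rule: the p-value
sums the probabilities of all tables with the observed margins that are no
more probable than the observed table (with a 1e-7 relative tolerance for
floating-point ties, matching R's exact-test convention).

## Conservation summaries

Promoter windows are strand-aware: TSS −200 to +100 bases in 0-based
half-open coordinates (`[tss-200, tss+100)` on `+`; the mirror image
`[tss-99, tss+201)` on `−`; always 300 bases). Per-gene scores are the
arithmetic mean of the per-base conservation values over all *covered* bases;
bases absent from a sparse bedGraph are excluded rather than imputed as zero,
and a gene with no covered base gets `NA`.

The published high/low dichotomy left its split point unstated; we use the
median of the genome-wide per-gene means, with ties assigned to *low*. This
is the simplest reproducible rule and is recorded in output metadata.

## Permutation framework

All set-level permutation tests share one engine: the observed statistic
(median or mean of per-gene values, fraction in the high class, or overlap
count with a reference membership list) is compared with `n_perm` draws of
equally many genes sampled from the universe without replacement. The
one-sided p-values count *strictly* higher / strictly lower null draws
divided by `n_perm`: ties count toward neither tail, and p = 0 is possible.
This is implemented verbatim as the default because it is the published rule;
an optional add-one estimator `(k+1)/(n_perm+1)` is available (off by
default) for users needing strictly positive p-values. Draws on which the
statistic is undefined (all values missing) are resampled and counted. The
default is 10,000 permutations.

## GWAS-catalog handling

`MAPPED_GENE` strings are split on commas **and** hyphens, trimmed,
de-duplicated preserving order. The hyphen rule follows the published method
verbatim even though it breaks genuinely hyphenated symbols; per-row token
counts are kept so users can audit the effect. Gene matching is
case-sensitive exact symbol matching. Two enrichment statistics are offered:
overlap with one GWAS's target list, and membership in the catalog-wide
unique-gene index, both via the permutation engine with both one-sided
p-values reported.

## The synthetic-data generator

The generator emulates the study that motivated this pipeline, and its
defaults *are* those study conditions: 7 boy–girl pairs plus 3 boy–boy and 4
girl–girl pairs at birth; 43 female / 129 male adults (the recovery analyses
in `scripts/acceptance.R` use the stated benchmark of 40/120); 2,000 genes
with 5% sex-chromosomal; 30 intrinsic and 30 acquired genes planted at
|log2 FC| = 1.5; adult residual sd 0.5.

Structure worth knowing when interpreting results:

* Birth counts are negative-binomial around
  `2^(baseline + sex + mother + activation + log2 libfactor)` with gene-wise
  log-normal baselines (`log2` mean 9, sd 1.5). The maternal effect is a
  **gene × pair** Gaussian intercept shared by co-twins (sd `mother_sd` = 1):
  per-gene nuisance that pair blocking removes exactly and that a library-size
  normalization cannot touch. The activation covariate additively shifts a
  random 10% of genes with gene-specific slopes.
* `nb_dispersion` defaults to 0.02, the low biological dispersion typical of
  clonal cultured cell lines once the shared-mother term is modelled
  separately; population-level cohorts would be far more dispersed.
* Library sizes vary log-normally with sd 0.3 — sequencing-depth variation is
  a free design choice here, set to a typical RNA-seq spread.
* Adult intensities are Gaussian on the log2 scale (baseline mean 7, sd 1.5;
  residual sd `noise_sd`), emulating normalized microarray data without
  probe-level artefacts.
* Intrinsic genes get the same-signed sex effect at both stages; acquired
  genes only in adults. Consequently the birth p-values of acquired genes are
  uniform, and the definitional gate `birth p > 0.5` passes for about half of
  them — full recovery of the acquired set is impossible by construction,
  which is a property of the definition, not of the implementation.
* All planted genes carry a `+0.3` conservation boost on their promoter
  window over a U(0, 0.6) background; the 100 promoter bases downstream of
  the TSS lie inside the gene body, so a small known fraction of the boost
  appears in gene-body means.
* The hormonal-target flag has a 5% background rate, enriched to 35% on
  planted acquired genes; the first synthetic GWAS trait (CAD-like) includes
  6 planted intrinsic genes among its targets.
* All randomness derives from a single integer seed (fixed offsets per
  generator component), so identical configs produce byte-identical outputs.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: read-level sequencing noise, microarray probe effects,
batch structure beyond the maternal effect, absence of Y-linked expression in
female samples, correlated gene modules, and population-level dispersion.
Recovery results on synthetic data are a check of the machinery, not a power
analysis for real cohorts.

## Numerical and degenerate-input conventions

* Zero-variance genes: `lfc = 0, p = 1`, flagged, never dropped.
* Empty shared universe or duplicated gene ids: error, never silent
  subsetting.
* No adult-significant genes: the stringency median is undefined and both
  classes are empty (the definitions are unsatisfiable).
* Promoter windows clipped at coordinate 0 emit a warning.
* Hypergeometric `N` smaller than a query or set size: error.
* Permutation p-values of exactly 0 are reported as such (see above).

## Problem sizes used in the shipped checks

The test-suite and acceptance script exercise the generator at its default
study shape (2,000 genes; 7 opposite-sex pairs; 40–172 adults), 10,000
permutations for the planted-signal tests, 500 × 200 permutations for the
calibration check, and exhaustive enumeration oracles up to universes of 12
genes (hypergeometric) and 2×2 tables with totals up to 30 (Fisher). These
sizes make every check exact or tightly Monte-Carlo-bounded while keeping a
full run in the order of seconds to minutes.

## Known limitations

* The DE engines are ordinary least squares on log2 values; genes with very
  low counts are better served by count models.
* The acquired-class definition caps its own recall near 50% on genes with
  truly null birth signal (uniform p > 0.5 gate) — a property inherited from
  the definition itself.
* The high/low conservation split is a package convention (median, ties low);
  other dichotomies will move the class-fraction statistics.
* Hyphen splitting of `MAPPED_GENE` breaks hyphenated gene symbols by design.
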