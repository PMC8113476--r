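---
title: "Methods: ageing-related DNA methylation at tRNA gene loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ageing-related DNA methylation at tRNA gene loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind the package, the
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## The scientific question

Human tRNA genes are short (60–86 bp, median 73 bp), highly similar,
multi-copy loci that are poorly covered by methylation arrays. A windowed,
fragment-scale methylome assay (MeDIP-seq scored as reads-per-million in
500 bp windows with a 250 bp slide) gives regional access to them: every
tRNA gene is covered by 2–3 windows. The question the pipeline answers is
whether tRNA gene loci accumulate DNA methylation with age beyond what
their CpG density alone would predict, and whether individual loci — rather
than whole isodecoder families — carry the change.

## Windowed age models

Window scores are quantile-normalised across samples (`quantile_normalize`,
backed by `limma::normalizeQuantiles` with mean-of-ties handling) and each
window is fitted by ordinary least squares with one of the standard
covariate sets:

* model 1 — no covariates;
* model 2 — processing batch (categorical, first level reference);
* model 3 — lymphocyte, monocyte, neutrophil and eosinophil counts;
* model 4 — batch plus the four cell counts (the primary model);
* longitudinal — model 4 plus participant identifier as a fixed effect,
  on the subset of participants with two visits at least 5 years apart,
  so the age effect is identified within person;
* mixed — a likelihood-ratio test adding the methylation score to a null
  mixed model with the model-4 fixed effects and family id and zygosity
  as random intercepts (`lme4`, maximum likelihood, χ²(1)).

The association p-value is always the partial F-test for the
age–methylation term; for model 1 this is identical to the
simple-regression F-test. Two directions are supported because regional
methylome studies have used both: `meth_response` (methylation ~ age,
slope in score units per year; the default, matching slope units quoted
"per unit time") and `age_response` (age ~ methylation, the array-style
formula). The association p-value is near-identical either way; only the
slope's units change. Positive slope always means hypermethylation with
age.

Window results are lifted to gene level by the any-overlap rule: a tRNA is
significant if any overlapping window passes the threshold, with the
minimum-p window reported (ties broken by larger |slope|, then window
name). A window shared by two genes counts for both — a documented source
of "pulled-up" calls for immediate neighbours, which the reporting keeps
visible rather than resolving silently. Thresholds are Bonferroni:
study-wide α/(number of tRNA features) and genome-wide α/(number of
windows), both computed, never transcribed, and echoed in the run
manifest with α and m.

Degenerate windows (zero variance, e.g. all-zero scores) return a flagged
p = 1 and slope 0 instead of dropping rows, so batch output stays aligned
with input. A rank-deficient design is an error naming the collinear
columns; a factor covariate left with a single level after subsetting
(e.g. one batch in a longitudinal subset) is dropped, since it carries no
contrast.

One deliberate deviation from a conservative fallback rule: the mixed
model falls back to the fixed-effects partial F only when the fit *fails*,
not when a variance component is estimated at the boundary (singular fit).
A zero variance estimate is a legitimate maximum-likelihood solution and
the LRT remains valid there, approaching the fixed-effects F — falling
back on every boundary fit would silently disable the mixed model in
exactly the datasets where family structure is weak.

## CpG-density-matched permutation enrichment

CpG density is defined so that both bases of a CpG count:
`density% = 100 · 2 · count / length`, hence 45 CpGs in a 500 bp window
= 18%. Windows are stratified by *exact* CpG count below the 18%
threshold (count and density are interchangeable at fixed window length);
all windows at or above 45 CpGs per 500 bp form one pooled stratum, both
because exact-count strata become too thin there and because CpG-island
density windows behave as a single consistently hypomethylated class.

Each permutation draws, without replacement within the draw, a random
background window set matching the feature set's stratum histogram.
Feature windows are excluded from the background pool so the null cannot
contain the signal. With `r` the number of permutations whose
significant-window count is **at least** the observed count, the
empirical p-value is `(r + 1) / (N + 1)`; ties count against the feature
set and the +1 correction means the p-value can never be zero — its floor
at N = 1000 is 1/1001 ≈ 9.99 × 10⁻⁴. The `≥` convention is the standard
conservative choice for empirical p-values. Hyper- and hypomethylation
can be tested separately by passing direction-restricted significance
flags; the headline question is hypermethylation-only.

A property worth knowing: with a finite background, the background
significance rate is itself estimated, so the empirical p is only
approximately uniform under the null and the approximation improves with
background size. The calibration test therefore uses the generator's
full desk-scale genome (~8000 windows) rather than a toy one.

The one-sided Fisher's exact test (`fisher_enrichment`) is the companion
coarse test against the whole background, reported with the sample odds
ratio (a·d)/(b·c), with IEEE semantics for zero cells (x/0 = Inf,
0/0 = NaN).

## tRNA gene clustering

Clustering is bedtools-merge-style single linkage: sorted genes join one
group while the gap from the group's running end to the next start is at
most 5 Mb; groups survive as clusters with at least 5 genes and at least
5 genes/Mb. The density span runs from the minimum start to the maximum
end of the members (the merged-interval span; the natural reading where
"per Mb" is otherwise undefined). Strand is ignored throughout; all
overlap arithmetic is BED-convention half-open, so an interval ending at
position x does not overlap one starting at x.

## Pooled targeted bisulfite analysis

The validation design pools equal-mass DNA from age-matched individuals —
8 pools at 4 time points (~4, 28, 63, 78 years; 190 contributors) — so a
pool's methylation proportion approximates its group mean. Counts in
Bismark-coverage form pass a minimum-coverage filter (≥ 25 reads; the
RRBS preset uses strictly > 50 reads per CpG and strictly > 10 retained
data points per tRNA). Technical replicates are averaged within pool
before testing.

For a pairwise age-group comparison within one region, pools — not
individuals — are the replicates, and two interpretations of a "paired"
test are possible. The package pairs **CpG sites** across the two groups
(pool-averaged per group) for the region's primary p-value, because the
alternative — pairing the two pools per age point — leaves two pairs and
essentially no power. The per-CpG two-sample p-values are additionally
combined across the region by Fisher's method, with an optional
Brown-type dependence adjustment (Kost–McDermott covariance polynomial)
for the correlated neighbouring CpGs; the output labels which was used.
`delta` is the plain mean over CpGs of (older − younger) methylation
proportion. When every per-CpG difference is identical the paired t
statistic degenerates; the result carries a `zero_variance` flag with
p = 1 for an all-zero difference and the limiting p = 0 otherwise.

Group comparisons of methylation level distributions (e.g. oldest versus
youngest individual, lymphoid versus myeloid) use the one-sided Wilcoxon
rank-sum test with the first-sample W convention (rank sum minus its
minimum), exact for small tie-free samples, tie-corrected normal
approximation otherwise, plus the Hodges–Lehmann shift estimate and
one-sided confidence interval. Per-region rates of change across pools
come from simple linear regression, reported in both orientations with
the shared F-test p-value.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure the analysis
assumes, not the sequencing process:

* window scores are `baseline(CpG density) + slope·age·1[affected]
  + batch offset + Σ celltype_effect·count + participant/family
  intercepts + Gaussian noise`, floored at 0. Noise is Gaussian on the
  score scale because the pipeline consumes post-RPM quantile-normalised
  scores; the read-level generative detail is immaterial to the tested
  statistics.
* `baseline(density)` is monotone saturating with a hypomethylated
  regime at ≥ 18% density, so that density matching in the permutation
  test is consequential: an unmatched test would be confounded by
  density alone.
* tRNA-overlapping windows draw CpG counts from a denser distribution
  than background, and the background itself is a mixture with a
  CpG-island-like dense tail — without that tail, density matching would
  be impossible at tRNA-like densities.
* the cohort has ages 16–82, a mostly-female twin structure (MZ/DZ pairs
  sharing family intercepts and ages), a minority of participants
  revisited 5–16 years later, batch labels, and blood cell counts whose
  age trends are configurable so cell-composition confounding can be
  switched on and off.
* `simulate_pooled_bis()` draws per-CpG read depth from a negative
  binomial (default mean 679) and methylated reads binomially at
  `baseline + slope·pool_age` for affected regions. The default planted
  slope of 5 × 10⁻⁴ proportion/yr gives ~3.7% between the 4- and
  78-year pools, the magnitude scale of interest.

Default cohort size is 3001 samples (the full-covariate subset size of
the motivating design); the default genome is two 1 Mb chromosomes
(~8000 windows) carrying 100 tRNA genes. The genome is deliberately
desk-scale: it preserves every structural feature the statistics touch
(window geometry, density strata, gene/window overlap multiplicity)
while keeping a full simulate–fit–permute cycle in minutes. Tests use
smaller cohorts and genomes per case; each test states its own sizes.

What passing tests on these simulations do **not** show about real data:
mappability artefacts, GC/IP efficiency biases, the empirical RPM score
distribution, fine-scale CpG spatial correlation within windows, and
cell-subtype effects below the four measured fractions are all outside
the generator. Results here validate the statistical machinery, not any
biological claim about a particular dataset.

## Numerical and reproducibility choices

* Quantile-normalisation ties take the mean of tied reference values; a
  one-window matrix is returned unchanged.
* Empirical p-values use the +1/(N+1) correction; `r` counts `≥`.
* p = 0 inputs to Fisher's combination are clipped to the smallest
  positive double, with a warning.
* Every stochastic stage takes an explicit seed; pipeline stages write
  JSON manifests with parameters, seeds and output md5 checksums, so
  deterministic stages can be re-run and verified bit-identically.
* Window generation drops partial terminal windows rather than
  truncating them, keeping window length — and hence density — exactly
  comparable.
* Degenerate inputs prefer flagged results over dropped rows wherever an
  output must stay aligned with an input table.

## Known limitations

* The blacklist is user input; the package does not ship or pin one, so
  feature counts after filtering depend on the blacklist version
  supplied.
* The exact variant of the "generalisation of Fisher's method" used by
  upstream array toolchains is not pinned; the package offers standard
  Fisher and a Brown-type adjustment and labels which was used.
* At small window counts, quantile normalisation couples windows: a
  very large planted effect can saturate a window's within-sample rank
  and compress the fitted slope. This is a property of quantile
  normalisation at toy scale, not of the estimator; realistic effect
  sizes on genome-scale window sets are unaffected.
* The permutation test's empirical p is exactly valid as a Monte Carlo
  p-value given the flags, but its null calibration over repeated
  studies is approximate for small backgrounds (see above).
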