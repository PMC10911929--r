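---
title: "Calling passenger coamplifications and screening for collateral dependencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling passenger coamplifications and screening for collateral dependencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coamplikon)
```

## The model

High-level DNA amplification in cancer rarely elevates a single gene. The
amplified unit — an amplicon, whether chromosomal (HSR) or extrachromosomal
(ecDNA) — typically spans one to several megabases around the selected
oncogene and drags neighboring *passenger* genes to the same copy number.
Because expression follows dosage, a coamplified passenger is constitutively
overexpressed, and that overexpression can rewire the cell enough to create a
*collateral dependency*: a gene whose knockout is tolerated in
oncogene-amplified cells but lethal when the passenger is coamplified.

`coamplikon` operationalises this idea as a pipeline of small, testable
steps: segment-level amplification calling, gene-level lifting, amplicon
assembly, cohort summaries, and a two-group differential dependency screen,
plus correlation, enrichment and disorder-region nomination as downstream
analyses, and a synthetic-cohort generator that plants every effect the
pipeline is supposed to detect.

## Amplification calling

Copy-number input is a SEG-style table of per-sample segments with log2
tumor/reference ratios. Internally all genomic coordinates are 1-based
closed (the SEG dialect); BED annotation is converted at the boundary, and
chromosome names are normalized to a single prefix-free dialect at load so
`"chr2"` and `"2"` inputs yield identical calls.

A segment is **amplified** when its log2 ratio reaches the platform's
threshold (closed comparison): 1.5 for Affymetrix and NimbleGen arrays, 2
for Agilent, 0.7 for Illumina. These cutoffs separate high-level
amplification from broad gains on each array chemistry; they are constants
of the method, overridable per platform, and samples with no platform
annotation fall back to the most permissive array cutoff (1.5). A segment is
a **homozygous deletion** when its log2 ratio is strictly below −2.
Gene-level inputs that already encode high-level amplification as the
discrete label 2 (cBioPortal-style) bypass the thresholds via
`calls_from_labels()`.

Three numerical choices matter here, all deterministic:

* **Gene status = maximum-overlap segment.** A gene straddling a breakpoint
  takes the status of the segment covering most of it, with overlap ties
  broken toward the larger |log2 ratio|. This is robust to boundary
  segments, unlike "any overlap" (which would over-call) or a midpoint rule
  (which ignores most of the gene). Genes with no overlapping segment are
  `missing`, so statuses always partition the annotation per sample.
* **Gap tolerance 10 kb.** Array amplicons are frequently split by probe
  gaps; amplified segments on the same chromosome separated by at most
  10 kb are merged into one amplicon interval. The default is small relative
  to the 1–3 Mb amplicon scale and large relative to inter-probe spacing;
  merging is idempotent.
* **Interval membership = any overlap; coamplification = amplified status.**
  An amplicon's member list contains every annotated gene overlapping its
  span, but cohort statistics count a passenger as coamplified only when the
  passenger's own gene-level status is amplified (a fragment at the amplicon
  edge does not count; an any-overlap mode is available by flag).

Amplicon members are split into oncogenes and passengers by a user-supplied
oncogene list; intervals without any oncogene are *orphan* amplicons, and
the cohort-wide count of passenger amplifications on orphan amplicons is
exposed because its rarity is exactly what motivates treating passengers as
hitchhikers rather than drivers.

## The dependency screen

Cell lines are stratified by a pair (oncogene, passenger) on gene-level copy
number: *coamplified* when both values are at or above τ = 2 (closed),
*oncogene-only* when only the oncogene passes, excluded otherwise (no
oncogene amplification, or missing copy number for either gene). τ is
applied to the matrix as provided; whether the matrix is linear or
log-scaled copy number is the caller's responsibility and is documented
rather than guessed.

For every gene with at least `min_group = 3` non-missing dependency scores
per arm, the screen computes the difference of median dependency scores
(coamplified minus oncogene-only; CERES convention, more negative = more
dependent) and a two-sided Wilcoxon rank-sum p-value. Two-sided is the
default because the screen has no a-priori sign, even though candidate
collateral dependencies are the negative tail. Nominal p-values are the
primary readout, with BH q-values computed alongside; the volcano plot and
summaries therefore show both.

The Wilcoxon kernel uses the exact null distribution of the Mann–Whitney U
statistic whenever the smaller group has at most 10 observations and the
pooled sample is tie-free, and otherwise a midrank normal approximation with
tie-corrected variance and continuity correction. Two numerical notes:

* With identical pooled values the tie-corrected variance is zero; the null
  is perfectly symmetric and p = 1 is returned directly.
* Exact tests are discrete: at 10 vs 10 lines the largest attainable
  two-sided p below 0.05 gives a true type-I level of ≈ 0.043, not 0.050.
  Null-screen calibration checks must therefore allow Monte-Carlo slack
  around the nominal level; the package's own checks use a
  ±3·SE binomial band, which contains the discrete level.

Welch's t (used for generic two-group comparisons) implements the standard
statistic with Welch–Satterthwaite degrees of freedom and explicit
degenerate rules: both variances zero with equal means gives t = 0, p = 1;
both zero with unequal means is an error rather than a silent infinity.

## Correlation and enrichment conventions

`pearson_corr_test()` defaults to two-sided p-values. Published correlation
p-values are sometimes quoted under a one-sided convention (for a
correlation of −0.5996 at n = 13, the t-oracle gives ≈ 0.030 two-sided and
≈ 0.0152 one-sided); the one-sided convention, testing in the direction of
the observed r, is available by flag, and the discrepancy is documented
rather than silently matched.

Over-representation uses the one-sided hypergeometric tail within a finite,
user-supplied universe — no ontology data ships with the package, because
enrichment conclusions are only as good as the background. Preranked
enrichment implements the weighted Kolmogorov–Smirnov running sum with
weight exponent 1 (hit increments ∝ |score|, uniform miss decrements), a
gene-label permutation null of equal-size random sets (default 1000
permutations), NES = ES divided by the mean |null ES| of matching sign, and
an add-one-smoothed same-sign permutation p so p is never exactly zero.
Ranking ties are broken lexicographically by gene symbol so results are
bit-reproducible for a fixed seed. All-zero score vectors fall back to
uniform hit weights, the one input where the weighted sum is undefined.

## Disorder-region nomination

Per-residue disorder tracks from different predictors are min-max normalized
to [0, 1] (a constant track is degenerate and maps to zero) and averaged
into a consensus. A least-squares polynomial (default degree 9) smooths the
consensus, and the nominated region is the longest contiguous run of
residues whose fitted value clears the threshold (default 0.5), optionally
within a search window; ties go to the earliest run, and raising the
threshold can only shrink the region. Degree, threshold and the averaging
rule are deliberately exposed: the procedure's shape (smooth, threshold,
take the contiguous run) is the method; the specific published residue
ranges depend on the original predictor outputs, which are inputs here, not
reproductions.

## What the synthetic cohorts emulate

`simulation_config()` encodes the study conditions the package is designed
around, and its defaults are fixed once:

* `f_amp = 0.43`, `f_coamp = 0.58` — an oncogene amplified in ~43% of a
  cohort with the primary passenger included on ~58% of those amplicons,
  the regime of a recurrently coamplified passenger on a *MYCN*-like
  amplicon.
* `amplicon_width = 1–3 Mb`, genes of 100 kb every 500 kb — the amplicon is
  an order of magnitude wider than a gene, so passenger inclusion is
  genuinely probabilistic geometry, not a coin flip glued to a label. The
  amplicon's left endpoint is drawn uniformly among positions containing
  the oncogene, and endpoints are rejection-sampled against a
  Bernoulli(`f_coamp`) target so inclusion hits the target rate exactly in
  expectation. Inclusion truth uses the same maximum-overlap rule as the
  caller, computed arithmetically and independently of the calling code.
* `log2_amp_mean = 3`, `log2_noise_sd = 0.1` — a ~16-copy amplification
  with segment-level noise well below the cutoff margins; platform labels
  are drawn from an even mix of the four array types so every cutoff is
  exercised.
* Tumor gene copy number is linear absolute CN (`2·2^log2ratio`, diploid
  = 2); **cell-line** copy number is emitted on a DepMap-like relative
  scale (diploid ≈ 1, amplified `2^log2_amp_mean`) so that the screen's
  closed τ = 2 threshold separates amplified from neutral lines even at
  zero noise — on an absolute scale a noiseless diploid sits exactly at the
  closed threshold, which is a property of that scale, not of the screen.
* `dep_noise_sd = 0.3`, `delta = 1` — CERES-like score scatter for
  non-essential genes, with planted collateral targets shifted by −δ in
  coamplified lines only.
* Expression = baseline + 0.5·CN + noise, a plain dosage model.

A single mandatory seed drives every draw in a fixed order, so identical
configs are bit-identical. What the generator does **not** emulate: ecDNA
copy-number heterogeneity and clonal evolution, segment-boundary
uncertainty from probe density, GC/wave artifacts, lineage structure among
cell lines, and correlated dependencies within pathways. Passing recovery
tests therefore demonstrates that the pipeline's logic is correct under its
own assumptions — clean segments, independent lines, additive shifts — not
that real cohorts are free of the confounders above.

## Validation problem sizes

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to keep full runs in tens of seconds while leaving Monte-Carlo error
well inside the asserted bands: exact-Wilcoxon enumeration up to 6+6 (all 36
group-size combinations), null and mixed screens over 2000 genes at 10 vs 10
lines, power curves over 200 replicates per condition, frequency convergence
on 2000-sample cohorts (3 binomial SE bands), and zero-noise end-to-end
closure on 80-sample cohorts where precision and recall are required to be
exactly 1.

## Limitations

The package calls amplification from segment means only — no probe-level
re-segmentation, no liftover, no ecDNA/HSR topology inference. The screen
treats cell lines as exchangeable; lineage or batch structure must be
handled upstream. The statistics are rank- and median-based by design and
will not beat parametric power when normality genuinely holds. Dependency
scores, gene sets, disorder tracks and drug-response tables are consumed as
given; their generation (CERES, ontology curation, disorder predictors,
dose–response fitting) is out of scope.
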