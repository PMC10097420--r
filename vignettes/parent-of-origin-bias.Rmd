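---
title: "Methods: decomposing and validating parent-of-origin expression bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing and validating parent-of-origin expression bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poebias)
```

## The measurement model

In a reciprocal F1 hybrid design, two inbred strains (here C57BL/6 "B" and
CastEiJ "C") are crossed in both directions. Strain-distinguishing SNPs let
each RNA-seq read (or pyrosequencing signal) be assigned to the maternal or
paternal allele. Two confounded influences act on the allelic fraction of a
gene: its parental origin (imprinting) and its strain of origin. The
reciprocal design disentangles them because swapping the cross direction
swaps which parent contributes the Cast allele.

Writing `p_BC` and `p_CB` for the percent of expression from the paternal
allele in the B×C and C×B crosses, the package uses the linear
decomposition

* parental score `P = (p_BC + p_CB)/2` (`reciprocal_mean_paternal()`),
* strain score `S = (p_BC + (100 − p_CB))/2` (`strain_percent()`),

an exact, invertible transform (`cross_percents_from_scores()`). This is a
modelling assumption: effects are taken as additive on the fraction scale.
It is exact for the package's own generator and a good first-order
approximation otherwise; it degrades near the 0/100 boundaries where
fractions saturate, which is one reason extreme biases are reported in the
top bin rather than as point estimates.

Per-cross fractions are computed from replicate counts pooled by summation
(`gene_ase()`), which weights replicates by their depth and matches how
pooled-count allelic ratios are usually formed; a per-replicate-mean
alternative (`pool_replicates = FALSE`) is available when replicates have
very uneven depth. Fold-change inputs from studies that report
maternal/paternal ratios rather than fractions are converted with
`100·FC/(1+FC)` (`maternal_percent_from_fold_change()`), the unique
monotone map sending FC = 1 to 50% — the published formula strings for this
quantity are ambiguous about parenthesisation, and this reading is the only
one that is a probability.

## Bias bins and the canonical threshold

Per-gene summaries use the *maximum symmetric bias*: each per-tissue value
`v` is reflected to `max(v, 100 − v)` and the maximum over tissues taken
(`max_bias()`). The preferred parent is the direction achieving that
maximum; when tissues favouring opposite parents tie at the maximum the
gene is labelled `both`. Binning (`assign_bin()`) uses the five 10-point
bins `50-60 … 90-100` with left-closed/right-open boundaries and a closed
top bin — the standard histogram convention, stated here because the bin
labels alone do not determine it. The canonical-imprinting flag
(`canonical_flag()`) is strict: a gene must exceed 70% from the preferred
allele; exactly 70:30 is still "weak".

## Genomic-context classification

`assign_class()` labels novel candidates by proximity: within 1 Mb of a
known imprinted gene → class 3; otherwise within 1 Mb of another novel
candidate → class 2; otherwise class 1. Precedence matters (class 3 is
checked first) so the classes partition the candidates. Distance is the
interval gap — zero for overlapping intervals, infinite across chromosomes
— rather than TSS-to-TSS, because the gap is insensitive to strand and to
how generously a transcript is annotated; "within 1 Mb" is implemented as
gap ≤ 1,000,000 so that the complementary phrase "more than 1 Mb" is its
exact negation. The nearest-neighbour search runs on
`GenomicRanges::distanceToNearest()`; the test suite checks it against an
independent O(n²) arithmetic oracle on hundreds of random instances.

Within a known cluster, a class-3 gene is *flanked* when known genes lie on
both sides of it and *peripheral* otherwise. "Side" is decided by interval
midpoints with strict inequalities — a midpoint tie does not count as
flanking. This midpoint rule is a stated convention (position within a
cluster has no canonical formalisation); users comparing against other
definitions should check boundary genes by eye. ICR orientation
(`icr_orientation()`) simply compares the preferred parent with the ICR's
methylated parent: `meth_icr` when they agree, `un_icr` when they differ,
propagating `both` and `no_icr` cases.

Alias merging (`merge_aliases()`) collapses records whose name sets
intersect under a user-supplied alias closure, spanning the union interval.
The alias list is deliberately an input, not a built-in table: name
harmonisation between annotation releases is editorial, and hard-coding one
would hide it. Merging is union-find based, idempotent, order-independent,
and refuses to merge records on different chromosomes.

## Pyrosequencing validation calling

`correct_amplification()` removes primer amplification bias by odds
normalisation: measured odds are divided by the odds the assay reads on
genomic DNA, which is truly 50:50. This is the unique odds-multiplicative
correction that (a) is the identity for an unbiased assay and (b) maps the
gDNA measurement itself to exactly 50; both identities are tested across
the whole domain. Measurements at 0 or 100 are clamped to [1, 99] with a
warning before odds are formed — beyond those bounds the assay carries no
ratio information and the correction would be infinite.

`tissue_mean()` averages corrected replicates within each cross and then
across the two crosses (strain cancellation); a tissue missing either cross
yields `NA` rather than a one-cross mean. `call_gene()` then applies, in
precedence order: `Low_expression` when no tissue passes the expression
gate (`expression_gate()`, strict `< 0.05` of the housekeeping reference)
or carries data; `Placental_maternal`/`Placental_paternal` when the only
out-of-window tissue is the placenta; directional `Paternal`/`Maternal`
when any somatic tissue exceeds 55% or falls below 45%; `Biallelic`
otherwise. The biallelic window [45, 55] is closed — directional calls
require strict inequality. Conflicting somatic directions are resolved by
majority (ties by mean deviation from 50) with a warning and a
`conflicting` flag; this fallback is a package convention for robustness,
not something the bundled panel exercises. `strain_flag()` is raised when
the per-tissue strain score leaves [45, 55] in at least two tissues.

The bundled panel (`load_validation_panel()`) is a transcription of a
published allele-specific pyrosequencing summary of 49 candidates × 13
tissues. The strict caller reproduces its printed status for 47 of 49
rows. The two exceptions are documented rather than patched: one gene is
printed as biallelic despite a single sub-45 value in one tissue (the
strict rule calls it maternal; the printed call appears to incorporate a
strain-bias judgement the stated rule does not encode), and one row
duplicates a long run of its neighbour's values and is treated as
potentially corrupted, so neither participates in per-row regression
assertions.

## Promoter signal summaries

Promoters are defined as the 500 bp immediately upstream of the
transcription start site, strand-aware (`promoter_window()`): `[start−500,
start)` on `+`, `[end, end+500)` on `−`, clipped at coordinate 0 with a
warning. Unknown strand is an error — assuming `+` would silently place
half the windows inside gene bodies. `mean_signal()` computes a
base-pair-weighted mean of bedGraph values over the covered bases of each
window; uncovered bases are excluded by default because bedGraph coverage
is sparse (a `zero_fill` mode treats them as zeros instead, appropriate for
tracks where absence means absence of signal rather than absence of data).
Overlapping track intervals are disjoined and averaged on load, with a
warning.

## The synthetic generator

`simulate_counts()` draws paternal reads per replicate as
`Binomial(depth, clip(θ_p + s·θ_s))`, with `s = +1` in B×C (paternal
allele Cast) and `−1` in C×B. Effects are additive on the probability
scale so the reciprocal-mean estimator is *exactly* unbiased away from the
clip bounds, making estimator-bias tests sharp; clip bounds [0.02, 0.98]
prevent degenerate binomials while permitting 98:2 imprinting.
`simulate_pyro()` distorts the true percent with the exact inverse of the
amplification correction and adds Gaussian assay noise.
`simulate_registry()` lays out known clusters (with one ICR each), class-3
candidates within 1 Mb of them, novel clusters, and singletons in slots 8
Mb apart, so true class labels are unambiguous by construction. All
generators are pure functions of `(config, seed)` and restore the caller's
RNG state.

Default conditions are fixed once: 6 biological replicates per reciprocal
cross and ~10⁴ informative reads per gene and replicate (the replicate
structure of the better-powered published designs), pyrosequencing with 4
biological replicates and 1.5-point Gaussian noise (typical assay
variability), gDNA bias 50 (unbiased) unless a scenario sets otherwise,
and a panel geometry of 7 known clusters, 8 singletons and 5 novel
clusters of 3 — the shape of the validation panels the workflow targets.
The generator emulates binomial counting noise, strain and parental
effects, replicate structure, amplification bias and assay noise. It does
**not** emulate SNP-level mapping bias, overdispersion beyond binomial,
tissue heterogeneity of imprinting, or correlated replicates — so passing
tests demonstrate correctness of the estimators and callers under their
stated model, not robustness to every artefact of real libraries.

The permutation screen (`permutation_parent_test()`) is a deliberately
simple stand-in for heavier resampling-based ASE callers: the statistic is
the parental score's deviation from 50 on replicate-level fractions, and
the null flips maternal/paternal labels within replicates, preserving
cross structure. Under the null the fractions are symmetric about 0.5, so
the flip group is exact; type-I error at α = 0.05 is verified to sit in
[0.03, 0.07] over 1000 null genes. It has no "undetermined" category and
no variance shrinkage; it screens, it does not adjudicate.

## Problem sizes and numerical choices

The test and acceptance runs use: 200 random registries (plus one
simulated registry of ~70 genes) for the classifier-versus-oracle check,
500 genes at depth 10⁴ for estimator bias (tolerance ±0.3 points), 1000
null genes × 199 permutations for type-I calibration, and a 50-gene
zero-noise round-trip for the correction identity — sizes chosen so the
full suite runs in well under a minute while keeping Monte-Carlo error a
few-fold smaller than each tolerance. Floating-point ties in the
permutation statistic are counted with a 1e-12 slack so exchangeable
permutations are never under-counted (which would anti-conservatively
shrink p-values).

## Limitations

* The class window (1 Mb), biallelic window (45–55), canonical cutoff
  (70%) and expression gate (0.05×) are field conventions, all
  overridable; conclusions can be sensitive to them near boundaries.
* Cross-study overlap treats a study as a set of called genes; it cannot
  model differing per-study power.
* The pipeline consumes allele-resolved counts and interval tracks; read
  alignment, SNP phasing and allele-splitting are upstream of its scope.
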