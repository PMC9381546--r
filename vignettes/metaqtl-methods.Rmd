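---
title: "Meta-QTL detection on a consensus map: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL detection on a consensus map: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaqtl)
```

## The problem

A QTL reported by one bi-parental study is a noisy interval estimate:
its position uncertainty depends on the mapping population's size and
on how much phenotypic variance the locus explains, and its coordinates
live on that study's private genetic map. Meta-QTL analysis asks
whether QTL reported independently for the same trait co-locate, and if
so, where the consensus locus is and how precisely the pooled evidence
pins it down. This package implements that workflow for compiled QTL
tables: consensus-map projection, CI re-estimation, per-chromosome
mixture/cluster modelling, physical anchoring, and marker validation.

## Coordinate transfer

Study maps are projected one by one onto a fixed, saturated reference
map (a *star* topology), rather than merged pairwise into an evolving
consensus. This is simpler, deterministic, order-independent, and
matches the practice of anchoring to a dense public SSR map. The
consensus frame *is* the reference frame; we make no attempt to
re-estimate map distances from genotype data.

Transfer uses the markers shared between a study map and the reference
on each chromosome. Because marker orders occasionally conflict (local
inversions, genotyping error), anchors are first filtered to a longest
subsequence whose reference positions strictly increase
(longest-increasing-subsequence on the reference coordinate). Ties are
broken toward the subsequence with the smallest total rank displacement
between source and reference order, then leftmost — a declared
convention; the literature is silent on conflict handling. Positions
are then mapped by piecewise-linear interpolation between bracketing
anchors. Beyond the terminal anchors we extrapolate with the terminal
interval's slope rather than clamping, so off-end QTL keep their
ordering; this is conservative in that it never collapses distinct
positions onto a chromosome end.

## Confidence intervals and the known-variance trick

Each QTL needs a 95% CI on the consensus map. Two sources exist:

* the study's reported interval `ci_end − ci_start`;
* the empirical Darvasi–Soller estimate `CI = 530/(N·R²)` cM, from the
  population size `N` and the variance explained `R²` (a proportion;
  percent inputs are auto-detected by the >1 rule, since source tables
  mix conventions).

The `ci_policy` argument chooses: `reported_first` respects the
original authors and recomputes only to fill gaps; `recomputed_always`
applies Darvasi–Soller to every QTL carrying `N` and `R²` (the
full-pipeline default, mirroring the meta-analysis practice of
harmonizing all CIs with one rule). A record with neither source is
flagged unusable at projection time — not at parse time, because a
partially-informative record is still worth retaining in the table.

A source-frame CI is transferred by multiplying with the local
expansion ratio λ = (consensus span)/(source span) of the anchor
interval containing the QTL; whether the original BioMercator-style
tools rescale or recompute on consensus coordinates is not documented,
so λ-rescaling is our declared convention. The Gaussian rule converts
CI to a standard deviation, σ = CI/3.92 (3.92 = 2 × 1.96); the factor
is stated explicitly because "Gaussian distribution rule" alone
under-determines it.

## The mixture model (dense chromosomes)

With `x_i` the projected positions and `s_i` the per-QTL standard
deviations, a chromosome with more than nine QTL is modelled as

x_i ~ Σ_k π_k N(μ_k, s_i²), k = 1..K,

with the `s_i²` **known**. Only K means and K−1 weights are free, so
the free-parameter count is ν = 2K−1 — the paper-style criteria
formulas need a ν and this is the honest one for known variances. EM
updates are closed-form: responsibilities z_ik ∝ π_k φ(x_i; μ_k, s_i²);
μ_k is the z-weighted inverse-variance mean; π_k the mean
responsibility. The likelihood is multimodal, so we run a
quantile-spread start plus nine seeded random restarts (10 total,
configurable) and keep the best; convergence is |ΔlogL| < 1e-8 or 500
iterations, and logL is asserted non-decreasing every iteration. All
randomness flows from one integer seed, so a fixed seed gives
byte-identical pipelines.

K is selected by vote among five penalized criteria (AIC, AICc, AIC3,
BIC, AWE; AWE's penalty is 2ν(1.5 + ln n), the standard form of that
criterion family; AICc is +∞ when n − ν − 1 ≤ 0). Each criterion votes
for its argmin over K = 1..min(K_max, n) (K_max defaults to 10 to bound
runtime); the chosen K is the smallest one with at least three votes,
falling back to plurality (ties toward smaller K). The full criteria
table, votes and rule are recorded in the decision log.

## The contiguous-cluster model (sparse chromosomes)

Nine or fewer QTL cannot support a 5-criterion mixture comparison, so
the ordered QTL are instead partitioned into k contiguous blocks
maximizing the Gaussian log-likelihood with block-wise inverse-variance
means. The optimum is found exactly by dynamic programming over block
boundaries (ties toward the leftmost boundaries), and k is chosen among
{1, 2, 3, 4, n} by C(k) = −2 logL + 2k ln n. The candidate set follows
the classical model-reduction method; the BIC-like penalty is our
declared choice — the original criterion's exact penalty is not stated
in the sources this design follows — selected for consistency at small
n. The chosen model is labelled "Model k" ("Model n" for the
one-block-per-QTL model).

Each component/block is summarized into an MQTL: position = weighted
inverse-variance mean (weights = responsibilities in the mixture
branch, 1 in blocks), σ_meta = (Σ w_i/s_i²)^(−1/2), CI = ±1.96 σ_meta,
weight = π_k or block share. Membership for reporting is by maximum
responsibility (ties toward the lower-index component). Peak marker =
nearest consensus marker; flanking markers = nearest markers strictly
outside the CI on each side (absent when the CI reaches the chromosome
end with no marker beyond it).

## Physical anchoring, genes, variants

Flanking markers are mapped to bp through a user-supplied marker table;
the MQTL physical interval is the closed 1-based interval between them
(argument order irrelevant) and its length is reported in Mb. Gene
extraction from a GFF3 annotation uses **overlap** (not containment)
against the closed interval — stated prominently because gene counts
depend critically on this convention — and ignores strand; annotations
listing minus-strand loci with reversed coordinates are normalized so
start ≤ end. Gene counts are only reproducible against the annotation
snapshot supplied; no remote database is consulted.

Class-distinguishing variant detection consumes a pre-computed multiple
alignment (we do not align) with each sequence labelled low or high.
Columns where both classes are internally unanimous and differ from
each other are reported; adjacent such columns merge into one variant,
typed indel when a gap is involved. Coordinates are 0-based alignment
columns, not reference bp, since gene-internal offsets depend on the
annotation used.

## Marker validation

The validation panel design is seven extreme-low plus seven
extreme-high genotypes by trait thresholds (defaults 12.50 g and
25.00 g of thousand-grain weight; in-between genotypes are excluded
and logged). The class-by-allele 2×2 table is tested with a two-sided
Fisher exact p computed by full hypergeometric enumeration — sum of all
same-margin tables whose point probability does not exceed the
observed's — because the sources report no test statistic; we declare
this standard one and additionally report the operative field evidence,
allele–class concordance. A marker is flagged validated when p < 0.05
and concordance = 1; the threshold choice is exposed to the user.

## The synthetic world

The generator emulates the statistical shape of a real grain-weight QTL
survey, so every stage is testable offline:

* 114 QTL from 22 studies over 12 chromosomes, allocated
  (8, 14, 22, 3, 14, 9, 5, 12, 9, 8, 6, 4) — chromosome 3 richest,
  chromosome 12 poorest; studies assigned round-robin so each
  contributes ~5 QTL (real surveys report 3–22 per study).
* Population sizes per study, uniform on [39, 353], with the two
  extremes pinned; R² ~ Beta(1.2, 5.68) rescaled to (0.004, 0.60),
  giving mean 0.108 (the Beta shape is our choice — only the range,
  mean and histogram shape are known); LOD ~ Lognormal(log 5.1, 0.6),
  giving P(LOD < 5) ≈ 0.49.
* True chromosome-3 MQTL at 39.5, 92.82 and 116.66 cM with weights
  proportional to 0.19/0.33/0.37 renormalized to sum to 1 (the
  published weights sum to 0.89, inconsistent with a unit-sum mixture;
  we enforce unit sum). Other chromosomes get evenly spaced components
  with equal weights, counts (4, 4, 3, 3, 4, 2, 3, 4, 3, 3, 4, 2).
* Observed positions ~ N(μ_k, s_i²) truncated to the chromosome by
  rejection, with s_i from the Darvasi–Soller rule — exactly the
  mixture the analysis fits. Reported CI bounds are clamped to the
  chromosome (an unclamped CI can exceed the chromosome length whenever
  R² is tiny, which is why positions, not CIs, are the truncated
  quantity).
* Study maps are subsets (60%) of a uniform 1 marker/cM reference grid
  with order-preserving 0.1 cM jitter; QTL positions are drawn in the
  consensus frame and used directly as study-frame positions, so
  projection adds only jitter-scale distortion — far below positional
  noise. Chromosome lengths follow typical rice consensus maps
  (83–181 cM).
* A fixed 14-genotype validation panel with extremes 9.50 g and
  37.27 g and a perfectly class-specific SSR (100 bp low / 85 bp high
  amplicons); toy genes tiled around each true MQTL position.

What the generator does **not** emulate: epistasis and linked-QTL
interference, study-specific ascertainment (publication bias toward
large effects), shared parents between studies, map-order errors larger
than local jitter, and real annotation density. A green end-to-end test
therefore establishes that the machinery recovers the generating
mixture under honest noise — not that any particular biological survey
is reproduced.

## Numerical choices and degenerate inputs

EM tolerance 1e-8 on logL; weights floored at 1e-12 and renormalized;
responsibilities computed in log space (log-sum-exp). K = 1 bypasses EM
for the closed-form inverse-variance mean. DP ties broken leftmost with
a 1e-12 slack; criterion ties toward smaller K everywhere. A chromosome
with a single QTL returns that QTL as its own MQTL unchanged. Anchor
intervals of zero source span raise a degenerate-interval error rather
than producing infinite expansion.

## Known limitations

* The mean-recovery accuracy of the mixture branch degrades when
  component gaps shrink below ~5× the median per-QTL σ; with heavily
  overlapping components, occasional ~10 cM displacements of a
  component mean are genuine maximum-likelihood optima, not fitting
  failures. The package reports the criteria table so such cases can
  be audited.
* λ-rescaling of CIs and the 2k ln n cluster penalty are declared
  conventions, not reconstructions of any specific legacy tool's
  numerics; results will differ from BioMercator in detail.
* SNP-linked QTL re-anchored to "closest" SSR markers use nearest-bp
  as the closeness rule — an interpretation, exposed, not a standard.
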