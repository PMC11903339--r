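---
title: "Statistical methods for optical pooled screen profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for optical pooled screen profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscreen)
```

## The problem

In an optical pooled CRISPR screen, every cell carries one guide RNA whose
identity is read out *in situ* by cycle-wise fluorescent sequencing of a
barcode, while five-channel fluorescence imaging (nucleus, endoplasmic
reticulum, actin, mitochondria, Golgi/membrane) yields thousands of
quantitative morphological features per cell. The analysis task is to turn
tens of millions of barcode-assigned single-cell feature vectors into
gene-level statements: which knockouts change cell morphology at all, in
which subcellular compartment the change concentrates, and which genes
produce mutually similar profiles. `morphoscreen` implements that
post-imaging statistical pipeline together with a synthetic screen
generator, so every stage can be exercised and validated at desk scale
without the multi-terabyte imaging data.

## Profile processing

Single cells are median-aggregated per guide within each plate, because the
median is robust to segmentation failures and dying cells. Each plate's
guide profiles are then standardized feature-by-feature (center = mean,
scale = population standard deviation, denominator $n$), which removes
plate-level staining and illumination offsets; a feature that is constant
within a plate cannot be scaled and is set missing there. Feature selection
then removes features with missing values, features with near-zero
variance (s.d. $< 10^{-8}$), and redundant features: while any pair of
retained features has $|r| > 0.9$, the member of the worst pair with the
larger mean absolute correlation to everything else is dropped. This
greedy rule guarantees the advertised bound (the retained set's maximum
$|r|$ is at most the threshold) and is idempotent, two properties the test
suite checks by exhaustive recomputation. Guide-level profiles are the
median over plates; gene-level profiles the median over a gene's guides.

For correlation-based analyses (complex benchmarking, clustering, merged
heatmaps), gene profiles are first projected onto the smallest set of
principal components reaching 90% cumulative explained variance; this
suppresses the noise floor spread across hundreds of weakly informative
features while keeping nearly all structure.

## Hit calling

For each gene, every feature's distribution over the gene's guide-level
profiles is compared with the nontargeting guide profiles by a two-sided
Mann-Whitney U test. The test is exact whenever the smaller group has at
most 8 units and the feature has no ties, and a tie-corrected normal
approximation with continuity correction otherwise. Because thousands of
4-versus-601 comparisons reuse the same null distribution, the exact U
distribution is computed once per group-size pair by a Gaussian-binomial
dynamic program and cached; the suite verifies it against full enumeration
at small sizes and against `stats::wilcox.test`/`pwilcox` elsewhere.

The **profile score** of a gene is the count of features with $p < 0.001$;
the **morphological signal score** is $\sum_i -\log_{10} p_i$ over those
significant features (base 10 chosen and recorded, since a rank statistic
in log units is only defined up to base). Per-compartment scores count the
significant features among one channel's texture, intensity, correlation,
radial-distribution and granularity measures; a two-channel correlation
feature belongs to both of its channels.

Two nested controls mirror the screen's design. Nontargeting guides are the
*test* control arm. False-discovery control instead uses the guides
targeting unexpressed (zero-TPM) genes: those knockouts cannot produce a
gene-specific phenotype, so their profile scores sample the score noise
floor, including any nonspecific consequences of CRISPR cutting. The hit
threshold at FDR $f$ is the empirical order statistic at rank
$\lceil (1-f)\,m \rceil$ of the $m$ null scores, with hits strictly above
it — a rule that guarantees at most a fraction $f$ of the null genes can be
flagged, with no distributional assumptions. Each compartment uses its own
null threshold computed from the same zero-TPM genes' per-channel scores
(the alternative — reusing the whole-cell threshold — would be
miscalibrated because compartment scores live on a smaller scale). A gene
can be a compartment hit without being a whole-cell hit.

## Profile strength (mAP)

Replicate retrieval quantifies profile strength: each of a gene's $M$
guide profiles queries the pool of its $M-1$ siblings plus $N$ control
profiles, ranked by cosine similarity, and non-interpolated average
precision accumulates $P_k \, \Delta R_k$ at sibling ranks with
$P_k = \mathrm{TP}_k / k$ and $R_k = \mathrm{TP}_k / (M-1)$; mAP is the
mean over the $M$ queries. We take the recall increment as
$\Delta R_k = R_k - R_{k-1}$, which is the only sign convention under
which average precision is nonnegative (recall is non-decreasing in rank).
Similarity ties are broken by stable input order and recorded as such.
Nontargeting guide profiles serve as the control pool.

## Barcode library design

Guide barcodes are read over 12 sequencing cycles, so the designer
constrains only the first 12 bases: greedy first-fit selection from a
(seeded-shuffled) candidate pool accepts a barcode only if its 12-base
prefix has Levenshtein distance $\ge 2$ to every accepted prefix and its
11-base prefix is distinct from all accepted ones (complete deconvolution
in 11 bases). Distance $\ge 2$ makes every single substitution detectable,
so the decoder is deliberately detect-only: a read is assigned only on an
exact prefix match, and a corrupted read can never be silently assigned to
the wrong barcode — the suite proves this over all $500 \times 12 \times 3$
single substitutions. Distance 2 cannot guarantee *correction*, so no
nearest-neighbour rescue is attempted. "Balanced per-position composition"
is quantified, absent a published number, as keeping each base's frequency
within [0.15, 0.40] per position; the band is enforced softly (a candidate
is skipped only if it would push a base it contributes to above the upper
bound, and only once 25 barcodes are accepted — a hard lower bound is
arithmetically unsatisfiable for small accepted sets).

## The synthetic screen generator

`generate_screen()` emulates the statistical structure the analysis relies
on, not images. Its defaults are fixed at the screen conditions the
pipeline is meant for: 4 guides per gene, 601 nontargeting guides, 125
cells per guide on average with negative-binomial size 0.15 (fitted once to
per-guide mean 125 / s.d. ≈ 330, equivalently per-gene mean ≈ 500 /
s.d. ≈ 650), guide activity probability 0.9 (a high-efficiency Cas9 clone;
lower it to ~0.6 to emulate a poorly editing line), five channels, and
eight granularity sizes per channel. Values no study states were chosen
once on realism grounds and not revisited: 200 genes at desk scale, 25%
zero-TPM genes, 10% hit genes (matching the order of hit rates genome-wide
screens report), planted effect size 0.5 cell-level standard deviations per
feature (root-mean-square), compartment specificity 0.55 so that the
primary channel holds a plurality — not a totality — of a hit's signal,
plate offsets of 0.2 s.d., and within-channel noise correlation 0.3 to
create the redundancy feature selection must remove.

Hit genes are grouped into co-functional modules of 2–6 genes that share an
effect direction up to a small angular jitter; 10% of a module's members
are sign-flipped to emulate inhibitory pathway members that anticorrelate
with the rest (phenocopying dominates within real protein complexes, which
is why the default fraction is small). One designated module carries the
lysosome-acidification signature: a coordinated shift of Golgi/membrane
(WGA) granularity mass away from the finest structure size into larger
ones. Granularity features are generated compositionally — per channel, a
softmax over logits times a fixed total — so every cell conserves total
granularity mass to machine precision, the property that makes
"up at one size, down at another" a structural fact rather than a
statistical accident. Inactive guides draw exactly the null distribution
(the cleanest model of Cas9 failure), and an off-by-default flat "cutting
effect" can be added to all targeting guides, including zero-TPM genes, to
probe what the zero-TPM null is for.

`generate_annotations()` derives complex-style groupings, 0–999 link
scores (a monotone noisy transform of effect-vector $|\cos|$), GMT gene
sets, expression and dependency scores from the same planted truth, so
benchmark analyses have a known answer.

What the generator does **not** emulate: spatial neighbourhoods and
cell-density effects, segmentation artefacts, feature distributions with
heavy tails (noise is Gaussian by assumption — the real screens' per-feature
noise family is not published), barcode-calling errors upstream of the cell
table, and correlated guide dropout (per-guide counts are independent
negative binomials, which at the default dispersion leaves roughly a third
of guides with no cells; real screens distribute dropout less brutally).
Passing tests therefore certify the statistical machinery — calibration,
bounds, monotonicity, recovery of planted structure — not performance on
real imaging data.

## Numerical and design choices

- Population (denominator-$n$) standard deviation for standardization,
  matching the standard scaler convention of profiling workflows.
- "Missing values" rule: a feature missing on *any* plate is dropped; with
  per-plate standardization a feature constant on one plate is unusable for
  cross-plate comparison. Configurable.
- Complex retention compares the hit fraction with 1/3 after exact
  arithmetic (2 of 6 members passes), read as the fraction of a complex's
  subunits among hit genes.
- Correlation bins span [−1, 1] with right-closed edges regardless of the
  observed range, so bins are comparable across screens.
- Ward clustering (`ward.D2`, the variance-minimising form equivalent to
  the common SciPy implementation) runs on Euclidean distances between
  correlation-matrix rows; leaf order is the dendrogram order with ties
  resolved by input order, and no optimal-leaf-ordering is applied (the
  reference procedure does not state one). In diagonally merged comparative
  heatmaps, one screen's clustering fixes the order for both; the two
  triangles jointly lose no information (either input is reconstructible on
  the shared genes).
- Degenerate inputs fail loudly: plates with one profile, zero-norm
  profiles in cosine similarity, zero-variance genes in correlation
  matrices, empty null sets, and mixed-length barcode libraries are all
  errors, while zero-cell guides and genes with fewer than two scored guide
  profiles are kept visible (0 rows, `NA` scores) rather than silently
  dropped.
- Single-feature screens reuse the hit-calling rank test on one feature
  (two-sided, for consistency), extend the top list through ties at rank
  20, and report one-sided Fisher enrichment with Benjamini–Hochberg and
  an additional Bonferroni column side by side.

## Problem sizes used in validation

The acceptance-style checks run at sizes chosen to be decisive yet quick on
one core: FDR calibration on a 2,000-gene screen with 500 zero-TPM nulls
and 601 nontargeting guides (~1.1 million synthetic cells); type-I error
over 10^6 null feature tests at 8-vs-30 units; feature selection on 200 ×
500 block-correlated profiles with exhaustive recomputation; barcode
guarantees on a 500-barcode library designed from 5,000 candidates with all
18,000 single substitutions enumerated; the mAP oracle on 1,000 random
instances; and planted-structure recovery (complex correlations,
granularity signature, recall monotonicity in effect size and coverage) on
60–120-gene screens.

## Limitations

Power at the default desk scale is deliberately moderate: with 125 cells
per guide and effect size 0.5 the pipeline recalls roughly two-thirds of
planted hits at 1% FDR, mirroring the regime where coverage, not the test,
limits sensitivity — the recall-versus-coverage monotonicity test makes
that dependence explicit. The empirical-null FDR guarantee is exact only
for the null set itself; genes with very low but nonzero expression can
still carry real signal and are not part of the null. The mAP module
reports the metric, not a permutation calibration of it (only the
permutation-null property is tested). GSEA, UMAP embedding and GO-DAG
handling are out of scope: the package emits their inputs (`.rnk` rankings,
PCA-reduced profiles, flat GMT sets) instead.
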