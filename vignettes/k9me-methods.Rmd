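---
title: "Methods: models, parameters and design choices in k9me"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in k9me}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical models, the parameters that matter, what the synthetic
data generator does and does not emulate, and the choices made where the
design was genuinely open. The worked numbers shown in the README are
produced by the code paths described here; nothing below states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The biological question and the pipeline shape

In worms, two histone methyltransferases write H3K9 methylation: MET-2
(H3K9me2) and SET-25 (H3K9me3, downstream of MET-2's me2). Loss of both
derepresses a set of tissue-specific genes in differentiated cells, but
expression and chromatin accessibility decouple: most derepressed genes
gain no promoter accessibility (Group A), a minority gain both (Group B),
and a large set of loci gains accessibility without expression (Group C).
Group membership correlates with nuclear-periphery association (DamID,
imaging). The pipeline implements each measurement arm of that design:

1. RNA-seq count normalization, exact differential testing, derepressed
   gene sets;
2. ChIC-seq window quantification against an MNase control, H3K9me domain
   calling, per-gene marking;
3. PWM scanning and promoter motif enrichment;
4. ATAC-seq Tn5 cut-site shifting, differential peaks, feature
   annotation, intergenic peak selection, Group A/B/C classification;
5. DamID bin ratios with group contrasts; 3D imaging with
   distance-to-periphery measurement.

All coordinates are 0-based half-open (BED-native) in every user-facing
table; GFF3 input is converted at the boundary. A single convention
removes off-by-one drift between seven interacting modules.

## Count models

**Normalization.** Column `j` of a count matrix is scaled by
`mean(totals) / totals[j]`, so all column totals equal the original mean
total. This is rank-preserving within columns and is reused verbatim for
window tracks, exon counts, peak counts and DamID bins, so every ratio in
the package sits on the same scale.

**The pseudo-count of 8.** Every log-ratio in the package is computed as
`log2((x + 8) / (y + 8))`. The pseudo-count damps fold-change estimates
at low counts (an empty window over an empty control gives exactly 1) and
is applied *after* averaging replicates — one transform per condition.
Applying it before averaging would change results only at very low
counts; one-per-condition is the simpler contract and is what the
fold-change definition in `de_test()` documents.

**Exact conditional-binomial test.** Differential calls use a two-sided
exact test on pooled scaled counts: conditional on `t = a + b`, `a` is
binomial with probability equal to the condition's replicate share, and
the p-value sums the probability of all outcomes no more likely than the
observed one (relative tolerance `1e-7` guards floating-point ties at the
mode). Pooled scaled counts are rounded half-up — a deterministic,
documented integerization. The test is intentionally fully specified and
oracle-verifiable; the cost is that it ignores biological overdispersion
and is therefore anti-conservative on noisy replicates. Two design
consequences follow:

* the derepression call couples the test with a fold-change floor
  (FDR < 0.01 *and* log2FC > 2), which in practice controls the
  false-positive rate even under NB dispersion 0.1 (measured on the
  synthetic world: background FPR ≤ 1%);
* calibration is asserted on a Poisson null world, where the test is
  exact (2,000 genes; fraction of FDR < 0.01 calls is ~0).

BH adjustment is the standard step-up procedure (`stats::p.adjust`);
the Wilcoxon rank-sum test similarly delegates to `stats::wilcox.test`
(exact when the pooled size is ≤ 12 without ties, tie-corrected normal
approximation with continuity correction otherwise; fully tied samples
return p = 1).

**Thresholds.** The derepression default is log2FC > 2 (16-fold). A
linear "FC > 2" reading of the same cut is also defensible; the threshold
is an explicit argument of `call_derepressed()` so either convention is
one keystroke away.

## ChIC-seq

Windows are 500 bp, non-overlapping, final window truncated. A fragment
increments every window it overlaps by ≥ 1 bp (any-overlap; symmetric and
testable against a per-base oracle — window counts therefore sum to at
least the fragment count, with equality iff no fragment spans a
boundary). The ratio track is `(mean scaled antibody + 8) / (scaled
control + 8)`. Domains are maximal runs of at least `min_run = 2`
consecutive windows above `fc_min = 2`; both knobs are exposed because
"consecutive enrichment" fixes neither. The per-gene statistic counts
fragments overlapping any exon (once per gene), and `marked` uses the
same threshold of 2.

**Enrichment attenuation — why the generator's silenced fraction is
moderate.** With equal-total library scaling, a mark emitted at rate `r`
inside domains covering fraction `f` of the genome yields an observable
in-domain ratio of `r / (1 + (r − 1) f)`, not `r`: the antibody library
has nowhere else to come from, so a large domain fraction compresses the
ratio toward 1. At the generator's `r = 8`, domains must cover ≲ 15% of
the genome for in-domain windows to clear the calling threshold of 2 with
headroom (`f = 0.15` gives ≈ 3.5). The default world therefore plants 60
silenced genes (of 300) with 250-bp domain padding. The same algebra
explains why the DamID absolute log-ratio under-shoots the planted bias
when biased bins are dense; the scientific claim defended there is the
*contrast* between groups, which scaling cannot invert.

**Genotype emission rules.** H3K9me2 requires MET-2 (present in WT and
*set-25*); H3K9me3 requires both writers (present in WT, emitted at half
the in-domain excess in *met-2* to emulate partial maintenance, absent in
*set-25* and the double mutant); H3K27ac appears at Group B/C promoters
only in the double mutant. These rules are the generator's encoding of
the genotype logic, not estimates of rates.

Arm/centre annotation ships the worm border coordinates (chromosome 1:
3,745,632 / 10,809,938, etc.). Chromosome X is printed with a single
border; it is treated as a left-arm/centre split (positions at or beyond
the border are "centre"), and custom border tables are accepted for
other assemblies.

## Motif analysis

Scores are direct sums of matrix entries at matched bases — the matrices
are taken at face value, not converted to log-odds, because the
threshold rule ("minimum score of ten, or the maximum obtainable score if
lower") only makes sense on the matrices as distributed. Both strands are
scanned (the reverse-complement matrix over the forward sequence), hits
are reported in forward coordinates, and any window containing `N` is
disqualified — a conservative choice where the convention is unstated.

Enrichment for a gene set compares per-promoter hit rates:
`log2((rate_set + ε) / (rate_all + ε))` with `ε = 1/|universe|` so
zero-rate motifs stay finite, against `log2(total genomic hits + 1)` as
abundance. Open conventions resolved here: abundance counts *genomic*
hits (the x-axis is genome-wide occurrence; promoter-restricted counting
is available by passing promoter totals); per-promoter counting is
site-count-weighted (the number of sites, not a binary flag); overlapping
hits of one motif all count. The same statistic serves arbitrary region
sets (e.g. newly accessible intergenic peaks) via
`motif_enrichment_regions()`.

The generator plants each of three motif consensi twice in every
derepressible promoter, at fixed offsets upstream of the TSS, and keeps
three never-planted decoys. Motif weights (1.2 per consensus base over
L = 12) were chosen once so that a random genome yields several hundred
genome-wide hits — enough to clear the abundance gate while keeping the
background promoter rate low enough that two planted copies roughly
double the set rate. Very rarely, insertions from adjacent
divergently-oriented derepressible genes can overwrite one another; the
affected copies simply revert to background and the recorded truth table
is what the substring checks verify.

## Accessibility and gene groups

The Tn5 shift maps a `+` fragment to `start + 4` and a `-` fragment to
`(end − 1) − 5` — the anchor for the minus strand is the last covered
base, a convention the coordinate contract makes explicit (the
alternative anchor is a two-line change and is covered by the unit
tests' expectations). Cut sites are single-base positions; counting uses
those, which is the entire point of the correction.

Feature annotation resolves multi-label peaks by precedence
promoter > repeat > exon > intron > intergenic (the classes are reported
in the source design without a tie rule; the order is exposed as an
argument). Class percentages are reported relative to genome-wide base
fractions computed under the same precedence, so the two sides of the
ratio share one definition. Intergenic peaks are > 1.5 kb from any
promoter (1 kb/100 bp definition) with zero repeat overlap.

Groups: A = expression-up only, B = both, C = accessibility-up only,
with expression-up at FDR < 0.01 & log2FC > 2 and accessibility-up at
FDR < 0.01 & log2FC > 0. Classification is a pure function of the two
differential tables.

## Imaging

The renderer builds one nucleus per scene: a filled sphere (envelope
channel) and Gaussian foci at subvoxel centres (focus channel), with
Poisson shot noise plus Gaussian read noise of SD `focus_amp / snr`.
Truth distances are analytic: `radius − |focus − centre|` in physical
units, so anisotropic voxels are handled exactly by construction.

Analysis: (1) Otsu threshold on the Gaussian-smoothed envelope channel
(the between-class-variance maximum ties across the whole intensity gap
of a well-separated mixture; the plateau middle is taken); (2) seeds are
local maxima of the smoothed image — flat-top plateaus are merged into
one seed per connected component, then greedy non-maximum suppression
removes seeds within `4 × smooth_sigma` (physical) of a stronger one;
(3) labels grow by priority flooding (voxels claimed in order of
decreasing smoothed intensity from labelled 26-neighborhoods), a seeded
watershed; (4) foci are local maxima of the scale-normalized negative
Laplacian of Gaussian above a quality floor, at voxel resolution — no
subvoxel fit, so localization error is bounded by half a voxel per axis
and the end-to-end distance error budget is one voxel spacing;
(5) distances come from an exact anisotropic Euclidean distance
transform (Felzenszwalb's separable lower-envelope algorithm over squared
distances, physical spacings per axis), read at each focus voxel. Foci in
background are excluded, matching the rule that foci outside a nucleus
are ignored. A boundary foreground voxel is one spacing from background
by this definition, which fixes the sign convention at the boundary.

## Determinism and problem sizes

Every simulator draws from a seed derived deterministically from the
config seed and a stage tag, so stages can be re-run in any order and the
whole pipeline is byte-identical under a fixed seed (asserted by
serializing the full result list twice).

Reference problem sizes, chosen once as desk-scale defaults: 3 × 300 kb
chromosomes, 300 genes (60 muscle / 30 derepressible / 30 silenced-stable
/ 180 background), 3 replicates, NB dispersion 0.1, 90k ChIC fragments
per sample, 10-kb DamID bins at baseline 200 with 3 replicates, 48×48×24
stacks at 0.1×0.1×0.2 units with 2 foci per nucleus at SNR 10. The null
calibration world uses 2,000 Poisson genes; the imaging recovery check
renders 20 nuclei; oracle checks run exhaustively at small n (all pooled
counts ≤ 30 for the exact test, ≤ 32³ masks for the distance transform,
1,000 random tracks for domain calling).

## What the generator does and does not emulate

It emulates: overdispersed counts with library-size variation; the
four-genotype derepression pattern (including *set-25* ≈ WT); domain-
confined mark emission with an MNase control; planted promoter motifs;
the A/B/C accessibility split with promoter and intergenic peaks;
periphery-biased DamID bins; and realistic two-channel nucleus stacks
with exact truth geometry.

It does not emulate: read-level artifacts (quality, mappability,
duplication), realistic worm karyotype or sequence composition (the
genome is uniform-random, so PWM hit rates are cleaner than in a real
genome), spatial autocorrelation of chromatin marks beyond planted
domains, partial or nested domain structure, cell-type mixtures, or
optical aberrations beyond Poisson+Gaussian noise. Passing the recovery
tests therefore demonstrates that the implementations measure what they
claim under known truth — not that the defaults describe real data. The
exact test's behaviour on strongly overdispersed real replicates remains
its documented limitation.
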