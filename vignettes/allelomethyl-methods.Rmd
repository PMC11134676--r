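---
title: "Methods: haplotype-resolved methylation and allelic expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved methylation and allelic expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(allelomethyl)
```

# The problem

In an allodiploid plant — a hybrid carrying one complete chromosome set
from each parental species — every gene exists as a pair of alleles, one
per subgenome. With haplotype-resolved assemblies, per-cytosine
methylation calls and replicated RNA-seq for both haplotypes, one can ask
how allelic expression divergence relates to allelic methylation
divergence. This package implements that analysis at desk scale, together
with a simulator that plants known truth so that every stage can be
validated quantitatively.

# Cytosine contexts

Plant cytosine methylation is analysed in the CpG, CHG and CHH sequence
contexts (H = A, C or T), defined by the two bases immediately 3' of the
cytosine on its own strand. The classifier scans both strands: a G on the
plus strand is a cytosine on the minus strand whose downstream bases are
the complements of the two plus-strand bases to its left. Sites whose
trinucleotide is truncated by the sequence end or contains an N are
labelled `ambiguous` and excluded from all level computations. The two
strands of a symmetric CpG are deliberately kept as separate sites, which
matches the per-strand output of single-molecule methylation callers; no
strand merging is performed.

Positions are 0-based half-open internally; GFF3 (1-based inclusive) is
converted once at the IO boundary. Having a single conversion point is
what keeps a pipeline of interval operations free of off-by-one drift.

# Weighted methylation levels

All levels are pooled-count ratios, `sum(methylated) / sum(coverage)`
over the qualifying cytosines of a region and context, not means of
per-site fractions. The pooled ratio is robust to coverage heterogeneity
(a 2x-covered site does not get the same weight as a 60x site) and is
invariant to how reads are split across input rows, which the test suite
checks as a property. Duplicate site rows are pooled *before* the
minimum-coverage filter for the same reason.

Defaults: flank width 2000 bp (a 1 kb flank is equally supported through
the `flank` argument, since both conventions are common in metaplots);
minimum site coverage 4, a typical floor for single-molecule callers;
metaprofiles use 20 bins per flank and 40 proportional bins across the
gene body. Genes shorter than the bin count simply populate fewer bins
(each 1 bp site falls into exactly one proportional bin); they are not
skipped. Minus-strand genes are reversed so bin 0 is always farthest
upstream of the TSS.

# DMR calling

The caller is a deliberately transparent windowed test rather than a
smoothed dispersion-shrinkage model:

1. windows of 1000 bp slide at 500 bp steps; a window is tested when at
   least 5 cytosines of the context are covered (>= 4x) in both samples;
2. counts are pooled per window and compared with a two-sided
   two-proportion z-test with continuity correction (numerically equal to
   `prop.test`, verified in the tests); zero pooled variance (both
   samples fully methylated or fully unmethylated) gives p = 1 by
   convention;
3. Benjamini-Hochberg correction is applied across all tested windows,
   per context, because the three contexts are biologically distinct
   methylation systems and are analysed separately throughout;
4. significant windows (q <= 0.05, |delta| >= 0.1) with the same delta
   sign and gaps of at most one step are merged;
5. each merged span is refined on a 100 bp sub-window grid: a sub-window
   supports the region when its pooled delta has the region's sign and
   at least half the magnitude of the strongest same-sign sub-window
   (never below `delta_min`). Supporting sub-windows more than 500 bp
   apart split the span, and single-sub-window runs are discarded.
   Statistics of the final spans are recomputed from pooled counts; p and
   q are reported as the minimum over member windows.

Step 5 deserves justification. With 1 kb windows at 500 bp steps, a
merged span systematically overhangs the true differential region by up
to `window - step` on each side, and two nearby regions of the same sign
can be bridged through a quiet stretch; window-granularity boundaries
alone leave a large fraction of called bases outside the true region.
The sub-window refinement anchors its threshold to the *strongest*
sub-window rather than the span average precisely because the span
average is diluted by the overhang it is meant to remove. On the
benchmark below this brings stray bases from roughly a third of called
bases down to a few percent while leaving recovery at 100%.

Calibration caveat: the z-test assumes binomial counts. The simulator's
default beta-binomial overdispersion (rho = 0.05) makes the test
anti-conservative at the site level, which surfaces as occasional weak
false calls (|delta| just above `delta_min`) in overdispersed data. The
null-calibration benchmark therefore uses rho = 0 (binomial), which is
the sampling model the test is exact for; under overdispersion a
dispersion-aware model (the route taken by shrinkage-based DMR tools)
would be required for strict error control. Users comparing noisy real
samples should treat weak calls near `delta_min` with caution.

Annotation assigns each DMR exactly one category with priority
promoter > gene body > intergenic, where the promoter is the 2 kb
strand-aware region upstream of the TSS and any 1 bp overlap triggers a
category.

# Allele pairing

Anchors (homology hits with scores, e.g. alignment bit-scores; the
package does not run homology search) are chained per chromosome pair by
weighted longest-increasing-subsequence over gene ranks, trying both
orientations, extracting the best chain repeatedly so each anchor belongs
to at most one block. Chains need at least 5 anchors and rank gaps of at
most 25 — MCScanX-like scales. Within blocks, genes are paired with their
best-scoring in-block partner; ties break by smaller rank distance, then
lexicographic gene id; one-to-one matching is enforced greedily in
descending score order, and cross-block conflicts go to the longer block.
Greedy matching (rather than optimal bipartite matching) directly encodes
the "best homolog" rule; on collinear haplotypes the two coincide.
A canonical sort of the anchor table makes the whole procedure invariant
to input row order, which is tested as a property, and an exhaustive
enumeration oracle confirms the chain scores are optimal on small
instances.

# Expression filtering and allelic differential expression

Two filters precede any allelic comparison. Genes whose mean TPM is zero
in every tissue are discarded as non-expressed. Then, within each tissue
with positive mean, the replicate-consistency statistic
`d = (max - min) / mean` must stay below 0.5. The denominator is the
replicate mean — the least biased of the candidates (max, min, mean) when
the rule is stated only as "< 50% difference" — and the rule is applied
per tissue: a gene silent in one tissue is not penalised there. The
filter is idempotent.

A pair's fold change in a tissue is
`r = (max(mean_a, mean_b) + pseudo) / (min(mean_a, mean_b) + pseudo)`
with a pseudocount of 0.1 TPM, preventing division by zero and spurious
calls at trace expression; `r > 2` calls the pair `A_high` or `B_high`,
both-zero means give `not_expressed`, everything else `balanced`. Classes
are exactly antisymmetric under swapping the haplotype labels (tested).
Expressed-pair percentages are reported as `100 * expressed / total` to
two decimals.

At the default replicate noise (log-normal, sigma 0.2) the consistency
filter removes roughly a third of genes — the filter is doing real work
at realistic noise, and any recovery benchmark downstream is therefore
evaluated over the pairs that remain scorable after filtering; pairs
removed by the consistency filter are never scored at all.

# Integration

For every differentially expressed pair the methylation level of the
higher-expressed allele is put against that of the lower-expressed one,
per region (upstream / body / downstream) and context. The summary
reports, per tissue x region x context, the two means, a paired
one-sided Wilcoxon signed-rank p-value for "higher expression goes with
lower methylation" (a paired nonparametric test matches the paired-allele
design; no distributional assumption on levels), and the Spearman
correlation between the per-pair log2 expression ratio (high over low)
and the methylation difference. Pairs missing a level in a cell are
dropped from that cell only. Degenerate cells (all differences zero,
constant ranks, fewer than 3 pairs) report p = 1 for the Wilcoxon
convention and missing Spearman values. The per-cell means are exactly
recomputable from the emitted per-pair records (tested), and the
high/low orientation is invariant to relabelling the haplotypes.

The metric report is plain arithmetic: per-metric values of the two
haplotype assemblies and their mean to 3 decimals.

# The simulator

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once as realistic study conditions:

* two collinear haplotypes (same gene order; positions jittered
  independently), 60 gene pairs on 2 x 350 kb chromosomes, genes
  1-2.5 kb on either strand with >= 1 flank width of clearance;
* context means ordered CG > CHH > CHG (0.60 / 0.30 / 0.20 scale), with
  one haplotype slightly more methylated in flowers and the other in
  leaves (differences <= 0.03, well under the DMR effect sizes);
* methylation counts beta-binomial around the site mean with
  overdispersion rho = 0.05 and Poisson coverage around 30x — pure
  binomial is unrealistically tight for power studies;
* 8 planted flower-vs-leaf DMRs per haplotype (1 kb, |delta| 0.25),
  placed in intergenic space at least 3 kb apart (`dmr_margin` 1500 bp):
  distinct planted regions must be separated by more than the caller's
  window + step resolution, otherwise adjacent truth regions are
  operationally one region and "recovery of 50 distinct DMRs" is not
  well defined;
* 20% of pairs with planted >= 2-fold allelic divergence (log2 fold
  drawn from 1.5-3), TPM log-normal with sigma 0.2 per replicate, 10% of
  pairs silent everywhere;
* a negative methylation-expression coupling: for a coupled pair the
  allelic promoter methylation difference is the log2 expression ratio
  divided by `meth_expr_slope` (default -6 log2 units per methylation
  fraction), with the gene-body difference at 0.6 of the promoter
  difference and no coupling downstream. With slope 0 the planted
  expression divergence is independent of methylation, giving a true
  null for the integration test;
* anchors for every true pair (scores 500-1500) plus 10% decoy anchors
  with random partners and lower scores (50-300), exercising the
  chaining;
* contexts are realised from the actual simulated sequence, so the
  context caller is validated against the same genome the calls refer
  to, and a truth bundle (planted DMRs, planted DE pairs with direction
  and fold, per-gene true levels per region/context/tissue, coupling
  slope) round-trips losslessly through TSV.

Stored truth values are rounded to 6 decimals at creation so that the
written files are bit-exact on re-reading. A fixed seed makes every
emitted file byte-identical across runs.

What the simulator does *not* emulate: sequence homology between
haplotypes (anchors are tabulated, not aligned), repeats and TEs,
CHH-island structure, mapping bias, chromatin state, or any raw signal
level process. Passing benchmarks on these data therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated sampling models — not performance on the full complexity of real
plant methylomes.

# Benchmark problem sizes

The end-to-end checks run at sizes chosen for statistical decisiveness:

* null calibration: 3 simulations of a 1 Mb genome (about 2000 CG
  windows each), binomial sampling, identical tissue means;
* DMR recovery: 3 simulations with 50 planted 1 kb regions each
  (delta 0.3, 30x), evaluated in the CG context (the densest) at 50%
  reciprocal overlap, plus the fraction of called bases outside planted
  regions;
* allelic DE: 3 simulations of 200 pairs (20% planted), sensitivity and
  false-call rate over scorable pairs;
* integration: 3 simulations of 200 pairs with 40% planted divergence —
  at the default 20% only ~10 DE pairs per tissue survive filtering,
  too few for a stable rank correlation, so the coupling benchmark
  raises the planted fraction and pools the two tissues per region,
  giving ~60 pairs per test; the per-tissue correlation sign is checked
  as well. The null (slope 0) uses the same sizes.

# Known limitations

* The DMR test is binomial; overdispersed data make it anti-conservative
  (see above). Between-replicate biological variance of methylation is
  not modelled at all — the caller compares two pooled samples.
* Boundary refinement resolution is `refine_bp` (100 bp); boundaries
  inherit that granularity.
* The expressed-pair definition counts any positive mean TPM as
  expressed (`expressed_min = 0`); stricter floors change the reported
  coverage percentages.
* The two-sample DMR contrast is generic: the caller does not know
  whether the samples are tissues within a haplotype or the two
  haplotypes; the pipeline config names the contrast explicitly.
* Greedy one-to-one pairing can differ from optimal bipartite matching
  on tangled (non-collinear) anchor sets; for the collinear-haplotype
  use case they agree.
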