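---
title: "scbav: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scbav: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbav)
```

## The problem

Time-series single-cell RNA-seq of a differentiating tissue — the
motivating system is the peri-implantation conceptus, where multipotent
trophoblasts segregate into sublineages — poses two linked questions:
*when* does a cell-fate split happen, and *which gene drives it*? scbav
answers both with a deliberately simple, fully seeded pipeline: a
cluster-linkage lineage tree locates the split, and a two-criterion
statistical screen nominates upstream regulators. The screen rests on a
hierarchical picture of fate control: a driver gene becomes
heterogeneous (bimodal) across the parent population just before the
split, and its two modes resolve into the two daughter lineages after
it. Neither criterion alone suffices — plenty of genes are noisy before
a split, and hundreds are differentially expressed after one — but their
conjunction is rare.

## Pipeline and model assumptions

**Normalization.** Counts are library-size scaled and log-transformed,
$v = \ln(1 + s\,x/\mathrm{total})$ with $s = 10{,}000$. Every cell must
have a positive total; a zero-total cell is reported by name rather than
silently dropped.

**Highly variable genes.** Each gene's dispersion (variance/mean of the
log-normalized values; 0 for zero-mean genes, avoiding 0/0) is
standardized within 20 equal-frequency bins of mean expression, so that
lowly and highly expressed genes compete only against abundance-matched
peers. The embedding uses the top decile of genes by this z (capped at
2,000, which reduces to the field-standard 2,000 genes on a whole
transcriptome). The decile choice matters: with a compact gene panel an
all-gene embedding is dominated by noise dimensions, and the
per-timepoint cluster-number selection below becomes sensitive to
single-cell outliers; restricting to the top decile concentrates the
structure and makes the recovered cluster-number sequence markedly more
stable on the default simulation.

**Embedding.** Genes are centered and unit-scaled (scaled values clipped
at ±10 standard deviations, the usual guard against one cell dominating
a component), and all cells from all timepoints are embedded jointly by
PCA. The embedding keeps the smallest $N$ with cumulative explained
variance at least `var_threshold` (default 0.40). The 40% rule is a
method constant, not a tuning knob; "total variation" is computed on
the scaled data, where every gene contributes equally.

**Cluster number per timepoint.** The Gap statistic in Tibshirani's
original formulation: $W_k$ is the pooled within-cluster sum of squared
distances from seeded K-means (Hartigan–Wong, 25 random restarts, 300
iteration cap; base R has no k-means++ initializer, and with 25 restarts
on these problem sizes the converged optimum is the same);
$\mathrm{gap}(k) = \overline{\log W^*_k} - \log W_k$ over $B = 50$
reference sets drawn uniformly over the bounding box of the timepoint's
coordinates, $s_k = \mathrm{sd}(\log W^*_k)\sqrt{1 + 1/B}$, and
$k^\star$ is the smallest $k$ with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$. Note that
`cluster::clusGap`'s *default* uses unsquared distances (`d.power = 1`);
the squared-distance mode (`d.power = 2`) reproduces our $\log W_k$ up
to the constant $\ln 2$ and the same $k^\star$, which is exactly what
the cross-check test asserts. `kmax` defaults to 6 — real data here show
at most three subpopulations per day, so 6 leaves headroom without
inviting pathological splits.

**Tree linking.** Each cluster at timepoint $t+1$ attaches to the
cluster at $t$ whose centroid has the highest Pearson correlation with
its own. The direction matters: a parent picking its single best child
can never produce a two-child node, so bifurcations require the
child-picks-parent direction (as in the SCUBA family of methods). With
an embedding of ≤2 components a correlation over coordinates is
meaningless, so similarity falls back to negative Euclidean distance;
ties attach to the lowest-numbered parent and are logged. Cluster labels
within a timepoint are canonicalized by centroid order, so results do
not depend on cell order.

**Regulator screen.** Criterion (1), consistency: Wilcoxon rank-sum per
gene between the two branches' cells (all tree descendants of each child
node) at *every* shared post-bifurcation timepoint, BH-adjusted across
genes within each timepoint; a gene passes at level α (default 0.05)
only if significant at every shared timepoint with the same fold-change
direction. A pooled test was rejected: "consistently" means
per-timepoint agreement, and the pooled version is fooled by a
sign-flipping gene. Criterion (2), pre-split variability: the same
bin-standardized dispersion as HVG selection, computed on the parent
node's cells only; a gene passes if it ranks in the top `var_quantile`
(default 10%). The DE rank orders by worst adjusted p across timepoints,
ties by smallest absolute log2 fold change (larger wins) — rewarding
genes strong at all timepoints; the combined rank is the worse of the
two ranks, ties by rank sum then gene id. Log fold changes use a
pseudocount of 1 on de-logged means. Events with more than two children
are screened per child pair.

**Small-sample tests.** The Wilcoxon implementation uses mid-ranks, the
exact null distribution when the pooled size is ≤16 with no ties, and
otherwise the normal approximation with tie-corrected variance and
continuity correction; p-values are clamped to (0, 1], and a
zero-rank-variance comparison (all values tied) returns p = 1. "Adjusted
p" is Benjamini–Hochberg throughout — the field default for scRNA-seq
DE. Marker enrichment is the hypergeometric upper tail
$P(X \ge k)$ computed through the distribution function (log-space
internally), with the universe defaulting to the genes tested in the DE
step. One caution surfaced by testing: BH is *not* idempotent on spread
inputs (BH of (0.2, 0.6) is (0.4, 0.6); BH of that is (0.6, 0.6)); the
suite asserts order preservation, which is the property that matters.

**Lineage scoring.** Module scores follow the control-gene convention:
genes are binned by mean expression into 25 equal-frequency bins, each
marker gene draws 100 control genes from its own bin (without
replacement when the bin allows, else with replacement and a warning),
and a cell's score is its marker mean minus control mean. The score is
invariant to adding a constant to all genes of one cell. All marker sets
share one control-sampling seed so that the lineage call cannot depend
on the order the sets are supplied in; exact ties go to the first-listed
set with a flag. Pure argmax is used — no score threshold — since any
threshold would be an extra, unjustified parameter. The
maintained-marker filter applies its threshold to per-timepoint means in
whatever unit the matrix carries; the default of 10 corresponds to the
conventional mean-FPKM cutoff, so supply FPKM if that is the rule you
want.

## The simulator

`simulate_bifurcation()` emulates the structure the method assumes:
negative-binomial counts (dispersion 0.2) with gamma(0.6, scale 2)
baseline gene means and log-normal library sizes (meanlog ln 5000,
sdlog 0.3); four timepoints × 100 cells; three lineages at fixed
proportions (TE 80%, EPI 10%, PE 10% — a dissociated conceptus is mostly
trophoblast) with 50 markers per lineage elevated 4-fold in their own
lineage's cells; one split of the TE compartment after timepoint 2 into
50/50 branches; 200 branch-DE genes at log2 effect 1.5; and one
regulator gene that is a 50/50 two-component mixture (modes ±1 log2) in
TE cells at the bifurcation timepoint and shifts ±2 log2 per branch
afterwards.

Three baseline choices are deliberate. Branch-DE genes draw their
baseline means from the top 30% of the gene-mean distribution: a planted
fold change on a near-zero-mean gene is not observable in counts (with
pseudocount fold changes, the empirical mean log2FC of DE genes planted
across all means compresses to ~0.95 instead of the intended 1.5).
Markers draw from the upper half, and the regulator sits at the 95th
percentile — a robustly expressed transcription factor, which is the
kind of gene the screen is designed to find; a bimodal switch on a
weakly expressed gene is statistically invisible at 80 parent cells. The
`null` preset zeroes every planted effect while keeping the nominal
labels, so false-positive behaviour can be calibrated;
`three-cluster` gives equal lineage proportions with no branch
structure. `truth_tree()` reconstructs the planted tree directly from
the truth, which is how the screen is calibrated on null data (where the
trajectory, correctly, finds nothing to screen).

What the simulator does **not** emulate: batch effects, doublets,
cell-cycle structure, gene–gene correlation beyond the planted blocks,
dropout beyond what the NB at low means produces, or continuous
(gradual) fate transitions — the planted split is instantaneous. Passing
tests on this substrate therefore show that the method recovers the
structure it models, not that it is robust to everything real data can
do.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
default study conditions (400 cells × 2,000 genes) over 20 seeds for the
recovery checks, 10 seeds for lineage assignment, and 20 seeds for null
calibration; unit tests use smaller instances (40 cells per timepoint,
300 genes) of the same generator. Every stochastic step — simulation,
reference draws, K-means restarts, control-gene sampling — flows from an
explicit seed, and seeded functions restore the caller's RNG state, so
whole-pipeline runs are bit-reproducible.

## Known limitations

- The child-picks-parent linkage forces every cluster into the tree; a
  genuinely disappearing population will still be attached somewhere.
- The Gap statistic with box references oversplits heavy-tailed clusters
  when the embedding carries many noise dimensions; the decile HVG
  default mitigates but does not eliminate this (an occasional singleton
  cluster of one outlier cell can still appear at a post-split
  timepoint).
- The screen tests each bifurcation independently and pairwise; it makes
  no claim about regulatory mechanism, only about the statistical
  signature of one.
- Lineage calls are pure argmax: a cell far from all marker profiles is
  still assigned to its least-bad lineage (the tie flag, not a quality
  score, is the only caveat raised).
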