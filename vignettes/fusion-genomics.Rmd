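---
title: "Distinguishing tumor genomes from tumor-leukocyte fusion genomes in single cells"
author: "ctcfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing tumor genomes from tumor-leukocyte fusion genomes in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcfusion)
```

## The problem

Rare-cell liquid biopsy assays find circulating cells that co-express
cytokeratin (CK, an epithelial/tumor marker) and CD45 (the pan-leukocyte
marker). Two hypotheses compete for such double-positive cells: they are
tumor cells that have acquired an immune-like expression state, or they are
tumor-leukocyte hybrids formed by cell fusion. Single-cell copy-number
profiles can separate the hypotheses, because fusion has an unavoidable
genomic signature.

A copy-number profile here is a vector of per-bin read counts over a few
thousand variable-length genomic bins, GC-corrected and divided by the
genome-wide mean, so that ratio 1 corresponds to baseline ploidy. In a
near-diploid tumor cell, a one-copy gain sits at ratio $3/2 = 1.5$ and a
one-copy loss at $1/2 = 0.5$. If a full diploid genome is added by fusion,
the same segments move to $(3+2)/4 = 1.25$ and $(1+2)/4 = 0.75$: every
alteration's amplitude is *compressed* toward 1 (`expected_ratio()`
implements this arithmetic). A cell whose profile shows the full amplitudes
of the clonal alterations cannot be carrying an extra diploid complement.

## The attenuation statistic

Visual comparison of profiles is formalized as a single number. Let $r$ be
the clonal reference ratio at each bin (the segment mean of a consensus
tumor profile) and $q$ the query cell's ratio. Over bins falling in
non-neutral reference segments (called state $\ne 2$), the attenuation is
the least-squares slope through the origin

$$ a \;=\; \frac{\sum_b (r_b - 1)(q_b - 1)}{\sum_b (r_b - 1)^2}. $$

Under the tumor hypothesis $E[q_b] = r_b$ and $a \approx 1$; under a 1:1
fusion with a diploid cell at equal per-genome depth $q_b - 1 \approx
(r_b - 1)/2$ and $a \approx 0.5$; a plain leukocyte shares no deviations and
gives $a \approx 0$. More generally, mixing a fraction $w$ of diploid reads
into a tumor profile gives $a = 1 - w$ (verified as a property test). The
verdict threshold is 0.75, the midpoint between the two hypotheses'
expectations; both the threshold and the minimum number of informative bins
(default 50) are arguments of `attenuation_statistic()`.

Three choices deserve comment:

* **Reference segment means, not per-bin reference values.** Regressing on a
  noisy covariate attenuates slopes (errors-in-variables); using the
  segment means of a consensus reference removes that bias, which matters
  because the statistic's whole point is to *measure* attenuation.
* **X-chromosome exclusion (default).** Partial or complete X loss can occur
  subclonally in tumor cell populations; leaving chrX in the clonal
  reference would contaminate the statistic for cells on either side of
  that subclonal split.
* **The near-diploid assumption.** The fusion expectation $(s+2)/4$ assumes
  the partner contributes exactly two copies per bin and equal per-genome
  depth. Unequal depth moves the fusion expectation along $1 - w$; the
  statistic reports the slope and leaves interpretation of intermediate
  values to the analyst rather than silently correcting.

## Clonality

`detect_clonal_events()` calls an alteration clonal when segments with the
same gain/loss direction and reciprocal bin overlap $\ge$ 0.5 recur in at
least half of the cells (both fractions configurable), and flags a cell as
clonal when it carries at least half of the clonal events. Candidate
segments are canonically sorted before clustering, so the report is
invariant to the order of the cell list. Diploid control cells carry no
non-neutral segments and can never be flagged.

## The profiling pipeline

* **GC correction** (`gc_correct`): a robust lowess fit (span 0.3) of
  length-normalized counts against GC fraction, applied as a multiplicative
  correction that preserves the genome-wide mean; with fewer than 100 bins a
  quadratic fit replaces the lowess. The fitted bias is floored at 5% of the
  mean rate to avoid division blow-ups in sparse GC tails.
* **Ratio normalization** (`ratio_normalize`): counts are divided by bin
  length (expected counts scale with the variable bin length) and then by
  the genome-wide mean; every `ratio_profile` has mean exactly 1, asserted
  on construction.
* **Segmentation** (`segment_cbs`): circular binary segmentation on
  $\log_2(\text{ratio} + 10^{-6})$ (variance stabilization; the small offset
  guards zero ratios), reporting segment means on the linear scale. Within a
  (sub-)chromosome the scan maximizes the pooled-variance two-sample
  $t$-statistic over all circular arcs; scanning contiguous windows of every
  admissible length covers all circular arcs because a wrapped arc has a
  contiguous complement and $|t|$ is symmetric in the two groups. A split is
  accepted when its permutation p-value, computed with the conservative
  $(1 + c)/(1 + B)$ estimator, is below `alpha`; permutations stop early
  once acceptance is impossible. Defaults `alpha = 0.01`, `n_perm = 1000`,
  `min_width = 3` are conventional CBS settings. No post-segmentation
  merging or pruning is applied. Bin indices are 1-based inclusive
  throughout the package (R convention); BED-style output uses 0-based
  half-open coordinates.
* **State calls** (`call_states`): state $=$ round(mean ratio $\times$
  ploidy), rounded half-up so results do not depend on banker's rounding.
* **Region comparison** (`region_ratio_test`): textbook pooled-variance
  two-sided Student's $t$ on $n_A + n_B - 2$ degrees of freedom, with
  explicit degenerate handling (zero pooled variance with equal means gives
  $t = 0$, $p = 1$; with unequal means $p = 0$ and a degeneracy flag).

## What the generator emulates — and what it does not

`make_bin_map()` builds an abstract genome: bins apportioned over
chromosomes by human-like relative sizes, log-normal bin lengths around a
600 kb mean, Beta-distributed GC truncated to (0.2, 0.8). `simulate_counts()`
draws multinomial counts at `dispersion = 0`, Gamma-Poisson counts
otherwise, with expected counts proportional to state × length × a
quadratic multiplicative GC bias; an `exact` mode returns the expectations
themselves (a noise-free cell). The default clone
(`breast_clone_events()`) encodes gains/losses on chr1, 4q loss, a chr8
firestorm (six alternating narrow gains/losses; the signature is simulated,
not formally defined), 16p gain and 16q loss, with extents expressed as
chromosome fractions so the clone scales with any bin map. The per-cell
depth (default $10^6$ reads) is a configuration choice with no claim of
fidelity to any particular sequencing run.

The generator does **not** emulate whole-genome-amplification dropout or
jackpotting, mappability structure, replication-timing waves, or the
designed equal-mappable-reads property of real variable bins (bins here are
variable in length but independent of any alignability track). Passing
tests therefore demonstrate correctness of the *methods* under a controlled
noise model, not performance on any particular amplification chemistry.
Similarly, `simulate_feature_table()` and `simulate_ion_counts()` produce
clean Gaussian intensities and Poisson ion counts with planted QC failures;
they exercise thresholding, classification and gating logic, not optics or
spillover.

## Immunofluorescence classification

`call_ck_positive()` uses the slide-wide mean plus 6 standard deviations of
mean CK intensity, with a strict inequality and the *population* SD
(divide-by-$n$); over millions of cells per slide the sample/population
distinction is negligible, but a convention must be fixed. All cells on the
slide enter the statistic. The CD45 classifier is a logistic regression on
mean CD45 intensity fitted by IRLS with a tiny ridge penalty
($\lambda = 10^{-6}$ on the standardized slope), which keeps coefficients
finite under the complete separation that well-annotated data produces; on
non-separable data it agrees with `glm()` to four decimals (tested). The
annotated set is split 2/3 train / 1/3 test with stratification, and
accuracy is reported as the mean over 5-fold cross-validation repeated 5
times on the training split plus the held-out test accuracy. The decision
threshold is a strict 0.5 on predicted probability.

## IMC gating and clustering

Masks are filtered to area 40–200 pixels inclusive ("between 40–200" read
plainly) and DNA1 $\ge$ 4 ion counts, with an explicit `bypass` argument for
cells already identified by matched immunofluorescence. Marker columns are
scaled to their 99th percentile (linear-interpolation percentile, type 7;
all-zero columns are left unscaled and flagged), and clustering runs on the
percentile-normalized counts; the arcsinh transform (cofactor 1) is applied
for gating and display. Gate trees are ordered lists of threshold predicates
with parent links — CD4/CD8 leaves under the CD3+ node are only evaluated
inside the CD3+ population — and live in YAML, because real gate thresholds
are data-dependent configuration, not code.

`cluster_graph()` builds a k-nearest-neighbour graph (Euclidean, k = 30),
weights edges by the Jaccard overlap of neighbour sets, and runs Louvain
community detection. The default resolution is 0.1, deliberately coarse:
kNN graphs of single homogeneous populations fragment into
modularity-optimal sub-communities at resolution 1, while merging
communities joined by no edges never increases modularity at *any*
resolution — so a coarse default returns each well-separated population as
one cluster and still cannot merge populations that share no neighbours.
Raise the resolution to look for substructure within populations.

## Problem sizes and numerical tolerances in the test suite

The tests use downscaled genomes chosen so each check is sharp at its scale:
5000 bins for the ratio-arithmetic checks (the altered segment shifts the
genome mean by ~1%, which is why a 100-bin gain sits at 1.485 rather than
exactly 1.5), 800–1500 bins for segmentation and clonality (the firestorm's
alternating segments must span clearly more than `min_width` bins for a
permutation test to resolve them, as they do at the method's native
resolution), 100-seed batches for stochastic recovery checks, and a 2.5-SD
binomial allowance for Monte-Carlo error when the type-I rate of the
permutation test is itself being estimated.

## Known limitations

* Ploidy beyond round(2 × ratio) is not estimated; a genome-doubled tumor
  or a grossly aneuploid baseline would need an external ploidy estimate.
* The attenuation statistic assumes the clonal reference is correct; it
  measures compression relative to that reference, not tumor origin per se.
* Late-stage hybrid evolution (novel post-fusion aberrations) is out of
  scope; the test addresses the early additive-genome model only.
* Clustering and gating operate on provided per-cell tables; segmentation
  of images and marker panel QC happen upstream.
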