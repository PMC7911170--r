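---
title: "Motif frequencies, the Markov D-ratio, and composition-based clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif frequencies, the Markov D-ratio, and composition-based clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifclust)
```

## The problem

Viral genome collections — hundreds to thousands of whole genomes of, say,
hepatitis B virus — are usually compared by alignment against a reference.
When no credible ancestral reference exists, alignment-free composition
statistics are an alternative: every sequence is summarized by the usage of
its short motifs (k-mers, here k = 1..5), and sequences are compared,
clustered and visualized in that feature space. motifclust implements this
workflow end to end: profiling, representation scoring, feature-matrix
assembly, clustering, and plotting, plus a synthetic-sequence generator that
provides ground truth for testing every stage.

## Observed motif frequency

For a sequence of length $L$ and a motif $m$ of length $k$, every
overlapping window of length $k$ is counted and

$$P_{obs}(m) = \frac{\text{count}(m)}{\text{valid windows}},$$

where the denominator is the number of counted windows of that same length
(at most $L - k + 1$). Frequencies over a fixed $k$ therefore sum to 1.
Windows containing any non-`ACGT` letter (IUPAC ambiguity codes, common in
deposited viral genomes) are skipped and excluded from **both** the count
and the denominator, so an `N` never dilutes a frequency. A sequence with no
valid window at some order yields an all-zero profile flagged *degenerate*.

Two conventions are worth making explicit because nothing in the file
formats forces them:

* **Overlapping windows**, not disjoint ones. The Markov identities below
  only hold for overlapping counts.
* **Forward strand only.** Sequences are profiled exactly as deposited; no
  reverse-complement collapsing, and no wrap-around windows even though some
  viral genomes (HBV among them) are physically circular. A circular genome
  deposited linearly loses at most $k - 1$ windows at the join, which is
  negligible at genome scale.

## Expected frequency and the D-ratio

The *representation* of a motif is the ratio of its observed frequency to
the frequency expected from its own sub-motifs under a Markov model. The
package uses the maximal-order expectation throughout: for $k \ge 3$,

$$P_{exp}(m) = \frac{P_{obs}(m_{1..k-1}) \; P_{obs}(m_{2..k})}{P_{obs}(m_{2..k-1})},$$

the prefix and suffix $(k-1)$-mers divided by their shared interior
$(k-2)$-mer — a first-order model for trinucleotides, second-order for
tetranucleotides, and by the same pattern third-order for pentanucleotides.
For dinucleotides the zeroth-order product of the two mononucleotide
frequencies is used. The D-ratio is then

$$D(m) = \frac{P_{obs}(m)}{P_{exp}(m)},$$

with $D > 1$ over-representation and $D < 1$ under-representation (the
classic example in DNA composition work is CpG depletion). The virtue of the
maximal-order form is that $D(m)$ is insensitive to changes in the usage of
the constituent sub-motifs themselves: for sequences generated by a
stationary Markov chain of order $k - 2$ with strictly positive transition
probabilities, $D$ of every $k$-mer centers on 1 regardless of how skewed
the chain is. The test suite verifies this null calibration empirically —
mean $D$ over 100 replicates of length 10{,}000 lies in $[0.95, 1.05]$ for
every 3-mer and 4-mer, both under i.i.d. sequences and under matched first-
and second-order chains. (These problem sizes — 100 replicates, 10 kb — are
the package's chosen calibration conditions; they keep per-motif standard
errors near 1–2%.)

A hand-checkable instance: on the sequence `TGGGTGGG`,
$P_{obs}(\mathrm{TGGG}) = 2/5$, $P_{obs}(\mathrm{TGG}) = P_{obs}(\mathrm{GGG}) = 1/3$,
$P_{obs}(\mathrm{GG}) = 4/7$, so $P_{exp} = (1/3 \cdot 1/3)/(4/7) = 7/36$
and $D(\mathrm{TGGG}) = 72/35 \approx 2.057$:

```{r}
dratio("TGGG", profile_sequence("TGGGTGGG", ks = 1:4))
```

**Zero handling.** When the interior frequency is 0 the expectation is
undefined; when the expectation is 0 or undefined, $D$ is undefined. Both
are reported as `NA`, never coerced to infinity. Per-sequence profiles are
used throughout (each sequence is its own null), not pooled counts. $k = 1$
is excluded from the D-ratio basis because $D$ is identically 1 there.

## Feature matrices and normalization

`build_matrix()` stacks per-sequence profiles into a sequences × motifs
matrix (rows in input order; columns grouped by ascending k, lexicographic
within k; mixed-k matrices allowed). On the D-ratio basis, undefined values
are imputed as 0 at build time and the imputation count is kept on the
object and echoed in CLI manifests, so the audit trail survives the
requirement that clustering inputs be finite.

`maxabs_normalize()` divides the **whole matrix** by its single largest
absolute value, mapping it into $[-1, 1]$ while preserving every ratio
between entries. Global rather than per-column scaling is deliberate: the
columns of a motif profile share units, and per-column scaling would erase
the relative magnitudes between motifs that the plots display. The CLI
applies operations in pipeline order — subset first, then normalize — so a
normalized subset always has max |value| = 1.

## Clustering

Four complementary views of the same feature space:

* **K-means** (`kmeans_cluster()`): `stats::kmeans` with 10 random restarts
  (best within-cluster sum of squares kept) and an explicit seed. Restarts
  rather than a k-means++ initializer: with ≥ 10 restarts on feature spaces
  this size the best-of inertia is as stable, and it keeps the
  implementation on the canonical library routine. `k` equal to the row
  count short-circuits to the exact answer (every point its own cluster).
* **PCA + K-means** (`pca_kmeans()`): max-abs normalization (if not already
  applied), column-centered PCA (`stats::prcomp`), K-means on the leading
  `n_components` (default 2) scores. Component signs are fixed so the
  largest-magnitude loading is positive, making embeddings reproducible.
  The 2-D embedding is stored for scatter plots.
* **Mean shift** (`meanshift_cluster()`): flat-kernel mode seeking; the
  cluster count emerges from the kernel density estimate instead of being
  user-set. When no bandwidth is given it is estimated as the mean distance
  to each point's `floor(0.3 n)`-th nearest neighbour (quantile 0.3 is the
  conventional default for this estimator). Iteration stops at a shift
  below `1e-3 × bandwidth` or 300 iterations; converged modes closer than
  one bandwidth are merged, most-populated first; ties in nearest-mode
  assignment break toward the lowest index. No installed R routine provides
  mean shift, so this one is implemented in the package and pinned by
  limit-behaviour tests (bandwidth → ∞ gives 1 cluster, → 0⁺ gives n).
* **Clustermap ordering** (`clustermap()`): agglomerative hierarchical
  clustering of rows and of columns (`stats::hclust`), returning leaf
  orders and merge records for clustered-heatmap rendering. Average linkage
  is the default, matching standard clustermap practice; single linkage is
  the documented alternative because it is mathematically equivalent to
  building a minimum spanning tree of the pairwise distance graph — the
  test suite checks its merge heights against a brute-force Prim MST
  exactly.

All quality checks on simulated data use the adjusted Rand index, which is
invariant to label permutation. Seeds are explicit everywhere and recorded
in `ClusteringResult$params` and in CLI manifests.

## The synthetic generator, and what passing tests do not show

`generate_iid()` (independent draws from a base composition),
`generate_markov()` (stationary chains of a given order; uniform start
context) and `planted_clusters()` (one i.i.d. block per composition, labels
returned) exist so that every stage has ground truth without downloading
anything. The `hbv-like` preset — five base compositions, 100 sequences of
3.2 kb — mimics the *shape* of a multi-genotype HBV collection at desk
scale. Cluster-recovery fixtures use compositions separated by well over
5 standard errors of a mononucleotide frequency at the chosen length
(e.g. GC-rich 0.1/0.4/0.4/0.1 vs AT-rich 0.4/0.1/0.1/0.4 at 2 kb), so a
perfect ARI is the expected outcome, not luck.

Two honest caveats. First, real viral genomes are not i.i.d. or low-order
Markov: they carry genes, overlapping reading frames, phylogenetic
correlation, indels and recombination. Passing the planted-cluster tests
shows the pipeline recovers composition structure when present; it does not
certify genotype recovery on real data. Second, the D-ratio is *designed*
to factor base composition out — so clusters planted purely as composition
differences between i.i.d. sequences are invisible on the D-ratio basis
(every such sequence has $D \approx 1$ everywhere). That is the method
working as intended: on real genomes, D-ratio structure reflects
motif-level selection (e.g. CpG suppression) rather than GC content. The
end-to-end demo therefore checks the D-ratio pipeline for reproducibility
and shape, and demonstrates cluster recovery on the frequency basis.

## Numerical and interface conventions

* Windows are 0-based half-open internally; all outputs address motifs by
  name, so no off-by-one surface exists.
* `kmax` defaults to 5 (4^k feature growth) but is configurable upward.
* Label files are 0-based; R-side permutations (`row_order`, `col_order`)
  are 1-based R indices.
* Matrices are written with 12 significant digits and round-trip within
  1e-9; ids containing the delimiter are RFC-4180-quoted.
* CLI exit codes: 0 success, 1 usage, 2 input format/validation,
  3 computation. Every run writes a JSON manifest (tool version, full
  config, seed, imputation count) sufficient to re-run bit-identically;
  manifests contain no timestamps for exactly that reason.
* Heatmaps of D-ratios use a diverging palette centered at $D = 1$ so over-
  and under-representation are visually symmetric; frequency heatmaps use a
  perceptually uniform sequential palette. Raw values are plotted by
  default (no row standardization).

## Known limitations

Only DNA (RNA input is transliterated U→T; proteins are rejected). No
canonical/strand-collapsed k-mers, no gapped motifs, no significance tests
on D, no automatic choice of K for K-means, and the counting path is
per-sequence in-memory — appropriate for viral genomes, not chromosomes.
Lower-than-maximal-order expectations (e.g. the plain product of
mononucleotides for a trinucleotide) are not offered as options; the
maximal-order form is the one with the constituent-independence property
that motivates the D-ratio in the first place.
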