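---
title: "Minimum span clustering of sequence similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum span clustering of sequence similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscnet)
```

## The problem

Large protein superfamilies — the G-protein-coupled receptors are the
motivating case — are routinely summarised as sequence similarity
networks: every sequence is a node, and an edge between two sequences
carries a distance derived from their all-vs-all BLAST E-values. This
package implements an unsupervised, multi-resolution clustering of such
networks, minimum span clustering (MSC), together with the surrounding
analyses that make the clustering interpretable: minimum-spanning-tree
visualisation, threshold-based family detection tuned by the F measure,
Nei–Gojobori estimation of selective pressure (dN/dS), and consistency
scoring against an external hierarchical classification.

## The distance

For sequences $i$ and $j$, the directed BLAST E-values $E_{i,j}$ and
$E_{j,i}$ are symmetrized into

$$d_{i,j} = \sqrt{E_{i,j}\,E_{j,i}},$$

computed in log space so that products as small as $10^{-400}$ do not
underflow (`symmetrize()`). E-values above 1 carry essentially no
similarity signal and are discarded before symmetrization (the ceiling is
configurable). Pairs reported in only one direction leave the geometric
mean undefined; the default policy drops them, which is conservative for
clustering because it cannot create spurious short edges. A `cap` policy
(missing direction replaced by 10, BLAST's default reporting cutoff) is
available for sensitivity analysis. Distances are stored as plain
doubles, so values below roughly $10^{-308}$ would themselves underflow;
E-values that small are not produced by BLAST.

Groups of sequences with mutual E-value exactly zero — fully conserved
groups, drawn as hexagons in the network figures this style of analysis
produces — are collapsed into single super-nodes before clustering
(`collapse_zero_groups()`): a zero log-distance is undefined, and the
group behaves as one sequence for every network purpose. Member counts
are carried along and re-expanded in all reported memberships.

## The clustering algorithm

One MSC level runs four steps (`run_msc()` drives them):

1. **Simplification** (`nearest_neighbor_list()`): record each node's
   single nearest neighbour, sorted by ascending distance. A network of
   $N$ nodes is thus reduced from $N^2$ distances to at most $N$.
2. **Clustering** (`build_clusters()`): walk the list in ascending
   order. A pair with no clustered endpoint founds a new cluster (its
   *core* pair); a pair with one clustered endpoint grows that cluster;
   a pair whose endpoints sit in two different clusters merges them.
   The accepted pairs form one spanning tree per cluster, and the
   clusters are exactly the connected components of the undirected
   nearest-neighbour graph.
3. **Truncation** (`estimate_threshold()`, `truncate_clusters()`):
   spanning edges longer than a threshold distance $D_t$ are cut; units
   that end up alone become outliers, reported separately.
4. **Renormalization** (`renormalize()`): each cluster becomes a single
   node, each outlier is carried as a singleton node, and the distance
   between two nodes is the minimum distance over their cross pairs.
   The coarser network feeds the next level, until a single unit
   remains, a level merges nothing, or `max_levels` (default 10) is
   reached.

Determinism is guaranteed by a fixed tie rule everywhere: pairs sort by
(distance, lexicographically smaller id, larger id), and per-node argmin
ties resolve to the smallest neighbour id. Identical inputs therefore
produce bit-identical cluster tables and graph files.

### What the nearest-neighbour construction implies

Because every node contributes only its single shortest bond, the
level-1 clusters are *fine*: a homogeneous family of $n$ sequences
fragments into roughly $n/4$ small clusters (each component of a random
nearest-neighbour graph contains exactly one mutual-nearest pair). This
is intrinsic to the method, and it is why the original analyses report
hundreds of level-1 clusters for a few thousand sequences. Level-1
clusters are best read as high-purity seeds; coarser levels merge them
into families. Consequently, on synthetic data with planted blocks the
correct expectations are that every level-1 cluster is a *pure subset*
of one block, and that the blocks are recovered *exactly* at a coarser
level — not that level 1 reproduces the blocks as-is. Both properties
are asserted in the test suite over 50 seeds.

### Choosing the threshold distance

$D_t$ is located by comparing two log10 edge-length histograms built
from the same network (`edge_length_histogram()`): $P_{all}$, the edge
lengths of the network's minimum spanning tree (which contains intra-
and inter-cluster edges), and $P_{intra}$, the lengths of the
intra-cluster spanning edges. Where only intra-cluster edges live, the
ratio $P_{all}/P_{intra}$ sits near 1; inter-cluster edges push it up.
The estimator scans bins in ascending length for the first bin where
$P_{all}/P_{intra} - 1 > \varepsilon$ (ratio infinite where
$P_{intra} = 0$), then demands confirmation before accepting it:

* **Gap evidence**: the candidate is separated from the preceding
  populated bin by at least `gap_bins` (default 2) empty bins. This is
  the unambiguous bimodal case; the threshold is placed at the log
  midpoint of the empty gap, where any value is equivalent for
  truncation but the midpoint is maximally robust to sampling noise at
  either mode's tail.
* **Persistence**: otherwise the next `persistence` (default 2)
  populated bins must also qualify, with non-decreasing ratio, and must
  lie in the same mode as the candidate (the confirmation window stops
  at the first `gap_bins`-wide run of empty bins — bins beyond such a
  gap are evidence for a larger threshold, not for the candidate). In
  this case $D_t$ is the candidate bin's lower edge. This is the
  behaviour that applies to real, overlapping distance distributions.

Defaults: $\varepsilon = 0.5$, `persistence = 2`, bin width 5 decades.
The parameterisation replaces the by-eye reading of "the ratio departs
from 1 and keeps rising" with an explicit rule; on well-separated data
the two branches agree up to the placement within the empty gap. When
no bin qualifies (single-family data) no truncation is applied.
Explicit per-level overrides are supported (for example fixing
$10^{-80}$, the value used for the GPCR network this method was
developed on).

By default the level-1 estimate is reused at coarser levels
(`threshold_policy = "reuse-first"`). After renormalization only a
handful of edges remain, far too few for a stable histogram ratio, and
re-estimating there tends to return nothing — which would silently
allow genuinely distant families to merge. Reusing the finest-level
threshold keeps "too far to be one family" meaning the same thing at
every resolution; `"per-level"` re-estimation remains available.

## Family detection

Given a labelled network, `min_target_distance()` computes each
sequence's minimum distance to the positive class, excluding
self-matches (a target trivially matches itself). A query is called a
family member when $\log_{10}$ of that minimum distance is below a
threshold $V_t$; `tune_threshold()` picks $V_t$ by maximising
$F = 2PR/(P+R)$ over a grid of step 0.05 log units covering the
observed support. The grid is augmented with the midpoints between
consecutive distinct observed values, so every achievable prediction
set is visited and the reported optimum is exact (a fixed grid alone
can step over two observations closer than one grid step). Ties resolve
to the smallest — most stringent — $V_t$. Queries with no finite
distance to any target are never called; an exact zero distance always
is.

## Selective pressure (Nei–Gojobori with Jukes–Cantor correction)

For an aligned codon pair, `pairwise_rates()` composes three steps:

1. **Sites** (`site_counts()`): per codon, the synonymous site count at
   each position is the fraction of the three alternative nucleotides
   that preserve the amino acid, summed over positions and codons and
   averaged between the two sequences; $S + N = 3r$ holds exactly for
   $r$ retained codons. Single changes that create a stop codon count
   as nonsynonymous by default (the method weights all substitution
   types equally); an `exclude` option removes them from the site
   total, in which case $S + N < 3r$.
2. **Differences** (`diff_counts()`): codon pairs differing at $k$
   positions are connected by $k!$ single-step orderings (1, 2 or 6
   pathways; `codon_pathways()` enumerates them). Each step is
   synonymous or nonsynonymous; pathways passing through a stop codon
   are excluded from the average, and when every ordering is blocked
   the $k$ differences are split in proportion to the direct
   single-step changes that stay sense. Per codon the synonymous plus
   nonsynonymous differences always equal $k$.
3. **Correction**: the difference proportions $p_X = X_d / X$ are
   converted to substitutions per site with the Jukes–Cantor formula
   $d_X = -\tfrac34 \ln(1 - \tfrac43 p_X)$, undefined at
   $p_X \ge \tfrac34$ where the correction saturates.

The ratio $d_N/d_S$ classifies each pair: below 1 negative (purifying)
selection, 1 neutral, above 1 positive; the ratio is reported undefined
when $d_S = 0$ or either correction saturates. Codons with gaps,
ambiguity characters or stop codons in either sequence are excluded
pairwise before any counting. `selection_summary()` aggregates a set of
pairs into class fractions and the empirical cumulative distribution of
the ratio, the form in which intra-family selective pressure is usually
inspected.

Two properties of this estimator are worth remembering when reading
results: it weights all substitution types equally, which tends to give
accurate $d_S$ but to underestimate $d_N$; and pathway averaging can
assign fractional nonsynonymous differences to codon pairs whose
history was purely synonymous (two synonymous one-step changes on the
two lineages can be bridged only through a nonsynonymous intermediate).
The synthetic-regime tests therefore assert the recovered selection
*class*, not a literal zero.

## Consistency against a reference classification

`consistency()` scores a clustering level against a hierarchical
reference (for example a curated receptor classification): a cluster is
consistent at a reference depth when all its member sequences share one
label there, and the score is the fraction of consistent clusters.
Outliers and singletons are excluded from both numerator and
denominator by default (they are reported separately by the pipeline);
`include_singletons = TRUE` adds them as trivially consistent. Collapsed
zero-distance super-nodes vote through their member sequences, so a
conserved group that mixes labels makes its cluster inconsistent.
`network_stats()` reports the companion quantities: mean intra-cluster
and mean inter-cluster (renormalized) distance, log-binned
sequence-sequence and cluster-cluster distance histograms, and the
most connected hub of each spanning-forest component.

## Synthetic data: what it emulates and what it does not

`generate_distances()` draws a planted-partition network: blocks of
nodes with intra-block log10 distances at one scale and inter-block
distances at a much larger one, both normal on the log scale. Defaults
are three blocks of 20, intra $10^{-120}$, inter $10^{-10}$, both with
a spread of 2 decades — the strongly bimodal structure real E-value
networks show between family and non-family comparisons; an optional
`zero_frac` plants conserved zero-distance groups. It does not emulate
Karlin–Altschul E-value statistics, sequence-length effects, or the
heavy overlap between intra- and inter-family distances seen in diverse
superfamilies — so passing the planted-recovery tests shows the
machinery is correct, not that threshold estimation is easy on hard
real data (there, the persistence branch and manual overrides matter).

`generate_codon_pairs()` evolves both members of each pair from a
uniform random sense-codon ancestor, applying at every nucleotide site
a synonymous substitution with probability `p_syn` and a nonsynonymous
one with probability `p_nonsyn`, drawing only sense codons so stop
rejection never distorts counts. Regimes with `p_nonsyn/p_syn` at 2 and
at 1/2 (r = 300 codons) are separated well enough that the sign of
$d_N/d_S - 1$ recovers the regime in at least 95% of replicates; this
is the calibration the acceptance checks use. All generators are
seed-deterministic.

## Numerical and design choices

* Distances combine in log space; zero distances are collapsed, never
  floored.
* Histograms use log10 bins of width 5 decades anchored at the floor of
  the smallest observed log distance.
* Cluster labels are `C<level>-<zero-padded index>`, assigned by
  ascending smallest member id — stable under rerun by construction.
* The problem sizes used by the test and acceptance suites (50-node
  random networks, 3×20-node planted blocks over 50 seeds, 30-codon
  oracle pairs, 300-codon regime replicates) were chosen so each
  property is exercised well past its failure modes while the full
  suite stays interactive.
* Sequence ids are the first whitespace-delimited FASTA header token,
  matching BLAST's naming so E-value tables join without a mapping
  file.

## Known limitations

* The level-1 resolution is a property of the nearest-neighbour
  construction, not a tunable: if coarse families are wanted directly,
  read them off a higher level.
* Threshold estimation needs enough edges to populate a histogram;
  very small networks fall back to no truncation unless an override is
  given.
* BLAST parameters upstream of the E-value table (word size,
  composition-based statistics) are not recorded by this package and
  affect reproducibility of any absolute distance scale.
* dN/dS is the approximate counting estimator; for saturated pairs
  ($p_X \ge 3/4$) it is reported undefined rather than extrapolated,
  and maximum-likelihood codon models are out of scope.
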