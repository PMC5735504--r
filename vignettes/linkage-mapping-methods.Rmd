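---
title: "Linkage map construction with TSP solvers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage map construction with TSP solvers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salesmap)
```

## The mapping model

A genetic linkage map orders markers along chromosomes and assigns additive
map distances. The only data the method consumes is the matrix of pairwise
recombination frequencies rf(*i*, *j*) ∈ [0, 0.5]: the fraction of
informative meioses (or inbred lines) in which markers *i* and *j* are in a
recombinant configuration. Because rf grows monotonically with genetic
distance, the true marker order of a chromosome is the minimum-cost
Hamiltonian path through its markers under rf edge weights, and noise in rf
is exactly what makes greedy or tree-based orderings fragile. `salesmap`
therefore treats ordering as a traveling-salesperson problem and solves it
with explicit solvers, while using the minimum spanning tree (MST) only for
what it is robust at: separating groups of markers that are far apart.

A TSP tour is cyclic, but the edge joining a chromosome's two ends is
meaningless and expensive (its rf is near 0.5). Every instance is therefore
augmented with a **dummy vertex** connected to all markers by zero-weight
edges; the optimal tour passes through the dummy, and cutting it there
yields an open path with no closing-edge penalty.

## Recombination-frequency estimation

For homozygous designs (RILs by selfing, doubled haploids) and backcrosses,
rf is estimated by direct counting. With *d* disagreements among *c*
mutually observed individuals and *u* individuals missing at least one of
the two calls, the attainable rf range is [*d*/(*c*+*u*), (*d*+*u*)/(*c*+*u*)];
the estimator reports its midpoint

rf = (*d* + *u*/2)/(*c* + *u*),

clamped to 0.5. The midpoint keeps missing data from either under- or
over-linking a pair. Since *c* + *u* equals the population size *n*, the
whole matrix reduces to two matrix cross-products of a ±1/0 encoding, which
is what keeps rf estimation at *m* = 2000, *n* = 300 in the sub-second
range.

For F2 intercrosses the double-heterozygote class is ambiguous (it can
arise from two parental or two recombinant gametes), so rf is fitted by EM
on the 3×3 joint genotype counts. The E-step replaces the latent
recombinant-gamete count of the (H,H) cell with 2r²/(r² + (1−r)²); the
M-step divides expected recombinant gametes by 2*N*. The update runs
simultaneously for all marker pairs on the nine count matrices
(initialized at r = 0.25, tolerance 1e−6, at most 100 iterations). Tests
check it against an independent grid-search maximization of the same
likelihood.

Note that for RILs the estimated quantity is the line-level recombinant
fraction R = 2r/(1+2r), not the per-meiosis r. No inverse transformation is
applied before ordering: ordering only needs a monotone function of
distance, and the merge/split thresholds below are calibrated on the
R scale. Map distances are produced only at output time (Haldane by
default, Kosambi optional) from the adjacent rf values of the final path.

**Cutoff inflation.** Off-diagonal rf values strictly above a cutoff
(default 0.4) are inflated to exactly 0.5. Values that large carry no
ordering information, and flattening them stops the solvers from wasting
moves on noise. The inflation is applied once, to the matrix every
downstream stage uses; applying it again is a no-op (idempotent,
monotone). Setting the cutoff too low can delete genuinely informative
mid-range values in noisy data, which is why it is exposed as a parameter.

## Clustering, splitting, merging

With the expected linkage-group count *k* supplied by the user (the method
is deliberately biased toward this prior), a cluster is **significant**
when its size reaches *s* = *m*/(2*k*) — half an average chromosome's share
of markers, tolerating sizeable chromosome-size variation.

1. **MST cut.** Kruskal's algorithm (edges ordered by rf, then the index
   pair, making ties deterministic) builds the tree; its
   `ceiling(1.5 k)` largest-rf edges are removed. While fewer than *k*
   components are significant, the next-largest tree edge is cut. The
   over-cut is intentional: it is cheaper to reassemble fragments later
   than to separate fused chromosomes. If the cut loop exhausts every edge
   without reaching *k* significant components (possible when the extra
   cuts land mid-chromosome and both halves fall below *s*), the
   implementation reverts to the cut count that maximized the number of
   significant components and lets the merge stage reassemble the rest;
   a warning reports this.
2. **Path split.** Each cluster is solved by the heuristic TSP solver; the
   path is cut at every adjacent pair with rf above `break_threshold`
   (default 0.35). A clean chromosome's path has small adjacencies
   everywhere, so a large jump means foreign markers. The default sits
   well above realistic within-group adjacent rf (even at 0.5 cM spacing
   with 5% genotyping error and 10% missing data, adjacent rf stays below
   ~0.25) and below the ~0.5 seen between chromosomes.
3. **Three-stage merge**, smallest cluster first (ties by cluster id),
   with the cluster list refreshed after every merge:
   * *Direct*: merge into the cluster with the smallest inter-cluster
     minimum rf if it is ≤ `direct_threshold` (default 0.15) and at most
     half the second-best link — an unambiguous nearest neighbour.
   * *Path*: otherwise solve the merged instance with each candidate and
     record J, the maximum adjacent rf anywhere in the merged path; merge
     when the smallest J is less than half the second smallest.
   * *Reciprocal*: otherwise, if the best candidate's own best candidate
     is the current cluster, merge.

   Every merge additionally requires the merged path's maximum adjacent rf
   to be at most `break_threshold` — the same criterion the split stage
   enforces — so merging can never produce a cluster that splitting would
   immediately cut. (This single guard also subsumes a looser
   cutoff-based guard one might place on reciprocal merges; using one
   threshold for both directions keeps split and merge exactly dual.)
   The direct-merge threshold and the factor-of-two uniqueness rules are
   this package's concrete definitions of stages that are qualitative in
   the method's original description; each decision is logged with its
   evidence (`link`, `J` statistics) in the returned decision table.

## Solvers

* **Heuristic** (clustering, splitting, merging, large-group ordering):
  nearest-neighbour construction followed by 2-opt and Or-opt (segment
  lengths 1–3) local search over 12-nearest-neighbour candidate lists with
  don't-look bits, multi-started (default 8 starts) and chained with
  double-bridge perturbations (default 10 rounds during clustering and
  merging, 30 during final ordering with 12 starts). The perturbation
  budget matters: a single locally-optimal flaw in a merged path shows up
  as a spurious ~0.5 adjacency and would veto a correct merge. All
  randomness comes from an internal splitmix64 stream seeded from the
  pipeline seed, so results are reproducible to the byte and independent
  of R's RNG state.
* **Exact** (groups of up to `hk_limit − 1 = 17` markers): Held–Karp
  dynamic programming over vertex subsets anchored at the dummy vertex —
  a proven global optimum, with ties broken toward the lexicographically
  smaller of the path and its reversal. Beyond that size, "optimal" means
  best-found under the fixed, seeded ordering budget; the map records
  which tier ordered each group.

rf fractions are mapped to integer weights by `round(1e5 × rf)`: integer
weights are the conventional solver contract, and 1e−5 resolution is far
below the rf precision attainable at realistic population sizes. A TSPLIB
(`FULL_MATRIX`) writer is provided for anyone wishing to cross-check an
instance with external solvers; nothing in the package depends on them.

## The simulator

The simulator generates the study conditions the pipeline is tested under:
populations of *n* lines, *m* markers spread as evenly as possible over
*k* chromosomes (default 100 cM each), for `riself`, `f2`, and `bc`
designs. Genotypes follow a Markov chain along each chromosome with
adjacent-interval recombination probability given by the Haldane inverse
of the spacing — no crossover interference is modeled. The per-meiosis r
is used directly for backcross gametes, transformed to R = 2r/(1+2r)
between the fixed homozygous states of selfed RILs, and applied to two
independent meioses for F2. Genotyping errors are injected first (each
call replaced by a uniformly chosen different legal genotype with
probability η), then missing data (probability γ); the order is fixed for
reproducibility and immaterial to the marginal rates. Residual RIL
heterozygosity and segregation distortion are not simulated, and marker
spacing is exactly even — passing tests therefore demonstrate robustness
to call-level noise, not to interference, distorted segregation, or the
extreme marker-density heterogeneity of some real GBS data. Simulated
marker rows are shuffled (seeded) before entering the pipeline so nothing
can exploit input order.

## Evaluation statistics

* **E (erroneous pairs)**: the number of marker pairs whose relative order
  in the estimated group contradicts their true order — an inversion
  count, computed by merge sort and checked against a quadratic oracle in
  tests. Because group orientation is arbitrary, E is minimized over the
  two orientations: a wholly reversed but internally correct group scores
  0. This choice matters when comparing against conventions that fix
  orientation.
* **c**: the number of linkage groups produced, compared to the true
  chromosome count.
* **Order correlation**: size-weighted absolute Spearman correlation
  between true and estimated within-group ranks.
* **Group purity**: fraction of groups whose markers all come from one
  true chromosome. Markers landing in a group dominated by another
  chromosome are excluded from that group's E and surface here instead,
  keeping E a pure ordering statistic.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at desk scale:
linkage-group recovery on 2000 markers × 10 chromosomes and a full
γ ∈ {0, 0.05, 0.10} × η ∈ {0, 0.01, 0.05} grid at 1000 markers ×
5 chromosomes (2 replicates per cell), and ordering accuracy on F2 and
backcross populations of 255 markers (2 cM spacing) at η = γ = 0.001 —
five replicates per design, every one required to reach rank correlation
0.999. These sizes exercise every code path (both solver tiers, the EM
estimator, all three merge stages) while keeping a full run in minutes on
one core.

Degenerate inputs are handled explicitly: single-marker clusters pass
through splitting unchanged; an all-zero rf matrix yields one cluster with
a warning; a marker pair with no mutually observed individuals is an
error (never a silent 0); adjacent rf of 0.5 in a final path is an error
under Haldane/Kosambi (it signals an unsplit group) but allowed in the
rf-sum map. Threshold parameters are validated against their domains, and
asymmetric or out-of-range rf files are rejected at read time.

## Known limitations

* k must be supplied; the pipeline is strongly biased toward it and makes
  no attempt to infer the chromosome count.
* The minimum-size rule s = m/2k penalizes genuinely tiny chromosomes
  (micro-chromosomes) — fragments below s survive only by being merged.
* Above the exact-solver limit, ordering optimality is empirical (budget-
  bounded local search), not proven.
* Highly erroneous individual markers are not dropped post hoc; the map
  CSV is designed to be imported into standard QTL tools for that kind of
  curation.
* 4-way crosses and dominant/partially informative markers are supported
  only through externally supplied rf matrices.
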