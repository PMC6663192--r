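---
title: "Topological inference on weighted networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological inference on weighted networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bettinet)
```

## The model

A weighted network is a node set $V = \{1,\dots,p\}$ with symmetric
nonnegative edge weights $w = (w_{ij})$. In the correlation-network
setting, the weight is a decreasing function of the Pearson correlation
$\rho_{ij}$ between the measurement vectors on nodes $i$ and $j$; the
package provides both $w_{ij} = (1-\rho_{ij})^{1/2}$, which satisfies the
triangle inequality and makes $(V, w)$ a metric space, and the simpler
$w_{ij} = 1-\rho_{ij}$. Both are strictly decreasing in $\rho$, so they
induce the same edge ranking; every rank-based quantity below is
identical under either choice, and the metric transform is the default.

Thresholding at a level $\varepsilon \ge 0$ keeps the edges with
$w_{ij} > \varepsilon$ (strictly; edges equal to the level are removed).
As $\varepsilon$ grows the binary graphs are nested — the *graph
filtration* — running from the complete graph at $\varepsilon = 0$ down
to the bare node set beyond the largest weight. Only the sorted unique
positive weights $w_{(1)} < \dots < w_{(q)}$ produce distinct graphs, so
the whole filtration is a finite object with $q+1$ states. Tied weights
are legal here (real data contain duplicates) and collapse to a single
level, with all tied edges entering or leaving together.

On a graph (the 1-skeleton of a simplicial complex) the zeroth Betti
number $\beta_0$ is the number of connected components and the first
Betti number $\beta_1$ the number of independent cycles, linked through
the Euler characteristic:
$$\beta_1 = \beta_0 - p + q_E,$$
with $q_E$ the current edge count. Because edges leave one at a time
along the filtration, $\beta_0$ is nondecreasing and $\beta_1$
nonincreasing, each moving by at most one per deleted edge. These two
monotone step functions — the *Betti curves* — are the topological
summary everything else is built on.

`betti_curves()` computes both curves in one pass: edges are inserted in
decreasing weight order into a union-find forest (compiled code), which
is the node-connecting mirror of the deletion filtration. The same pass,
run in increasing weight order, yields the single-linkage dendrogram
(components merge exactly at single-linkage distances) and the
persistence diagrams: components are born at 0 and die at merge levels;
a cycle is born at each edge that closes a loop and never dies, since a
1-skeleton has no 2-cells to fill it. Essential classes get a finite
death substitute (the maximum edge weight by default) so that bottleneck
computations have finite coordinates.

## Network distances

For two networks on a common node set the package implements:

* **Lp distances** on upper-triangle weight differences (orders 1, 2,
  $\infty$); each edge counted once.
* **Gromov-Hausdorff**: $\tfrac12 \max_{ij} |s^1_{ij}-s^2_{ij}|$ on the
  two single-linkage matrices, the ultrametrics recording minimax path
  weights.
* **Bottleneck** between persistence diagrams, computed exactly: each
  diagram is augmented with the other's diagonal projections, and the
  optimal bijection is found by binary search over candidate costs with
  an augmenting-path perfect-matching feasibility test.
* **KS distance**: $D_q = \max_i |\beta_j(\mathcal{X}^1_{\varepsilon_i})
  - \beta_j(\mathcal{X}^2_{\varepsilon_i})|$ over a filtration grid, for
  $j \in \{0, 1\}$. With the default grid — the union of both networks'
  unique positive weights plus zero — the discrete maximum equals the
  supremum over all levels, and the statistic depends on the weights
  only through their order, hence is invariant under any common strictly
  increasing transform.
* **Q-modularity difference**, a graph-theory comparator: the absolute
  difference of the weighted Newman modularity of the partitions found
  by deterministic greedy agglomerative maximization
  (`igraph::cluster_fast_greedy`). The community-detection routine is a
  configuration choice, not part of the statistic's definition.

## Exact inference for the KS statistic

Under exchangeability of the two networks' level sequence, the paired
Betti step functions trace a monotone lattice path from $(0,0)$ to
$(q,q)$, and
$$P(D_q \ge d) = 1 - \frac{A_{q,q}}{\binom{2q}{q}},$$
where $A_{u,v}$ counts the paths staying strictly inside the band
$|u-v| < d$ ($A_{u,v} = A_{u-1,v} + A_{u,v-1}$, in-band axis cells 1,
$A_{0,0} = 0$). `exact_tail_probability()` carries this recursion in
arbitrary-precision integer arithmetic (base-$2^{32}$ limbs), builds
$\binom{2q}{q}$ exactly from its prime factorization, and converts the
exact ratio to double only at the end: the central binomial coefficient
already overflows double precision near $q \approx 514$, far below
realistic grids. For large $q$ the limiting law
$$\lim_{q\to\infty} P\!\left(D_q/\sqrt{2q} \ge d\right)
  = 2\sum_{i\ge 1}(-1)^{i-1} e^{-2 i^2 d^2}$$
is used (`asymptotic_pvalue()`, series summed to $10^{-16}$); the two
agree within 0.01 already at $q = 500$ over the relevant range, which
the test suite asserts. The normalized statistic enters the series as
the raw value $D_q/\sqrt{2q}$; an integer-ceiling variant is exposed as
an option but not used by default, since the limit theorem is stated for
the raw ratio.

**Binding of $q$.** The exact law is indexed by the number of filtration
steps. For two-sample use we bind $q$ to the number of positive levels
in the filtration grid: the union grid in `ks_test()`, the supplied grid
in the twin pipeline. For the union grid this counts both networks'
levels and is therefore conservative (it inflates $q$ by about a factor
of two relative to the per-network step count); the same-$k$ false
positive rates in the benchmark reflect that. Calibration also requires
the grid to be no coarser than informative: when a fixed uniform grid is
much *smaller* than the number of distinct edge weights, the observed
maximum gap lives on a finer walk than the null assumes and p-values
become anti-conservative. The null-calibration property test therefore
uses cohorts whose edge count ($\binom{13}{2} = 78$) matches the default
101-level grid. Users analyzing dense matrices on coarse grids should
prefer the union grid.

`ks_test()` computes the exact p-value when $q \le$ `exact_q_budget`
(default 1000; the band recursion costs $O(qd)$ big-integer additions)
and reports the asymptotic value alongside; beyond the budget the
asymptotic value is used. Both are returned, so the choice is always
visible.

## Permutation engine

For distances without a known null, `permutation_test()` pools the two
groups' sample rows, reassigns them in every possible way when
$\binom{m+n}{m}$ is within `max_exact` (all 252 assignments for two
groups of five) and otherwise samples assignments uniformly, rebuilding
both correlation networks per assignment. The p-value is
$\#\{D_{perm} \ge D_{obs}\}/N$; the observed split is among the
enumerated assignments, so the p-value is never zero and degenerate
all-equal configurations return 1.

## The simulation benchmark

`simulate_null_group()` draws $n$ samples of $p$ independent standard
normal node measurements. `simulate_modular_group()` imposes a modular
topology via a hierarchical linear model: the $p$ nodes split into $k$
blocks of size $c = p/k$, and every node in a block equals its block's
anchor column plus fresh $N(0, \sigma^2)$ noise (noise on every node,
including the anchor's own copy — the displayed model adds noise to each
$\mathbf{y}$). Within-block population correlation is
$1/(1+\sigma^2) \approx 0.990$ at the benchmark's $\sigma = 0.1$;
between-block correlations are centered on zero.

`rejection_rate_experiment()` reproduces the benchmark protocol: 100
replicates, $n = 5$ samples per group, $\sigma = 0.1$; same-$k$ pairs
share the anchor draw (the stated null of identical parameters and
initial data) and report false positive rates, different-$k$ pairs use
independent anchors and report false negative rates; KS tests use the
combinatorial/asymptotic null, every other distance the enumerated
permutation test. The node sizes exercised in the tests and the
acceptance script are $p = 20$, 100 and 500, each at the benchmark's own
100-replicate scale.

## The twin pipeline

The application pipeline compresses parcel time series, correlates
parcels within subject, correlates subjects within twin pairs, and tests
MZ against DZ topology:

1. `cosine_representation()`: each parcel's series is mapped to $[0,1]$,
   mean-centered, and least-squares expanded in $\psi_0 = 1$,
   $\psi_l(t) = \sqrt{2}\cos(l\pi t)$. We use the orthonormal constant
   $\sqrt{2}$ (a plain factor 2 is available as an option): it makes the
   design well conditioned and basis signals come back with unit
   coefficients. The default order $k = 119$ gives 120 spectral features.
2. `subject_connectivity()`: Pearson correlation between coefficient
   vectors of parcel pairs.
3. `twin_group_correlation()`: per edge, the correlation across pairs
   between co-twins' connectivity values, symmetrized as
   $(M + M^\top)/2$ since twin order is arbitrary. Edges with zero
   variance are reported as undefined (and excluded from filtrations as
   absent edges), never silently zeroed.
4. `falconer_heritability()`: $HI = 2(C_{MZ} - C_{DZ})$, the additive
   genetic share under the ACE identities $corr_{MZ} = A + C$,
   $corr_{DZ} = A/2 + C$. Raw values are returned; thresholded display
   (e.g. at 100% heritability) is a reporting option.
5. `twin_ks_inference()`: Betti curves of $C_{MZ}$ and $C_{DZ}$ directly
   on the correlation scale over a default grid of 101 levels from 0 to
   1 in steps of 0.01 — legitimate because the KS statistic is invariant
   under the monotone map between correlations and weights — followed by
   the exact/asymptotic KS test on the maximum $\beta_0$ and $\beta_1$
   gaps. Negative correlations are never kept by the strict threshold at
   $\varepsilon \ge 0$.

## The synthetic ACE cohort generator

`simulate_twin_cohort()` exists so the pipeline is testable without any
external download. It applies the ACE decomposition *directly to
connectivity edges*: each edge's latent score per twin is
$\sqrt{a^2}\,g + \sqrt{c^2}\,h + \sqrt{e^2}\,e$, with the genetic
component $g$ identical across MZ co-twins and correlated exactly 0.5
across DZ co-twins (built from shared plus independent halves of its
variance), $h$ shared within every pair and $e$ unique. Edgewise twin
correlations are then exactly $a^2 + c^2$ (MZ) and $a^2/2 + c^2$ (DZ),
so Falconer's formula recovers $a^2$ by construction — the property the
recovery tests measure. A node-level construction (shared feature
vectors per node, connectivity derived afterwards) looks closer to the
real data-generating process but provably yields $(A+C)^2$ and
$(A/2+C)^2$ at the edge level — the correlation of products of weakly
correlated vectors squares the sharing — and cannot satisfy the Falconer
identities; we chose the edge-level construction because those
identities are the contract the pipeline is validated against. Latent
scores are mapped affinely to the correlation scale (default mean 0.3,
sd 0.15, clipped at $\pm 1$); correlations are invariant to the affine
map, and clipping is negligible at the defaults.

What the generator does *not* emulate: positive-definiteness of subject
matrices, spatial autocorrelation between edges, within-subject noise
structure, or group-level mean connectivity gradients. Passing tests
therefore show that the estimator and test behave correctly under the
ACE sharing structure, not that real fMRI cohorts satisfy that
structure.

## Numerical choices and degenerate inputs

* Symmetry/diagonal/nonnegativity checks use tolerance $10^{-12}$;
  correlation range checks $10^{-8}$.
* Ties in edge weights collapse to one filtration level; the Betti
  profile code handles them naturally (counts of edges strictly above
  the level).
* `single_linkage_matrix()` requires a complete positive weight matrix
  and errors on structural zeros rather than guessing a disconnected
  ultrametric.
* Permutation p-values use the $\ge$ counting rule (never zero, exact
  under enumeration).
* All-zero weight matrices have no filtration and error in
  `filtration_levels()`.
* Every stochastic function takes an explicit seed; experiment objects
  record seed, replicate count and level in attributes or metadata
  headers.

## Problem sizes

The defaults used by the test suite and the acceptance script were
chosen as the smallest scales at which each claim is meaningful: the
benchmark cells at their native 100 replicates with $p$ up to 500
(a per-replicate cost of a few milliseconds for KS, thanks to the
compiled union-find core); oracle comparisons at $p \le 8$ nodes, $q \le
6$ lattice paths and diagrams of $\le 4$ points, where exhaustive
enumeration is feasible; twin recovery at 200 pairs per group and 13
nodes, where the Monte-Carlo error of the mean edgewise HI is well below
the $\pm 0.05$ recovery band.

## Known limitations

* Only $\beta_0$ and $\beta_1$: no higher homology, no clique or Rips
  complexes beyond the 1-skeleton.
* The exact null assumes exchangeable interleaving of the two Betti
  step functions; dependence between networks built from overlapping
  samples is outside its scope.
* The exact recursion is $O(qd)$ big-integer additions — practical to a
  few thousand levels, after which the asymptotic series is the intended
  tool.
* Heritability beyond Falconer's formula (maximum-likelihood ACE,
  covariates, selection) is out of scope.
* No fMRI volume I/O or parcellation: the pipeline starts from parcel
  time series or connectivity matrices.
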