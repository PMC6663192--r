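# bettinet

Exact topological inference for weighted networks built from multivariate
measurements — functional brain networks being the motivating case. Instead
of picking one arbitrary threshold to binarize a connectivity matrix,
`bettinet` analyzes *every* threshold at once: the graph filtration. Over the
filtration, the number of connected components (the zeroth Betti number,
β₀) can only grow and the number of independent cycles (the first Betti
number, β₁) can only shrink, each by at most one per deleted edge, tied
together by the Euler identity β₁ = β₀ − p + q. These two monotone Betti
curves summarize a network's topology across all scales, and their maximum
gap between two networks,

    D_q = max_i | β_j(X¹_εᵢ) − β_j(X²_εᵢ) |,     j ∈ {0, 1},

is a Kolmogorov-Smirnov-type network distance whose null distribution is
known **exactly**:

    P(D_q ≥ d) = 1 − A_{q,q} / C(2q, q),

where A_{u,v} counts monotone lattice paths staying strictly inside the band
|u − v| < d. The package evaluates this in big-integer arithmetic (C(2q, q)
overflows doubles near q ≈ 514) and by its asymptotic alternating series for
large q — so two networks can be compared in milliseconds where a permutation
test would need astronomically many reassignments.

Around that core the package provides:

* **Network construction** — Pearson correlation matrices, the metric weight
  √(1 − ρ) (triangle inequality holds) and the simpler 1 − ρ, strict
  thresholding, filtration levels (`correlation_matrix`, `metric_weights`,
  `threshold_network`, `filtration_levels`).
* **Topology** — Betti curves via a compiled union-find filtration core,
  single-linkage ultrametrics and dendrograms, persistence diagrams of
  1-skeletons (`betti_curves`, `single_linkage_matrix`, `sl_dendrogram`,
  `persistence_diagram`).
* **Distances** — L1/L2/L∞, Gromov-Hausdorff (half the L∞ gap of
  single-linkage matrices), exact bottleneck, KS on β₀/β₁, Q-modularity
  difference (`network_distance` and friends).
* **Inference** — the exact lattice-path null, its asymptotic series, the
  combined `ks_test`, and a two-sample permutation engine with full
  enumeration when feasible (`exact_tail_probability`, `asymptotic_pvalue`,
  `permutation_test`).
* **Benchmark** — the modular correlation-network simulation and its false
  positive/negative rate tables (`simulate_modular_group`,
  `rejection_rate_experiment`).
* **Twin heritability** — cosine-series compression of parcel time series,
  subject connectivity, edgewise twin correlations, Falconer's
  HI = 2(C_MZ − C_DZ), KS inference between MZ and DZ groups, and a
  synthetic ACE cohort generator (`cosine_representation`,
  `twin_group_correlation`, `falconer_heritability`, `twin_ks_inference`,
  `simulate_twin_cohort`).

## Worked example

Two groups of 5 samples on 20 nodes, one with 2 modules and one with 4,
compared by the KS cycle test and by a permutation test on the
Gromov-Hausdorff distance:

```r
library(bettinet)
set.seed(42)
g1 <- simulate_modular_group(simulate_null_group(20, 5), k = 2, sigma = 0.1)
g2 <- simulate_modular_group(simulate_null_group(20, 5), k = 4, sigma = 0.1)
net1 <- metric_weights(correlation_matrix(g1))
net2 <- metric_weights(correlation_matrix(g2))

betti_curves(net1)
#> Betti curves over 191 levels: beta0 1..20, beta1 171..0

ks_test(net1, net2, dimension = 1)
#> KS test (beta1): D = 81, q = 380, p_exact = 5.686e-08, p_asymptotic = 6.347e-08

permutation_test(g1, g2, method = "gh", max_exact = 300)
#> Permutation test (gh): observed = 0.502, p = 0.03968 (exact enumeration, 252 assignments)
```

The two-module group keeps far more cycles alive at mid-filtration than the
four-module group — a maximum β₁ gap of 81 across the 380-level union grid,
which the exact combinatorial null puts at p ≈ 6×10⁻⁸. The permutation test
on GH agrees that the groups differ, but needed all 252 reassignments to say
so at p ≈ 0.04.

The twin pipeline on a synthetic ACE cohort (additive genetic share
a² = 0.6, common environment c² = 0.2, 200 pairs per group):

```r
coh <- simulate_twin_cohort(ace_config(p = 13, a2 = 0.6, c2 = 0.2,
                                       n_mz = 200, n_dz = 200, seed = 1))
twin_ks_inference(twin_group_correlation(coh$mz_pairs),
                  twin_group_correlation(coh$dz_pairs))
#> Twin KS inference on 13 nodes (0 undefined edges)
#>   beta0: D = 12, p = 0.47
#>   beta1: D = 66, p = 0
#>   mean edgewise HI = 0.578
```

MZ edgewise correlations sit near A + C = 0.8 and DZ near A/2 + C = 0.5, so
the mean heritability index recovers a² ≈ 0.6, and the cycle curves separate
the groups decisively while the component curves alone do not — the reason
for extending KS inference from β₀ to β₁.

## Command line

A thin CLI wraps the same functions (installed at `exec/bettinet` inside the
package):

```sh
bettinet kstest --a A.csv --b B.csv --dim 1 --out ks.json
bettinet distance --a A.csv --b B.csv --method gh
bettinet permtest --group1 G1.csv --group2 G2.csv --method gh --nperm 5000 --seed 1
bettinet benchmark --config cfg.json --out rates.csv
bettinet twin-simulate --a2 0.6 --c2 0.2 --p 20 --nmz 100 --ndz 60 --seed 7 --out cohort/
bettinet twin --mz cohort/mz --dz cohort/dz --grid 0:1:0.01 --out result/
```

Matrices are plain CSV (optional label row/column, auto-detected); scalar
results are JSON with provenance metadata.

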