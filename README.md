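# egosig

Extraction of compact, functionally coherent **active-signaling network
signatures** from phosphoproteomics data.

## The problem

A phosphoproteomics experiment yields thousands of phosphosites with log2
fold changes (LFC), most of which are noise. Naive network propagation from
the differentially phosphorylated proteins recovers sub-networks of
thousands of nodes that are hard to interpret. `egosig` combines three
ideas to produce small, functionally organized signatures:

1. **Semantic edge weighting and hub correction.** Every edge of a
   protein–protein interaction network is weighted by the simGIC Gene
   Ontology similarity of its endpoints,
   `simGIC(a, b) = Σ_{t ∈ A∩B} IC(t) / Σ_{t ∈ A∪B} IC(t)`,
   over ancestor-closed annotation sets with all three GO namespaces joined
   under a virtual root, and then Laplacian-normalized,
   `w_ij ← w_ij / √(d_i d_j)`, to correct hub bias.
2. **Layered random walk with restart (RWR) with an empirical null.** Up- and
   down-regulated seed proteins are split into tyrosine kinases, other
   kinases and substrates; each layer propagates with damping 0.85; a node
   survives only if its score beats 95% of its scores on 1000
   degree-preserving random networks (simGIC re-weighted and re-normalized
   after every rewiring).
3. **Ego decomposition into supernodes and modules.** Each seed becomes the
   ego of its 2-step neighborhood, filtered by a semantic z-score
   (`z > 1.64`), re-weighted, and reduced by a joint kernel-density
   selection over topological affinity `1000·log2(2 − jsd(p_ego, p_j))` and
   functional distance `1000·log2(1 + simGIC(ego, j))`. Supernodes are
   linked by Jensen–Shannon distances between restart walks and partitioned
   into functional modules with the Leiden algorithm.

All tabular inputs and outputs are data frames / tibbles; fitted signatures
support `tidy()`, `glance()`, `autoplot()`.

## Worked example

The built-in generator creates a complete toy study — OBO ontology,
annotations, an interaction network with three planted communities of 30
proteins, and a phospho table whose signal sites sit on one "active"
community:

```r
library(egosig)
library(dplyr)

study <- synth_study(fixture_spec(seed = 1))
sig <- run_pipeline(study$edges, study$ontology, study$phospho,
                    study$tyr_kinases, study$kinases,
                    n_randoms = 100, seed = 1)
sig
#> <ego_signature>
#>   network: 90 nodes / 471 edges
#>   up: 8 nodes, 4 supernodes, 1 modules
#>   down: 17 nodes, 6 supernodes, 1 modules

tidy(sig) |> count(direction, module)
#> # A tibble: 2 × 3
#>   direction module       n
#>   <chr>     <chr>    <int>
#> 1 down      down_m01    12
#> 2 up        up_m01       7

planted_recovery(sig, study)
#> # A tibble: 1 × 3
#>   recovered off_community union_size
#>       <dbl>         <dbl>      <int>
#> 1       0.6             0         18
```

Reading: from 10 seeds the pipeline reconstructed modules covering 60% of
the planted active community's 30 proteins while admitting no protein from
the other two communities. `best_module_match()`, `fisher_enrichment()`,
`overlap_coefficient()` and friends evaluate signatures against reference
sets:

```r
active <- study$communities$protein[study$communities$community == 1]
best_module_match(sig$modules$down, active, min_size = 5)
#> # A tibble: 1 × 3
#>   module    size coefficient
#>   <chr>    <int>       <dbl>
#> 1 down_m01    12           1
```

A thin command-line wrapper covers the same flow
(`exec/egosig simulate ...`, `exec/egosig run --network ... --phospho ...`);
`write_signature()` emits GraphML/SIF/TSV/JSON artifacts plus a
reproducibility manifest.

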