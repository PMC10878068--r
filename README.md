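# hyperfilter

Analyse higher-order (hypergraph) datasets by **filtering interactions by
their size**.

Group emails, co-authored papers, protein complexes and social gatherings
are interactions among more than two entities, naturally modelled as a
hypergraph H = (V, E) with hyperedges e ⊆ V of arbitrary size. Analyses
that pool all interaction sizes implicitly assume every size tells the same
structural story. When connection patterns are instead *stratified by
interaction size*, pooling averages that structure away. `hyperfilter` is
for network-science practitioners who want to ask: *what does this dataset
look like at each scale of interaction?*

## What it does

A **size-dependent filtering** H₍∗,k₎ keeps the hyperedges with |e| ∗ k and
retains the full node set, for ∗ ∈ {=, ≥, ≤, ≠} (uniform, GEQ, LEQ,
exclusion filters) and filtering parameter k. The package provides

* the filtering algebra — `size_filter()`, `filtering_set()`,
  `is_disjoint()`, `union_filterings()` — with its identities (the uniform
  set partitions E; E₍≤k₎ ⊎ E₍≥k+1₎ = E; E₍≠k₎ = E \ E₍₌k₎) under test;
* structural measures per filtering:
  * **effective information** EI = ℋ(⟨Wᵢᵒᵘᵗ⟩) − ⟨ℋ(Wᵢᵒᵘᵗ)⟩ on the weighted
    clique projection (entropies in bits) — the strength of unique
    associations;
  * **degree assortativity**, four variants: dynamical
    ρ = ⟨k⟩²⟨k k₁⟩_E / ⟨k²⟩² − 1 and the top-bottom / top-2 / uniform
    Pearson rules over within-hyperedge degree pairs;
  * **betweenness centrality** BC(n) = Σ σᵤᵥ(n)/σᵤᵥ on shortest
    co-membership paths, per connected component;
  * **spectral communities** from the normalized hypergraph Laplacian
    L = I − D_v^{-1/2} B D_e^{-1} Bᵀ D_v^{-1/2}, with exact Hungarian
    matching (`match_labels()`) to compare labels across filterings;
* preprocessing (`preprocess()`: drop multi-edges, singleton edges, isolated
  nodes), plain-text edgelist and JSON I/O (including the public
  hypergraph-JSON dialect), seeded synthetic generators with planted
  size-stratified community structure, a tidy sweep driver
  (`sweep_metrics()`), and a CLI.

## Worked example

Small interactions are planted on one node partition (A: halves) and large
interactions on another (B: odd/even); does filtering by size recover both?

```r
library(hyperfilter)
g <- size_stratified_hypergraph(seed = 1)   # reference defaults
H <- g$hypergraph
H
#> Hypergraph: 40 nodes, 160 hyperedges
#>   edge sizes: 2:40 3:40 5:40 6:40

tab <- sweep_metrics(H, filters = c("eq", "geq", "leq", "neq"),
                     k_range = 2:6, metrics = c("ei_norm", "rho_dyn"),
                     seed = 1)
head(subset(tab, metric == "ei_norm" & filter_type %in% c("eq", "geq")), 10)
#>    filter_type k  metric  scope     value seed c
#> 1           eq 2 ei_norm global 0.7551219    1 2
#> 3           eq 3 ei_norm global 0.5203258    1 2
#> 5           eq 4 ei_norm global        NA    1 2
#> 7           eq 5 ei_norm global 0.3178855    1 2
#> 9           eq 6 ei_norm global 0.2766043    1 2
#> 11         geq 2 ei_norm global 0.1970055    1 2
#> 13         geq 3 ei_norm global 0.2029384    1 2
#> 15         geq 4 ei_norm global 0.2341327    1 2
#> 17         geq 5 ei_norm global 0.2341327    1 2
#> 19         geq 6 ei_norm global 0.2766043    1 2
```

Normalized EI falls with k for the uniform filtering — larger interactions
project to denser, more homogeneous neighborhoods with fewer unique
associations — and the k = 4 row is `NA`, not 0: no size-4 edges exist, so
the measure is undefined there and the table says so explicitly.

```r
la <- spectral_communities(size_filter(H, "leq", 3), c = 2, seed = 1)
lb <- spectral_communities(size_filter(H, "geq", 4), c = 2, seed = 1)
lf <- spectral_communities(H, c = 2, seed = 1)
mclust::adjustedRandIndex(la, g$labels_small)  #  1
mclust::adjustedRandIndex(lb, g$labels_large)  #  1
mclust::adjustedRandIndex(lf, g$labels_small)  # -0.026
mclust::adjustedRandIndex(lf, g$labels_large)  #  1
```

Each filtering recovers its stratum's planted partition perfectly
(ARI = 1). The unfiltered hypergraph locks onto the partition favored by
the denser large interactions (B) and is blind to A (ARI ≈ 0): the
lower-order structure only becomes visible after filtering.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hyperfilter.R", package = "hyperfilter"))')
Rscript $CLI generate   --type stratified --output synth.json --seed 7
Rscript $CLI preprocess --input raw.txt --output clean.txt
Rscript $CLI filter     --input clean.txt --filter geq5 --output large.txt
Rscript $CLI sweep      --input synth.json --output table.csv \
                        --filters eq,geq,leq,neq --metrics ei_norm,rho_dyn
```

Logs go to stderr; outputs are byte-reproducible given the seed.

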