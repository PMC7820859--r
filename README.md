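# eabench

`eabench` is an R package for benchmarking gene set enrichment
analysis (EA) methods. It is aimed at method developers and analysts
who want to compare EA methods under controlled conditions: six widely
used methods — ORA, GSEA, SAFE, PADOG, CAMERA (competitive null) and
SAMGS (self-contained null) — are re-implemented behind one interface,
and a synthetic-data module generates expression matrices, gene set
collections and phenotype relevance rankings with known ground truth,
so every evaluation runs without downloads.

Methods are evaluated along four axes:

- **Significance behaviour** — fraction of gene sets with nominal and
  BH-adjusted p below a cutoff.
- **Type I error** — mean fraction of sets with nominal p < 0.05 when
  the binary sample labels are repeatedly shuffled.
- **Gene-set-size dependency** — fraction of *random* gene sets called
  significant as a function of set size (5–500).
- **Phenotype relevance** — how much a-priori relevance a method's
  ranking accumulates near its top. A ranking of N sets assigns each
  set the weight `w = 1 − r_A/N` (tie-aware generalization available),
  and is scored against a relevance ranking `S_p` by

  ```
  X = Σᵢ w(i) · S_p(i),   X̄ = X / O_p ∈ [0, 1],
  ```

  where `O_p` is the score of the ranking ordered by `S_p` itself.
  Two empirical nulls qualify an observed score: random rankings
  (enumerated exhaustively for small N) and rankings from re-running
  the method under label permutations.

RNA-seq counts are bridged to the microarray-era statistics by a
variance-stabilizing log-CPM transform whose prior count is
`0.5 / φ̂`, with `φ̂` a common negative-binomial dispersion estimate.

## Worked example

```r
library(eabench)

sim <- simulate_expression(n_genes = 1000, n_per_group = 8,
                           de_fraction = 0.25, effect_size = 1, seed = 1)
sc  <- make_scenario(sim$dataset, sim$truth, n_sets = 40,
                     frac_enriched = 0.25, relevance_noise = 0.5, seed = 1)

rk <- run_method("padog", sim$dataset, sc$collection, n_perm = 1000, seed = 1)
rk
#> EARanking: padog ( competitive ), 40 gene sets
#>    set_id size statistic p_value  adj_p rank weight
#> 1  set006   52    1.9655 0.02897 0.5195    1  0.975
#> 2  set008   27    2.4060 0.03197 0.5195    2  0.950
#> 3  set009   60    1.3553 0.03896 0.5195    3  0.925
#> ...
```

The scenario planted sets `set001`–`set010` as truly enriched; PADOG
ranks them at the top. Scoring the ranking against the scenario's
relevance ranking:

```r
res <- optimal_and_relative(rk, sc$relevance)
p   <- random_ranking_pvalue(rk, sc$relevance, n_random = 1000, seed = 1)
#> X = 88.36, O = 91.74, X_bar = 0.963, p_random = 0.000999
```

`X_bar = 0.963` says PADOG's ranking realizes 96% of the maximum
achievable relevance; no random ranking among 1000 came close. The
full driver compares methods side by side:

```r
report <- run_benchmark(
  list(scenario1 = list(dataset = sim$dataset,
                        collection = sc$collection,
                        relevance = sc$relevance)),
  methods = c("ora", "padog", "camera", "samgs"), n_perm = 200, seed = 1)
#>   method     hypothesis frac_nominal frac_fdr X_bar p_random
#> 1    ora    competitive        0.125     0.05 0.877 0.011988
#> 2  padog    competitive        0.075     0.00 0.965 0.000999
#> 3 camera    competitive        0.000     0.00 0.806 0.375624
#> 4  samgs self_contained        0.900     0.90 0.468 1.000000
```

The self-contained SAMGS calls 90% of all sets significant (its null
is violated by the dataset's background differential expression) yet
accumulates far less relevance near the top of its ranking than the
competitive methods — the central trade-off this harness is built to
expose. Assays for type-I error and set-size dependency are available
as `type_one_error_assay()` and `random_set_size_assay()`; see the
vignette in `vignettes/` for the model, parameter and design details.

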