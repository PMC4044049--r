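# astax

Taxonomy-aware subsampling of homologous sequences for phylogenetics.

## The problem

Gene-tree inference starts from the homologs of a query sequence, and that
pool is usually both too large for accuracy-oriented alignment/tree methods
and heavily biased toward densely sequenced clades. The common shortcuts —
keep the `m` hits most similar to the query, or pick `m` at random — lose
deep taxonomic lineages: similarity sampling concentrates in the query's own
neighbourhood, random sampling under-represents sparse clades. `astax` is
for anyone who needs a defensible, automated, reproducible subset: it
selects `m` of `n` homologs so that taxonomic diversity is maximised and the
selection spreads as evenly as the pool allows over a rooted taxonomy (the
NCBI taxonomy or any child–parent edge list).

## The algorithm

Levels count from the root (root = level 1). At a taxon `T` with children
`T_1 … T_G`, of which `G'` contain homologs (`n_i` of them in the subtree of
`T_i`), a quota `m` is split

```
m_i = int(m/G') + 1   for the first m − G'·int(m/G') children
m_i = int(m/G')       for the rest
m_i = 0               where n_i = 0
```

with children sorted by descending `n_i` (ties by id), so non-zero quotas
are equal or differ by 1. Quotas are capped at `n_i`, surplus flows to the
smallest quota with remaining capacity, and the recursion descends: a leaf
taxon returns its `m_i` best-scoring sequences; a subtree whose quota
reaches 1 returns its single best-scoring sequence. Everything is
deterministic — identical inputs give byte-identical outputs. Baselines:
similarity sampling (`ss_sample()`) and seeded uniform sampling
(`rs_sample()`).

## Worked example

The bundled toy taxonomy has three domains under the root `C`: archaea `A`
(sub-taxa `A1`–`A3`, 8 sequences), bacteria `B` (`B1`–`B2`, 3 sequences) and
eukaryotes `E` (empty):

```r
library(astax)
tree <- read_taxonomy_edges(system.file("extdata", "cellular_example_edges.tsv", package = "astax"))
pool <- read_homolog_table(system.file("extdata", "cellular_example_homologs.tsv", package = "astax"))
ast_sample(pool, tree, m = 5)
#> <AST sample> 5 of 5 requested sequence(s)
#> # A tibble: 5 × 5
#>   seq_id taxon_id score lineage rule
#>   <chr>  <chr>    <dbl> <chr>   <chr>
#> 1 s01    A1        412  C;A;A1  leaf-top-similarity
#> 2 s05    A2        362. C;A;A2  leaf-top-similarity
#> 3 s08    A3        278. C;A;A3  leaf-top-similarity
#> 4 s09    B1        256. C;B;B1  leaf-top-similarity
#> 5 s11    B2        188  C;B;B2  leaf-top-similarity
```

The quota 5 was split 3:2 over archaea and bacteria (8 vs 3 homologs), then
one sequence — the best-scoring — was taken per sub-taxon: all five deepest
taxa are covered. Similarity sampling at the same size keeps only the two
archaeal taxa with the strongest hits:

```r
c(AST = coverage_at_level(ast_sample(pool, tree, 5), tree, 3),
  SS  = coverage_at_level(ss_sample(pool, 5), tree, 3),
  all = coverage_at_level(pool, tree, 3))
#> AST  SS all
#>   5   2   5
```

The same comparison at scale, on simulated biased taxonomies (1024 of 2048
leaves, 10% from the left root branch), measuring how many of the ~116
occupied level-8 taxa each method covers:

```r
res <- run_benchmark(kind = "asymmetric", x = 0.1, m_list = c(50, 100, 200),
                     n_replicates = 20, methods = c("AST", "RS", "all-seq"),
                     levels = 8, base_seed = 1)
tidy(res)
#> # A tibble: 7 × 6
#>   method      m level  mean    sd n_replicates
#>   <chr>   <dbl> <dbl> <dbl> <dbl>        <int>
#> 1 AST        50     8  50    0              20
#> 2 AST       100     8  96.2  1.44           20
#> 3 AST       200     8 117.   2.01           20
#> 4 RS         50     8  38.4  2.59           20
#> 5 RS        100     8  58.4  3.98           20
#> 6 RS        200     8  77.9  3.74           20
#> 7 all-seq  1024     8 117.   2.01           20
```

At `m = 50` the taxonomy-aware sampler covers essentially one taxon per
sequence (50 of 50 possible); at `m = 200` it saturates the coverage of the
full 1024-sequence pool, while random sampling still misses a third of the
occupied taxa. `autoplot(res)` draws the coverage-vs-`m` curves.

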