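# mirtrait

Infer and analyse miRNA–disease association networks in R.

MicroRNAs (miRNAs) silence their target mRNAs post-transcriptionally, and
their dysregulation propagates through gene-regulatory networks into disease.
Curated resources catalogue two halves of that chain separately:
miRNA → target-gene interaction databases (miRTarBase-style exports) and
gene → disease association databases (DisGeNET-style exports). `mirtrait`
joins the two halves on the shared gene key,

    miRNA → gene,  gene → disease   ⟹   miRNA → disease,

and builds a bidirectional association database (miRNA → diseases and
disease → miRNAs) together with a toolkit for interrogating it. It is aimed
at computational biologists who want reproducible, scriptable miRNA–disease
analyses: querying, spectrum statistics, enrichment testing of miRNA lists,
diseasome profiling, and network-level hub discovery.

## The statistics at the core

**Spectrum widths.** With `M_N` miRNAs and `D_N` diseases in the merged
database, the disease spectrum width of miRNA *i* with `d_i` associated
diseases is `DSW(i) = d_i / D_N`, and the miRNA spectrum width of disease *j*
with `m_j` associated miRNAs is `MSW(j) = m_j / M_N`. High DSW flags putative
master-regulator miRNAs; high MSW flags multifactorial pathologies.

**Disease enrichment of a miRNA list.** For each disease the 2×2 table

|                    | associated | not associated | sum |
|--------------------|-----------:|---------------:|----:|
| miRNAs in input    | a          | b              | a+b |
| miRNAs not in input| c          | d              | c+d |
| sum                | a+c        | b+d            | n = M_N |

is scored with the one-sided upper-tail hypergeometric probability
`P(X ≥ a)`, `X ~ Hypergeom(n, a+c, a+b)` — identical to the one-sided Fisher
exact test — plus the sample odds ratio `(a·d)/(b·c)` (`Inf` when `b = 0`,
i.e. the whole query list is associated). All `D_N` diseases are tested and
corrected with Benjamini–Hochberg (default), Holm, or Bonferroni.

**Diseasome abundance.** For a disease set selected explicitly or by
case-insensitive regex keyword, each miRNA's occurrence is the number of
diseasome diseases whose miRNA set contains it.

**Enrichment networks and consensus hubs.** Every miRNA–miRNA (or
disease–disease) pair is scored by the same hypergeometric overlap test over
the full universe, BH-corrected across all N(N−1)/2 pairs; significant edges,
weighted by odds ratio, form a network ranked by −log10 p and truncated to
the top k. Seven weighted centrality measures (degree, betweenness,
closeness, eigenvector, network/ECC, local average connectivity, information)
plus optional Monte-Carlo edge-percolation centrality rank the nodes, and
nodes appearing in ≥ 5 of the 7 top-100 lists are reported as consensus hubs.

## Worked example

The package ships a small synthetic mapping pair under `inst/extdata`
(generated by its own fixture module, with one planted enriched disease).

```r
library(mirtrait)

mg <- read_mapping(system.file("extdata", "synthetic_mirna2gene.tsv",   package = "mirtrait"))
gd <- read_mapping(system.file("extdata", "synthetic_gene2disease.tsv", package = "mirtrait"))
db <- build_db(merge_on_key(mg, gd))
#> merge_on_key: 12 source(s) did not map to any target
db
#> <assoc_db> 27 miRNAs (M_N) <-> 23 diseases (D_N), 49 associations
```

Twelve synthetic miRNAs target only genes with no disease annotation and are
dropped by the merge — the count is always reported, since the merged
universes `M_N`/`D_N` are the denominators of everything downstream.

```r
rank_spectrum(db, by = "DSW", top = 3)
#> # A tibble: 3 × 4
#>    rank name            count width
#>   <int> <chr>           <int> <dbl>
#> 1     1 hsa-miR-0004-3p     4 0.174
#> 2     2 hsa-miR-0014-3p     4 0.174
#> 3     3 hsa-miR-0018-3p     4 0.174
```

Each of the top miRNAs is associated with 4 of the 23 diseases
(DSW = 4/23 ≈ 0.17). Enrichment of the planted query list recovers the
planted disease as the single significant hit, with the infinite odds ratio
that signals full containment (`b = 0`):

```r
query <- c("hsa-miR-0040-3p", "hsa-miR-0023-5p", "hsa-miR-0035-5p",
           "hsa-miR-0025-5p", "hsa-miR-0028-3p")
enrich(db, query, alpha = 0.05, method = "bh")
#> <mirtrait_enrichment> 1 of 23 diseases at q <= 0.05 (bh; 5 input miRNAs)
#> # A tibble: 1 × 9
#>   disease          a     b     c     d odds_ratio log2_or        p      q
#> * <chr>        <int> <int> <int> <int>      <dbl>   <dbl>    <dbl>  <dbl>
#> 1 Disease 0001     5     0     3    19        Inf     Inf 0.000694 0.0160
```

All five query miRNAs are associated with `Disease 0001` (`a = 5`, `b = 0`);
under the null, a random 5-miRNA draw would contain at least five of its
eight associated miRNAs with probability 6.9×10⁻⁴, and the BH-adjusted
q-value across all 23 diseases is 0.016. Results are tibbles, so they chain
with dplyr verbs; `tidy()`, `glance()` and `autoplot()` methods are provided
for enrichment results and centrality reports.

The same pipeline is scriptable from a shell via `exec/mir2trait`
(subcommands `build`, `query`, `spectrum`, `enrich`, `diseasome`, `network`,
`hubs`, `simulate`; results on stdout, logs on stderr).

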