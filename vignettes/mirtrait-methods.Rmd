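---
title: "Methods: merging, enrichment, and network statistics in mirtrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merging, enrichment, and network statistics in mirtrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrait)
```

## The model

`mirtrait` treats miRNA–disease association as a composition of two curated
binary relations. If $T \subseteq \mathcal{M} \times \mathcal{G}$ records
experimentally supported miRNA–target interactions and
$A \subseteq \mathcal{G} \times \mathcal{D}$ records gene–disease
associations, the inferred relation is the relational join on the gene key:

$$ (m, d) \in R \iff \exists\, g:\ (m, g) \in T \ \wedge\ (g, d) \in A. $$

The assumption is transitivity of association evidence through the shared
gene: a miRNA that regulates a disease gene is a candidate participant in
that disease. This is deliberately permissive — it proposes hypotheses, not
causal claims — and it inherits every curation bias of the two sources.
miRNAs none of whose targets carry a disease annotation vanish in the join;
the package always reports that dropped count because the post-merge
universes $M_N$ (miRNAs) and $D_N$ (diseases) are the denominators of every
statistic downstream.

Name identity is exact string match after trimming surrounding whitespace.
There is no case folding of stored keys and no identifier normalisation:
the merge is on literal gene symbols, and disease names are kept verbatim
(so near-duplicate disease labels in the source remain distinct entries).
Query-side matching (user miRNA lists, disease keywords) is
case-insensitive, since capitalisation of miRNA names varies wildly in
practice.

## Spectrum widths

$\mathrm{DSW}(i) = d_i / D_N$ and $\mathrm{MSW}(j) = m_j / M_N$, where $d_i$
is the number of diseases associated with miRNA $i$ and $m_j$ the number of
miRNAs associated with disease $j$. Both are kept at full precision
internally; report tables round half-up to two decimals, matching the
convention of published spectrum tables (half-up, not banker's rounding, so
0.175 prints as 0.18). Ranking ties are broken lexicographically by name so
output is deterministic.

## Enrichment of a miRNA list

For each disease the 2×2 contingency table $(a, b, c, d)$ with total
$n = M_N$ is scored with the one-sided upper-tail hypergeometric probability

$$ p = P(X \ge a), \qquad X \sim \mathrm{Hypergeom}(n,\ a{+}c,\ a{+}b), $$

which coincides exactly with the one-sided Fisher exact test. One-sided is
the right choice here: "enrichment" is over-representation only, and only in
the one-sided case does the Fisher/hypergeometric identity hold exactly.
The implementation delegates the tail to `stats::phyper`; the test suite
checks it against an independent exact enumeration over every table with
$n \le 60$ (agreement within $10^{-12}$).

Decisions worth stating explicitly:

* **Hypothesis family.** Every disease in the database is tested
  ($m = D_N$ hypotheses), not only diseases overlapping the query. Testing
  only overlapping diseases would make the family — and hence the adjusted
  q-values — depend on the query itself.
* **Correction.** Benjamini–Hochberg is the default; Holm and Bonferroni are
  available. All three preserve input order and satisfy $q \ge p$;
  Holm $\le$ Bonferroni everywhere.
* **Effect size.** The unconditioned sample odds ratio $(a d)/(b c)$ with
  explicit sentinels: `Inf` when $ad > 0,\ bc = 0$ (in particular $b = 0$:
  the whole query list is associated with the disease), `0` when
  $ad = 0,\ bc > 0$, `NaN` (not applicable) for $0/0$. No Haldane–Anscombe
  half-count correction is applied — the sentinel is informative and the
  ranking uses q-values, with the odds ratio only as a tie-break
  (descending, `Inf` first).
* **Defaults.** q-value threshold `alpha = 0.05`, method `"bh"`.

## Diseasome abundance

A diseasome is selected either explicitly or by a case-insensitive,
unanchored regular expression over disease names (R's default regex
dialect; the same semantics as the package's query operation). Abundance is
pure occurrence counting — the number of diseasome diseases whose miRNA set
contains a given miRNA — with a user-specified minimum count that is always
echoed in the output. No statistical test is attached; enrichment belongs to
the module above.

## Pairwise enrichment networks

For miRNA mode, each unordered pair $(u, v)$ is scored by the overlap of
their disease sets against the disease universe:
$a = |S_u \cap S_v|$, $b = |S_u| - a$, $c = |S_v| - a$,
$d = D_N - a - b - c$, with the same hypergeometric tail and odds ratio as
above (disease mode swaps the roles). The construction is symmetric in the
pair. BH correction runs across all $N(N-1)/2$ scored pairs; edges with
$q \le \alpha$ (default 0.05) are kept, ranked by $-\log_{10} p$ and
truncated to the top $k$ (default 10,000). Overlap counts for all pairs come
from one sparse cross-product, so full-scale databases (thousands of nodes,
millions of pairs) are feasible on a desktop.

Numerical and determinism choices: $-\log_{10} p$ is capped at 320 where
$p$ underflows to zero; ranking among capped values falls back to odds
ratio descending, then the lexicographic $(u, v)$ pair. Node pairs are
always emitted with $u < v$ lexicographically, and the exported TSV is
byte-identical across runs and input row orderings.

## Centrality and consensus hubs

The analysis graph is undirected, simple, and weighted by the odds ratio;
infinite odds-ratio weights are replaced by the maximum finite weight in the
network (configurable) so all weights are finite and positive. Seven
measures are computed:

* **degree** — sum of incident weights;
* **betweenness, closeness** — shortest paths under distance $1/w$ (stronger
  enrichment = closer), per connected component; isolated nodes score 0;
  closeness of $v$ is $(n_c - 1)/\sum_u \delta(v, u)$ within its component;
* **eigenvector** — principal eigenvector of the weighted adjacency by power
  iteration at tolerance $10^{-10}$, scaled to unit maximum; the iteration
  matrix is shifted by the identity so bipartite components (whose spectrum
  is symmetric) still converge;
* **network centrality** — $NC(v) = \sum_{u \in N(v)} \mathrm{ECC}(u, v)$,
  where the edge clustering coefficient is the weighted triangle count
  through the edge (geometric-mean edge weights) divided by
  $\min(\deg_u, \deg_v) - 1$ (unweighted degrees), and 0 when the
  denominator or the triangle count vanishes;
* **local average connectivity** — the mean degree of $v$'s neighbours
  within the subgraph induced by $N(v)$;
* **information centrality** — the resistance-distance (current-flow)
  formulation with conductances equal to the weights, computed per
  component from the inverse of $L + J$ ($L$ the weighted Laplacian, $J$ the
  all-ones matrix).

These formulas are fixed in code so results are reproducible without any
external network tool. Betweenness/closeness/components use igraph;
eigenvector, NC, LAC and information centrality are implemented here
because no installed package provides these exact weighted variants.

**Edge-percolation centrality** is Monte-Carlo: each replicate retains edge
$e$ independently with probability $w_e / \sum w$, and a node's score is the
mean fraction of other nodes remaining in its component. It is seeded,
deterministic given (graph, reps, seed), and documented as approximate; it
is excluded from any exact comparison and is off by default in the
consensus.

**Consensus.** Each measure ranks all nodes (score descending, ties broken
by name); a node's agreement is the number of measures whose top-$t$ list
(default $t = 100$) contains it, and nodes with agreement $\ge 5$ (of 7)
are consensus hubs. The boundary is inclusive: agreement exactly 5 is in,
exactly 4 is out.

## The synthetic fixture generator

The generator emulates the two source mappings so the entire pipeline is
testable offline: independent Bernoulli edges at stated densities, with
optional planted structure overlaid (edges are only added, never removed, so
the densities are lower bounds). Names mimic real nomenclature
(`hsa-miR-<k>-5p/-3p` with alternating arms, `GENE<k>`, `Disease <k>`) so
regex queries are exercised realistically, including arm suffixes.

Defaults: 100 miRNAs × 600 genes × 80 diseases with miRNA–gene density
0.005 and gene–disease density 0.01. These were chosen, once, to mirror the
sparsity scale of the real resources: ≈3 target genes per miRNA, ≈0.5
miRNAs per gene, and a merged association fill of ≈4% — the same order as
the real merged resource, where the modal miRNA is associated with a few
percent of diseases. At these densities a few miRNAs per fixture target
only disease-free genes and drop out of the merge, reproducing in
miniature the small contraction the real merge exhibits. A power analysis
at these defaults (100 seeds) recovers the planted enriched disease at rank
1 with infinite odds ratio in 100/100 fixtures for 5-miRNA queries.

Planted structures:

* **hub** — one miRNA wired to a stated fraction of all genes (top DSW after
  the merge);
* **enriched disease** — one disease whose gene set is extended to contain
  every target of a sampled query set, so the query is fully contained
  ($b = 0$, odds ratio `Inf`) after the merge;
* **cliques** — miRNA blocks given identical dedicated gene sets wired to
  sampled disease sets. The dedicated genes live outside the background
  gene pool; otherwise background miRNAs that happen to target a clique
  gene would inherit the whole block's diseases. Even so, the Bernoulli
  background occasionally produces twin miRNAs that share a background gene
  and therefore share that gene's disease set — such pairs are genuinely
  high-overlap and may legitimately appear in the significant edge set
  alongside the planted cliques.

What the generator does *not* emulate: the heavy-tailed degree
distributions, name synonymy, and curation biases of the real databases.
Passing tests demonstrate correctness of the algorithms under controlled
structure, not fidelity of any particular biological conclusion.

## Null calibration and the discreteness of exact p-values

`null_db()` generates a structure-free database directly: each disease
draws its miRNA-set size as a uniform fraction of the miRNA universe
(default $U(0.3, 0.7)$ of $M = 4000$, 600 diseases) and fills it uniformly
at random. Against random queries, the enrichment p-values are then exactly
valid, and their distribution should look uniform.

"Look uniform" needs care with an exact discrete test. A one-sided
hypergeometric p-value for a query of size $q$ takes at most
$\min(q, K) - \max(0, q{+}K{-}M) + 2$ values per disease; its ECDF is a step
function that touches the diagonal only at attainable points, and the
pooled ECDF sits *below* the diagonal by roughly half the local support
spacing — about $1/(4\sqrt{\pi}\,\sigma)$ for hypergeometric standard
deviation $\sigma$. For 5-miRNA queries ($\le 6$ support atoms) that
deficit is ±0.2 and no mixture of margins can remove it: a
Kolmogorov–Smirnov test against the uniform will always reject, not
because the test is miscalibrated but because discreteness makes strict
uniformity unattainable. The calibration study therefore uses queries of
half the universe ($q = M/2 = 2000$), where $\sigma \approx 16$ and the
deficit is below 0.01, safely inside the KS acceptance region at 1,000
draws. The acceptance suite runs exactly this study at a fixed seed and
additionally checks the empirical type-I rate at the 0.05 level within
three binomial standard errors. Small-query validity is still exercised —
conservatively, as theory dictates — by the planted-recovery tests, which
use 5-miRNA queries throughout.

## Problem sizes and runtime choices

The test suite exercises networks up to ~200 nodes (exhaustive
$N(N-1)/2$-pair coverage is asserted there), exhaustively enumerates all
contingency tables with $n \le 60$ against an independent oracle,
and uses 100-seed recovery and 1,000-draw calibration studies; the whole
suite runs in about a minute. These sizes are the package's own choice of
desk-scale study; the implementation itself supports full-scale databases
(the all-pairs scorer is a single sparse matrix product).

## Degenerate inputs and edge cases

* Empty forward map → hard error at `build_db()`; empty merge results are
  legal and logged.
* Queries matching nothing return empty tibbles, not errors; invalid regex
  patterns error naming the dialect.
* Unknown miRNAs in an enrichment query are dropped with a warning; an
  all-unknown query is a hard error listing the rejects.
* An all-`a` table ($b = c = d = 0$) yields $p = 1$ (the upper tail at the
  minimum of a degenerate distribution) and an undefined odds ratio.
* Self-loops and duplicate edges are rejected when building the analysis
  graph; infinite weights are substituted before any centrality runs.
* `top` / `top_k` larger than the universe are clamped, never errors.

## Known limitations

* The merge proposes associations by transitivity; it cannot distinguish
  direction of effect, and a hub gene shared by many diseases inflates all
  its miRNAs' spectra.
* Disease names are verbatim strings; synonymous labels are distinct
  entries unless the input is pre-normalised.
* The pairwise network construction reads "pair enrichment" as set-overlap
  enrichment against the full universe — a symmetric and well-defined
  choice, but not the only conceivable one.
* Edge-percolation centrality depends on a normalisation convention
  (retention probability $w_e/\sum w$); rankings, not raw scores, are the
  meaningful output, and the measure is reported as approximate.
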