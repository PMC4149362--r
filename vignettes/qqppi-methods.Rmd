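---
title: "Methods: QQPPI network construction and disease-marker discovery"
author: "qqppi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QQPPI network construction and disease-marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qqppi)
```

# Overview

`qqppi` implements a network-based procedure for prioritising disease
markers from case/control expression data, of the kind used to study
neurodegenerative disease transcriptomes (e.g. post-mortem substantia
nigra samples from Parkinson's disease patients against controls). The
pipeline has eight stages:

1. **Differential expression.** Two parallel selections: a two-sample
   *t* statistic at a raw two-sided P threshold, and Significance
   Analysis of Microarrays (SAM) at a permutation-estimated FDR target.
2. **Functional filtering.** A hypergeometric over-representation test
   against a biological-process annotation; only differentially
   expressed (DE) genes that fall in significant terms proceed.
3. **QQPPI construction.** The filtered gene set is used as a query
   against one or more interactome edge lists; the Query-Query PPI
   network is the interactome subgraph induced on the query set.
   Networks from separate interactome sources are merged by edge union.
4. **Topology.** Degree and betweenness centrality; hubs and
   bottlenecks are classified by the rules below.
5. **Cliques.** All 3- and 4-cliques; their union is the core
   functional module.
6. **Complexes.** Clique-forming proteins are matched against a
   protein-complex catalog.
7. **Co-expression.** Per-edge Pearson correlation within the control
   group (C) and within the disease group (D), the change C − D, and
   the percent of the maximum possible change, 100·(C − D)/2.
8. **Markers.** Per network, (hubs ∪ bottlenecks) minus a curated
   known-disease-gene list; the cross-network union is the novel-marker
   set, annotated with clique, complex and neurotransmitter evidence.

The two DE branches stay separate through stages 2-7 and are combined
only at the marker stage, mirroring the two-network study design.

# Statistical model and rules

## Two-sample t

For each gene, with control values $x_1,\dots,x_n$ and disease values
$y_1,\dots,y_m$,

$$ t = \frac{\bar{x} - \bar{y}}{\sqrt{s_x^2/n + s_y^2/m}} $$

with sample standard deviations ($n-1$ denominators). The default is
this Welch form with Welch-Satterthwaite degrees of freedom; the
classical pooled-variance form is available via `variant = "pooled"`.
The two forms coincide for equal group sizes and equal variances, and
on data of this type (moderate, unequal group sizes; heteroskedastic
genes) Welch is the safer default; the separate $s_x$, $s_y$, $n$, $m$
symbols in the statistic match the Welch form. Selection uses the raw
two-sided P value with **no multiplicity adjustment** — the procedure
deliberately mirrors designs that select at raw P < 0.001 — so the
expected false-positive count is $\alpha \cdot n_{\text{genes}}$ and is
verified by the calibration tests. Genes constant at the same value in
both groups have an undefined statistic; they are flagged and excluded
rather than silently assigned $t = 0$.

## SAM

The relative difference for gene $i$ is

$$ d_i = \frac{\bar{y}_i - \bar{x}_i}{s_i + s_0} $$

where $s_i$ is the pooled gene-specific scatter and $s_0$ an
exchangeability constant that damps the statistic for low-variance
genes. $s_0$ is chosen as the percentile of the $s$ distribution
minimising the coefficient of variation of the median absolute
deviation of $d$ across windows of $s$ (the classical automatic
choice); `s0Policy = "median"` uses the median of $s$ instead.

Significance is assessed against expected order statistics of $d$
under group-label permutations: all distinct assignments when their
count does not exceed `nPermutations` (default 200), otherwise a
seeded sample without replacement. For a threshold $\delta$, the upper
cut is the smallest positive sorted $d$ whose excess over its expected
order statistic reaches $\delta$ (symmetrically for the lower cut);
genes beyond the cuts are called, UR for $d > 0$ and DR for $d < 0$.
The FDR at $\delta$ is the median across permutations of the number of
permuted $d$ values beyond the cuts, divided by the observed called
count. Two numerical choices:

* when no genes are called the ratio is reported as 0 (with a logged
  note) rather than 0/0;
* the reported FDR column is the **running minimum over the ascending
  delta grid**. The raw median-ratio estimate is not guaranteed
  monotone in $\delta$ even though called sets are nested; the monotone
  envelope makes "smallest delta with FDR at most the target" well
  defined and the called set monotone in the target.

An optional fold-change filter additionally requires the average
disease/control ratio, $2^{\bar{y}-\bar{x}}$ on the log2 scale, to
exceed the threshold (or fall below its inverse for DR calls). It is
off by default: the reference analysis states the mechanism but no
threshold for its FDR-0.19% run.

## Enrichment filter

For a term with $K$ background genes, a query of size $n$ from a
background of size $N$, and an overlap of $k$, the p-value is the
upper hypergeometric tail $P(X \ge k)$. The background is the full
expression dataset after probe collapse. The threshold is raw
p < 0.05 with no adjustment, matching the stated selection rule of the
reference procedure; Benjamini-Hochberg is available via
`adjust = "BH"`. Term-graph propagation (ancestor closure) is out of
scope; terms are taken as flat gene sets.

## Hubs and bottlenecks

With $M$ and $S$ the mean and standard deviation of the degree
distribution, the hub cutoff is $M + 2S$; hubs are nodes with degree
at least the **unrounded** cutoff (degrees are integers, so a printed
cutoff of 11.8 ≈ 12 behaves identically). $S$ uses the sample
($n-1$) convention by default (`sdMode = "population"` available); the
printed tables this rule reproduces do not state which was used. A
regular graph has $S = 0$, making every node a hub; this degenerate
case is flagged with a warning rather than treated as an error.

Bottlenecks satisfy all three of: betweenness in the top half of the
descending-sorted distribution, with **ties at the boundary value
included** (the rule is positional, and excluding ties would make the
result depend on sort stability); degree strictly below the hub
cutoff; and at least two hub neighbours. A network with fewer than
two hubs therefore has no bottlenecks.

Betweenness is the Brandes shortest-path centrality on the unweighted,
undirected graph: each unordered pair counted once, endpoints
excluded, no normalisation — the convention consistent with the
magnitudes in the summary tables this package reproduces (e.g. a
maximum near 21,000 on a 406-node network). Disconnected networks are
handled per component with the rules applied globally.

## Cliques, complexes, co-expression, markers

Clique enumeration is an edge-iterator: triangles arise from common
neighbours of each edge's endpoints (each triangle once, in canonical
node order), 4-cliques extend each triangle by a common neighbour
above its largest member. By default **all** complete subgraphs are
counted, so a 4-clique contributes its four triangles to the 3-clique
list; `maximalOnly = TRUE` excludes contained cliques. The counting
convention of the published totals is unstated; all-subgraph counting
is the simpler, invariant-checkable semantics (every 4-clique implies
exactly four 3-cliques). A 5-clique, which would violate the
assumption that only 3- and 4-cliques occur, is detected and warned
about. The core functional module is the union of all 3-/4-cliques
with per-node occurrence counts.

Complex matching reports every catalog complex containing at least
`minQuery` clique-forming proteins (5 and 4 were the per-network
values in the reference analysis; the package takes it per run).
No enrichment statistic is attached: membership counting is the
published procedure.

Per-edge co-expression uses the Pearson product-moment correlation of
the endpoint genes across control samples and across disease samples
separately (at least 3 samples per group). Since $r \in [-1, 1]$, the
change $C - D$ has maximum magnitude 2, and the percent of maximum
change is $100 (C - D)/2$. Constant expression vectors make $r$
undefined; such records are excluded with a warning — a silent zero
would bias change statistics toward 0. Report tables print 6 decimals;
recomputation from printed (rounded) inputs can differ in the last
digit, which the acceptance checks restrict to rounding-consistent
cells.

Marker identification is set arithmetic: per network the candidates
are (hubs ∪ bottlenecks) \\ known, the multiplicity total is the sum
of per-network candidate counts, and the unique marker set is the
union with per-network provenance. Equality of the two counts holds
exactly when no candidate is shared between networks. The known list
is an opaque curated input (literature/database snapshots are not
reproducible programmatically). Neurotransmitter association is
likewise consumed as a curated table, never computed.

## Merging networks

The merged QQPPI network is the **union** of nodes and edges, with
per-edge provenance concatenated. The alternative reading
(intersection) is available via `mode = "intersection"` but is not the
default: merging exists to maximise interactome coverage across
database exports, and the workflow that motivated it combined over a
dozen databases. Isolated query genes are dropped by default — only
interacting queries become network nodes, which is what makes a
779-gene query yield a 406-node network in the reference tables —
and can be kept with `keepIsolated = TRUE`.

# The synthetic-data module

The generators emulate the statistical shape of the study inputs, with
ground truth for recovery testing. Defaults are the package's fixed
study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `nGenes` | 2000 | genes in the expression matrix |
| `nControl`, `nDisease` | 15, 24 | small unbalanced groups, as in pooled brain-region designs |
| `deFraction` | 0.1 | planted DE fraction |
| `upFraction` | 0.2 | share of DE genes up-regulated (the reference SAM split was ~19% UR) |
| `effectSize` | 2 | mean log2 shift in the disease group |
| `noiseSd` | 0.5 | within-group SD, log2 units |
| `nProteins`, `edgesPerNode` | 500, 2 | interactome size/density |
| `nPlantedCliques`, sizes | 4, {3, 4} | planted fully connected subsets |
| `nPlantedHubs` | 5 | planted high-degree nodes |

Expression is generated directly on the log2 scale (normalised
microarray output is log2; nothing downstream needs raw intensities):
baseline means uniform on [4, 10], i.i.d. Gaussian noise, DE genes
shifted by ±`effectSize` in the disease group only. The variance
structure of the motivating dataset is not published; `noiseSd` is a
free parameter of the generator, not an estimate of that study.

Interactomes come in three models: preferential-attachment
(`scale_free`, the default null for heavy-tailed degree
distributions the hub rule assumes), a truncated-power-law
configuration model, and `planted` — an Erdős-Rényi background
overlaid with fully connected planted cliques and with hub nodes wired
until they clear the empirical $M + 2S$ cutoff with a one-edge margin.
Planted cliques and hubs are placed on planted DE genes when enough of
them fall in the node set, and 80% of each hub's added edges go to DE
nodes: planted hubs are hubs *of the disease module*, reflecting the
assumption that similarly expressed proteins preferentially interact.
This is what lets the end-to-end pipeline recover planted structure
after the query induction step; a hub wired uniformly at random would
lose most of its degree when the network is restricted to DE queries.

What the generator does **not** emulate: probe-level noise and probe
multiplicity beyond identical replicate rows (`probesPerGene` writes
duplicate rows purely to exercise the collapse policy), batch and
array effects, correlated gene-gene noise outside the planted
co-expression pairs, and the topology of any real interactome beyond
degree heavy-tailedness. Passing recovery tests on these inputs
demonstrates internal consistency of the statistics and rules, not
performance on real microarray data.

All generators are deterministic given `seed`; sub-stages draw from
fixed seed offsets so the expression matrix, interactome, catalog and
annotation can be generated independently yet consistently.

# Problem sizes and verification

The test suite verifies the implementation against independent
oracles: betweenness against an all-pairs path-counting BFS oracle and
clique enumeration against exhaustive subset scans (200 random graphs
of up to 30 nodes in the acceptance suite), the hypergeometric tail
against an explicit binomial-coefficient sum, group summaries and
correlations against two-pass summation, and the t statistic against
both the closed form and `stats::t.test`. Calibration and recovery
run at the default study conditions (2000 genes, 15 + 24 samples) over
20 seeds: the t stage's type-I rate at α = 0.001 is checked against a
three-sigma binomial bound, and SAM at an FDR target of 0.0019 is
required to recover at least 90% of planted DE genes with a realized
false-call fraction at most 1%. Published-table arithmetic (hub
cutoffs M + 2S, average degrees 2E/V, co-expression changes C − D,
and the 39-with-multiplicity / 37-unique marker counts) is recomputed
from table fixtures shipped under `inst/extdata/`.

`scripts/acceptance.R` reruns all of the above from scratch against
the installed package and writes a JSON report.

# Known limitations

* The hub/bottleneck rules depend on global degree moments, so they
  are sensitive to how the query network was induced; comparing
  classifications across networks of very different density is not
  meaningful.
* The SAM FDR estimate is a plug-in median ratio without a $\pi_0$
  correction; at very small targets it is conservative on null data
  but can be optimistic when many genes are truly DE.
* Raw-P selection and raw-p enrichment thresholds are faithful to the
  reference procedure but are not error-controlled in the
  multiple-testing sense; the configurable BH option exists for users
  who want control.
* Gene identity is the trimmed, case-sensitive symbol; no alias
  resolution is attempted.
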