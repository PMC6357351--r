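---
title: "Methods: miRNA-TF feed-forward loop co-regulatory network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-TF feed-forward loop co-regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflnet)
```

## The model

fflnet analyses gene regulation at two levels simultaneously:
transcriptional control by transcription factors (TFs) and
post-transcriptional repression by miRNAs. Its unit of analysis is the
3-node feed-forward loop (FFL): a TF and a miRNA that both target the same
protein-coding (non-TF) gene, with the two regulators themselves linked.
Three motif classes are distinguished by the direction of the
regulator-regulator edge:

* **motif A** — the TF also drives the miRNA (TF→miRNA);
* **motif B** — the miRNA also represses the TF (miRNA→TF);
* **motif C** — both edges are present (mutual regulation, a feedback
  loop embedded in the FFL).

Classification is *exclusive*: a triple with both regulator edges is C and
only C, so per-class counts always sum to the total. The joint-target slot
accepts only nodes of kind `gene`; a TF targeted by another TF and a miRNA
is not counted as an FFL. Input is four typed pair tables (TF-gene,
TF-miRNA, miRNA-gene, miRNA-TF); because the three roles must be disjoint,
a symbol appearing with conflicting kinds across tables is a hard error
rather than a silent merge. Symbols are compared case-sensitively after
whitespace trimming, and miRNA names are stored verbatim — mixed-case
variants of the same name are deliberately *not* merged, since silent
case-folding across species conventions causes more damage than duplicate
nodes that remain visible.

Merging the instances of one motif class gives the motif-specific networks;
merging all instances gives the combined network. Edge identity is the
triple (source, target, edge type); each merged edge remembers which motif
classes contributed it, which later lets subnetworks trace their motif
provenance.

## Hub ranking by Maximal Clique Centrality

Hubs are ranked by Maximal Clique Centrality (MCC): for node $v$,

$$\mathrm{MCC}(v) = \sum_{C \in S(v)} (|C| - 1)!$$

where $S(v)$ is the set of *maximal* cliques containing $v$. MCC is
computed on the undirected simple projection of the combined network
(reciprocal and typed multi-edges collapse to one edge), which is how the
score is conventionally applied to directed regulatory networks. Cliques
are enumerated with Bron–Kerbosch with pivoting (igraph). Consequences
worth knowing: a node whose neighbours are pairwise non-adjacent scores
exactly its degree (each incident edge is a maximal 2-clique), and isolated
nodes score 0. Factorials are computed exactly; clique sizes in these
networks are far too small for overflow. Ties in the ranking are broken
lexicographically by node id, and `top_k()` warns when a tie straddles the
cut, so a "top 10" is always reproducible.

## Module detection by Markov clustering

Modules come from the MCL algorithm on the same undirected projection with
unit edge weights. Self-loops of weight 1 are added before
column-normalization (standard MCL regularization), then expansion (matrix
power $e$) and inflation (entrywise power $r$ with renormalization)
alternate until the maximum absolute entry change drops below the
tolerance. Defaults are the canonical MCL settings: $e = 2$, $r = 2.0$,
pruning threshold $10^{-5}$, tolerance $10^{-6}$, at most 100 iterations.
Clusters are read off the supports of attractor rows (positive diagonal
mass); attractors of one cluster share an identical support, so distinct
supports define the modules. In the rare case of genuinely overlapping
supports, nodes go to the first cluster in sorted-attractor order and the
overlap is logged. Modules with fewer than three nodes carry little
functional signal and are moved to an explicit `unassigned` set rather than
dropped silently; the reported partition therefore always covers the node
set exactly. Column sums are tracked every iteration and stay within
$10^{-9}$ of 1, which the test suite asserts.

## Edge validation against independent expression

A TF-gene edge is *verified* when the two genes co-express in an
independent dataset: Pearson correlation over pairwise-complete samples
with

$$|r| > 0.3, \qquad P < 0.05, \qquad \mathrm{FDR} < 0.1,$$

where the two-sided $P$ comes from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$
degrees of freedom and FDR is Benjamini–Hochberg computed across the
testable TF-gene edges of the queried network (not across all gene pairs —
the per-network family is what makes a headline "fraction verified"
meaningful). All three gates are applied conjunctively. Edges whose TF or
gene is absent from the matrix, or with fewer than 3 complete pairs or zero
variance, are `untestable`; they remain in the denominator of the verified
fraction, so the headline number cannot be inflated by dropping hard cases.
The sign of $r$ is deliberately not compared with the regulation mode:
activation versus repression is not inferred anywhere in the package.

Two practical mappings sit in front of this test. Probe-level matrices are
collapsed to symbols with `collapse_probes()`; the default `max_mean` rule
(keep the probe with the highest mean expression) is a common array
convention, and `mean`/`median` aggregation are available because the
choice measurably moves the verified fraction — it is surfaced as a
parameter, not hidden. Cross-species symbol matching defaults to
case-normalized equality (human `WNT3A` vs mouse `Wnt3a`), overridable by
an explicit two-column ortholog map.

## Enrichment

Over-representation uses the plain hypergeometric upper tail
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$ with BH
correction across all tested sets and a default significance level of
$q < 0.05$. Gene sets come from user-supplied GMT files; the background
defaults to the union of all set members and should be overridden when a
better universe (platform, genome) is known — web annotation tools use
tool-internal universes that cannot be replicated locally, so the choice is
explicit here. The EASE-style modified statistic of some tools is
intentionally *not* reproduced. Hub-target enrichment queries each hub's
direct targets; module enrichment queries each retained module's members.

## Pathway-seeded subnetworks

`extract_subnetwork()` keeps every FFL whose joint-target gene lies in a
seed list (optionally any slot), merges them, and reports connected
components of the undirected projection in deterministic order. This
reproduces the pathway-focused view in which all motifs touching a small
panel — e.g. Wnt-pathway members WNT3A, WNT5A, WNT5B, DVL2 — are pulled out
of the combined network; the "subnetworks" are exactly the components, with
no additional splitting rule.

## The synthetic-data generator

Every stage is testable without downloads because the generator plants
known structure:

* **Pair tables.** Defaults emulate the curated cleft-lip regulatory
  universe: 27 TFs, 18 miRNAs, 127 candidate genes; 71/50/7 planted
  A/B/C FFLs; background edge rates per type (0.196, 0.156, 0.034, 0.043)
  chosen so the four tables carry roughly the curated pair densities
  (about 671 TF-gene, 76 TF-miRNA, 77 miRNA-gene, 21 miRNA-TF pairs).
  Planted FFLs receive pairwise-distinct (TF, miRNA) pairs so their
  exclusive classes cannot collide, and gene assignment is checked so the
  planted edges imply no triple beyond the planted ones — without that
  check, reused genes close accidental co-targeting patterns and
  enumeration finds more FFLs than were planted even with zero background.
  Background regulator edges that would flip a planted A- or B-motif into
  C are likewise excluded; only then does "enumeration recovers at least
  the planted count per type, exactly at zero background" hold as an
  invariant rather than a tendency.
* **Expression.** 35 samples by default, with planted TF-gene correlation
  $\rho = 0.9$ on a set of edges covering ~64.8% of the network's TF-gene
  edges. Selected edges' endpoints load on shared latent factors (one per
  connected component of the selected subgraph) with loading
  $\sqrt{|\rho|}$, giving every selected edge population correlation
  exactly $\rho$ while cross-component profiles stay independent; disjoint
  planted pairs therefore give fully independent draws, which the power
  calibration tests rely on. A byproduct of the factor construction is
  that regulators sharing a component are mutually correlated at $|\rho|$
  — accepted, since the validation statistic only reads TF-gene pairs.
* **Gene sets.** One planted set equal to the most prolific TF's target
  genes plus matched-size random decoys, against the full gene universe as
  background (the analogue of a platform-wide annotation background).

One global seed drives a named pseudo-random stream per artifact (tables,
expression, gene sets), so regenerating one artifact never perturbs
another — this keeps stage-wise tests isolated.

What the generator does *not* emulate: real promoter sequences or binding
scores, miRNA seed matches, scale-free topology, array normalization
artefacts, batch structure, or heavy-tailed expression noise. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under a clean Gaussian design, not robustness to the messiness
of real array data.

## Numerical and degenerate-input conventions

* `|r| = 1` maps to $P = 0$ by convention; fewer than 3 complete pairs or
  zero variance is `untestable`, never a numeric result.
* Hypergeometric tails are computed in log space via `phyper`; $k = 0$
  gives $p = 1$ exactly.
* Empty inputs return empty, typed results (enumeration of an empty edge
  set, stats of an empty network); errors are reserved for contract
  violations (self-loops, kind conflicts, malformed rows with their line
  numbers, zero samples, inflation ≤ 1).
* All orderings (FFL lists, rankings, modules, components) are
  deterministic, so byte-identical reruns are the norm and the pipeline
  manifest is reproducible from (inputs, config) alone.

## Problem sizes in the shipped checks

The test suite and the acceptance script run on deliberately modest sizes
chosen to probe the statistics, not the hardware: oracle comparisons use
graphs of up to ~50 nodes (exhaustive clique enumeration up to 12),
validation power uses 1000 independent planted edges at $n = 35$, null
calibration uses 100 seeds of 100 edges, and the end-to-end synthetic run
uses the full default universe (Table-1-scale, a few hundred FFLs). Each
completes in seconds on one CPU.

## Known limitations

Upstream evidence generation is out of scope: no TF-binding-site scanning,
no miRNA target prediction, no literature curation — the four pair tables
are consumed as given, and their quality bounds everything downstream.
Networks here are small and dense relative to genome-scale graphs; the
dense-matrix MCL implementation is appropriate at this scale but not for
$10^5$-node graphs. Enrichment results depend strongly on the gene-set
collection and background supplied; reproducing any specific historical
annotation run requires that era's annotation files.
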