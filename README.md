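# fflnet

Construction and analysis of miRNA–transcription-factor co-regulatory
networks built from 3-node feed-forward loops (FFLs).

## The problem

Congenital disorders such as cleft lip involve many candidate genes whose
regulation — transcriptional control by transcription factors (TFs) and
post-transcriptional repression by miRNAs — is scattered across four kinds
of evidence: TF→gene, TF→miRNA, miRNA→gene and miRNA→TF pairs. fflnet turns
such typed pair tables into an analysable network object and runs the full
downstream workflow that regulatory-network studies in this area use:

1. **FFL enumeration** — every (TF, miRNA, gene) triple in which both
   regulators target the same protein-coding gene and are themselves
   linked, exclusively classified as motif **A** (TF→miRNA), **B**
   (miRNA→TF) or **C** (both, a mutual-regulation feedback loop);
2. **network assembly** — motif-specific and combined networks with exact
   composition statistics;
3. **hub ranking** by Maximal Clique Centrality,
   MCC(v) = Σ over maximal cliques C containing v of (|C| − 1)!;
4. **module detection** by Markov clustering (MCL, inflation 2.0,
   modules under 3 nodes set aside);
5. **edge validation** against an independent expression matrix — a
   TF-gene edge is *verified* when |r| > 0.3, P < 0.05 and BH-FDR < 0.1
   for the Pearson correlation over pairwise-complete samples;
6. **hypergeometric enrichment** with BH correction over user GMT gene
   sets; and
7. **pathway-seeded subnetworks** — all motifs touching a seed gene panel
   (e.g. Wnt genes), split into connected components.

A synthetic-data generator plants FFLs, correlated TF-gene edges and an
enriched gene set with known ground truth, so every stage is testable
end to end without downloading anything.

## Worked example

```r
library(fflnet)

cfg  <- simulation_config(seed = 1)        # Table-1-scale synthetic universe
sim  <- generate_pair_tables(cfg)          # four typed pair tables + truth
ffls <- enumerate_ffls(sim$edges)
motif_summary(ffls)
#>   motif n_ffls n_tf n_mirna n_gene miRNA_gene miRNA_TF TF_gene TF_miRNA
#> 1     A    381   27      18     96        165        0     317      126
#> 2     B    199   26      17     83        123       64     185        0
#> 3     C     27    6       6     20         22        8      26        8
#> 4 Total    607   27      18    104        185       72     449      134

net <- build_network(ffls)
net
#> Regulatory network: 27 TFs, 18 miRNAs, 104 genes, 840 edges
#>   edges by type: TF_gene=449, TF_miRNA=134, miRNA_gene=185, miRNA_TF=72

top_k(mcc_scores(net), 5)
#>            id  kind mcc rank
#> 1 hsa-mir-016 miRNA 132    1
#> 2 hsa-mir-005 miRNA 118    2
#> 3 hsa-mir-015 miRNA 102    3
#> 4 hsa-mir-001 miRNA 100    4
#> 5 hsa-mir-006 miRNA  80    5

expr <- generate_expression(net, cfg)      # 35 samples, rho = 0.9 planted
v    <- validate_edges(net, expr$matrix)
v$summary
#> $n_edges    449
#> $n_testable 449
#> $n_verified 301
#> $fraction   0.67
```

The motif summary counts FFLs and the distinct TFs/miRNAs/genes and typed
edges they span; per-class counts always sum to the total because
classification is exclusive. The MCC column is the clique-factorial score —
here the top hubs are miRNAs that sit in many overlapping triangles of the
combined network. The validation summary says 301 of 449 TF-gene edges
(67%) pass all three co-expression gates, close to the 64.8% planting rate
(the small excess is expected: edge selection overshoots slightly and a few
null edges pass by chance). `run_pipeline(pipeline_config(sim = cfg))`
chains all stages and returns a manifest of every headline number together
with the planted ground truth.

To analyse real data, point `pipeline_config()` at the four pair-table
TSVs (`source<TAB>target[<TAB>edge_type]`), an expression matrix (plain
TSV or GEO series-matrix; `collapse_probes()` handles probe-level input),
a GMT file, and a seed gene list.

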