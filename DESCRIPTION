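Package: fflnet
Title: miRNA-TF Feed-Forward Loop Co-Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and analyses miRNA-transcription-factor co-regulatory
    networks from typed regulatory pair tables. Enumerates 3-node feed-forward
    loops (TF and miRNA jointly targeting a protein-coding gene, with the
    regulators linked in one or both directions), merges them into motif-specific
    and combined networks, ranks hub nodes by maximal clique centrality,
    partitions modules with Markov clustering, validates TF-gene edges against an
    independent expression matrix by Pearson correlation with Benjamini-Hochberg
    false-discovery-rate control, performs local hypergeometric gene-set
    enrichment, and extracts pathway-seeded subnetworks. A synthetic-data
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
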