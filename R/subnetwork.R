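#' Extract the pathway-seeded subnetwork
#'
#' Keeps every FFL whose joint-target gene belongs to the seed list (or, with
#' `match_slot = "any"`, whose TF, miRNA or gene does), merges the kept
#' instances into a network, and splits it into connected components of the
#' undirected projection. This reproduces the pathway-focused view in which
#' all motifs touching a small gene panel (e.g. Wnt-pathway members) are
#' pulled out of the combined network.
#'
#' @param ffls An `ffl_set` from [enumerate_ffls()].
#' @param seeds Non-empty character vector of seed gene symbols.
#' @param match_slot `"gene"` (default: seeds matched against the FFL's
#'   joint-target slot only) or `"any"`.
#' @return A `subnetwork_report`: list with `seeds_found`, `seeds_missing`,
#'   `network` (the merged subnetwork), `components` (list of
#'   `regulatory_network`, ordered by smallest node id), `component_stats`,
#'   and `overall_stats`.
#' @export
extract_subnetwork <- function(ffls, seeds, match_slot = c("gene", "any")) {
  stopifnot(is.data.frame(ffls), length(seeds) >= 1)
  match_slot <- match.arg(match_slot)
  seeds <- unique(trimws(as.character(seeds)))
  hit <- if (match_slot == "gene") {
    ffls$gene %in% seeds
  } else {
    ffls$gene %in% seeds | ffls$tf %in% seeds | ffls$mirna %in% seeds
  }
  kept <- ffls[hit, , drop = FALSE]
  slot_values <- if (match_slot == "gene") {
    kept$gene
  } else {
    c(kept$gene, kept$tf, kept$mirna)
  }
  found <- intersect(seeds, slot_values)
  if (nrow(kept) == 0L) {
    warning("no seed gene appears in any FFL; empty subnetwork")
    return(structure(list(seeds_found = character(0),
                          seeds_missing = sort(seeds),
                          network = regulatory_network(NULL),
                          components = list(), component_stats = list(),
                          overall_stats = network_stats(regulatory_network(NULL))),
                     class = "subnetwork_report"))
  }
  net <- build_network(kept)
  g <- undirected_projection(net)
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- groups[order(vapply(groups, function(v) min(sort(v)), character(1)))]
  components <- lapply(groups, function(nodes) {
    e <- net$edges[net$edges$source %in% nodes & net$edges$target %in% nodes, ,
                   drop = FALSE]
    regulatory_network(e)
  })
  names(components) <- paste0("component_", seq_along(components))
  structure(list(
    seeds_found = sort(found),
    seeds_missing = sort(setdiff(seeds, found)),
    network = net,
    components = components,
    component_stats = lapply(components, network_stats),
    overall_stats = network_stats(net)),
    class = "subnetwork_report")
}

#' @export
print.subnetwork_report <- function(x, ...) {
  s <- x$overall_stats
  cat("Seeded subnetwork:", length(x$components), "component(s);",
      s$n_mirna, "miRNAs,", s$n_tf, "TFs,", s$n_gene, "genes,",
      s$n_edges, "edges\n")
  cat("  seeds found:", paste(x$seeds_found, collapse = ", "), "\n")
  if (length(x$seeds_missing)) {
    cat("  seeds missing:", paste(x$seeds_missing, collapse = ", "), "\n")
  }
  invisible(x)
}
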