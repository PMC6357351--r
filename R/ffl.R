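#' Enumerate 3-node feed-forward loops
#'
#' A feed-forward loop (FFL) is a (TF, miRNA, gene) triple in which both
#' regulators target the same protein-coding (non-TF) gene — TF->gene and
#' miRNA->gene — and the regulators are themselves linked. The motif class is
#' exclusive:
#' \describe{
#'   \item{A}{the TF also regulates the miRNA (TF->miRNA), no miRNA->TF edge}
#'   \item{B}{the miRNA also regulates the TF (miRNA->TF), no TF->miRNA edge}
#'   \item{C}{both TF->miRNA and miRNA->TF are present (mutual regulation)}
#' }
#' so the per-class counts always sum to the total. Only nodes of kind
#' `gene` may occupy the joint-target slot.
#'
#' @param edges A `regulatory_network` or a data.frame of typed,
#'   kind-consistent, deduplicated edges (`source`, `target`, `edge_type`).
#' @return An `ffl_set`: data.frame with columns `tf`, `mirna`, `gene`,
#'   `motif_type`, sorted by (tf, mirna, gene).
#' @examples
#' edges <- data.frame(source = c("TF1", "TF1", "hsa-mir-1"),
#'                     target = c("G1", "hsa-mir-1", "G1"),
#'                     edge_type = c("TF_gene", "TF_miRNA", "miRNA_gene"))
#' enumerate_ffls(edges)
#' @export
enumerate_ffls <- function(edges) {
  if (inherits(edges, "regulatory_network")) {
    edges <- edges$edges
  } else {
    edges <- regulatory_network(edges)$edges  # validates kinds, dedups
  }
  empty <- data.frame(tf = character(), mirna = character(),
                      gene = character(), motif_type = character(),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) return(as_ffl_set(empty))

  tg <- edges[edges$edge_type == "TF_gene", c("source", "target")]
  mg <- edges[edges$edge_type == "miRNA_gene", c("source", "target")]
  tm <- edges[edges$edge_type == "TF_miRNA", c("source", "target")]
  mt <- edges[edges$edge_type == "miRNA_TF", c("source", "target")]
  if (nrow(tg) == 0L || nrow(mg) == 0L) return(as_ffl_set(empty))

  names(tg) <- c("tf", "gene")
  names(mg) <- c("mirna", "gene")
  cand <- merge(tg, mg, by = "gene")  # all co-targeting (tf, mirna, gene)
  if (nrow(cand) == 0L) return(as_ffl_set(empty))

  tm_key <- paste(tm$source, tm$target, sep = "\r")
  mt_key <- paste(mt$source, mt$target, sep = "\r")
  has_tm <- paste(cand$tf, cand$mirna, sep = "\r") %in% tm_key
  has_mt <- paste(cand$mirna, cand$tf, sep = "\r") %in% mt_key

  keep <- has_tm | has_mt
  if (!any(keep)) return(as_ffl_set(empty))
  out <- data.frame(
    tf = cand$tf[keep], mirna = cand$mirna[keep], gene = cand$gene[keep],
    motif_type = ifelse(has_tm[keep] & has_mt[keep], "C",
                        ifelse(has_tm[keep], "A", "B")),
    stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  as_ffl_set(out)
}

as_ffl_set <- function(df) {
  class(df) <- c("ffl_set", "data.frame")
  df
}

## The directed edges realizing one FFL instance, implied by its motif class.
ffl_edges <- function(tf, mirna, gene, motif_type) {
  e <- data.frame(
    source = c(tf, mirna), target = c(gene, gene),
    edge_type = c("TF_gene", "miRNA_gene"), stringsAsFactors = FALSE)
  if (motif_type %in% c("A", "C")) {
    e <- rbind(e, data.frame(source = tf, target = mirna,
                             edge_type = "TF_miRNA"))
  }
  if (motif_type %in% c("B", "C")) {
    e <- rbind(e, data.frame(source = mirna, target = tf,
                             edge_type = "miRNA_TF"))
  }
  e
}

#' Per-motif-type summary of an FFL list
#'
#' @param ffls An `ffl_set` from [enumerate_ffls()].
#' @return data.frame with one row per motif type plus a `Total` row:
#'   FFL count, distinct TFs/miRNAs/genes, and distinct edge counts per
#'   relationship type, each computed over the union of the instances.
#' @export
motif_summary <- function(ffls) {
  stopifnot(is.data.frame(ffls))
  one_row <- function(sub, label) {
    if (nrow(sub) == 0L) {
      return(data.frame(motif = label, n_ffls = 0L, n_tf = 0L, n_mirna = 0L,
                        n_gene = 0L, miRNA_gene = 0L, miRNA_TF = 0L,
                        TF_gene = 0L, TF_miRNA = 0L, stringsAsFactors = FALSE))
    }
    e <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      ffl_edges(sub$tf[i], sub$mirna[i], sub$gene[i], sub$motif_type[i])
    }))
    e <- unique(e)
    bt <- table(factor(e$edge_type, levels = EDGE_TYPES))
    data.frame(motif = label, n_ffls = nrow(sub),
               n_tf = length(unique(sub$tf)),
               n_mirna = length(unique(sub$mirna)),
               n_gene = length(unique(sub$gene)),
               miRNA_gene = as.integer(bt[["miRNA_gene"]]),
               miRNA_TF = as.integer(bt[["miRNA_TF"]]),
               TF_gene = as.integer(bt[["TF_gene"]]),
               TF_miRNA = as.integer(bt[["TF_miRNA"]]),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(c("A", "B", "C"), function(m) one_row(ffls[ffls$motif_type == m, ], m)),
    list(one_row(ffls, "Total"))))
  rownames(out) <- NULL
  out
}

#' Merge FFL instances into a regulatory network
#'
#' The node set is the union of the instance nodes and the edge set the
#' deduplicated union of the instance edges; each edge is annotated with the
#' motif classes that contributed it (`motifs` column). With `motif_filter`,
#' only instances of the listed classes contribute, giving the
#' motif-specific networks; the default builds the combined network.
#'
#' @param ffls An `ffl_set`.
#' @param motif_filter Optional subset of `c("A","B","C")`.
#' @return A `regulatory_network` whose edges carry a `motifs` annotation.
#' @export
build_network <- function(ffls, motif_filter = NULL) {
  stopifnot(is.data.frame(ffls))
  if (!is.null(motif_filter)) {
    stopifnot(all(motif_filter %in% c("A", "B", "C")))
    ffls <- ffls[ffls$motif_type %in% motif_filter, , drop = FALSE]
  }
  if (nrow(ffls) == 0L) return(regulatory_network(NULL))
  e <- do.call(rbind, lapply(seq_len(nrow(ffls)), function(i) {
    cbind(ffl_edges(ffls$tf[i], ffls$mirna[i], ffls$gene[i],
                    ffls$motif_type[i]),
          motif = ffls$motif_type[i], stringsAsFactors = FALSE)
  }))
  key <- paste(e$source, e$target, e$edge_type, sep = "\r")
  motifs <- vapply(split(e$motif, key), function(m) {
    paste(sort(unique(m)), collapse = ",")
  }, character(1))
  e <- e[!duplicated(key), c("source", "target", "edge_type")]
  e$motifs <- unname(motifs[paste(e$source, e$target, e$edge_type, sep = "\r")])
  regulatory_network(e)
}
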