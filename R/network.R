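#' Construct a typed regulatory network
#'
#' A regulatory network is a deduplicated directed graph whose nodes are
#' transcription factors, miRNAs and protein-coding (non-TF) genes, and whose
#' edges carry one of the four regulation types returned by [edge_types()].
#' Node kinds are inferred from the edge types; a symbol appearing with
#' conflicting kinds across edges (e.g. as a TF source and as a gene target)
#' is a hard error, because the feed-forward-loop definitions require the
#' three roles to be disjoint.
#'
#' @param edges data.frame with columns `source`, `target`, `edge_type`
#'   (optionally extra annotation columns such as `motifs`).
#' @return An object of class `regulatory_network`: a list with a `nodes`
#'   data.frame (`id`, `kind`) and the deduplicated `edges` data.frame.
#' @examples
#' net <- regulatory_network(data.frame(
#'   source = c("TF1", "TF1", "hsa-mir-1"),
#'   target = c("G1", "hsa-mir-1", "G1"),
#'   edge_type = c("TF_gene", "TF_miRNA", "miRNA_gene")))
#' network_stats(net)
#' @export
regulatory_network <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "edge_type") %in% names(edges)))
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  check_edge_type(edges$edge_type)
  if (any(edges$source == edges$target)) {
    stop("self-loop edge(s) not permitted: ",
         paste(unique(edges$source[edges$source == edges$target]),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(edges$source, edges$target, edges$edge_type, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$edge_type), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "dropped") <- NULL

  nodes <- infer_node_kinds(edges)
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

infer_node_kinds <- function(edges) {
  ids <- c(edges$source, edges$target)
  kinds <- c(unname(SOURCE_KIND[edges$edge_type]),
             unname(TARGET_KIND[edges$edge_type]))
  tab <- unique(data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE))
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup)) {
    offenders <- vapply(unique(dup), function(i) {
      paste0(i, " (", paste(sort(tab$kind[tab$id == i]), collapse = "/"), ")")
    }, character(1))
    stop("node(s) appear with conflicting kinds across tables: ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_stats(x)
  cat("Regulatory network:", s$n_tf, "TFs,", s$n_mirna, "miRNAs,",
      s$n_gene, "genes,", s$n_edges, "edges\n")
  if (s$n_edges > 0) {
    bt <- s$edges_by_type
    cat("  edges by type:",
        paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Composition statistics of a regulatory network
#'
#' @param network A `regulatory_network`.
#' @return List with node counts per kind (`n_tf`, `n_mirna`, `n_gene`),
#'   total `n_edges`, and `edges_by_type` (named integer vector over the four
#'   edge types).
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  bt <- table(factor(network$edges$edge_type, levels = EDGE_TYPES))
  list(
    n_mirna = sum(network$nodes$kind == "miRNA"),
    n_tf = sum(network$nodes$kind == "TF"),
    n_gene = sum(network$nodes$kind == "gene"),
    n_edges = nrow(network$edges),
    edges_by_type = stats::setNames(as.integer(bt), names(bt))
  )
}

#' Parse a two- or three-column regulatory pair table
#'
#' Reads a TSV of regulation pairs (`source<TAB>target[<TAB>edge_type]`,
#' `#`-prefixed comment lines ignored). Exact duplicate pairs are collapsed
#' and self-loop rows rejected; both are counted in the `dropped` attribute
#' of the result.
#'
#' @param path Path to the TSV file.
#' @param edge_type One of [edge_types()]; may be omitted when the file
#'   carries a third column. If both are present they must agree.
#' @return data.frame of deduplicated edges (`source`, `target`, `edge_type`)
#'   with attribute `dropped = list(duplicates =, self_loops =)`.
#' @export
parse_pair_table <- function(path, edge_type = NULL) {
  if (!is.null(edge_type)) check_edge_type(edge_type)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("malformed row (fewer than 2 tab-separated fields) at line ",
         idx[which(nf < 2L)[1]], " of ", path, call. = FALSE)
  }
  src <- trimws(vapply(parts, `[[`, character(1), 1L))
  tgt <- trimws(vapply(parts, `[[`, character(1), 2L))
  typ <- ifelse(nf >= 3L,
                trimws(vapply(parts, function(p) if (length(p) >= 3) p[[3]] else "",
                              character(1))),
                NA_character_)
  ## drop a header row if present
  if (length(src) && identical(tolower(src[1]), "source") &&
      identical(tolower(tgt[1]), "target")) {
    src <- src[-1]; tgt <- tgt[-1]; typ <- typ[-1]; idx <- idx[-1]
  }
  if (all(is.na(typ))) {
    if (is.null(edge_type)) {
      stop("edge_type not given and no edge_type column in ", path,
           call. = FALSE)
    }
    typ <- rep(edge_type, length(src))
  } else {
    if (anyNA(typ)) {
      stop("edge_type column present but missing at line ",
           idx[which(is.na(typ))[1]], " of ", path, call. = FALSE)
    }
    check_edge_type(unique(typ))
    if (!is.null(edge_type) && any(typ != edge_type)) {
      stop("edge_type column conflicts with edge_type argument ('",
           edge_type, "') at line ", idx[which(typ != edge_type)[1]],
           " of ", path, call. = FALSE)
    }
  }
  self <- src == tgt
  n_self <- sum(self)
  if (n_self) {
    message("parse_pair_table: dropped ", n_self, " self-loop row(s) in ", path)
  }
  src <- src[!self]; tgt <- tgt[!self]; typ <- typ[!self]
  key <- paste(src, tgt, typ, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(source = src[!dup], target = tgt[!dup],
                    edge_type = typ[!dup], stringsAsFactors = FALSE)
  attr(out, "dropped") <- list(duplicates = sum(dup), self_loops = n_self)
  out
}

#' Write a regulatory network to disk
#'
#' Supported formats: `edge_tsv` (`source<TAB>target<TAB>edge_type`,
#' round-trip safe with [read_network()]), `sif`
#' (`source<TAB>edge_type<TAB>target`), and `graphml` (node `kind` and edge
#' `edge_type` attributes).
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format One of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "regulatory_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "edge_tsv") {
    utils::write.table(e[, c("source", "target", "edge_type")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    utils::write.table(e[, c("source", "edge_type", "target")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("source", "target", "edge_type")], directed = TRUE,
      vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a regulatory network from an edge TSV
#'
#' Inverse of [write_network()] for the `edge_tsv` format.
#'
#' @param path Path to an edge TSV written by [write_network()].
#' @return A `regulatory_network`.
#' @export
read_network <- function(path) {
  edges <- parse_pair_table(path)
  regulatory_network(edges)
}

#' Undirected simple projection of a regulatory network
#'
#' The edge \{u, v\} is present iff any directed edge u->v or v->u exists;
#' multi-edges are collapsed. All network nodes are kept, including
#' isolated ones. Centrality and clustering operate on this projection.
#'
#' @param network A `regulatory_network`.
#' @return An undirected simple `igraph` graph with a `kind` vertex attribute.
#' @export
undirected_projection <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target")], directed = TRUE,
    vertices = network$nodes)
  igraph::as_undirected(g, mode = "collapse")
}
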