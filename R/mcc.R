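#' Maximal cliques of the undirected projection
#'
#' Enumerates all maximal cliques (Bron–Kerbosch with pivoting, via igraph).
#' Cliques of size 1 (isolated nodes) are excluded.
#'
#' @param graph An undirected simple `igraph` graph, or a
#'   `regulatory_network` (projected first).
#' @return List of character vectors of node ids, each sorted; the list is
#'   ordered deterministically (by size then lexicographic members).
#' @export
maximal_cliques <- function(graph) {
  if (inherits(graph, "regulatory_network")) graph <- undirected_projection(graph)
  stopifnot(inherits(graph, "igraph"))
  graph <- ensure_named(graph)
  cl <- igraph::max_cliques(graph, min = 2)
  cl <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  ord <- order(lengths(cl), vapply(cl, paste, character(1), collapse = "\r"))
  cl[ord]
}

ensure_named <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("n%04d", seq_len(igraph::vcount(g)))
  }
  g
}

#' Rank nodes by Maximal Clique Centrality (MCC)
#'
#' MCC(v) is the sum over all maximal cliques C containing v of
#' `factorial(|C| - 1)`, computed on the undirected projection of the network
#' with edge types ignored. A node whose neighbours are pairwise non-adjacent
#' therefore scores its degree (each incident edge is a maximal 2-clique);
#' isolated nodes score 0.
#'
#' @param network A `regulatory_network` or an undirected `igraph` graph.
#' @return A `hub_ranking`: data.frame (`id`, `kind`, `mcc`, `rank`), sorted
#'   by score descending with ties broken by node id.
#' @export
mcc_scores <- function(network) {
  if (inherits(network, "regulatory_network")) {
    g <- undirected_projection(network)
    kinds <- stats::setNames(network$nodes$kind, network$nodes$id)
  } else {
    g <- ensure_named(network)
    kinds <- stats::setNames(rep(NA_character_, igraph::vcount(g)),
                             igraph::V(g)$name)
  }
  ids <- igraph::V(g)$name
  score <- stats::setNames(numeric(length(ids)), ids)
  for (cl in maximal_cliques(g)) {
    score[cl] <- score[cl] + factorial(length(cl) - 1L)
  }
  ord <- order(-score, ids)
  out <- data.frame(id = ids[ord], kind = unname(kinds[ids[ord]]),
                    mcc = unname(score[ord]), rank = seq_along(ids),
                    stringsAsFactors = FALSE)
  class(out) <- c("hub_ranking", "data.frame")
  out
}

#' Top-k hubs of a ranking
#'
#' @param ranking A `hub_ranking` from [mcc_scores()].
#' @param k Number of hubs (default 10). If `k` exceeds the node count the
#'   whole ranking is returned with a warning; a score tie straddling the
#'   cut is also warned about.
#' @return The first `k` rows of the ranking.
#' @export
top_k <- function(ranking, k = 10) {
  stopifnot(is.data.frame(ranking), k >= 1)
  n <- nrow(ranking)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n, "-node ranking; returning all")
    return(ranking)
  }
  if (k < n && ranking$mcc[k] == ranking$mcc[k + 1]) {
    warning("score tie straddles the top-", k,
            " cut (score ", ranking$mcc[k], "); ties broken by node id")
  }
  ranking[seq_len(k), , drop = FALSE]
}
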