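#' Hypergeometric upper-tail p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated: `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' `k = 0` gives p = 1 (the upper tail covers all outcomes).
#'
#' @param k Query hits in the set.
#' @param K Set size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (N < K || N < n || k > min(K, n) || k < 0) {
    stop("invalid hypergeometric arguments: need N >= K, N >= n, ",
         "0 <= k <= min(K, n)", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis with BH correction
#'
#' Local replacement for web-based annotation tools: each gene set is tested
#' for over-representation of the query by the hypergeometric upper tail,
#' and Benjamini-Hochberg q-values are computed across all tested sets.
#' The background defaults to the union of all set members; query genes
#' absent from the background are dropped (with a logged count).
#'
#' @param query Character vector of gene symbols.
#' @param sets A `gene_set_collection` (see [read_gmt()]).
#' @param background Optional character vector overriding the collection's
#'   universe.
#' @param q_threshold Significance level on q (default 0.05).
#' @return data.frame, one row per set with at least one background member:
#'   `term`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`; sorted by `q`,
#'   then `p`, then term.
#' @export
enrich <- function(query, sets, background = NULL, q_threshold = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(background)) background <- sets$background
  if (is.null(background)) background <- unique(unlist(sets$sets))
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  dropped <- setdiff(query, background)
  if (length(dropped)) {
    message("enrich: ", length(dropped),
            " query gene(s) absent from the background, dropped")
  }
  query <- intersect(query, background)
  if (!length(query)) stop("empty query after background intersection",
                           call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(term) {
    members <- intersect(sets$sets[[term]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p = hypergeom_pvalue(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Enrichment of each hub's direct targets
#'
#' For every hub TF or miRNA in the ranking prefix, the query is the set of
#' its direct targets in the network (outgoing edges); enrichment runs as in
#' [enrich()]. Hubs without outgoing edges are skipped with a warning.
#'
#' @param network A `regulatory_network`.
#' @param hubs A `hub_ranking` prefix (see [top_k()]), or a character vector
#'   of node ids.
#' @param sets A `gene_set_collection`.
#' @param background Optional background universe.
#' @param q_threshold Significance level on q (default 0.05).
#' @return Named list (one element per hub with targets) of enrichment
#'   data.frames.
#' @export
hub_target_enrichment <- function(network, hubs, sets, background = NULL,
                                  q_threshold = 0.05) {
  stopifnot(inherits(network, "regulatory_network"))
  ids <- if (is.data.frame(hubs)) hubs$id else as.character(hubs)
  out <- list()
  for (h in ids) {
    targets <- network$edges$target[network$edges$source == h]
    if (!length(targets)) {
      warning("hub '", h, "' has no targets; skipped")
      next
    }
    out[[h]] <- enrich(targets, sets, background, q_threshold)
  }
  out
}
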