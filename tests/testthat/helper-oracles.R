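# Independent oracles, deliberately written as naive brute-force or textbook
# procedures so they share no code path with the package implementation.

# Exhaustive triple scan over all (TF, miRNA, gene) combinations.
oracle_ffls <- function(edges) {
  has <- function(s, t, ty) {
    any(edges$source == s & edges$target == t & edges$edge_type == ty)
  }
  tfs <- unique(edges$source[edges$edge_type %in% c("TF_gene", "TF_miRNA")])
  tfs <- union(tfs, edges$target[edges$edge_type == "miRNA_TF"])
  mirs <- unique(edges$source[edges$edge_type %in% c("miRNA_gene", "miRNA_TF")])
  mirs <- union(mirs, edges$target[edges$edge_type == "TF_miRNA"])
  genes <- unique(edges$target[edges$edge_type %in% c("TF_gene", "miRNA_gene")])
  out <- list()
  for (t in tfs) for (m in mirs) for (g in genes) {
    if (!has(t, g, "TF_gene") || !has(m, g, "miRNA_gene")) next
    tm <- has(t, m, "TF_miRNA")
    mt <- has(m, t, "miRNA_TF")
    if (!tm && !mt) next
    type <- if (tm && mt) "C" else if (tm) "A" else "B"
    out[[length(out) + 1L]] <- data.frame(tf = t, mirna = m, gene = g,
                                          motif_type = type,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), motif_type = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$tf, df$mirna, df$gene), ]
  rownames(df) <- NULL
  df
}

# Random kind-consistent typed edge set over disjoint symbol universes.
random_typed_edges <- function(n_tf, n_mirna, n_gene, density) {
  tfs <- sprintf("t%02d", seq_len(n_tf))
  mirs <- sprintf("m%02d", seq_len(n_mirna))
  genes <- sprintf("g%02d", seq_len(n_gene))
  pick <- function(src, tgt, ty) {
    grid <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < density, , drop = FALSE]
    if (nrow(grid)) grid$edge_type <- ty
    grid
  }
  out <- rbind(pick(tfs, genes, "TF_gene"), pick(tfs, mirs, "TF_miRNA"),
               pick(mirs, genes, "miRNA_gene"), pick(mirs, tfs, "miRNA_TF"))
  out[nrow(out) > 0 | TRUE, , drop = FALSE]
}

# All maximal cliques by exhaustive subset enumeration (n <= 15 or so).
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  ids <- rownames(adj)
  is_clique <- function(v) all(adj[v, v][upper.tri(matrix(0, length(v), length(v)))] == 1)
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(v) < 2 || !is_clique(v)) next
    cliques[[length(cliques) + 1L]] <- v
  }
  maximal <- Filter(function(v) {
    !any(vapply(cliques, function(w) length(w) > length(v) && all(v %in% w),
                logical(1)))
  }, cliques)
  lapply(maximal, function(v) sort(ids[v]))
}

oracle_mcc <- function(adj) {
  score <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (cl in oracle_max_cliques(adj)) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  score
}

# Textbook Benjamini-Hochberg step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  if (m > 1) {
    for (i in (m - 1):1) {
      q[ord[i]] <- min(q[ord[i]], q[ord[i + 1]])
    }
  }
  pmin(q, 1)
}

# Hypergeometric upper tail by direct combinatorial summation.
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Independent dense MCL (loop-based normalization, no shared helpers).
oracle_mcl_modules <- function(adj, inflation = 2, max_iter = 200) {
  n <- nrow(adj)
  A <- adj
  for (i in 1:n) A[i, i] <- 1
  M <- A
  for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    for (j in 1:n) {
      s <- sum(M2[, j])
      M2[, j] <- if (s > 0) M2[, j] / s else replace(numeric(n), j, 1)
    }
    M2[M2 < 1e-8] <- 0
    if (max(abs(M2 - M)) < 1e-9) { M <- M2; break }
    M <- M2
  }
  clusters <- list()
  for (i in which(diag(M) > 1e-6)) {
    support <- sort(rownames(adj)[M[i, ] > 1e-6])
    if (!any(vapply(clusters, identical, logical(1), support))) {
      clusters[[length(clusters) + 1L]] <- support
    }
  }
  clusters[order(vapply(clusters, `[[`, character(1), 1L))]
}

# Analytic power of the edge-verification rule via the Fisher-z approximation:
# P(r > r_crit) for positive rho, where r_crit is the binding |r|/P threshold.
fisher_z_power <- function(rho, n, r_min = 0.3, p_max = 0.05) {
  t_crit <- stats::qt(1 - p_max / 2, df = n - 2)
  r_p <- sqrt(t_crit^2 / (t_crit^2 + n - 2))
  r_crit <- max(r_min, r_p)
  stats::pnorm((atanh(rho) - atanh(r_crit)) * sqrt(n - 3))
}

# igraph helpers for clique/MCL fixtures
adj_from_igraph <- function(g) {
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

disjoint_cliques_graph <- function(sizes) {
  gs <- lapply(seq_along(sizes), function(i) {
    g <- igraph::make_full_graph(sizes[i])
    igraph::set_vertex_attr(g, "name",
                            value = sprintf("c%d_%d", i, seq_len(sizes[i])))
  })
  Reduce(igraph::disjoint_union, gs)
}
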