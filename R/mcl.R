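#' Markov clustering (MCL) of a regulatory network
#'
#' Runs the MCL algorithm on the undirected projection with unit edge weights
#' and self-loops of weight 1: the adjacency-plus-identity matrix is
#' column-normalized, then expansion (matrix power `expansion`) and inflation
#' (entrywise power `inflation`, followed by column renormalization with
#' pruning of entries below `prune_threshold`) alternate until the maximum
#' absolute entry change falls below `tol` or `max_iter` is reached. Clusters
#' are read off the supports of attractor rows (rows with positive diagonal
#' mass); in the rare case of overlapping supports a node goes to the first
#' cluster in deterministic (sorted attractor id) order and the overlap is
#' logged.
#'
#' @param network A `regulatory_network` or an undirected `igraph` graph.
#' @param inflation Inflation parameter r > 1 (default 2.0, the conventional
#'   MCL default).
#' @param expansion Expansion power e (default 2).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the max absolute entry change
#'   (default 1e-6).
#' @param prune_threshold Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @return A `module_partition`: list with `modules` (list of sorted node-id
#'   vectors, largest first), `unassigned` (character vector, empty before
#'   filtering), `converged` flag, `n_iter`, and `params`.
#' @seealso [filter_modules()] to drop modules below a minimum size.
#' @export
mcl <- function(network, inflation = 2, expansion = 2L, max_iter = 100L,
                tol = 1e-6, prune_threshold = 1e-5) {
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  stopifnot(expansion >= 2)
  if (inherits(network, "regulatory_network")) {
    g <- undirected_projection(network)
  } else {
    g <- ensure_named(network)
  }
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network", call. = FALSE)
  ids <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A > 0) + 0
  diag(A) <- 1  # self-loops: standard MCL regularization
  M <- sweep(A, 2, colSums(A), "/")

  normalize <- function(M) {
    cs <- colSums(M)
    zero <- cs == 0
    if (any(zero)) {  # a fully pruned column re-attracts to itself
      M[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    sweep(M, 2, cs, "/")
  }

  converged <- FALSE
  iter <- 0L
  colsum_dev <- 0  # worst deviation of any column sum from 1, all iterations
  while (iter < max_iter) {
    iter <- iter + 1L
    M_prev <- M
    ## expansion: e-th matrix power
    E <- M
    for (i in seq_len(expansion - 1L)) E <- E %*% M
    ## inflation + pruning + renormalization
    E <- E^inflation
    E[E < prune_threshold] <- 0
    M <- normalize(E)
    colsum_dev <- max(colsum_dev, abs(colSums(M) - 1))
    if (max(abs(M - M_prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current clustering")
  }

  ## attractors: rows with positive diagonal mass; attractors of one cluster
  ## share an identical support, so distinct supports define the clusters
  attractors <- which(diag(M) > prune_threshold)
  supports <- unique(lapply(attractors, function(a) {
    sort(ids[M[a, ] > prune_threshold])
  }))
  supports <- supports[order(vapply(supports, `[[`, character(1), 1L))]
  assigned <- character(0)
  modules <- list()
  overlap <- character(0)
  for (support in supports) {
    new <- setdiff(support, assigned)
    overlap <- c(overlap, intersect(support, assigned))
    if (length(new)) {
      modules[[length(modules) + 1L]] <- new
      assigned <- c(assigned, new)
    }
  }
  leftover <- setdiff(ids, assigned)
  for (v in sort(leftover)) modules[[length(modules) + 1L]] <- v
  if (length(overlap)) {
    message("MCL: ", length(unique(overlap)),
            " node(s) in overlapping attractor supports assigned ",
            "to their first cluster")
  }
  modules <- modules[order(-lengths(modules),
                           vapply(modules, `[[`, character(1), 1L))]
  structure(list(
    modules = modules, unassigned = character(0),
    converged = converged, n_iter = iter, max_colsum_dev = colsum_dev,
    params = list(inflation = inflation, expansion = expansion,
                  max_iter = max_iter, tol = tol,
                  prune_threshold = prune_threshold)),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("MCL partition:", length(x$modules), "module(s) of sizes",
      paste(lengths(x$modules), collapse = ", "),
      if (length(x$unassigned)) paste0("; ", length(x$unassigned), " unassigned"),
      "\n")
  invisible(x)
}

#' Drop modules below a minimum size
#'
#' Modules with fewer than `min_size` nodes carry little biological signal;
#' their members are moved to the partition's `unassigned` set.
#'
#' @param partition A `module_partition` from [mcl()].
#' @param min_size Minimum retained module size (default 3).
#' @return The filtered `module_partition`.
#' @export
filter_modules <- function(partition, min_size = 3L) {
  stopifnot(inherits(partition, "module_partition"))
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  small <- lengths(partition$modules) < min_size
  partition$unassigned <- sort(c(partition$unassigned,
                                 unlist(partition$modules[small])))
  partition$modules <- partition$modules[!small]
  partition$params$min_size <- min_size
  partition
}
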