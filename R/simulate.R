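#' Simulation configuration
#'
#' Defaults emulate the scale of the curated cleft-lip regulatory universe:
#' 27 TFs, 18 miRNAs and 127 candidate genes; 71/50/7 planted feed-forward
#' loops of motifs A/B/C; background edge rates chosen so the four pair
#' tables have roughly the densities of the curated tables (about 671
#' TF-gene, 76 TF-miRNA, 77 miRNA-gene and 21 miRNA-TF pairs); a 35-sample
#' expression matrix with planted TF-gene correlation 0.9 on about 64.8% of
#' the network's TF-gene edges.
#'
#' @param n_tf,n_mirna,n_gene Universe sizes (positive integers).
#' @param planted_ffls Named counts per motif type, `c(A=, B=, C=)`.
#' @param background_edge_rates Named per-edge-type probabilities in `[0,1]`.
#' @param n_samples Expression samples (>= 3; the Pearson p-value needs
#'   `df = n - 2 >= 1`).
#' @param rho Planted TF-gene correlation in (-1, 1).
#' @param frac_correlated Fraction of TF-gene edges planted as correlated.
#' @param noise_sd Expression noise standard deviation (> 0).
#' @param seed Integer seed; every artifact draws from its own named stream
#'   derived from it, so regenerating one artifact does not perturb another.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_tf = 27L, n_mirna = 18L, n_gene = 127L,
                              planted_ffls = c(A = 71L, B = 50L, C = 7L),
                              background_edge_rates = c(
                                TF_gene = 0.196, TF_miRNA = 0.156,
                                miRNA_gene = 0.034, miRNA_TF = 0.043),
                              n_samples = 35L, rho = 0.9,
                              frac_correlated = 0.648, noise_sd = 1,
                              seed = 1L) {
  stopifnot(n_tf >= 1, n_mirna >= 1, n_gene >= 1)
  planted_ffls <- planted_ffls[c("A", "B", "C")]
  names(planted_ffls) <- c("A", "B", "C")
  planted_ffls[is.na(planted_ffls)] <- 0L
  stopifnot(all(planted_ffls >= 0))
  stopifnot(all(names(background_edge_rates) %in% EDGE_TYPES),
            all(background_edge_rates >= 0), all(background_edge_rates <= 1))
  rates <- stats::setNames(numeric(length(EDGE_TYPES)), EDGE_TYPES)
  rates[names(background_edge_rates)] <- background_edge_rates
  if (n_samples < 3) stop("n_samples must be >= 3", call. = FALSE)
  stopifnot(rho > -1, rho < 1, frac_correlated >= 0, frac_correlated <= 1,
            noise_sd > 0)
  structure(list(n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
                 n_gene = as.integer(n_gene),
                 planted_ffls = vapply(planted_ffls, as.integer, integer(1)),
                 background_edge_rates = rates,
                 n_samples = as.integer(n_samples), rho = rho,
                 frac_correlated = frac_correlated, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_ids <- function(config) {
  list(tf = sprintf("TF%03d", seq_len(config$n_tf)),
       mirna = sprintf("hsa-mir-%03d", seq_len(config$n_mirna)),
       gene = sprintf("G%03d", seq_len(config$n_gene)))
}

#' Generate the four regulatory pair tables with planted FFLs
#'
#' Plants the configured number of motif-A/B/C feed-forward loops on
#' pairwise-distinct (TF, miRNA) regulator pairs (so the exclusive
#' classification of planted triples can never collide), then adds
#' background edges by independent coin flips over the remaining
#' kind-consistent ordered pairs. Background TF->miRNA and miRNA->TF edges
#' that would convert a planted A- or B-motif into motif C are excluded, so
#' enumeration always recovers at least the planted count per motif type,
#' and exactly the planted counts when all background rates are zero.
#'
#' @param config A `simulation_config`.
#' @return List with `tables` (named list of `source`/`target` data.frames,
#'   one per edge type), `edges` (single typed edge data.frame), and `truth`
#'   (list with the planted `ffls` data.frame).
#' @export
generate_pair_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- sim_ids(config)
  planted <- config$planted_ffls
  total <- sum(planted)
  capacity <- config$n_tf * config$n_mirna
  if (total > capacity) {
    stop("planted FFL count (", total, ") exceeds the TF x miRNA pair ",
         "capacity (", capacity, ")", call. = FALSE)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, "tables"))

  truth_ffls <- data.frame(tf = character(), mirna = character(),
                           gene = character(), motif_type = character(),
                           stringsAsFactors = FALSE)
  edges <- data.frame(source = character(), target = character(),
                      edge_type = character(), stringsAsFactors = FALSE)
  forbidden <- character(0)  # keys of regulator edges that would flip A/B -> C

  if (total > 0) {
    motif <- rep(c("A", "B", "C"), times = planted)
    ## Pairwise-distinct (TF, miRNA) pairs keep the exclusive classification
    ## of planted triples from colliding. Gene assignment is checked so that
    ## the planted edges imply no triple beyond the planted ones: reusing a
    ## gene is fine unless it closes an unplanted co-targeting pattern.
    avail <- sample.int(capacity)
    ptr <- 0L
    pair_key <- character(0)              # planted regulator pairs "t\rm"
    tf_of_gene <- list()                  # gene -> TFs targeting it
    mir_of_gene <- list()                 # gene -> miRNAs targeting it
    genes_of_tf <- list()
    genes_of_mir <- list()
    triple_key <- character(0)
    tf_v <- mir_v <- gene_v <- character(total)
    for (i in seq_len(total)) {
      placed <- FALSE
      while (!placed && ptr < capacity) {
        ptr <- ptr + 1L
        t <- ids$tf[((avail[ptr] - 1L) %% config$n_tf) + 1L]
        m <- ids$mirna[((avail[ptr] - 1L) %/% config$n_tf) + 1L]
        ## linking t and m must not complete a loop over a gene both
        ## already target through different planted FFLs
        shared <- intersect(genes_of_tf[[t]], genes_of_mir[[m]])
        if (length(shared) &&
            any(!(paste(t, m, shared, sep = "\r") %in% triple_key))) next
        for (g in ids$gene[sample.int(config$n_gene)]) {
          ## t -> g must not co-target g with a linked miRNA of another FFL,
          ## nor m -> g with a linked TF of another FFL
          mirs <- mir_of_gene[[g]]
          tfs <- tf_of_gene[[g]]
          bad1 <- length(mirs) &&
            any(paste(t, mirs, sep = "\r") %in% pair_key &
                !(paste(t, mirs, g, sep = "\r") %in% triple_key))
          bad2 <- length(tfs) &&
            any(paste(tfs, m, sep = "\r") %in% pair_key &
                !(paste(tfs, m, g, sep = "\r") %in% triple_key))
          if (bad1 || bad2) next
          tf_v[i] <- t; mir_v[i] <- m; gene_v[i] <- g
          pair_key <- c(pair_key, paste(t, m, sep = "\r"))
          tf_of_gene[[g]] <- union(tf_of_gene[[g]], t)
          mir_of_gene[[g]] <- union(mir_of_gene[[g]], m)
          genes_of_tf[[t]] <- union(genes_of_tf[[t]], g)
          genes_of_mir[[m]] <- union(genes_of_mir[[m]], g)
          triple_key <- c(triple_key, paste(t, m, g, sep = "\r"))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("planted FFL count (", total, ") exceeds the collision-free ",
             "capacity of the TF x miRNA x gene universe", call. = FALSE)
      }
    }
    truth_ffls <- data.frame(tf = tf_v, mirna = mir_v, gene = gene_v,
                             motif_type = motif, stringsAsFactors = FALSE)
    edges <- do.call(rbind, lapply(seq_len(total), function(i) {
      ffl_edges(truth_ffls$tf[i], truth_ffls$mirna[i], truth_ffls$gene[i],
                truth_ffls$motif_type[i])
    }))
    a <- truth_ffls$motif_type == "A"
    b <- truth_ffls$motif_type == "B"
    forbidden <- c(
      paste(truth_ffls$mirna[a], truth_ffls$tf[a], "miRNA_TF", sep = "\r"),
      paste(truth_ffls$tf[b], truth_ffls$mirna[b], "TF_miRNA", sep = "\r"))
  }

  universes <- list(
    TF_gene = expand.grid(source = ids$tf, target = ids$gene,
                          stringsAsFactors = FALSE),
    TF_miRNA = expand.grid(source = ids$tf, target = ids$mirna,
                           stringsAsFactors = FALSE),
    miRNA_gene = expand.grid(source = ids$mirna, target = ids$gene,
                             stringsAsFactors = FALSE),
    miRNA_TF = expand.grid(source = ids$mirna, target = ids$tf,
                           stringsAsFactors = FALSE))
  planted_keys <- paste(edges$source, edges$target, edges$edge_type, sep = "\r")
  for (et in EDGE_TYPES) {
    rate <- config$background_edge_rates[[et]]
    if (rate <= 0) next
    u <- universes[[et]]
    u <- u[order(u$source, u$target), , drop = FALSE]  # seed-stable order
    key <- paste(u$source, u$target, et, sep = "\r")
    eligible <- !(key %in% planted_keys) & !(key %in% forbidden)
    pick <- eligible & (stats::runif(nrow(u)) < rate)
    if (any(pick)) {
      edges <- rbind(edges, data.frame(source = u$source[pick],
                                       target = u$target[pick],
                                       edge_type = et,
                                       stringsAsFactors = FALSE))
    }
  }
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target, edges$edge_type), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  tables <- lapply(stats::setNames(EDGE_TYPES, EDGE_TYPES), function(et) {
    e <- edges[edges$edge_type == et, c("source", "target"), drop = FALSE]
    rownames(e) <- NULL
    e
  })
  truth_ffls <- truth_ffls[order(truth_ffls$tf, truth_ffls$mirna,
                                 truth_ffls$gene), , drop = FALSE]
  rownames(truth_ffls) <- NULL
  list(tables = tables, edges = edges,
       truth = list(ffls = as_ffl_set(truth_ffls)))
}

#' Generate an expression matrix with planted TF-gene correlation
#'
#' Rows are produced for every TF and gene node of the network. A set of
#' TF-gene edges covering about `frac_correlated` of the network's TF-gene
#' edges is selected; the selected edges' endpoints load on shared latent
#' factors (one per connected component of the selected subgraph) with
#' loading `sqrt(|rho|)` (gene loading negated for negative `rho`), so every
#' selected edge has population Pearson correlation exactly `rho` while
#' unselected edges and nodes in different components stay independent.
#' Values are `8 + noise_sd * z` — a unit-variance Gaussian profile around a
#' log-scale baseline.
#'
#' @param network A `regulatory_network` with at least one TF_gene edge.
#' @param config A `simulation_config` (`n_samples`, `rho`,
#'   `frac_correlated`, `noise_sd`, `seed` are used).
#' @return List with `matrix` (rows = TF/gene symbols, columns = samples)
#'   and `truth` (data.frame `correlated_edges` of the planted edges).
#' @export
generate_expression <- function(network, config) {
  stopifnot(inherits(network, "regulatory_network"),
            inherits(config, "simulation_config"))
  tg <- network$edges[network$edges$edge_type == "TF_gene", , drop = FALSE]
  if (nrow(tg) == 0L) stop("network has no TF_gene edges", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, "expression"))

  n_target <- round(config$frac_correlated * nrow(tg))
  sel <- logical(nrow(tg))
  if (n_target > 0 && abs(config$rho) > 0) {
    ord <- sample.int(nrow(tg))
    tf_set <- character(0)
    gene_set <- character(0)
    for (i in ord) {
      if (sum(sel) >= n_target) break
      tf_set <- union(tf_set, tg$source[i])
      gene_set <- union(gene_set, tg$target[i])
      ## selected set = every network TF-gene edge inside the factor node
      ## sets, so no unselected edge can be accidentally correlated
      sel <- tg$source %in% tf_set & tg$target %in% gene_set
    }
  }
  planted <- tg[sel, c("source", "target"), drop = FALSE]
  rownames(planted) <- NULL

  rows <- network$nodes$id[network$nodes$kind %in% c("TF", "gene")]
  rows <- sort(rows)
  n <- config$n_samples
  a <- sqrt(abs(config$rho))

  ## one latent factor per connected component of the planted subgraph
  comp_of <- integer(0)
  n_comp <- 0L
  if (nrow(planted) > 0) {
    gsub_ <- igraph::graph_from_data_frame(planted, directed = FALSE)
    comp <- igraph::components(gsub_)
    comp_of <- stats::setNames(comp$membership, igraph::V(gsub_)$name)
    n_comp <- comp$no
  }
  W <- if (n_comp > 0) {
    matrix(stats::rnorm(n_comp * n), nrow = n_comp)
  } else {
    matrix(numeric(0), nrow = 0, ncol = n)
  }

  kinds <- stats::setNames(network$nodes$kind, network$nodes$id)
  Z <- matrix(NA_real_, nrow = length(rows), ncol = n,
              dimnames = list(rows, sprintf("S%02d", seq_len(n))))
  for (v in rows) {
    eps <- stats::rnorm(n)
    if (v %in% names(comp_of)) {
      load <- if (kinds[[v]] == "gene" && config$rho < 0) -a else a
      Z[v, ] <- load * W[comp_of[[v]], ] + sqrt(1 - a^2) * eps
    } else {
      Z[v, ] <- eps
    }
  }
  list(matrix = 8 + config$noise_sd * Z,
       truth = list(correlated_edges = planted,
                    n_requested = n_target))
}

#' Generate synthetic gene sets with one planted enriched set
#'
#' The planted set is exactly the gene-kind target set of the TF with the
#' most gene targets (ties broken by id); decoy sets are uniform draws from
#' the full simulated gene universe. The background is that whole universe —
#' the analogue of a platform- or genome-wide annotation background — so the
#' planted hub's targets are maximally enriched in the planted term.
#'
#' @param network A `regulatory_network`.
#' @param config A `simulation_config` (`n_gene` fixes the background
#'   universe, `seed` the decoy draws).
#' @param n_sets Total number of sets, including the planted one.
#' @param decoy_size Size of each decoy set; defaults to the planted set's
#'   size (matched-size decoys), floored at 5 and capped at the universe.
#' @return List with `sets` (a `gene_set_collection` whose background is the
#'   gene universe) and `truth` (`planted_term`, `planted_hub`).
#' @export
generate_gene_sets <- function(network, config, n_sets = 20L,
                               decoy_size = NULL) {
  stopifnot(inherits(network, "regulatory_network"), n_sets >= 1)
  genes <- sim_ids(config)$gene
  tg <- network$edges[network$edges$edge_type == "TF_gene", , drop = FALSE]
  if (nrow(tg) == 0L) stop("network has no TF_gene edges", call. = FALSE)
  deg <- sort(table(tg$source), decreasing = TRUE)
  hub <- names(deg)[order(-as.integer(deg), names(deg))][1]
  planted <- sort(unique(tg$target[tg$source == hub]))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, "genesets"))

  if (is.null(decoy_size)) decoy_size <- max(length(planted), 5L)
  k <- min(decoy_size, length(genes))
  sets <- c(list(planted),
            lapply(seq_len(n_sets - 1L), function(i) sort(sample(genes, k))))
  names(sets) <- sprintf("GS%03d", seq_len(n_sets))
  desc <- stats::setNames(c("planted: hub target set",
                            rep("decoy", n_sets - 1L)), names(sets))
  list(sets = gene_set_collection(sets, descriptions = desc,
                                  background = genes),
       truth = list(planted_term = names(sets)[1], planted_hub = hub))
}

#' Write simulated artifacts to a directory
#'
#' Emits the four pair TSVs, the expression TSV, a GMT of the synthetic gene
#' sets, and a ground-truth JSON.
#'
#' @param sim Output of [generate_pair_tables()].
#' @param expr Output of [generate_expression()] (optional).
#' @param gene_sets Output of [generate_gene_sets()] (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, expr = NULL, gene_sets = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (et in names(sim$tables)) {
    utils::write.table(sim$tables[[et]],
                       file.path(dir, paste0(et, "_pairs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(ffls = sim$truth$ffls)
  if (!is.null(expr)) {
    m <- expr$matrix
    utils::write.table(cbind(id = rownames(m), as.data.frame(m)),
                       file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth$correlated_edges <- expr$truth$correlated_edges
  }
  if (!is.null(gene_sets)) {
    write_gmt(gene_sets$sets, file.path(dir, "gene_sets.gmt"))
    truth$planted_term <- gene_sets$truth$planted_term
    truth$planted_hub <- gene_sets$truth$planted_hub
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

## save/restore the global RNG state so generators with internal seeds do
## not disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
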