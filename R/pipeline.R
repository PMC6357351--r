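#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_pipeline()]. Inputs come
#' either from a [simulation_config()] (`sim`) or from file paths; stage
#' parameters default to the analysis conventions used throughout the
#' package (top-10 hubs, MCL inflation 2.0 with minimum module size 3,
#' verification thresholds |r| > 0.3, P < 0.05, FDR < 0.1, enrichment
#' FDR < 0.05).
#'
#' @param sim Optional `simulation_config`; when given, pair tables,
#'   expression and gene sets are generated in memory with ground truth.
#' @param pair_tables Named list of pair-table paths (names in
#'   [edge_types()]), used when `sim` is NULL.
#' @param expression Optional expression-matrix path (TSV or series-matrix).
#' @param gmt Optional GMT path.
#' @param pathway_seeds Optional character vector of seed gene symbols for
#'   subnetwork extraction (for simulated runs it defaults to the first four
#'   genes occupying FFL gene slots).
#' @param probe_map,ortholog_map Optional mapping files/vectors for
#'   [collapse_probes()] and [map_symbols()].
#' @param k Hub count (default 10).
#' @param inflation,min_module_size MCL parameters (defaults 2.0, 3).
#' @param r_min,p_max,q_max Edge-verification thresholds.
#' @param fdr Enrichment significance level on q (default 0.05).
#' @param out_dir Optional output directory for stage artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, pair_tables = NULL, expression = NULL,
                            gmt = NULL, pathway_seeds = NULL,
                            probe_map = NULL, ortholog_map = NULL,
                            k = 10L, inflation = 2, min_module_size = 3L,
                            r_min = 0.3, p_max = 0.05, q_max = 0.1,
                            fdr = 0.05, out_dir = NULL) {
  if (is.null(sim) && is.null(pair_tables)) {
    stop("either 'sim' or 'pair_tables' must be given", call. = FALSE)
  }
  stopifnot(k >= 1, inflation > 1, min_module_size >= 1,
            r_min >= 0, p_max > 0, p_max <= 1, q_max > 0, q_max <= 1,
            fdr > 0, fdr <= 1)
  structure(list(sim = sim, pair_tables = pair_tables,
                 expression = expression, gmt = gmt,
                 pathway_seeds = pathway_seeds, probe_map = probe_map,
                 ortholog_map = ortholog_map, k = as.integer(k),
                 inflation = inflation,
                 min_module_size = as.integer(min_module_size),
                 r_min = r_min, p_max = p_max, q_max = q_max, fdr = fdr,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full co-regulatory network analysis
#'
#' Chains every stage in order: ingest or simulate the four pair tables,
#' enumerate and classify feed-forward loops, build the motif-specific and
#' combined networks, rank hubs by maximal clique centrality, partition
#' modules by Markov clustering, validate TF-gene edges against the
#' expression matrix, run hypergeometric enrichment for hub targets and
#' modules, and extract the pathway-seeded subnetwork. Stages whose inputs
#' are absent are recorded as `"skipped"`; any stage failure aborts with the
#' stage name, retaining artifacts already written. Identical configuration
#' and inputs give an identical manifest.
#'
#' @param config A `pipeline_config`.
#' @return The manifest: a list with one entry per stage holding the
#'   headline numbers and tables, plus `params` and (for simulated runs)
#'   `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  manifest <- list(params = config[c("k", "inflation", "min_module_size",
                                     "r_min", "p_max", "q_max", "fdr")])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## -- ingest / simulate ------------------------------------------------
  truth <- NULL
  expr_matrix <- NULL
  gene_sets <- NULL
  edges <- stage("ingest", {
    if (!is.null(config$sim)) {
      sim <- generate_pair_tables(config$sim)
      truth <- sim$truth
      sim$edges
    } else {
      checksums <- vapply(unlist(config$pair_tables), function(p) {
        unname(tools::md5sum(p))
      }, character(1))
      manifest$params$input_md5 <- as.list(checksums)
      do.call(rbind, lapply(names(config$pair_tables), function(et) {
        parse_pair_table(config$pair_tables[[et]], et)
      }))
    }
  })

  ## -- enumerate --------------------------------------------------------
  ffls <- stage("enumerate", enumerate_ffls(edges))
  msum <- motif_summary(ffls)
  manifest$ffls <- list(
    n_total = nrow(ffls),
    by_type = as.list(stats::setNames(
      msum$n_ffls[match(c("A", "B", "C"), msum$motif)], c("A", "B", "C"))))
  if (!is.null(out_dir)) {
    utils::write.table(ffls, file.path(out_dir, "ffls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(msum, file.path(out_dir, "motif_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- build ------------------------------------------------------------
  combined <- stage("build", build_network(ffls))
  manifest$network <- network_stats(combined)
  manifest$network$edges_by_type <- as.list(manifest$network$edges_by_type)
  manifest$network$by_motif <- lapply(
    stats::setNames(c("A", "B", "C"), c("A", "B", "C")),
    function(m) {
      s <- network_stats(build_network(ffls, motif_filter = m))
      s$edges_by_type <- as.list(s$edges_by_type)
      s
    })
  if (!is.null(out_dir)) {
    write_network(combined, file.path(out_dir, "combined_network.tsv"))
  }

  ## -- hubs -------------------------------------------------------------
  hubs <- stage("hubs", {
    if (nrow(combined$edges) == 0L) NULL else
      suppressWarnings(top_k(mcc_scores(combined), config$k))
  })
  manifest$hubs <- if (is.null(hubs)) "skipped" else
    list(ids = hubs$id, mcc = hubs$mcc)
  if (!is.null(out_dir) && !is.null(hubs)) {
    utils::write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- cluster ----------------------------------------------------------
  partition <- stage("cluster", {
    if (nrow(combined$edges) == 0L) NULL else
      filter_modules(mcl(combined, inflation = config$inflation),
                     min_size = config$min_module_size)
  })
  manifest$modules <- if (is.null(partition)) "skipped" else
    list(n_modules = length(partition$modules),
         sizes = lengths(partition$modules),
         n_unassigned = length(partition$unassigned))
  if (!is.null(out_dir) && !is.null(partition)) {
    df <- data.frame(
      node = c(unlist(partition$modules), partition$unassigned),
      module = c(rep(seq_along(partition$modules),
                     lengths(partition$modules)),
                 rep("unassigned", length(partition$unassigned))))
    utils::write.table(df, file.path(out_dir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- validate ---------------------------------------------------------
  has_tg <- any(combined$edges$edge_type == "TF_gene")
  validation <- stage("validate", {
    if (!is.null(config$sim) && has_tg) {
      gen <- generate_expression(combined, config$sim)
      truth$correlated_edges <- gen$truth$correlated_edges
      expr_matrix <- gen$matrix
    } else if (!is.null(config$expression)) {
      expr_matrix <- read_expression_matrix(config$expression)
      if (!is.null(config$probe_map)) {
        expr_matrix <- collapse_probes(expr_matrix, config$probe_map)
      }
    }
    if (is.null(expr_matrix) || !has_tg) NULL else
      validate_edges(combined, expr_matrix, config$ortholog_map,
                     r_min = config$r_min, p_max = config$p_max,
                     q_max = config$q_max)
  })
  manifest$validation <- if (is.null(validation)) "skipped" else
    validation$summary
  if (!is.null(out_dir) && !is.null(validation)) {
    utils::write.table(validation$results,
                       file.path(out_dir, "edge_validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- enrich -----------------------------------------------------------
  enrichment <- stage("enrich", {
    if (!is.null(config$sim) && has_tg) {
      gs <- generate_gene_sets(combined, config$sim)
      truth$planted_term <- gs$truth$planted_term
      truth$planted_hub <- gs$truth$planted_hub
      gene_sets <- gs$sets
    } else if (!is.null(config$gmt)) {
      gene_sets <- read_gmt(config$gmt)
    }
    if (is.null(gene_sets) || is.null(hubs)) NULL else {
      hub_res <- suppressWarnings(hub_target_enrichment(
        combined, hubs, gene_sets, q_threshold = config$fdr))
      module_res <- if (is.null(partition)) list() else
        lapply(partition$modules, function(m) {
          bg <- if (is.null(gene_sets$background))
            unique(unlist(gene_sets$sets)) else gene_sets$background
          q <- intersect(m, bg)
          if (!length(q)) NULL else enrich(q, gene_sets,
                                           q_threshold = config$fdr)
        })
      list(hub = hub_res, module = module_res)
    }
  })
  manifest$enrichment <- if (is.null(enrichment)) "skipped" else list(
    hub_top_terms = lapply(enrichment$hub, function(df) {
      if (nrow(df)) list(term = df$term[1], q = df$q[1]) else NULL
    }),
    n_significant_module_terms = vapply(enrichment$module, function(df) {
      if (is.null(df)) 0L else sum(df$significant)
    }, integer(1)))
  if (!is.null(enrichment) && !is.null(truth$planted_hub)) {
    ## ground-truth recovery record for simulated runs: enrichment of the
    ## planted hub's target set must surface the planted term
    targets <- combined$edges$target[combined$edges$source ==
                                       truth$planted_hub]
    check <- enrich(targets, gene_sets, q_threshold = config$fdr)
    manifest$enrichment$planted_recovery <- list(
      top_term = check$term[1], top_q = check$q[1],
      planted_term = truth$planted_term,
      planted_q = check$q[match(truth$planted_term, check$term)])
  }

  ## -- subnet -----------------------------------------------------------
  seeds <- config$pathway_seeds
  if (is.null(seeds) && !is.null(config$sim) && nrow(ffls) > 0) {
    seeds <- utils::head(sort(unique(ffls$gene)), 4L)
  }
  subnet <- stage("subnet", {
    if (is.null(seeds) || nrow(ffls) == 0L) NULL else
      suppressWarnings(extract_subnetwork(ffls, seeds))
  })
  manifest$subnetwork <- if (is.null(subnet)) "skipped" else list(
    seeds_found = subnet$seeds_found,
    n_components = length(subnet$components),
    overall = {
      s <- subnet$overall_stats
      s$edges_by_type <- as.list(s$edges_by_type)
      s
    })

  if (!is.null(truth)) manifest$truth <- truth
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  manifest
}
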