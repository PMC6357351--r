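small_config <- function(planted = c(A = 5L, B = 0L, C = 0L)) {
  simulation_config(n_tf = 8L, n_mirna = 6L, n_gene = 15L,
                    planted_ffls = planted,
                    background_edge_rates = c(TF_gene = 0, TF_miRNA = 0,
                                              miRNA_gene = 0, miRNA_TF = 0),
                    n_samples = 20L, seed = 7L)
}

test_that("planted motifs are recovered exactly when background is off", {
  sim <- generate_pair_tables(small_config())
  ffls <- enumerate_ffls(sim$edges)
  expect_equal(nrow(ffls), 5L)
  expect_equal(unique(ffls$motif_type), "A")
  expect_equal(ffls, sim$truth$ffls, ignore_attr = TRUE)

  cfg <- small_config(planted = c(A = 0L, B = 0L, C = 2L))
  sim <- generate_pair_tables(cfg)
  ffls <- enumerate_ffls(sim$edges)
  expect_equal(as.vector(table(factor(ffls$motif_type, c("A", "B", "C")))),
               c(0L, 0L, 2L))
  # independent brute-force pattern scan agrees
  expect_equal(as.data.frame(ffls), oracle_ffls(sim$edges))
})

test_that("generation is deterministic per seed and stream-isolated", {
  cfg <- simulation_config(n_tf = 6L, n_mirna = 5L, n_gene = 10L,
                           planted_ffls = c(A = 3L, B = 2L, C = 1L),
                           background_edge_rates = c(TF_gene = 0.1,
                                                     miRNA_gene = 0.1),
                           n_samples = 10L, seed = 11L)
  s1 <- generate_pair_tables(cfg)
  s2 <- generate_pair_tables(cfg)
  expect_identical(s1, s2)

  # the expression stream does not perturb the tables stream
  net <- build_network(enumerate_ffls(s1$edges))
  e1 <- generate_expression(net, cfg)
  s3 <- generate_pair_tables(cfg)
  expect_identical(s1, s3)
  e2 <- generate_expression(net, cfg)
  expect_identical(e1, e2)

  cfg2 <- simulation_config(n_tf = 6L, n_mirna = 5L, n_gene = 10L,
                            planted_ffls = c(A = 3L, B = 2L, C = 1L),
                            n_samples = 10L, seed = 12L)
  expect_false(identical(generate_pair_tables(cfg2)$edges, s1$edges))
})

test_that("planted counts exceeding pair capacity are rejected", {
  expect_error(generate_pair_tables(
    simulation_config(n_tf = 2L, n_mirna = 2L, n_gene = 10L,
                      planted_ffls = c(A = 5L, B = 0L, C = 0L))),
    "capacity")
})

test_that("enumeration recovers at least the planted count per type under background", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- simulation_config(n_tf = 10L, n_mirna = 8L, n_gene = 20L,
                             planted_ffls = c(A = 6L, B = 4L, C = 3L),
                             background_edge_rates = c(
                               TF_gene = 0.15, TF_miRNA = 0.1,
                               miRNA_gene = 0.1, miRNA_TF = 0.05),
                             n_samples = 10L, seed = seed)
    sim <- generate_pair_tables(cfg)
    counts <- table(factor(enumerate_ffls(sim$edges)$motif_type,
                           c("A", "B", "C")))
    expect_true(all(counts >= c(A = 6L, B = 4L, C = 3L)),
                label = paste("seed", seed, "planted counts dominated"))
    # and planted triples appear verbatim with their planted class
    found <- merge(sim$truth$ffls, as.data.frame(enumerate_ffls(sim$edges)))
    expect_equal(nrow(found), nrow(sim$truth$ffls))
  }
})

test_that("planted expression correlation concentrates around rho", {
  edge <- regulatory_network(data.frame(source = "TF1", target = "G1",
                                        edge_type = "TF_gene"))
  hits <- 0L
  for (seed in 1:50) {
    cfg <- simulation_config(n_tf = 1L, n_mirna = 1L, n_gene = 1L,
                             planted_ffls = c(A = 0L, B = 0L, C = 0L),
                             n_samples = 200L, rho = 0.95,
                             frac_correlated = 1, seed = seed)
    ex <- generate_expression(edge, cfg)
    r <- cor(ex$matrix["TF1", ], ex$matrix["G1", ])
    hits <- hits + (abs(r - 0.95) <= 0.05)
  }
  # Fisher-z: at n = 200 the sampling sd of atanh(r) is ~0.071, so nearly
  # every draw lands within +/- 0.05 of rho
  expect_gte(hits, 47L)
})

test_that("negative planted correlation and the null are honoured", {
  edge <- regulatory_network(data.frame(source = "TF1", target = "G1",
                                        edge_type = "TF_gene"))
  cfg <- simulation_config(n_tf = 1L, n_mirna = 1L, n_gene = 1L,
                           planted_ffls = c(A = 0L, B = 0L, C = 0L),
                           n_samples = 500L, rho = -0.8,
                           frac_correlated = 1, seed = 3L)
  ex <- generate_expression(edge, cfg)
  expect_lt(cor(ex$matrix["TF1", ], ex$matrix["G1", ]), -0.6)

  cfg0 <- simulation_config(n_tf = 1L, n_mirna = 1L, n_gene = 1L,
                            planted_ffls = c(A = 0L, B = 0L, C = 0L),
                            n_samples = 500L, rho = 0,
                            frac_correlated = 1, seed = 3L)
  ex0 <- generate_expression(edge, cfg0)
  expect_equal(nrow(ex0$truth$correlated_edges), 0L)
  expect_lt(abs(cor(ex0$matrix["TF1", ], ex0$matrix["G1", ])), 0.2)
})

test_that("written simulation artifacts parse back through the readers", {
  cfg <- simulation_config(n_tf = 5L, n_mirna = 4L, n_gene = 8L,
                           planted_ffls = c(A = 3L, B = 1L, C = 1L),
                           background_edge_rates = c(TF_gene = 0.1),
                           n_samples = 6L, seed = 5L)
  sim <- generate_pair_tables(cfg)
  net <- build_network(enumerate_ffls(sim$edges))
  ex <- generate_expression(net, cfg)
  gs <- generate_gene_sets(net, cfg, n_sets = 4L, decoy_size = 3L)
  dir <- withr::local_tempdir()
  write_simulation(sim, ex, gs, dir)

  edges <- do.call(rbind, lapply(edge_types(), function(et) {
    p <- file.path(dir, paste0(et, "_pairs.tsv"))
    if (file.size(p) > nchar("source\ttarget") + 2) {
      parse_pair_table(p, et)
    }
  }))
  expect_equal(edges[order(edges$source, edges$target, edges$edge_type), ],
               sim$edges, ignore_attr = TRUE)
  m <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(unname(m), unname(ex$matrix), tolerance = 1e-10)
  gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(gmt$sets, gs$sets$sets)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
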