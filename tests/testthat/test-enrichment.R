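test_that("hypergeometric upper tail is exact", {
  expect_equal(hypergeom_pvalue(0, 5, 5, 10), 1)
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_pvalue(1, 1, 1, 1), 1)
  expect_error(hypergeom_pvalue(6, 5, 5, 10), "invalid")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "invalid")

  # exhaustive combinatorial sum for every configuration with N <= 25
  withr::local_seed(123)
  for (rep in 1:50) {
    N <- sample(2:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N), oracle_hyper(k, K, n, N),
                 tolerance = 1e-12,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
})

test_that("BH q-values equal the textbook step-up procedure", {
  fixed <- list(
    c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216),
    c(0.5), c(0.04, 0.04, 0.04), c(1, 0.2, 0.01, 0.005))
  for (p in fixed) {
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
  g <- enrich(c("a", "b"),
              gene_set_collection(list(s1 = c("a", "b", "c"),
                                       s2 = c("c", "d"),
                                       s3 = c("a", "d", "e"))))
  expect_equal(g$q, oracle_bh(g$p))
})

test_that("enrichment ranks a fully recovered set first", {
  sets <- gene_set_collection(list(
    hit = sprintf("g%d", 1:5),
    decoy1 = sprintf("g%d", 6:10),
    decoy2 = sprintf("g%d", 11:15)))
  res <- enrich(sprintf("g%d", 1:5), sets)
  expect_equal(res$term[1], "hit")
  expect_equal(res$p[1], min(res$p))
  expect_equal(res$p[1], oracle_hyper(5, 5, 5, 15))

  single <- enrich(c("g1", "g2"), gene_set_collection(list(only = c("g1", "g3"))),
                   background = sprintf("g%d", 1:10))
  expect_equal(single$q, single$p)  # BH identity at m = 1
})

test_that("enrichment is stable under query and set permutations", {
  withr::local_seed(9)
  bg <- sprintf("g%03d", 1:60)
  sets <- lapply(1:6, function(i) sample(bg, 10))
  names(sets) <- sprintf("s%d", 1:6)
  q <- sample(bg, 12)
  a <- enrich(q, gene_set_collection(sets), background = bg)
  b <- enrich(sample(q), gene_set_collection(sets[sample(6)]), background = bg)
  expect_equal(a, b)
})

test_that("query genes outside the background are dropped, not silently", {
  sets <- gene_set_collection(list(s = c("a", "b")), background = c("a", "b", "c"))
  expect_message(res <- enrich(c("a", "zzz"), sets), "absent from the background")
  expect_equal(res$n, 1L)
  expect_error(suppressMessages(enrich("zzz", sets)), "empty query")
})

test_that("null queries attain the nominal type-I level", {
  withr::local_seed(2718)
  bg <- sprintf("g%03d", 1:100)
  sets <- gene_set_collection(
    stats::setNames(lapply(1:10, function(i) sample(bg, 20)),
                    sprintf("s%02d", 1:10)))
  hits <- 0L
  total <- 0L
  for (rep in 1:100) {
    res <- enrich(sample(bg, 10), sets, background = bg, q_threshold = 0.05)
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  # hypergeometric p-values are discrete, so the attained level sits at or
  # below 0.05; allow Monte-Carlo slack above
  expect_lt(hits / total, 0.08)
})

test_that("hub-target enrichment queries each hub's direct targets", {
  edges <- data.frame(
    source = c(rep("TF1", 3), "m1"),
    target = c("g1", "g2", "g3", "g4"),
    edge_type = c(rep("TF_gene", 3), "miRNA_gene"))
  net <- regulatory_network(edges)
  bg <- sprintf("g%d", 1:100)
  sets <- gene_set_collection(list(
    target_set = c("g1", "g2", "g3"),
    with_g4 = c(sprintf("g%d", 4:13)),
    other = sprintf("g%d", 21:30)))
  res <- hub_target_enrichment(net, c("TF1", "m1"), sets, background = bg)
  expect_equal(res$TF1$term[1], "target_set")
  # n = 1 query: p = K/N for every containing set
  g4row <- res$m1[res$m1$term == "with_g4", ]
  expect_equal(g4row$p, 10 / 100)

  expect_warning(r2 <- hub_target_enrichment(net, c("TF1", "g1"), sets,
                                             background = bg),
                 "no targets")
  expect_named(r2, "TF1")
  expect_length(hub_target_enrichment(net, character(0), sets, bg), 0L)
})
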