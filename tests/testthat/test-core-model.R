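test_that("pair-table parsing deduplicates, rejects self-loops, and reports drops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "TF1\tG1", "TF1\tG2", "TF2\tG1"), path)
  e <- parse_pair_table(path, "TF_gene")
  expect_equal(nrow(e), 3L)
  expect_equal(attr(e, "dropped"), list(duplicates = 0L, self_loops = 0L))

  writeLines(c("TF1\tG1", "TF1\tG2", "TF1\tG1"), path)
  e <- parse_pair_table(path, "TF_gene")
  expect_equal(nrow(e), 2L)
  expect_equal(attr(e, "dropped")$duplicates, 1L)

  writeLines(c("TF1\tTF1", "TF1\tG1"), path)
  expect_message(e <- parse_pair_table(path, "TF_gene"), "self-loop")
  expect_equal(nrow(e), 1L)
  expect_equal(attr(e, "dropped")$self_loops, 1L)
})

test_that("pair-table parsing errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF1\tG1", "justonefield"), path)
  expect_error(parse_pair_table(path, "TF_gene"), "line 2")

  writeLines(c("TF1\tG1\tTF_gene", "TF2\tm1\tTF_miRNA"), path)
  expect_error(parse_pair_table(path, "TF_gene"), "conflicts.*line 2")
  # and without the conflicting argument, the column is honoured
  e <- parse_pair_table(path)
  expect_equal(e$edge_type, c("TF_gene", "TF_miRNA"))
})

test_that("network construction enforces kind consistency and uniqueness", {
  edges <- data.frame(
    source = c("TF1", "TF1", "m1", "TF1"),
    target = c("G1", "m1", "G1", "G1"),
    edge_type = c("TF_gene", "TF_miRNA", "miRNA_gene", "TF_gene"))
  net <- regulatory_network(edges)
  expect_equal(nrow(net$edges), 3L)  # duplicate collapsed
  expect_setequal(net$nodes$kind, c("gene", "miRNA", "TF"))

  # same symbol as TF source and gene target: impossible by the role rules
  bad <- data.frame(source = c("TF1", "TF2"), target = c("G1", "TF1"),
                    edge_type = c("TF_gene", "TF_gene"))
  expect_error(regulatory_network(bad), "conflicting kinds.*TF1")
})

test_that("expression matrices parse from TSV and series-matrix dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2\tS3",
               paste0("p", 1:4, "\t", 1:4, "\t", 5:8, "\t", 9:12)), path)
  m <- read_expression_matrix(path)
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(m["p2", "S3"], 10)

  smx <- withr::local_tempfile(fileext = ".txt")
  writeLines(c('!Series_title\t"craniofacial development"',
               "!series_matrix_table_begin",
               '"ID_REF"\t"GSM1"\t"GSM2"',
               '"probeA"\t1.5\t2.5',
               '"probeB"\t3.5\tnull',
               "!series_matrix_table_end",
               "trailing junk ignored only outside fences"), smx)
  m <- read_expression_matrix(smx)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(is.na(m["probeB", "GSM2"]))
  expect_match(attr(m, "metadata"), "Series_title", all = FALSE)

  writeLines(c("id\tS1\tS1", "p1\t1\t2"), path)
  expect_error(read_expression_matrix(path), "duplicate sample")
  writeLines(c("id\tS1\tS2", "p1\t1"), path)
  expect_error(read_expression_matrix(path), "ragged")
})

test_that("GMT parsing collapses repeated members and flags malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescA\tG1\tG2\tG2", "setB\tdescB\tG3"), path)
  gs <- read_gmt(path)
  expect_length(gs$sets, 2L)
  expect_equal(gs$sets$setA, c("G1", "G2"))

  writeLines("setA\tonlydesc", path)
  expect_error(read_gmt(path), "line 1")
  writeLines(character(0), path)
  expect_warning(gs <- read_gmt(path), "empty")
  expect_length(gs$sets, 0L)
})

test_that("network serialization round-trips through edge TSV", {
  edges <- data.frame(source = c("TF1", "TF1", "m1"),
                      target = c("G1", "m1", "G1"),
                      edge_type = c("TF_gene", "TF_miRNA", "miRNA_gene"))
  net <- regulatory_network(edges)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$edges, net$edges[, c("source", "target", "edge_type")])
  expect_equal(back$nodes, net$nodes)

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(net, sif, format = "sif")
  expect_equal(readLines(sif)[1], "TF1\tTF_gene\tG1")

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3L)
  expect_setequal(igraph::E(g)$edge_type, edges$edge_type)

  expect_error(write_network(net, path, format = "dot"))

  empty <- regulatory_network(NULL)
  write_network(empty, path)
  expect_equal(readLines(path), "source\ttarget\tedge_type")
})
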