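write_ppi_file <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  if (header) lines <- c("protein1 protein2 combined_score", lines)
  writeLines(lines, path)
  path
}

test_that("PPI reader filters on the inclusive score threshold", {
  p <- write_ppi_file(c("a b 900", "b c 700", "c d 699"))
  net <- read_ppi_edges(p, score_min = 700)
  expect_equal(igraph::ecount(net), 2)
  expect_setequal(igraph::V(net)$name, c("a", "b", "c"))
  expect_setequal(igraph::E(net)$score, c(900L, 700L))
  # headerless dialect reads identically
  p2 <- write_ppi_file(c("a b 900", "b c 700", "c d 699"), header = FALSE)
  expect_equal(igraph::ecount(read_ppi_edges(p2, score_min = 700)), 2)
})

test_that("duplicate and reversed records collapse to one edge keeping max score", {
  p <- write_ppi_file(c("a b 800", "b a 800", "a b 750"))
  net <- read_ppi_edges(p, score_min = 700)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$score, 800L)
})

test_that("self-loops are dropped and counted", {
  p <- write_ppi_file(c("a a 900", "a b 800"))
  expect_message(net <- read_ppi_edges(p, score_min = 700), "1 self-loop")
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::graph_attr(net, "n_self_loops"), 1)
})

test_that("PPI reader rejects bad inputs", {
  expect_error(read_ppi_edges(tempfile()), "cannot read")
  p <- write_ppi_file(c("a b 900.5"))
  expect_error(read_ppi_edges(p), "integer")
  p2 <- write_ppi_file(c("a b 500"))
  expect_error(read_ppi_edges(p2, score_min = 700), "threshold")
})

test_that("raising the score threshold never increases the edge count", {
  set.seed(7)
  lines <- sprintf("n%d n%d %d", sample(20, 60, TRUE), sample(20, 60, TRUE),
                   sample(0:1000, 60))
  lines <- lines[!grepl("^(n\\d+) \\1 ", lines)]
  p <- write_ppi_file(lines)
  counts <- vapply(c(0, 150, 400, 700, 900), function(s)
    igraph::ecount(suppressMessages(read_ppi_edges(p, score_min = s))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("network round-trips through write_network", {
  net <- toy_net(list(c("a", "b"), c("b", "c"), c("a", "c")),
                 score = c(999L, 701L, 800L))
  path <- withr::local_tempfile()
  write_network(net, path)
  back <- read_ppi_edges(path, score_min = 0)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  df <- igraph::as_data_frame(back)
  key <- paste(pmin(df$from, df$to), pmax(df$from, df$to))
  orig <- igraph::as_data_frame(net)
  okey <- paste(pmin(orig$from, orig$to), pmax(orig$from, orig$to))
  expect_equal(df$score[order(key)], orig$score[order(okey)])
})

test_that("expression reader preserves identifiers and validates", {
  d <- withr::local_tempdir()
  ep <- file.path(d, "expr.tsv"); mp <- file.path(d, "meta.tsv")
  writeLines(c("gene\tS1\tS2\tS3", "g1\t1.5\t2\t3", "g2\t4\t5\t6"), ep)
  writeLines(c("sample\tcondition\tday", "S1\tcase\t1", "S2\tcontrol\t1",
               "S3\tcase\t2"), mp)
  es <- read_expression(ep, mp)
  expect_equal(dim(es$values), c(2L, 3L))
  expect_equal(rownames(es$values), c("g1", "g2"))
  expect_equal(es$samples$sample, c("S1", "S2", "S3"))
  expect_equal(es$values["g2", "S2"], 5)

  writeLines(c("gene\tS1\tS2\tS3", "g1\t1\t2\t3", "g1\t4\t5\t6"), ep)
  expect_error(read_expression(ep, mp), "g1")

  writeLines(c("gene\tS1\tS9", "g1\t1\t2"), ep)
  expect_error(read_expression(ep, mp), "S9")
})

test_that("expr_set rejects non-finite values and missing conditions", {
  m <- matrix(c(1, NA, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(sample = c("s1", "s2"), condition = "case")
  expect_error(expr_set(m, meta), "finite")
  m[is.na(m)] <- 0
  expect_error(expr_set(m, data.frame(sample = "s1", condition = "case")), "s2")
})

test_that("annotation reader handles plain TSV and GAF, skipping NOT rows", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "ann.tsv")
  writeLines(c("gene\tterm\tname", "g1\tT1\talpha", "g2\tT1\talpha",
               "g1\tT1\talpha", "g1\tT2\tbeta"), tsv)
  ann <- read_annotations(tsv)
  expect_equal(nrow(ann), 3)  # duplicate collapsed
  expect_setequal(ann$term, c("T1", "T2"))

  gaf <- file.path(d, "ann.gaf")
  row <- function(gene, go, qual = "") paste(
    c("DB", gene, gene, qual, go, "REF", "IEA", "", "P", "", "", "protein",
      "taxon:9606", "20200101", "DB"), collapse = "\t")
  writeLines(c("!gaf-version: 2.1", row("g1", "GO:1"), row("g2", "GO:2"),
               row("g3", "GO:1", "NOT")), gaf)
  ag <- read_annotations(gaf)
  expect_equal(nrow(ag), 2)
  expect_false("g3" %in% ag$gene)
})

test_that("intersect_inputs restricts both sides to the shared genes", {
  net <- toy_net(list(c("a", "b"), c("b", "c")))
  m <- matrix(rnorm(12), 3, dimnames = list(c("b", "c", "d"), NULL))
  colnames(m) <- sprintf("s%d", 1:4)
  expr <- toy_expr(m)
  res <- suppressMessages(intersect_inputs(net, expr))
  expect_setequal(igraph::V(res$network)$name, c("b", "c"))
  expect_equal(rownames(res$expr$values), c("b", "c"))

  # identical gene sets pass through unchanged
  net2 <- toy_net(list(c("b", "c"), c("c", "d")), vertices = c("b", "c", "d"))
  res2 <- intersect_inputs(net2, expr)
  expect_identical(res2$expr$values, expr$values)

  m2 <- m; rownames(m2) <- c("x", "y", "z")
  expect_error(intersect_inputs(net, toy_expr(m2)), "no genes")
})
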