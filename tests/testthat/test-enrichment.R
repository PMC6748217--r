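mk_ann <- function(sets) {
  data.frame(gene = unlist(sets),
             term = rep(names(sets), lengths(sets)),
             name = NA_character_, stringsAsFactors = FALSE)
}

test_that("hypergeometric ORA matches hand-enumerated draws", {
  universe <- c("a", "b", "c", "d")
  ann <- mk_ann(list(T1 = c("a", "b"), T2 = universe))
  res <- ora(c("a", "b"), ann, universe, alpha = 1)
  # drawing {a, b} out of C(4,2) = 6 equally likely pairs: p = 1/6
  expect_equal(res$p[res$term == "T1"], 1 / 6)
  # a term equal to the universe is always fully drawn: p = 1
  expect_equal(res$p[res$term == "T2"], 1)
  # zero overlap: upper-tail probability of >= 0 successes is 1
  ann0 <- mk_ann(list(T3 = c("c", "d")))
  res0 <- ora(c("a", "b"), ann0, universe, alpha = 1)
  expect_equal(res0$p, 1)
  expect_error(ora(c("a"), ann, character(0)), "universe")
  expect_error(ora(c("zz"), ann, universe), "outside the universe")
})

test_that("ORA equals an exhaustive enumeration oracle on small universes", {
  enum_p <- function(universe, term, cluster) {
    k <- length(cluster)
    x <- length(intersect(term, cluster))
    draws <- utils::combn(universe, k, simplify = FALSE)
    mean(vapply(draws, function(d)
      length(intersect(d, term)) >= x, logical(1)))
  }
  set.seed(8)
  for (i in 1:25) {
    N <- sample(3:8, 1)
    universe <- sprintf("u%02d", seq_len(N))
    term <- sample(universe, sample(1:N, 1))
    cluster <- sample(universe, sample(1:N, 1))
    res <- ora(cluster, mk_ann(list(TT = term)), universe, alpha = 1)
    expect_equal(res$p, enum_p(universe, term, cluster), tolerance = 1e-12)
  }
})

test_that("occupation rates are normalized to the cluster maximum", {
  universe <- sprintf("u%02d", 1:20)
  ann <- mk_ann(list(T1 = universe[1:4], T2 = universe[1:10]))
  res <- ora(universe[1:4], ann, universe, alpha = 1)
  expect_equal(res$occupation[res$term == "T1"], 1)
  expect_equal(res$occupation[res$term == "T2"], 0.4)
  expect_equal(max(res$occupation_norm), 1)
  expect_equal(res$occupation_norm[res$term == "T2"], 0.4)
})

test_that("Jaccard matrix matches set arithmetic", {
  sets <- list(A = c("a", "b"), B = c("a", "b"), C = c("b", "c"),
               D = c("x", "y"))
  J <- jaccard_matrix(sets)
  expect_equal(unname(diag(J)), rep(1, 4))
  expect_equal(J["A", "B"], 1)
  expect_equal(J["A", "C"], 1 / 3)
  expect_equal(J["A", "D"], 0)
  expect_equal(J, t(J))
  expect_error(jaccard_matrix(sets[1]), ">= 2")
  expect_error(jaccard_matrix(list(A = "a", B = character(0))), "empty")
})

test_that("term dendrogram merges by similarity and cuts at the Jaccard cutoff", {
  sets <- list(A = c("a", "b"), B = c("a", "b"), C = c("x", "y"))
  tree <- term_dendrogram(jaccard_matrix(sets), cutoff = 0.25)
  h <- tree$hclust
  # the identical pair merges first at height 0
  expect_equal(min(h$height), 0)
  first <- sort(h$labels[-h$merge[1, ]])
  expect_equal(first, c("A", "B"))
  # disjoint C stays a separate group at the 0.25 cutoff (height 1 merge)
  expect_equal(max(h$height), 1)
  expect_equal(length(unique(tree$groups)), 2)
  expect_equal(tree$groups[["A"]], tree$groups[["B"]])
  expect_false(tree$groups[["A"]] == tree$groups[["C"]])
  # two disjoint terms: separate groups
  t2 <- term_dendrogram(jaccard_matrix(sets[c("A", "C")]), cutoff = 0.25)
  expect_equal(length(unique(t2$groups)), 2)
  # single term degenerates to a one-leaf tree
  t1 <- term_dendrogram(matrix(1, 1, 1, dimnames = list("A", "A")))
  expect_null(t1$hclust)
  expect_equal(unname(t1$groups), 1L)
})

test_that("term trees export as Newick plus attribute table", {
  sets <- list(A = c("a", "b"), B = c("a", "c"), C = c("x", "y"))
  tree <- term_dendrogram(jaccard_matrix(sets), cutoff = 0.25,
                          attributes = data.frame(term = c("A", "B", "C"),
                                                  term_size = c(2, 2, 2)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_term_tree(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  attrs <- read.delim(paste0(path, ".attrs.tsv"))
  expect_setequal(attrs$term, c("A", "B", "C"))
  expect_true(all(c("group", "term_size") %in% names(attrs)))
})

test_that("module-aligned annotations make the planted term the top hit", {
  res <- demo_analysis(seed = 1)
  enr <- suppressMessages(
    cluster_enrichment(res$clusters, res$ann, res$ordering))
  eff <- res$truth$de_effect
  for (k in seq_len(nrow(res$clusters))) {
    genes <- res$clusters$genes[[k]]
    planted <- names(which.max(table(res$truth$modules[genes])))
    top <- enr[[res$clusters$label[k]]]$terms
    expect_equal(top$term[1], paste0("MOD", planted))
    expect_equal(top$occupation_norm[1], 1.0)
  }
})
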