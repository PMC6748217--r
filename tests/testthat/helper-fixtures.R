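# Small builders shared across test files. Everything is generated in code;
# no fixture files.

# undirected scored network from a two-column edge matrix/list
toy_net <- function(edges, score = 800L, vertices = NULL) {
  el <- if (is.matrix(edges)) edges else matrix(unlist(edges), ncol = 2, byrow = TRUE)
  df <- data.frame(from = el[, 1], to = el[, 2], score = as.integer(score),
                   stringsAsFactors = FALSE)
  verts <- if (is.null(vertices)) unique(c(el)) else vertices
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = verts))
}

path_net <- function(n, prefix = "v") {
  v <- sprintf("%s%02d", prefix, seq_len(n))
  toy_net(cbind(v[-n], v[-1]))
}

complete_net <- function(n, prefix = "v") {
  v <- sprintf("%s%02d", prefix, seq_len(n))
  toy_net(t(utils::combn(v, 2)))
}

# expression set with the given matrix; conditions split half/half by default
toy_expr <- function(values, conditions = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(conditions))
    conditions <- rep(c("case", "control"), length.out = ncol(values))
  expr_set(values, data.frame(sample = colnames(values),
                              condition = conditions, day = 0L))
}

# identity ordering over an expression set's genes
identity_order <- function(expr) {
  gene_ordering(rownames(expr$values), seq_len(nrow(expr$values)))
}

# hand-made de_clusters table for netstats tests
mk_clusters <- function(label, start, end, direction, genes, checksum = NULL) {
  out <- data.frame(label = as.character(label), start = start, end = end,
                    direction = direction, stringsAsFactors = FALSE)
  out$min_padj <- rep(1e-6, nrow(out))
  out$genes <- genes
  out$n_genes <- lengths(genes)
  class(out) <- c("de_clusters", "data.frame")
  if (!is.null(checksum)) attr(out, "ordering_checksum") <- checksum
  out
}

# R-side brute-force minimum linear arrangement, independent of the C++ path
perms_r <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_r(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

brute_min_cost_r <- function(net) {
  genes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = TRUE)
  n <- length(genes)
  pm <- perms_r(n)
  min(apply(pm, 1, function(pos) {
    names(pos) <- genes
    sum(abs(pos[el[, 1]] - pos[el[, 2]]))
  }))
}

# one full demo analysis (shared by recovery and enrichment tests), memoised
.demo_cache <- new.env(parent = emptyenv())
demo_analysis <- function(seed, noise_frac = 0, radius = 5) {
  key <- paste(seed, noise_frac, radius)
  if (!is.null(.demo_cache[[key]])) return(.demo_cache[[key]])
  demo <- gen_demo(seed = seed, noise_frac = noise_frac)
  io <- suppressMessages(intersect_inputs(demo$network, demo$expr))
  ord <- order_genes(io$network, seed = seed)
  prof <- window_average(io$expr, ord, radius = radius)
  tests <- moderated_t(prof)
  clusters <- call_clusters(tests, alpha = 0.001)
  res <- list(truth = demo$truth, ann = demo$ann, network = io$network,
              expr = io$expr, ordering = ord, tests = tests,
              clusters = clusters)
  .demo_cache[[key]] <- res
  res
}

# planted-gene recovery and false-inclusion of one demo analysis
recovery_stats <- function(res) {
  eff <- res$truth$de_effect
  de_genes <- names(eff)[eff != 0]
  rec <- 0L; false_in <- 0L
  cl <- res$clusters
  for (k in seq_len(nrow(cl))) {
    e <- eff[cl$genes[[k]]]
    s <- if (cl$direction[k] == "up") 1 else -1
    rec <- rec + sum(sign(e) == s)
    false_in <- false_in + sum(e == 0)
  }
  c(recovery = rec / length(de_genes),
    false_inclusion = false_in / sum(eff == 0))
}
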