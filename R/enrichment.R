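#' Hypergeometric over-representation of terms in a cluster
#'
#' Tests every term with at least one universe gene for over-representation
#' of its genes in the cluster: upper-tail hypergeometric p for the observed
#' overlap, BH adjustment across the tested terms, and the occupation rate
#' (overlap over term size) normalized by the cluster's maximum rate. The
#' universe should be the annotated genes of the ordering, not the whole
#' genome.
#'
#' @param cluster_genes Gene set of one cluster (subset of `universe`).
#' @param ann Annotation table (gene, term, name), see [read_annotations()].
#' @param universe Background gene set.
#' @param alpha Keep terms with adjusted p <= alpha (default 0.05).
#' @return Data frame of enriched terms: term, name, term_size, overlap, p,
#'   padj, occupation, occupation_norm; sorted by p then term id. The full
#'   (unfiltered) table is attached as attribute `all_terms`.
#' @export
ora <- function(cluster_genes, ann, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  cluster_genes <- unique(as.character(cluster_genes))
  extra <- setdiff(cluster_genes, universe)
  if (length(extra)) stop("cluster gene(s) outside the universe: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  ann <- ann[ann$gene %in% universe, , drop = FALSE]
  if (!nrow(ann)) stop("no annotations overlap the universe")
  sets <- split(ann$gene, ann$term)
  sets <- lapply(sets, unique)
  N <- length(universe)
  k <- length(cluster_genes)
  m <- lengths(sets)
  x <- vapply(sets, function(s) length(intersect(s, cluster_genes)), integer(1))
  p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
  names_map <- ann$name[match(names(sets), ann$term)]
  res <- data.frame(term = names(sets), name = names_map,
                    term_size = unname(m), overlap = unname(x),
                    p = unname(p), padj = adjust_bh(unname(p)),
                    occupation = unname(x / m), stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  keep <- res[res$padj <= alpha, , drop = FALSE]
  keep$occupation_norm <- if (nrow(keep)) keep$occupation / max(keep$occupation)
                          else numeric(0)
  rownames(keep) <- NULL
  attr(keep, "all_terms") <- res
  attr(keep, "universe_size") <- N
  keep
}

#' Term gene sets restricted to a universe
#'
#' @param terms Character vector of term identifiers.
#' @param ann Annotation table.
#' @param universe Background gene set.
#' @return Named list of gene sets.
#' @export
term_gene_sets <- function(terms, ann, universe) {
  ann <- ann[ann$gene %in% universe & ann$term %in% terms, , drop = FALSE]
  sets <- lapply(split(ann$gene, factor(ann$term, levels = terms)), unique)
  empty <- lengths(sets) == 0
  if (any(empty)) stop("term(s) with empty gene set: ",
                       paste(names(sets)[empty], collapse = ", "))
  sets
}

#' All-against-all Jaccard similarity of term gene sets
#'
#' @param sets Named list of gene sets (see [term_gene_sets()]).
#' @return Symmetric matrix of Jaccard indices with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 terms")
  if (any(lengths(sets) == 0)) stop("term with empty gene set")
  n <- length(sets)
  J <- diag(1, n)
  dimnames(J) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- inter / length(union(sets[[i]], sets[[j]]))
  }
  J
}

#' Dendrogram over enriched terms from their Jaccard matrix
#'
#' Average-linkage agglomeration on the distance 1 - J; term groups are read
#' by cutting the tree at height 1 - cutoff (the conventional cutoff is a
#' Jaccard of 0.25). Node attributes (term size, occupation rate) travel with
#' the tree for export.
#'
#' @param J Symmetric Jaccard matrix with unit diagonal.
#' @param cutoff Jaccard cutoff in (0, 1) defining the groups (default 0.25).
#' @param attributes Optional data frame with a `term` column plus per-term
#'   attributes (e.g. the [ora()] output).
#' @return A `term_tree` list: `hclust` (NULL for a single term), `labels`,
#'   `groups` (named integer vector), `cutoff`, `attributes`.
#' @export
term_dendrogram <- function(J, cutoff = 0.25, attributes = NULL) {
  stopifnot(cutoff > 0, cutoff < 1)
  labels <- rownames(J)
  if (is.null(dim(J)) || nrow(J) < 2) {
    tree <- list(hclust = NULL, labels = labels,
                 groups = stats::setNames(1L, labels), cutoff = cutoff,
                 attributes = attributes)
    class(tree) <- "term_tree"
    return(tree)
  }
  if (!isTRUE(all.equal(J, t(J))) || any(abs(diag(J) - 1) > 1e-12))
    stop("J must be symmetric with unit diagonal")
  h <- stats::hclust(stats::as.dist(1 - J), method = "average")
  groups <- stats::cutree(h, h = 1 - cutoff)
  tree <- list(hclust = h, labels = labels, groups = groups, cutoff = cutoff,
               attributes = attributes)
  class(tree) <- "term_tree"
  tree
}

#' @export
print.term_tree <- function(x, ...) {
  cat("term_tree:", length(x$labels), "term(s),",
      length(unique(x$groups)), "group(s) at Jaccard cutoff", x$cutoff, "\n")
  invisible(x)
}

#' Write a term tree as Newick plus a node-attribute TSV
#'
#' @param tree A `term_tree`.
#' @param path Newick output path; attributes go to `<path>.attrs.tsv`
#'   (term, group, plus any columns of `tree$attributes`).
#' @export
write_term_tree <- function(tree, path) {
  if (!is.null(tree$hclust)) {
    phy <- ape::as.phylo(tree$hclust)
    ape::write.tree(phy, file = path)
  } else {
    writeLines(paste0("(", tree$labels, ");"), path)
  }
  df <- data.frame(term = tree$labels,
                   group = unname(tree$groups[tree$labels]),
                   stringsAsFactors = FALSE)
  if (!is.null(tree$attributes))
    df <- merge(df, tree$attributes, by = "term", all.x = TRUE, sort = FALSE)
  write_tsv_(df[order(df$group, df$term), , drop = FALSE],
             paste0(path, ".attrs.tsv"))
  invisible(path)
}

#' Per-cluster enrichment with term dendrograms
#'
#' Convenience wrapper running [ora()] for every cluster against the
#' annotated genes of the ordering, then building each cluster's Jaccard
#' dendrogram from its enriched terms.
#'
#' @param clusters A `de_clusters` data frame.
#' @param ann Annotation table.
#' @param order A [gene_ordering] (defines the universe: its annotated genes).
#' @param alpha Enrichment significance threshold on adjusted p.
#' @param cutoff Jaccard cutoff for the dendrogram groups.
#' @return Named list (by cluster label) of lists with elements `terms` (the
#'   [ora()] table) and `tree` (a `term_tree` or NULL when < 1 term).
#' @export
cluster_enrichment <- function(clusters, ann, order, alpha = 0.05,
                               cutoff = 0.25) {
  universe <- intersect(order$gene, unique(ann$gene))
  message("enrichment universe: ", length(universe),
          " annotated genes of the ordering")
  res <- lapply(seq_len(nrow(clusters)), function(k) {
    genes <- intersect(clusters$genes[[k]], universe)
    terms <- ora(genes, ann, universe, alpha = alpha)
    tree <- if (nrow(terms) >= 1) {
      if (nrow(terms) >= 2) {
        sets <- term_gene_sets(terms$term, ann, universe)
        term_dendrogram(jaccard_matrix(sets), cutoff = cutoff,
                        attributes = terms)
      } else {
        term_dendrogram(matrix(1, 1, 1, dimnames = list(terms$term, terms$term)),
                        cutoff = cutoff, attributes = terms)
      }
    } else NULL
    list(terms = terms, tree = tree)
  })
  stats::setNames(res, clusters$label)
}
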