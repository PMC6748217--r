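#' Induced PPI subnetwork of a cluster
#'
#' @param genes Character vector of cluster genes (or a one-row slice of a
#'   `de_clusters` table's `genes` column).
#' @param net Interaction network.
#' @return The induced igraph subgraph on the cluster genes present in the
#'   network.
#' @export
cluster_subnetwork <- function(genes, net) {
  igraph::induced_subgraph(net, intersect(genes, igraph::V(net)$name))
}

#' Inner/outer connectivity of a cluster
#'
#' Connections are counted as edges, once each: `inner` edges have both
#' endpoints in the cluster, `outer` edges exactly one. The average
#' connectivity is (inner + outer) / n_nodes — the ratio between the number
#' of all cluster protein connections and the number of cluster proteins. An
#' isolated triangle therefore has avg_k = 1, not 2.
#'
#' @param genes Cluster gene set (must be a subset of the network's nodes).
#' @param net Interaction network.
#' @return List with `n_nodes`, `inner_edges`, `outer_edges`, `avg_k`.
#' @export
cluster_connectivity <- function(genes, net) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty cluster")
  missing <- setdiff(genes, igraph::V(net)$name)
  if (length(missing)) stop("cluster gene(s) not in network: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  el <- igraph::as_edgelist(net, names = TRUE)
  in1 <- el[, 1] %in% genes
  in2 <- el[, 2] %in% genes
  inner <- sum(in1 & in2)
  outer <- sum(xor(in1, in2))
  list(n_nodes = length(genes), inner_edges = inner, outer_edges = outer,
       avg_k = (inner + outer) / length(genes))
}

#' Connectivity table over all clusters
#'
#' @param clusters A `de_clusters` data frame.
#' @param net Interaction network.
#' @return Data frame: label, n_nodes, inner_edges, outer_edges, avg_k.
#' @export
connectivity_table <- function(clusters, net) {
  rows <- lapply(seq_len(nrow(clusters)), function(k) {
    genes <- intersect(clusters$genes[[k]], igraph::V(net)$name)
    cc <- cluster_connectivity(genes, net)
    data.frame(label = clusters$label[k], n_nodes = cc$n_nodes,
               inner_edges = cc$inner_edges, outer_edges = cc$outer_edges,
               avg_k = cc$avg_k, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fraction of the interactome covered by clusters
#'
#' @param clusters A `de_clusters` data frame (or list of gene vectors).
#' @param net Interaction network.
#' @return The fraction in [0, 1] of network nodes belonging to at least one
#'   cluster.
#' @export
interactome_coverage <- function(clusters, net) {
  genes <- if (is.data.frame(clusters)) unlist(clusters$genes) else unlist(clusters)
  length(intersect(unique(genes), igraph::V(net)$name)) / igraph::vcount(net)
}

#' Match clusters between two analyses of the same ordering
#'
#' Each cluster of analysis B inherits the label of the analysis-A cluster
#' with the largest positional overlap (ties toward the leftmost A cluster).
#' B clusters with zero overlap, or whose best label was already claimed by an
#' earlier B cluster, receive fresh capital letters A, B, ... in left-to-right
#' order.
#'
#' @param a,b `de_clusters` data frames from two analyses. When both carry an
#'   ordering checksum they must agree.
#' @return Data frame with one row per B cluster: label_b (original), start,
#'   end, matched_a (A label of maximal overlap or NA), overlap (positions),
#'   new_label.
#' @export
match_clusters <- function(a, b) {
  ca <- attr(a, "ordering_checksum"); cb <- attr(b, "ordering_checksum")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop("cluster sets come from different orderings")
  a <- a[order(a$start), , drop = FALSE]
  b <- b[order(b$start), , drop = FALSE]
  taken <- character(0)
  letters_used <- 0L
  out <- lapply(seq_len(nrow(b)), function(k) {
    ov <- pmax(0, pmin(b$end[k], a$end) - pmax(b$start[k], a$start) + 1)
    if (length(ov) && max(ov) >= 1) {
      best <- which(ov == max(ov))[1]  # ties toward leftmost A
      data.frame(label_b = b$label[k], start = b$start[k], end = b$end[k],
                 matched_a = a$label[best], overlap = max(ov),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label_b = b$label[k], start = b$start[k], end = b$end[k],
                 matched_a = NA_character_, overlap = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$new_label <- NA_character_
  for (k in seq_len(nrow(out))) {
    lbl <- out$matched_a[k]
    if (!is.na(lbl) && !(lbl %in% taken)) {
      out$new_label[k] <- lbl
      taken <- c(taken, lbl)
    } else {
      letters_used <- letters_used + 1L
      out$new_label[k] <- LETTERS[letters_used]
    }
  }
  out
}

#' Node-count and connectivity evolution between two analyses
#'
#' Tabulates, per matched cluster, the number of nodes and average
#' connectivity in each analysis — the quantities whose change across time
#' intervals the transcriptogram figures track.
#'
#' @param a,b `de_clusters` data frames.
#' @param net Interaction network (shared by both analyses).
#' @return Data frame: new_label, label_a, label_b, n_nodes_a, n_nodes_b,
#'   avg_k_a, avg_k_b.
#' @export
cluster_evolution <- function(a, b, net) {
  m <- match_clusters(a, b)
  conn_a <- connectivity_table(a, net)
  conn_b <- connectivity_table(b, net)
  res <- lapply(seq_len(nrow(m)), function(k) {
    ia <- match(m$matched_a[k], conn_a$label)
    ib <- match(m$label_b[k], conn_b$label)
    data.frame(new_label = m$new_label[k],
               label_a = m$matched_a[k], label_b = m$label_b[k],
               n_nodes_a = if (is.na(ia)) NA_integer_ else conn_a$n_nodes[ia],
               n_nodes_b = conn_b$n_nodes[ib],
               avg_k_a = if (is.na(ia)) NA_real_ else conn_a$avg_k[ia],
               avg_k_b = conn_b$avg_k[ib], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
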