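#' @useDynLib transcriptogram, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# edge endpoints as 0-based indices into a fixed gene vector
edge_index_ <- function(net, genes) {
  el <- igraph::as_edgelist(net, names = TRUE)
  list(i = match(el[, 1], genes) - 1L, j = match(el[, 2], genes) - 1L)
}

#' Gene ordering constructor
#'
#' A `gene_ordering` is a data frame (gene, position) describing a bijection
#' from the network's genes onto line positions 1..N, with the arrangement
#' cost and provenance stored in attributes.
#'
#' @param gene Character vector of gene identifiers.
#' @param position Integer permutation of 1..N.
#' @param cost Arrangement cost of the permutation (recomputed if `NULL`
#'   and `net` is given).
#' @param net Optional network used to compute/verify the cost.
#' @param seed,n_steps Provenance of the optimizer run, if any.
#' @return A `gene_ordering` data frame sorted by position.
#' @export
gene_ordering <- function(gene, position, cost = NULL, net = NULL,
                          seed = NA_integer_, n_steps = NA_integer_) {
  stopifnot(length(gene) == length(position))
  position <- as.integer(position)
  if (!identical(sort(position), seq_along(position)))
    stop("positions must be a permutation of 1..N")
  ord <- data.frame(gene = as.character(gene), position = position,
                    stringsAsFactors = FALSE)
  ord <- ord[order(ord$position), , drop = FALSE]
  rownames(ord) <- NULL
  class(ord) <- c("gene_ordering", "data.frame")
  if (!is.null(net)) cost <- ordering_cost(ord, net)
  attr(ord, "cost") <- cost
  attr(ord, "cost_kind") <- "linear_arrangement"
  attr(ord, "seed") <- seed
  attr(ord, "n_steps") <- n_steps
  ord
}

#' @export
print.gene_ordering <- function(x, ...) {
  cat("gene_ordering of", nrow(x), "genes; cost =",
      format(attr(x, "cost")), "\n")
  invisible(x)
}

#' Arrangement cost of an ordering on a network
#'
#' The default (and only built-in) cost is the weighted linear arrangement
#' with unit weights: the sum over network edges (u, v) of
#' |position(u) - position(v)|. Orderings that place interacting genes at
#' nearby positions have low cost.
#'
#' @param order A [gene_ordering] covering all network genes.
#' @param net Interaction network (igraph).
#' @return Non-negative arrangement cost.
#' @export
ordering_cost <- function(order, net) {
  pos <- stats::setNames(order$position, order$gene)
  genes <- igraph::V(net)$name
  missing <- setdiff(genes, names(pos))
  if (length(missing)) stop("network gene(s) missing from ordering: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) return(0)
  sum(abs(pos[el[, 1]] - pos[el[, 2]]))
}

#' Exact minimum arrangement cost by enumeration
#'
#' Brute-force minimum of the linear arrangement cost over all permutations.
#' Feasible only for small networks (N <= 10).
#'
#' @param net Interaction network.
#' @return The minimum arrangement cost.
#' @export
min_arrangement_cost <- function(net) {
  genes <- sort(igraph::V(net)$name)
  n <- length(genes)
  if (n > 10) stop("exact enumeration limited to 10 nodes")
  if (n == 0) return(0)
  e <- edge_index_(net, genes)
  .exact_mla_cpp(e$i, e$j, n)
}

# connected components ordered largest-first (ties: smallest member id),
# members sorted by identifier
components_ <- function(net) {
  comp <- igraph::components(net)
  groups <- split(igraph::V(net)$name, comp$membership)
  groups <- lapply(groups, sort)
  sizes <- lengths(groups)
  first <- vapply(groups, `[[`, character(1), 1)
  groups[order(-sizes, first)]
}

#' Initial ordering of a network
#'
#' Builds a starting permutation for the annealer: either a seeded random
#' shuffle or the spectral ordering (nodes sorted by their Fiedler-vector
#' coordinate of the graph Laplacian), computed per connected component.
#' Components occupy contiguous position blocks, largest component first;
#' ties everywhere break by lexicographic gene identifier.
#'
#' @param net Interaction network.
#' @param mode `"spectral"` (default) or `"random"`.
#' @param seed Integer seed (used by `"random"`).
#' @return A [gene_ordering].
#' @export
initial_order <- function(net, mode = c("spectral", "random"), seed = 1L) {
  mode <- match.arg(mode)
  groups <- components_(net)
  placed <- character(0)
  for (genes in groups) {
    if (mode == "random") {
      rng <- local({ set.seed(seed + length(placed)); sample(length(genes)) })
      genes <- genes[rng]
    } else if (length(genes) > 2) {
      sub <- igraph::induced_subgraph(net, genes)
      genes_s <- sort(igraph::V(sub)$name)
      L <- igraph::laplacian_matrix(sub, sparse = FALSE)
      L <- L[genes_s, genes_s]
      ev <- eigen(L, symmetric = TRUE)
      fiedler <- ev$vectors[, ncol(L) - 1L]
      genes <- genes_s[order(fiedler, genes_s)]
    }
    placed <- c(placed, genes)
  }
  gene_ordering(placed, seq_along(placed), net = net, seed = seed)
}

#' Order network genes by simulated annealing
#'
#' Minimizes the linear arrangement cost with simulated annealing over
#' pairwise position swaps: geometric cooling, uphill moves accepted with
#' Boltzmann probability, best-visited permutation returned. Disconnected
#' networks are annealed component by component (largest first), each
#' component keeping a contiguous position block. The result is reproducible
#' for a given seed and its final cost never exceeds the initial cost.
#'
#' @param net Interaction network.
#' @param seed Integer seed for the optimizer.
#' @param n_steps Number of swap proposals per component; default
#'   `ceiling(200 * N * log(N))` for a component of N nodes.
#' @param t0 Initial temperature; by default calibrated so that roughly half
#'   of uphill moves are accepted on a 100-proposal probe.
#' @param cooling Geometric cooling factor applied every N proposals.
#' @param init Starting permutation mode, see [initial_order()].
#' @return A [gene_ordering] with attributes `cost`, `seed`, `n_steps` and
#'   `trace` (best-so-far cost at checkpoints, concatenated over components).
#' @export
order_genes <- function(net, seed = 1L, n_steps = NULL, t0 = NULL,
                        cooling = 0.995, init = "spectral") {
  if (igraph::vcount(net) == 0) stop("empty network")
  start <- initial_order(net, mode = init, seed = seed)
  pos0 <- stats::setNames(start$position, start$gene)
  groups <- components_(net)
  out_gene <- character(0)
  out_pos <- integer(0)
  trace <- numeric(0)
  steps_total <- 0L
  offset <- 0L
  for (genes in groups) {
    n <- length(genes)
    genes_block <- names(sort(pos0[genes]))  # initial order within block
    if (n > 1 && igraph::ecount(igraph::induced_subgraph(net, genes)) > 0) {
      sub <- igraph::induced_subgraph(net, genes_block)
      e <- edge_index_(sub, genes_block)
      steps <- if (is.null(n_steps)) as.integer(ceiling(200 * n * log(n))) else n_steps
      res <- .anneal_order_cpp(e$i, e$j, n, seq_len(n) - 1L, steps,
                               if (is.null(t0)) -1 else t0,
                               cooling, n, seed + offset)
      block_pos <- res$pos + 1L
      trace <- c(trace, res$trace)
      steps_total <- steps_total + steps
    } else {
      block_pos <- seq_len(n)
    }
    out_gene <- c(out_gene, genes_block)
    out_pos <- c(out_pos, block_pos + offset)
    offset <- offset + n
  }
  ord <- gene_ordering(out_gene, out_pos, net = net, seed = seed,
                       n_steps = steps_total)
  attr(ord, "trace") <- trace
  stopifnot(attr(ord, "cost") <= attr(start, "cost"))
  ord
}

#' Checksum of an ordering
#'
#' MD5 over the (gene, position) pairs in position order; used to verify that
#' two analyses share the same ordering before their clusters are matched.
#'
#' @param order A [gene_ordering].
#' @return Character MD5 digest.
#' @export
ordering_checksum <- function(order) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(order$gene, order$position, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read an ordering as TSV plus a JSON sidecar
#'
#' @param order A [gene_ordering].
#' @param path TSV output path (gene, position); the sidecar is written to
#'   `<path>.json` with seed, cost, cost kind and step count.
#' @export
write_ordering <- function(order, path) {
  write_tsv_(order[, c("gene", "position")], path)
  jsonlite::write_json(
    list(seed = attr(order, "seed"), cost = attr(order, "cost"),
         cost_kind = attr(order, "cost_kind"), n_steps = attr(order, "n_steps"),
         checksum = ordering_checksum(order)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ordering
#' @param net Optional network to recompute the cost against.
#' @export
read_ordering <- function(path, net = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  gene_ordering(df$gene, df$position, cost = meta$cost, net = net,
                seed = meta$seed %||% NA_integer_,
                n_steps = meta$n_steps %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
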