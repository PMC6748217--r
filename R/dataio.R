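#' Read a STRING-style PPI edge list
#'
#' Parses a whitespace-delimited edge list in the STRING `protein.links`
#' dialect (columns `protein1`, `protein2`, `combined_score`; header optional)
#' and returns the undirected interaction network of all edges whose combined
#' score passes the threshold. Duplicate and reversed records collapse to a
#' single undirected edge keeping the maximum score; self-loops are dropped
#' and counted.
#'
#' @param path Path to the edge-list file.
#' @param score_min Minimum combined score (inclusive), on the STRING 0-1000
#'   scale. Default 700, the conventional high-confidence cutoff.
#' @param id_map Optional two-column data frame (or path to a TSV) mapping
#'   source identifiers to the working gene namespace. Many-to-one mappings
#'   keep the first occurrence; later conflicting rows are dropped with a
#'   message.
#' @return An undirected \link[igraph]{igraph} graph with integer edge
#'   attribute `score` and graph attribute `n_self_loops`.
#' @export
read_ppi_edges <- function(path, score_min = 700, id_map = NULL) {
  if (!file.exists(path)) stop("cannot read PPI file: ", path)
  stopifnot(score_min >= 0, score_min <= 1000)
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(fields) >= 3 && is.na(suppressWarnings(as.numeric(fields[3])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("PPI file needs >= 3 columns (protein1, protein2, combined_score)")
  df <- df[, 1:3]
  names(df) <- c("protein1", "protein2", "combined_score")
  if (!is.numeric(df$combined_score) ||
      any(df$combined_score != round(df$combined_score))) {
    stop("combined_score column is not integer-valued")
  }
  if (any(df$combined_score < 0 | df$combined_score > 1000)) {
    stop("combined_score outside [0, 1000]")
  }
  ppi_network(df$protein1, df$protein2, df$combined_score,
              score_min = score_min, id_map = id_map)
}

#' Build an interaction network from edge vectors
#'
#' @param from,to Character vectors of edge endpoints.
#' @param score Integer combined scores in [0, 1000].
#' @inheritParams read_ppi_edges
#' @return An undirected igraph with edge attribute `score`.
#' @export
ppi_network <- function(from, to, score, score_min = 700, id_map = NULL) {
  from <- as.character(from); to <- as.character(to)
  if (!is.null(id_map)) {
    if (is.character(id_map) && length(id_map) == 1) {
      id_map <- utils::read.table(id_map, header = FALSE, sep = "\t",
                                  stringsAsFactors = FALSE)
    }
    map <- id_map[[2]]
    dup <- duplicated(id_map[[1]])
    if (any(dup)) {
      message(sum(dup), " duplicate identifier mapping(s) dropped (first kept)")
      map <- map[!dup]
      names(map) <- id_map[[1]][!dup]
    } else names(map) <- id_map[[1]]
    from <- ifelse(from %in% names(map), map[from], from)
    to <- ifelse(to %in% names(map), map[to], to)
  }
  self <- from == to
  n_self <- sum(self)
  if (n_self > 0) message(n_self, " self-loop record(s) dropped")
  from <- from[!self]; to <- to[!self]; score <- score[!self]
  # collapse both orientations and duplicates, keeping the max score
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -score)
  keep <- !duplicated(key[ord])
  a <- a[ord][keep]; b <- b[ord][keep]; score <- score[ord][keep]
  pass <- score >= score_min
  if (!any(pass)) stop("no edges with score >= ", score_min,
                       " (threshold too strict?)")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[pass], to = b[pass], score = as.integer(score[pass])),
    directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_self_loops", n_self)
  g
}

#' Expression set constructor
#'
#' Bundles a gene x sample log2-counts-per-million matrix with per-sample
#' metadata and validates their consistency.
#'
#' @param values Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames), on the log-CPM scale.
#' @param samples Data frame with columns `sample`, `condition` (values
#'   `case`/`control`) and optionally `day`.
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `samples` (rows aligned to the matrix columns).
#' @export
expr_set <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate gene identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier(s)")
  if (!all(is.finite(values))) stop("non-finite expression values")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(samples)))
    stop("sample metadata needs columns 'sample' and 'condition'")
  missing <- setdiff(colnames(values), samples$sample)
  if (length(missing)) stop("sample(s) missing from metadata: ",
                            paste(missing, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$samples$condition)),
                                   table(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix with its sample metadata
#'
#' The matrix is a TSV with a header row of sample identifiers and a first
#' column of gene identifiers, values in log-CPM. Metadata is a companion TSV
#' with columns `sample`, `condition` and optionally `day`.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @return An [expr_set].
#' @export
read_expression <- function(path, metadata_path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = NA)
  genes <- as.character(raw[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene identifier(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) stop("non-numeric expression column(s): ",
                     paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- genes
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expr_set(m, meta)
}

#' Read a gene-to-term annotation table
#'
#' Accepts a plain 2-3 column TSV (gene, term, optional term name) or GAF 2.x
#' (gene from column 2, term from column 5; rows with a `NOT` qualifier in
#' column 4 are skipped). Duplicate (gene, term) pairs are collapsed.
#'
#' @param path Path to the annotation file.
#' @return Data frame with columns `gene`, `term`, `name`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  if (!length(lines)) stop("empty annotation file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (all(ncols >= 15)) {  # GAF 2.x
    qual <- vapply(parts, `[[`, character(1), 4)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    parts <- parts[keep]
    ann <- data.frame(gene = vapply(parts, `[[`, character(1), 2),
                      term = vapply(parts, `[[`, character(1), 5),
                      name = NA_character_, stringsAsFactors = FALSE)
  } else {
    header <- tolower(parts[[1]][1]) %in% c("gene", "gene_id", "symbol")
    if (header) parts <- parts[-1]
    ann <- data.frame(gene = vapply(parts, `[[`, character(1), 1),
                      term = vapply(parts, `[[`, character(1), 2),
                      name = vapply(parts, function(p)
                        if (length(p) >= 3) p[[3]] else NA_character_,
                        character(1)),
                      stringsAsFactors = FALSE)
  }
  ann[!duplicated(ann[c("gene", "term")]), , drop = FALSE]
}

#' Restrict a network and an expression set to their common genes
#'
#' Downstream statistics refer to the restricted network as "the interactome".
#' Genes dropped from either side are reported with counts.
#'
#' @param net Interaction network (igraph).
#' @param expr An [expr_set].
#' @return List with elements `network` and `expr`, both restricted to the
#'   gene intersection.
#' @export
intersect_inputs <- function(net, expr) {
  net_genes <- igraph::V(net)$name
  expr_genes <- rownames(expr$values)
  common <- intersect(net_genes, expr_genes)
  if (!length(common)) stop("network and expression matrix share no genes")
  d_net <- length(net_genes) - length(common)
  d_expr <- length(expr_genes) - length(common)
  if (d_net > 0 || d_expr > 0)
    message("restricting to ", length(common), " shared genes (dropped ",
            d_net, " network-only, ", d_expr, " expression-only)")
  if (d_net > 0)
    net <- igraph::induced_subgraph(net, common)
  if (d_expr > 0)
    expr <- expr_set(expr$values[common, , drop = FALSE], expr$samples)
  list(network = net, expr = expr)
}

# deterministic TSV writer used by all pipeline outputs
write_tsv_ <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a network as a three-column edge-list TSV (gene, gene, score)
#' @param net igraph network with `score` edge attribute.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  if (!"score" %in% names(el)) el$score <- NA_integer_
  names(el)[1:2] <- c("protein1", "protein2")
  write_tsv_(el[order(el$protein1, el$protein2), c("protein1", "protein2", "score")],
             path)
}

#' Write an expression set as matrix + metadata TSVs
#' @param expr An [expr_set].
#' @param path Matrix output path.
#' @param metadata_path Metadata output path.
#' @export
write_expression <- function(expr, path, metadata_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(df, path)
  write_tsv_(expr$samples, metadata_path)
  invisible(path)
}
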