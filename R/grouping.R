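#' PCA of samples
#'
#' Principal components with samples as observations and centred (not scaled)
#' genes as variables; retains the smallest number of components whose
#' cumulative explained-variance fraction reaches the target (0.95 by
#' convention in the transcriptogram grouping step).
#'
#' @param expr An [expr_set] (or a genes x samples matrix).
#' @param variance_target Fraction in (0, 1] of variance to retain.
#' @return A `sample_pca` list: `scores` (all components), `retained` (the
#'   kept score columns), `cumvar`, `k_components`.
#' @export
pca_samples <- function(expr, variance_target = 0.95) {
  stopifnot(variance_target > 0, variance_target <= 1)
  values <- if (inherits(expr, "expr_set")) expr$values else as.matrix(expr)
  if (ncol(values) < 2) stop("need >= 2 samples")
  x <- t(values)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("constant expression matrix: no variance to analyse")
  cumvar <- cumsum(v) / sum(v)
  k <- which(cumvar >= variance_target - 1e-12)[1]
  out <- list(scores = pc$x, retained = pc$x[, seq_len(k), drop = FALSE],
              cumvar = cumvar, k_components = k)
  class(out) <- "sample_pca"
  out
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("sample_pca:", nrow(x$scores), "samples;", x$k_components,
      "components retained (cumvar =",
      format(x$cumvar[x$k_components], digits = 4), ")\n")
  invisible(x)
}

# within-group inertia (sum of squared distances to group centroids)
within_inertia_ <- function(scores, assignment) {
  sum(vapply(split(seq_len(nrow(scores)), assignment), function(idx) {
    block <- scores[idx, , drop = FALSE]
    sum(sweep(block, 2, colMeans(block))^2)
  }, numeric(1)))
}

#' Automatic sample grouping by Ward hierarchical clustering
#'
#' Ward-linkage hierarchical clustering on the retained PCA scores. The
#' number of groups k in [2, k_max] is chosen automatically as the cut
#' maximizing the relative loss of within-group inertia between consecutive
#' cuts, i.e. the k where adding the k-th group buys much more homogeneity
#' than adding the (k+1)-th; this is the criterion used by automatic
#' cluster-detection routines built on principal-component clustering. No
#' k-means consolidation is applied, so the result is deterministic.
#'
#' @param pca A `sample_pca` from [pca_samples()].
#' @param k_max Maximum number of groups considered (default 6).
#' @return The input with an `assignment` (named integer vector, groups
#'   numbered 1..k in order of first appearance) and `k_groups` added, plus
#'   `inertia_gain` (the criterion profile).
#' @export
cluster_samples <- function(pca, k_max = 6) {
  stopifnot(k_max >= 2)
  scores <- pca$retained
  if (nrow(scores) < 3) stop("need >= 3 samples to group")
  k_max <- min(k_max, nrow(scores) - 1)
  h <- stats::hclust(stats::dist(scores), method = "ward.D2")
  W <- vapply(1:(k_max + 1), function(k)
    within_inertia_(scores, stats::cutree(h, k = k)), numeric(1))
  if (W[1] <= .Machine$double.eps) {
    warning("all samples identical; returning a single group")
    assignment <- stats::setNames(rep(1L, nrow(scores)), rownames(scores))
    pca$assignment <- assignment
    pca$k_groups <- 1L
    return(pca)
  }
  delta <- W[-length(W)] - W[-1]          # delta[k] = W(k) - W(k+1), gain of cut k -> k+1
  crit <- delta[-length(delta)] / pmax(delta[-1], .Machine$double.eps)
  k <- which.max(crit) + 1L               # crit[i] compares gain at k=i+1 vs k=i+2
  raw <- stats::cutree(h, k = k)
  assignment <- as.integer(factor(raw, levels = unique(raw)))
  names(assignment) <- rownames(scores)
  pca$assignment <- assignment
  pca$k_groups <- k
  pca$inertia_gain <- crit
  pca
}

#' Pairwise marker-gene tests across sample groups
#'
#' For each marker gene, all pairwise group comparisons with pooled-variance
#' t-tests (the behaviour of [stats::pairwise.t.test()] with a common pooled
#' standard deviation across groups), BH-FDR correction applied within each
#' marker across its pairs, and significance flagged at the given threshold.
#'
#' @param expr An [expr_set].
#' @param assignment Named group assignment over samples (names = sample ids).
#' @param markers Character vector of marker genes; all must be present.
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @return Data frame: gene, group1, group2, t, p, padj, significant.
#' @export
marker_tests <- function(expr, assignment, markers, alpha = 0.01) {
  values <- expr$values
  absent <- setdiff(markers, rownames(values))
  if (length(absent)) stop("marker gene(s) absent from expression matrix: ",
                           paste(absent, collapse = ", "))
  samples <- intersect(colnames(values), names(assignment))
  g <- factor(assignment[samples])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  lv <- levels(g)
  ns <- table(g)
  df_pool <- sum(ns) - nlevels(g)
  out <- lapply(markers, function(gene) {
    y <- values[gene, samples]
    pt <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                                 pool.sd = TRUE)
    means <- tapply(y, g, mean)
    s_pool <- sqrt(sum(tapply(y, g, function(v)
      sum((v - mean(v))^2))) / df_pool)
    pairs <- utils::combn(lv, 2)
    p <- vapply(seq_len(ncol(pairs)), function(i) {
      pt$p.value[pairs[2, i], pairs[1, i]]
    }, numeric(1))
    tstat <- vapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      (means[b] - means[a]) /
        (s_pool * sqrt(1 / ns[a] + 1 / ns[b]))
    }, numeric(1))
    data.frame(gene = gene, group1 = pairs[1, ], group2 = pairs[2, ],
               t = unname(tstat), p = p, padj = adjust_bh(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out$significant <- out$padj <= alpha
  out
}

#' Default marker gene sets
#'
#' Neural progenitor (NPC) and neuronal marker genes conventionally used to
#' track differentiation of embryonic-stem-derived neural progenitors into
#' neurons.
#'
#' @return Named list with elements `npc` and `neuronal`.
#' @export
marker_genes <- function() {
  list(npc = c("MSI1", "NES", "NOTCH1", "SOX1"),
       neuronal = c("TH", "NEUROD6", "DCX", "RBFOX3", "GAD1", "GAD2"))
}
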