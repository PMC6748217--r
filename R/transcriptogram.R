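#' Sliding-window projection of expression along a gene ordering
#'
#' Computes, for every position i and sample, the arithmetic mean expression
#' of the genes at positions `max(1, i - radius) .. min(N, i + radius)` of the
#' ordering. Windows truncate at the ends of the list (the ordering is a line,
#' not a circle); with radius 0 the profile equals the reordered expression
#' matrix.
#'
#' @param expr An [expr_set]; its genes must match the ordering's genes.
#' @param order A [gene_ordering].
#' @param radius Non-negative integer window half-width (the field's r; 80 in
#'   the reference human analyses).
#' @return A `transcriptogram_profile`: a position x sample matrix with
#'   rownames giving the gene at each position and attributes `radius`,
#'   `genes`, `samples` (the metadata) and `ordering_checksum`.
#' @export
window_average <- function(expr, order, radius = 80) {
  stopifnot(radius >= 0, radius == round(radius))
  genes <- order$gene
  if (!setequal(genes, rownames(expr$values)))
    stop("ordering and expression matrix must share the same gene set")
  n <- length(genes)
  if (radius >= n)
    warning("radius >= number of positions; every window spans the whole list")
  m <- expr$values[genes, , drop = FALSE]
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)  # cs[i + 1, ] = sum of rows 1..i
  lo <- pmax(1L, seq_len(n) - radius)
  hi <- pmin(n, seq_len(n) + radius)
  prof <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  dimnames(prof) <- dimnames(m)
  structure(prof, radius = as.integer(radius), genes = genes,
            samples = expr$samples,
            ordering_checksum = ordering_checksum(order),
            class = c("transcriptogram_profile", "matrix", "array"))
}

profile_samples_ <- function(profile, samples = NULL) {
  if (is.null(samples)) samples <- attr(profile, "samples")
  if (is.null(samples)) stop("no sample metadata attached or supplied")
  samples
}

#' Case-minus-control relative profile
#'
#' Per position, the mean over case samples minus the mean over control
#' samples (a difference on the log scale), i.e. the treated expression
#' average relative to control that transcriptogram plots display.
#'
#' @param profile A `transcriptogram_profile` (or any position x sample matrix).
#' @param samples Sample metadata; taken from the profile if omitted.
#' @return Named numeric vector over positions.
#' @export
relative_profile <- function(profile, samples = NULL) {
  samples <- profile_samples_(profile, samples)
  case <- samples$sample[samples$condition == "case"]
  ctrl <- samples$sample[samples$condition == "control"]
  if (!length(case) || !length(ctrl))
    stop("both conditions must have at least one sample")
  rowMeans(profile[, case, drop = FALSE]) -
    rowMeans(profile[, ctrl, drop = FALSE])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' order-preserving with the input (a thin validated wrapper over
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Moderated t-tests per window position
#'
#' Fits the two-group case/control model at every position and shrinks the
#' residual variances with the empirical-Bayes machinery of limma: the
#' posterior variance is \eqn{(d0 s0^2 + d s^2) / (d0 + d)} with the prior
#' \eqn{(d0, s0^2)} estimated by moment matching on the scaled-F distribution
#' of the per-position variances, and the moderated t is referred to a
#' Student-t on \eqn{d0 + d} degrees of freedom.
#'
#' @param profile A `transcriptogram_profile`.
#' @param samples Sample metadata; taken from the profile if omitted.
#' @param d0,s02 Optional prior degrees of freedom and prior variance. When
#'   both are `NULL` (default) they are estimated via [limma::eBayes()];
#'   `d0 = 0` gives the ordinary pooled-variance t, `d0 = Inf` (with `s02`)
#'   uses the shared variance everywhere.
#' @return A `position_tests` data frame: position, gene, t, p, padj,
#'   direction (`up`/`down`/`zero` by the sign of mean case - mean control),
#'   with the fitted `d0`, `s02` and the profile's ordering checksum as
#'   attributes.
#' @export
moderated_t <- function(profile, samples = NULL, d0 = NULL, s02 = NULL) {
  samples <- profile_samples_(profile, samples)
  cond <- factor(samples$condition, levels = c("control", "case"))
  if (any(table(cond) < 2)) stop("need >= 2 samples per condition")
  y <- profile[, samples$sample, drop = FALSE]

  if (is.null(d0) && is.null(s02)) {
    design <- stats::model.matrix(~cond)
    fit <- limma::lmFit(unclass(y), design)
    if (all(fit$sigma == 0))
      stop("zero residual variance at every position (degenerate input)")
    eb <- limma::eBayes(fit)
    tstat <- eb$t[, 2]
    p <- eb$p.value[, 2]
    delta <- fit$coefficients[, 2]
    d0 <- eb$df.prior
    s02 <- eb$s2.prior
  } else {
    n1 <- sum(cond == "control"); n2 <- sum(cond == "case")
    m1 <- rowMeans(y[, cond == "control", drop = FALSE])
    m2 <- rowMeans(y[, cond == "case", drop = FALSE])
    v1 <- apply(y[, cond == "control", drop = FALSE], 1, stats::var)
    v2 <- apply(y[, cond == "case", drop = FALSE], 1, stats::var)
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    if (is.null(d0)) d0 <- 0
    if (is.infinite(d0)) {
      if (is.null(s02)) stop("d0 = Inf requires s02")
      s2post <- rep(s02, length(s2))
      df <- Inf
    } else {
      if (is.null(s02)) s02 <- 0
      s2post <- (d0 * s02 + d * s2) / (d0 + d)
      df <- d0 + d
    }
    delta <- m2 - m1
    tstat <- delta / sqrt(s2post * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }

  res <- data.frame(
    position = seq_len(nrow(profile)),
    gene = rownames(profile),
    t = unname(tstat),
    p = unname(p),
    padj = adjust_bh(unname(p)),
    direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "zero")),
    stringsAsFactors = FALSE)
  class(res) <- c("position_tests", "data.frame")
  attr(res, "d0") <- unname(d0)
  attr(res, "s02") <- unname(s02)
  attr(res, "ordering_checksum") <- attr(profile, "ordering_checksum")
  res
}

#' Call differentially expressed clusters
#'
#' A cluster is a maximal run of consecutive positions significant at the
#' adjusted-p threshold and sharing one direction. Runs of the same direction
#' separated by at most `gap` non-significant positions (with no opposing
#' significant position in between) are merged. Clusters are labelled 1, 2,
#' ... from left to right; each cluster's gene set is the genes whose ordering
#' position falls inside its interval.
#'
#' @param tests A `position_tests` data frame from [moderated_t()].
#' @param alpha Adjusted-p calling threshold (default 0.001).
#' @param gap Maximum tolerated run of non-significant positions inside a
#'   cluster (default 0).
#' @return A `de_clusters` data frame: label, start, end, direction, min_padj,
#'   n_genes, plus a list column `genes`. Empty (zero rows) when nothing is
#'   significant.
#' @export
call_clusters <- function(tests, alpha = 0.001, gap = 0) {
  stopifnot(alpha > 0, alpha < 1, gap >= 0)
  sig <- tests$padj <= alpha & tests$direction != "zero"
  runs <- list()
  i <- 1L
  n <- nrow(tests)
  while (i <= n) {
    if (sig[i]) {
      j <- i
      while (j < n && sig[j + 1L] && tests$direction[j + 1L] == tests$direction[i])
        j <- j + 1L
      runs[[length(runs) + 1L]] <-
        list(start = tests$position[i], end = tests$position[j],
             direction = tests$direction[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge same-direction runs across small gaps; an opposing significant run
  # in between blocks the merge because runs are processed in position order
  if (length(runs) > 1) {
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (r$direction == last$direction && r$start - last$end - 1L <= gap) {
        last$end <- r$end
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- r
    }
    runs <- merged
  }
  if (!length(runs)) {
    out <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      min_padj = numeric(0), n_genes = integer(0),
                      stringsAsFactors = FALSE)
    out$genes <- list()
  } else {
    out <- data.frame(
      label = as.character(seq_along(runs)),
      start = vapply(runs, `[[`, numeric(1), "start"),
      end = vapply(runs, `[[`, numeric(1), "end"),
      direction = vapply(runs, `[[`, character(1), "direction"),
      stringsAsFactors = FALSE)
    out$min_padj <- vapply(seq_along(runs), function(k)
      min(tests$padj[tests$position >= out$start[k] &
                     tests$position <= out$end[k]]), numeric(1))
    out$genes <- lapply(seq_along(runs), function(k)
      tests$gene[tests$position >= out$start[k] & tests$position <= out$end[k]])
    out$n_genes <- lengths(out$genes)
    out <- out[, c("label", "start", "end", "direction", "min_padj",
                   "n_genes", "genes")]
  }
  class(out) <- c("de_clusters", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "gap") <- gap
  attr(out, "ordering_checksum") <- attr(tests, "ordering_checksum")
  out
}

#' @export
print.de_clusters <- function(x, ...) {
  cat("de_clusters:", nrow(x), "cluster(s)\n")
  if (nrow(x)) print(as.data.frame(x[, setdiff(names(x), "genes")]))
  invisible(x)
}
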