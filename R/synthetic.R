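#' Planted-partition interaction network
#'
#' Generates a network of `n_modules` co-functional modules of
#' `module_size` genes each: every within-module gene pair is an edge with
#' probability `p_in`, every between-module pair with probability `p_out`.
#' Within-module edges get combined score 999 and between-module edges 701,
#' so both survive the conventional score >= 700 filter (score magnitudes are
#' unused downstream except for filtering). Gene identifiers are g001, g002,
#' ... assigned module by module.
#'
#' @param n_modules,module_size Module count and size.
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed Integer seed; the same seed reproduces the edge set exactly.
#' @return List with `network` (igraph including isolated genes) and `truth`
#'   (list: `modules` named gene -> module integer, parameters, seed).
#' @export
gen_network <- function(n_modules = 6, module_size = 50, p_in = 0.25,
                        p_out = 0.01, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, n_modules >= 1,
            module_size >= 2)
  n <- n_modules * module_size
  genes <- sprintf("g%03d", seq_len(n))
  modules <- stats::setNames(rep(seq_len(n_modules), each = module_size), genes)
  pairs <- utils::combn(n, 2)
  same <- modules[pairs[1, ]] == modules[pairs[2, ]]
  set.seed(seed)
  keep <- stats::runif(ncol(pairs)) < ifelse(same, p_in, p_out)
  el <- data.frame(from = genes[pairs[1, keep]], to = genes[pairs[2, keep]],
                   score = ifelse(same[keep], 999L, 701L),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = genes))
  truth <- list(modules = modules, n_modules = n_modules,
                module_size = module_size, p_in = p_in, p_out = p_out,
                seed = seed)
  list(network = g, truth = truth)
}

#' Case/control expression with planted module shifts
#'
#' Control samples draw each gene from Normal(baseline_g, sd), where the
#' per-gene baselines baseline_g ~ Normal(baseline, 2) are drawn once (a
#' typical between-gene spread on the log-CPM scale). Case samples add the
#' module's signed effect (log-CPM units) to every gene of a differentially
#' expressed module. Sample metadata (condition, day = 0) is attached.
#'
#' @param truth Truth list from [gen_network()].
#' @param n_case,n_control Sample counts (>= 2 each).
#' @param baseline Grand mean log-CPM of the baselines.
#' @param effects Named numeric vector: module number -> signed effect in
#'   log-CPM units (e.g. `c("2" = 1, "5" = -1)`); empty for a null data set.
#' @param sd Per-gene Gaussian noise standard deviation (log-CPM units).
#' @param seed Integer seed.
#' @return An [expr_set] with attributes `truth` (the input truth extended
#'   with `effects`, `sd` and the per-gene `de_effect` vector).
#' @export
gen_expression <- function(truth, n_case = 6, n_control = 6, baseline = 6,
                           effects = c("2" = 1, "5" = -1), sd = 0.5,
                           seed = 1L) {
  stopifnot(n_case >= 2, n_control >= 2)
  genes <- names(truth$modules)
  n <- length(genes)
  set.seed(seed)
  baseline_g <- stats::rnorm(n, baseline, 2)
  de_effect <- rep(0, n)
  for (m in names(effects))
    de_effect[truth$modules == as.integer(m)] <- effects[[m]]
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  cond <- rep(c("case", "control"), c(n_case, n_control))
  mu <- outer(baseline_g, rep(1, n_case + n_control)) +
    outer(de_effect, as.numeric(cond == "case"))
  values <- mu + matrix(stats::rnorm(n * (n_case + n_control), 0, sd), n)
  dimnames(values) <- list(genes, samples)
  expr <- expr_set(values, data.frame(sample = samples, condition = cond,
                                      day = 0L, stringsAsFactors = FALSE))
  truth$effects <- effects
  truth$sd <- sd
  truth$de_effect <- stats::setNames(de_effect, genes)
  attr(expr, "truth") <- truth
  expr
}

#' Module-aligned annotations with optional noise
#'
#' One term per module annotating exactly its genes (terms `MOD1`, `MOD2`,
#' ...), plus `extra_terms` random terms of random size. A fraction
#' `noise_frac` of all annotation rows is then reassigned to random genes;
#' at `noise_frac = 1` the table is independent of the modules, which should
#' destroy enrichment recovery.
#'
#' @param truth Truth list from [gen_network()].
#' @param extra_terms Number of additional random terms.
#' @param noise_frac Fraction in [0, 1] of annotations reassigned at random.
#' @param seed Integer seed.
#' @return Annotation data frame (gene, term, name).
#' @export
gen_annotation <- function(truth, extra_terms = 10, noise_frac = 0,
                           seed = 1L) {
  stopifnot(noise_frac >= 0, noise_frac <= 1)
  genes <- names(truth$modules)
  ann <- data.frame(gene = genes,
                    term = sprintf("MOD%d", truth$modules),
                    name = sprintf("module %d process", truth$modules),
                    stringsAsFactors = FALSE)
  set.seed(seed)
  if (extra_terms > 0) {
    extra <- do.call(rbind, lapply(seq_len(extra_terms), function(i) {
      size <- sample(10:truth$module_size, 1)
      data.frame(gene = sample(genes, size),
                 term = sprintf("RND%02d", i),
                 name = sprintf("random set %d", i),
                 stringsAsFactors = FALSE)
    }))
    ann <- rbind(ann, extra)
  }
  if (noise_frac > 0) {
    idx <- which(stats::runif(nrow(ann)) < noise_frac)
    ann$gene[idx] <- sample(genes, length(idx), replace = TRUE)
  }
  ann <- ann[!duplicated(ann[c("gene", "term")]), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Time-course expression with drifting sample blocks
#'
#' Emulates a multi-interval time course: `n_groups` blocks of samples whose
#' common mean drifts by `drift` log-CPM units per block (added to every
#' gene), with Normal(0, sd) noise. Ground-truth block labels are returned
#' for grouping-recovery tests.
#'
#' @param n_groups Number of blocks (>= 2).
#' @param n_per_group Samples per block.
#' @param n_genes Number of genes.
#' @param drift Mean shift per block, log-CPM units.
#' @param sd Noise standard deviation.
#' @param seed Integer seed.
#' @return List with `expr` (an [expr_set], day = block index) and `labels`
#'   (named integer vector of true blocks).
#' @export
gen_timecourse <- function(n_groups = 3, n_per_group = 8, n_genes = 200,
                           drift = 10, sd = 1, seed = 1L) {
  stopifnot(n_groups >= 2)
  set.seed(seed)
  baseline_g <- stats::rnorm(n_genes, 6, 2)
  samples <- sprintf("s%02d", seq_len(n_groups * n_per_group))
  block <- rep(seq_len(n_groups), each = n_per_group)
  mu <- outer(baseline_g, rep(1, length(samples))) +
    matrix(rep((block - 1) * drift, each = n_genes), n_genes)
  values <- mu + matrix(stats::rnorm(n_genes * length(samples), 0, sd), n_genes)
  dimnames(values) <- list(sprintf("g%03d", seq_len(n_genes)), samples)
  expr <- expr_set(values, data.frame(sample = samples, condition = "case",
                                      day = block, stringsAsFactors = FALSE))
  list(expr = expr, labels = stats::setNames(block, samples))
}

#' The demo planted-module scenario
#'
#' The package's reference synthetic study: 6 modules of 50 genes
#' (p_in = 0.25, p_out = 0.01), two differentially expressed modules with
#' effects +1 and -1 log-CPM (modules 2 and 5), noise sd 0.5, six case and
#' six control samples, module-aligned annotations with 10 extra random
#' terms.
#'
#' @param seed Integer seed driving every generator.
#' @param noise_frac Annotation noise fraction (default 0).
#' @return List: `network`, `truth`, `expr`, `ann`.
#' @export
gen_demo <- function(seed = 1L, noise_frac = 0) {
  net <- gen_network(n_modules = 6, module_size = 50, p_in = 0.25,
                     p_out = 0.01, seed = seed)
  expr <- gen_expression(net$truth, n_case = 6, n_control = 6,
                         effects = c("2" = 1, "5" = -1), sd = 0.5,
                         seed = seed + 1000L)
  ann <- gen_annotation(attr(expr, "truth"), extra_terms = 10,
                        noise_frac = noise_frac, seed = seed + 2000L)
  list(network = net$network, truth = attr(expr, "truth"), expr = expr,
       ann = ann)
}
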