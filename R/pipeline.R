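#' Pipeline run configuration
#'
#' Collects the input paths and tuning parameters of a full transcriptogram
#' run. Defaults follow the conventional published values: combined score
#' >= 700, window radius 80, position threshold 0.001 on BH-adjusted p,
#' enrichment threshold 0.05, Jaccard cutoff 0.25, PCA variance target 0.95,
#' marker threshold 0.01.
#'
#' @param ppi,expression,metadata,annotations Input file paths (annotations
#'   optional: `NULL` skips enrichment).
#' @param ordering Optional path to a precomputed ordering TSV to import
#'   verbatim instead of annealing.
#' @param score_min,radius,alpha_positions,alpha_enrichment,jaccard_cutoff,variance_target,marker_alpha,gap
#'   Tuning parameters, see module functions.
#' @param markers Character vector of marker genes for the grouping stage
#'   (default: the built-in NPC + neuronal sets, used when present).
#' @param seed Integer seed; the single source of randomness of the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(ppi, expression, metadata, annotations = NULL,
                       ordering = NULL, score_min = 700, radius = 80,
                       alpha_positions = 0.001, alpha_enrichment = 0.05,
                       jaccard_cutoff = 0.25, variance_target = 0.95,
                       marker_alpha = 0.01, gap = 0,
                       markers = unlist(marker_genes()), seed = 1L) {
  cfg <- list(ppi = ppi, expression = expression, metadata = metadata,
              annotations = annotations, ordering = ordering,
              score_min = score_min, radius = radius,
              alpha_positions = alpha_positions,
              alpha_enrichment = alpha_enrichment,
              jaccard_cutoff = jaccard_cutoff,
              variance_target = variance_target,
              marker_alpha = marker_alpha, gap = gap,
              markers = markers, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(cfg$score_min >= 0 && cfg$score_min <= 1000, "score_min outside [0, 1000]")
  chk(cfg$radius >= 0, "radius must be non-negative")
  chk(cfg$alpha_positions > 0 && cfg$alpha_positions < 1,
      "alpha_positions outside (0, 1)")
  chk(cfg$alpha_enrichment > 0 && cfg$alpha_enrichment < 1,
      "alpha_enrichment outside (0, 1)")
  chk(cfg$jaccard_cutoff > 0 && cfg$jaccard_cutoff < 1,
      "jaccard_cutoff outside (0, 1)")
  chk(cfg$variance_target > 0 && cfg$variance_target <= 1,
      "variance_target outside (0, 1]")
  chk(cfg$marker_alpha > 0 && cfg$marker_alpha < 1,
      "marker_alpha outside (0, 1)")
  chk(cfg$gap >= 0, "gap must be non-negative")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  base <- dirname(path)
  for (f in c("ppi", "expression", "metadata", "annotations", "ordering")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  }
  do.call(run_config, raw)
}

#' Write the demo synthetic scenario as pipeline input files
#'
#' Materializes [gen_demo()] in the dialects the readers consume: PPI edge
#' list, expression TSV, sample metadata TSV, annotation TSV and a
#' `truth.json` ground-truth sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param noise_frac Annotation noise fraction.
#' @return The directory path, invisibly; file names are fixed
#'   (`ppi.tsv`, `expression.tsv`, `metadata.tsv`, `annotations.tsv`,
#'   `truth.json`).
#' @export
simulate_inputs <- function(dir, seed = 1L, noise_frac = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- gen_demo(seed = seed, noise_frac = noise_frac)
  write_network(demo$network, file.path(dir, "ppi.tsv"))
  write_expression(demo$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "metadata.tsv"))
  write_tsv_(demo$ann, file.path(dir, "annotations.tsv"))
  jsonlite::write_json(
    list(modules = as.list(demo$truth$modules),
         effects = as.list(demo$truth$effects),
         sd = demo$truth$sd, seed = seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

run_stage_ <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full transcriptogram pipeline
#'
#' Executes dataio -> ordering (annealed or imported) -> window projection ->
#' position tests -> cluster calling -> network statistics -> enrichment, and
#' the PCA grouping / marker stage when the sample metadata carries more than
#' one distinct day. All tabular outputs and a JSON manifest (parameters,
#' seed, input checksums, stage list) are written under `out_dir`; rerunning
#' the same configuration and seed reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the main in-memory results (network,
#'   ordering, profile, tests, clusters, connectivity, coverage, enrichment,
#'   grouping).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)

  io <- run_stage_("dataio", {
    net <- read_ppi_edges(config$ppi, score_min = config$score_min)
    expr <- read_expression(config$expression, config$metadata)
    intersect_inputs(net, expr)
  })
  stages <- c(stages, "dataio")
  net <- io$network; expr <- io$expr
  write_network(net, file.path(out_dir, "interactome.tsv"))

  ord <- run_stage_("ordering", {
    if (!is.null(config$ordering)) read_ordering(config$ordering, net = net)
    else order_genes(net, seed = config$seed)
  })
  write_ordering(ord, file.path(out_dir, "ordering.tsv"))
  stages <- c(stages, "ordering")

  trans <- run_stage_("transcriptogram", {
    prof <- window_average(expr, ord, radius = config$radius)
    tests <- moderated_t(prof)
    clusters <- call_clusters(tests, alpha = config$alpha_positions,
                              gap = config$gap)
    list(profile = prof, tests = tests, clusters = clusters,
         relative = relative_profile(prof))
  })
  stages <- c(stages, "transcriptogram")
  pos_out <- trans$tests
  pos_out$relative <- unname(trans$relative)
  write_tsv_(pos_out, file.path(out_dir, "positions.tsv"))
  cl <- trans$clusters
  write_tsv_(as.data.frame(cl[, setdiff(names(cl), "genes")]),
             file.path(out_dir, "clusters.tsv"))
  genes_tbl <- if (nrow(cl)) data.frame(
    label = rep(cl$label, lengths(cl$genes)),
    gene = unlist(cl$genes), stringsAsFactors = FALSE)
  else data.frame(label = character(0), gene = character(0))
  write_tsv_(genes_tbl, file.path(out_dir, "cluster_genes.tsv"))

  nets <- run_stage_("netstats", {
    conn <- if (nrow(cl)) connectivity_table(cl, net) else
      data.frame(label = character(0), n_nodes = integer(0),
                 inner_edges = integer(0), outer_edges = integer(0),
                 avg_k = numeric(0))
    cov <- interactome_coverage(cl, net)
    list(connectivity = conn, coverage = cov)
  })
  stages <- c(stages, "netstats")
  write_tsv_(nets$connectivity, file.path(out_dir, "connectivity.tsv"))
  write_tsv_(data.frame(metric = "interactome_coverage",
                        value = nets$coverage),
             file.path(out_dir, "coverage.tsv"))
  if (nrow(cl)) {
    dir.create(file.path(out_dir, "subnetworks"), showWarnings = FALSE)
    for (k in seq_len(nrow(cl)))
      write_network(cluster_subnetwork(cl$genes[[k]], net),
                    file.path(out_dir, "subnetworks",
                              paste0("cluster_", cl$label[k], ".tsv")))
  }

  enr <- NULL
  if (!is.null(config$annotations) && nrow(cl)) {
    enr <- run_stage_("enrichment", {
      ann <- read_annotations(config$annotations)
      cluster_enrichment(cl, ann, ord, alpha = config$alpha_enrichment,
                         cutoff = config$jaccard_cutoff)
    })
    stages <- c(stages, "enrichment")
    dir.create(file.path(out_dir, "enrichment"), showWarnings = FALSE)
    for (lbl in names(enr)) {
      write_tsv_(enr[[lbl]]$terms,
                 file.path(out_dir, "enrichment",
                           paste0("cluster_", lbl, ".tsv")))
      if (!is.null(enr[[lbl]]$tree))
        write_term_tree(enr[[lbl]]$tree,
                        file.path(out_dir, "enrichment",
                                  paste0("cluster_", lbl, ".nwk")))
    }
  }

  grouping <- NULL
  if (length(unique(expr$samples$day[!is.na(expr$samples$day)])) > 1) {
    grouping <- run_stage_("grouping", {
      pca <- pca_samples(expr, variance_target = config$variance_target)
      pca <- cluster_samples(pca)
      present <- intersect(config$markers, rownames(expr$values))
      mk <- if (length(present) && pca$k_groups > 1)
        marker_tests(expr, pca$assignment, present,
                     alpha = config$marker_alpha) else NULL
      list(pca = pca, markers = mk)
    })
    stages <- c(stages, "grouping")
    write_tsv_(data.frame(sample = names(grouping$pca$assignment),
                          group = unname(grouping$pca$assignment)),
               file.path(out_dir, "groups.tsv"))
    v <- grouping$pca$cumvar
    write_tsv_(data.frame(component = seq_along(v),
                          variance = c(v[1], diff(v)), cumulative = v),
               file.path(out_dir, "scree.tsv"))
    if (!is.null(grouping$markers))
      write_tsv_(grouping$markers, file.path(out_dir, "markers.tsv"))
  }

  manifest <- list(
    package = "transcriptogram",
    version = as.character(utils::packageVersion("transcriptogram")),
    seed = config$seed,
    parameters = config[c("score_min", "radius", "alpha_positions",
                          "alpha_enrichment", "jaccard_cutoff",
                          "variance_target", "marker_alpha", "gap")],
    inputs = lapply(config[c("ppi", "expression", "metadata", "annotations")],
                    function(p) if (is.null(p)) NULL else
                      unname(tools::md5sum(p))),
    ordering_checksum = ordering_checksum(ord),
    ordering_cost = attr(ord, "cost"),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(network = net, ordering = ord, profile = trans$profile,
                 tests = trans$tests, clusters = cl,
                 connectivity = nets$connectivity, coverage = nets$coverage,
                 enrichment = enr, grouping = grouping))
}

read_run_clusters_ <- function(dir) {
  cl <- utils::read.table(file.path(dir, "clusters.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(label = "character"))
  genes <- utils::read.table(file.path(dir, "cluster_genes.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  cl$genes <- lapply(cl$label, function(l) genes$gene[genes$label == l])
  side <- jsonlite::read_json(file.path(dir, "ordering.tsv.json"))
  class(cl) <- c("de_clusters", "data.frame")
  attr(cl, "ordering_checksum") <- side$checksum
  cl
}

#' Compare two pipeline runs sharing one ordering
#'
#' Matches run B's clusters to run A's by positional overlap and tabulates
#' the node-count and average-connectivity evolution, exactly as transition
#' figures between two time intervals report it. Both runs must have used the
#' same ordering (checked via the ordering checksum in each run directory).
#'
#' @param dir_a,dir_b Run directories written by [run_pipeline()].
#' @param out Optional directory to write `match.tsv` and `evolution.tsv`.
#' @return List with `match` and `evolution` data frames.
#' @export
compare_runs <- function(dir_a, dir_b, out = NULL) {
  a <- read_run_clusters_(dir_a)
  b <- read_run_clusters_(dir_b)
  if (!identical(attr(a, "ordering_checksum"), attr(b, "ordering_checksum")))
    stop("runs used different orderings (checksum mismatch)")
  net <- read_ppi_edges(file.path(dir_a, "interactome.tsv"), score_min = 0)
  m <- match_clusters(a, b)
  ev <- cluster_evolution(a, b, net)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_tsv_(m, file.path(out, "match.tsv"))
    write_tsv_(ev, file.path(out, "evolution.tsv"))
  }
  list(match = m, evolution = ev)
}
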