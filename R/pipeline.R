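#' Default pipeline configuration
#'
#' All stage parameters in one list, with the analysis defaults: replicate
#' presence fraction 2/3, strict-majority cohort presence, triage fold
#' change 1.5, presence-fraction filter 0.7, minimum-fraction imputation
#' 1/5, volcano FDR 0.1, gene-set minimum size 15 with 1000 permutations
#' and FDR 0.05, consensus inclusion at 4 significant members, network fold
#' change 1.15, kNN k 10, top 50 proteins, top 5 hubs. A single global
#' `seed` fans out to per-stage child seeds so stages are individually
#' reproducible.
#'
#' @param outdir output directory.
#' @param seed global seed.
#' @param ... overrides of any default entry (unknown names are an error).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "proteotriage_out", seed = 1L, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    quant = NULL, design = NULL, gmt = NULL, annotation = NULL, edges = NULL,
    sim = list(n_proteins = 1000, n_sets = 60, n_enriched = 5,
               enrichment_odds = 5, mean_degree = 4),
    tech_fraction = 2 / 3, triage_fc = 1.5,
    presence_fraction = 0.7, impute_fraction = 1 / 5,
    fdr = 0.1, fc_cutoff = 1.5, top_k = 50, n_components = 3,
    knn_k = 10, min_set_size = 15, n_perm = 1000,
    gsea_p_cut = 0.05, min_sig_members = 4, exclude_names = character(),
    network_fc = 1.15, ora_fdr = 0.05, top_hubs = 5)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entry: ", bad[1])
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @param config a `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(NULL)
}

# stable per-stage child seeds derived from the global seed
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "triage", "diffexpr", "gsea", "network"))
  as.integer((as.numeric(seed) * 31L + idx * 1009L) %% 2147483647)
}

#' Run the pipeline stages
#'
#' Stages run in dependency order: `simulate` (or user-supplied input
#' files), `triage`, `diffexpr`, `gsea`, `network`. Every output table is a
#' TSV under `config$outdir`; a JSON manifest records the resolved
#' parameters, the seed and the md5 of every artifact, so identical config
#' and seed give identical manifests. Requesting a downstream stage without
#' its upstream artifacts is an error naming the stage to run first.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("simulate", "triage", "diffexpr", "gsea",
#'   "network")`.
#' @return Invisibly, the manifest list. Side effect: artifact files and
#'   `manifest.json` under `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "triage", "diffexpr",
                                    "gsea", "network")) {
  all_stages <- c("simulate", "triage", "diffexpr", "gsea", "network")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pt <- function(...) file.path(out, paste0(...))
  artifacts <- character(0)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if ("simulate" %in% stages) {
    cfg <- sim_config(n_proteins = config$sim$n_proteins,
                      seed = stage_seed(config$seed, "simulate"))
    ds <- generate_dataset(cfg)
    write_quant_matrix(ds$quant, pt("quant.tsv"))
    write_table(ds$design, pt("design.tsv"))
    write_table(ds$truth, pt("truth.tsv"))
    gs <- generate_gene_sets(ds$truth, n_sets = config$sim$n_sets,
                             n_enriched = config$sim$n_enriched,
                             enrichment_odds = config$sim$enrichment_odds,
                             seed = stage_seed(config$seed, "simulate"))
    write_gmt(gs, pt("gene_sets.gmt"))
    net <- generate_interactions(ds$truth$protein_id,
                                 mean_degree = config$sim$mean_degree,
                                 seed = stage_seed(config$seed, "simulate"))
    write_table(net$edges, pt("edges.tsv"))
    artifacts <- c(artifacts, pt(c("quant.tsv", "design.tsv", "truth.tsv",
                                   "gene_sets.gmt", "edges.tsv")))
    note("simulate: ", nrow(ds$quant$values), " proteins, ",
         nrow(ds$design), " samples, ", length(gs), " gene sets")
  }

  need <- function(file, stage) {
    p <- if (!is.null(config[[file]])) config[[file]] else
      pt(paste0(file, if (file == "gmt") ".gmt" else ".tsv"))
    if (file == "gmt" && is.null(config$gmt)) p <- pt("gene_sets.gmt")
    if (!file.exists(p))
      stop("missing input '", p, "'; run stage '", stage, "' first ",
           "or set config$", file)
    p
  }

  if (any(c("triage", "diffexpr", "gsea", "network") %in% stages)) {
    qm <- read_quant_matrix(need("quant", "simulate"))
    design <- read_design(need("design", "simulate"))
    presence <- call_presence(qm, config$tech_fraction)
  }

  if ("triage" %in% stages) {
    summ <- summarize_cohorts(presence, design)
    tri <- classify_proteins(summ, config$triage_fc)
    write_table(tri, pt("triage.tsv"))
    artifacts <- c(artifacts, pt("triage.tsv"))
    n_sem <- sum(summ$reason == "sem_exceeds_mean")
    note("triage: ", sum(!tri$excluded), " of ", nrow(tri),
         " proteins kept; SEM-filter exclusions: ", n_sem)
    note("triage venn: ",
         paste(names(table(tri$venn_class)), table(tri$venn_class),
               sep = "=", collapse = " "))
  }

  if ("diffexpr" %in% stages) {
    if (!file.exists(pt("triage.tsv")))
      stop("missing triage output; run stage 'triage' first")
    raw <- as_expression_matrix(presence)
    filt <- filter_presence_fraction(raw, design, config$presence_fraction)
    note("diffexpr: ", nrow(filt), " of ", nrow(raw),
         " proteins pass the ", config$presence_fraction,
         " presence filter")
    imp <- impute_min_fraction(filt, config$impute_fraction)
    norm <- normalize_median(imp)
    de <- ttest_fc(norm, design, "Sham", "Irradiated",
                   fdr = config$fdr, fc_cutoff = config$fc_cutoff)
    write_table(de, pt("de_results.tsv"))
    scaled <- suppressWarnings(pareto_scale(norm))
    pc <- pca(scaled, config$n_components)
    write_table(data.frame(sample_id = rownames(pc$scores), pc$scores),
                pt("pca_scores.tsv"))
    write_table(data.frame(protein_id = rownames(pc$loadings), pc$loadings),
                pt("pca_loadings.tsv"))
    top <- top_k_by_test(de, config$top_k, matrix = scaled)
    write_table(data.frame(rank = seq_along(top$ids),
                           protein_id = top$ids), pt("top_proteins.tsv"))
    artifacts <- c(artifacts, pt(c("de_results.tsv", "pca_scores.tsv",
                                   "pca_loadings.tsv", "top_proteins.tsv")))
    note("diffexpr: ", sum(de$volcano_flag), " volcano-flagged proteins")
    if (!is.null(config$annotation)) {
      ann <- read_annotation(config$annotation)
      ov <- annotate_overlap(de, ann, sig_threshold = config$fdr)
      write_table(ov$summary, pt("annotation_summary.tsv"))
      artifacts <- c(artifacts, pt("annotation_summary.tsv"))
      note("diffexpr: ", nrow(ov$annotated), " annotated proteins in ",
           nrow(ov$summary), " categories")
    }
  }

  if ("gsea" %in% stages) {
    if (!file.exists(pt("triage.tsv")))
      stop("missing triage output; run stage 'triage' first")
    sets <- read_gmt(need("gmt", "simulate"))
    raw <- as_expression_matrix(presence)
    observed <- rowSums(!is.na(raw)) > 0
    if (any(!observed))
      note("gsea: ", sum(!observed),
           " protein(s) with no observation dropped before imputation")
    raw <- raw[observed, , drop = FALSE]
    imp <- knn_impute(raw, k = config$knn_k)
    tr <- transform_and_map(imp)
    comps <- c("Functional_vs_Sham", "Impaired_vs_Sham",
               "Irradiated_vs_Sham")
    res <- lapply(comps, function(cmp)
      gsea_run(tr, design, sets, cmp, min_size = config$min_set_size,
               n_perm = config$n_perm,
               seed = stage_seed(config$seed, "gsea")))
    for (r in res) {
      f <- pt("gsea_", r$comparison[1], ".tsv")
      write_table(r, f)
      artifacts <- c(artifacts, f)
      note("gsea ", r$comparison[1], ": ", nrow(r), " sets tested, ",
           sum(r$fdr_q < config$gsea_p_cut), " at q < ", config$gsea_p_cut)
    }
    graph <- build_consensus_graph(res, sets, p_cut = config$gsea_p_cut,
                                   min_sig_members = config$min_sig_members,
                                   exclude_names = config$exclude_names)
    write_table(graph$nodes, pt("consensus_nodes.tsv"))
    write_table(graph$edges, pt("consensus_edges.tsv"))
    jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges),
                         pt("consensus_graph.json"), dataframe = "rows")
    artifacts <- c(artifacts, pt(c("consensus_nodes.tsv",
                                   "consensus_edges.tsv",
                                   "consensus_graph.json")))
    note("gsea: consensus graph with ", sum(graph$nodes$included),
         " included sets and ", nrow(graph$edges), " edges")
  }

  if ("network" %in% stages) {
    if (!file.exists(pt("triage.tsv")))
      stop("missing triage output; run stage 'triage' first")
    edges <- read_edges(need("edges", "simulate"))
    raw <- as_expression_matrix(presence)
    imp <- impute_half_group_min(raw, design)
    dys <- select_dysregulated(imp, design, "Irradiated",
                               fc_cut = config$network_fc)
    write_table(data.frame(protein_id = c(dys$up, dys$down),
                           direction = rep(c("up", "down"),
                                           c(length(dys$up),
                                             length(dys$down))),
                           fc = unname(dys$fc[c(dys$up, dys$down)])),
                pt("dysregulated.tsv"))
    note("network: ", length(dys$up), " up, ", length(dys$down),
         " down at fc ", config$network_fc)
    sets <- read_gmt(need("gmt", "simulate"))
    ora <- ora_enrich(c(dys$up, dys$down), sets,
                      universe = rownames(imp), fdr_cut = config$ora_fdr)
    write_table(ora, pt("ora_results.tsv"))
    net <- induce_subnetwork(edges, dys)
    hubs <- hub_ranking(net, config$top_hubs)
    write_table(net$nodes, pt("network_nodes.tsv"))
    write_table(net$edges, pt("network_edges.tsv"))
    write_table(hubs$degree_table, pt("hub_degrees.tsv"))
    artifacts <- c(artifacts, pt(c("dysregulated.tsv", "ora_results.tsv",
                                   "network_nodes.tsv", "network_edges.tsv",
                                   "hub_degrees.tsv")))
    note("network: ", nrow(net$nodes), " nodes, ", nrow(net$edges),
         " edges; top hubs: ", paste(hubs$hubs, collapse = " "))
  }

  writeLines(log_lines, pt("pipeline.log"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("proteotriage")),
    seed = config$seed,
    stages = stages,
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    artifacts = lapply(sort(artifacts), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, pt("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
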