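stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, network = 2L, modules = 3L, consensus = 4L,
               diffexpr = 5L, enrich = 6L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + 104729L * offsets[[stage]]) %% 2147483629L
}

#' Run the full analysis on a synthetic study
#'
#' Orchestrates: simulation, co-expression network construction, PPI
#' intersection, power-law check, gene-category analysis, module mining,
#' per-module consensus clustering with chi-squared validation against the
#' true groups, per-module expression summaries with differential
#' expression and hypergeometric module enrichment, and pathway
#' over-representation. Per-stage seeds are derived deterministically from
#' the single `seed` in `config`, so any stage rerun in isolation matches
#' the full run.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param r_min,fdr_max Thresholds of [build_coexpression_network()].
#' @param min_size,max_modules Passed to [mine_modules()].
#' @param k_range,n_resamples,subsample_frac Passed to
#'   [consensus_cluster()].
#' @param thresholds Co-expression fractions reported per module.
#' @param de_p Per-gene DE cut-off (unadjusted p).
#' @param q_max ORA significance cut-off on the BH q.
#' @param out_dir Optional directory; when given, every stage's tables are
#'   written there as TSV/SIF/GMT text files.
#' @return A `pipeline_report` list with one element per stage; every
#'   headline number is recomputable from the returned stage objects.
#' @export
run_pipeline <- function(config = sim_config(),
                         r_min = 0.3, fdr_max = 0.05,
                         min_size = 5L, max_modules = 10L,
                         k_range = 2:5, n_resamples = 200L,
                         subsample_frac = 0.8,
                         thresholds = c(0.5, 0.7), de_p = 0.05,
                         q_max = 0.05, out_dir = NULL) {
  if (r_min < 0 || r_min > 1) stop("`r_min` must lie in [0, 1]")
  if (fdr_max <= 0 || fdr_max > 1) stop("`fdr_max` must lie in (0, 1]")
  if (q_max <= 0 || q_max > 1) stop("`q_max` must lie in (0, 1]")

  sim_cfg <- config
  sim_cfg$seed <- stage_seed(config$seed, "simulate")
  study <- simulate_study(sim_cfg)

  coexpr <- build_coexpression_network(study$expr, r_min = r_min,
                                       fdr_max = fdr_max)
  net <- intersect_with_ppi(coexpr, study$ppi)
  if (igraph::vcount(net) == 0L) {
    stop("stage 'network' failed: no PPI-supported co-expression edges")
  }
  plaw <- power_law_fit(degree_distribution_table(net))

  assignment <- classify_genes(net, study$annotation)
  cat_counts <- table(assignment)
  wilcox_p <- suppressWarnings(category_wilcoxon_matrix(net, assignment))
  gdnc_seeds <- category_members(assignment, "disease_all")
  gdnc <- if (length(gdnc_seeds)) {
    suppressWarnings(extract_neighbor_subnetwork(net, gdnc_seeds))
  }

  modules <- mine_modules(net, min_size = min_size,
                          max_modules = max_modules,
                          seed = stage_seed(config$seed, "modules"))

  consensus <- lapply(modules, function(m) {
    res <- consensus_cluster(subset_genes(study$expr, m$genes),
                             k_range = k_range,
                             n_resamples = n_resamples,
                             subsample_frac = subsample_frac,
                             seed = stage_seed(config$seed, "consensus") +
                               m$id)
    assoc <- suppressWarnings(
      chi_squared_association(res$labels,
                              stats::setNames(as.character(study$expr$groups),
                                              names(study$expr$groups))))
    list(module = m$id, k_selected = res$k_selected, result = res,
         chisq = assoc)
  })

  de <- per_gene_t_test(study$expr)
  de_genes <- de$gene[de$p < de_p]
  background <- igraph::V(net)$name
  summaries <- lapply(modules, function(m) {
    s <- module_expression_summary(study$expr, m, thresholds = thresholds,
                                   de_p = de_p)
    s$module <- m$id
    s$category_profile <- module_category_profile(m, assignment)
    s
  })
  all_module_genes <- sort(unique(unlist(lapply(modules, `[[`, "genes"))))
  module_enrich <- if (length(all_module_genes)) {
    module_de_enrichment(intersect(de_genes, background),
                         all_module_genes, background)
  }

  ora_tab <- if (length(all_module_genes)) {
    ora(all_module_genes, study$pathways, background, q_max = q_max)
  }

  report <- structure(list(
    config = config,
    study = study,
    network = list(graph = net, coexpr_edges = igraph::ecount(coexpr),
                   nodes = igraph::vcount(net),
                   edges = igraph::ecount(net),
                   power_law = plaw,
                   top_hubs = top_hub_genes(net, min(5L, igraph::vcount(net)))),
    categories = list(assignment = assignment, counts = cat_counts,
                      wilcoxon_p = wilcox_p, gdnc = gdnc),
    modules = modules,
    consensus = consensus,
    expression = list(de_table = de, n_de = length(de_genes),
                      summaries = summaries,
                      module_enrichment = module_enrich),
    enrichment = ora_tab), class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges (from %d co-expression edges); power-law R^2 = %.4f\n",
              x$network$nodes, x$network$edges, x$network$coexpr_edges,
              x$network$power_law$r_squared))
  cat("gene categories:",
      paste(sprintf("%s=%d", names(x$categories$counts),
                    as.integer(x$categories$counts)), collapse = ", "), "\n")
  cat(sprintf("modules mined: %d (sizes %s)\n", length(x$modules),
              paste(vapply(x$modules, `[[`, integer(1L), "size"),
                    collapse = ", ")))
  for (cc in x$consensus) {
    cat(sprintf("  module %d: k_selected = %d, chi-squared p = %.4g\n",
                cc$module, cc$k_selected, cc$chisq$p))
  }
  cat(sprintf("differentially expressed genes (p < 0.05): %d\n",
              x$expression$n_de))
  if (!is.null(x$expression$module_enrichment)) {
    cat(sprintf("module DE enrichment p = %.4g\n",
                x$expression$module_enrichment$p))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("pathway ORA: %d significant set(s) at q < 0.05\n",
                sum(x$enrichment$significant)))
  }
  invisible(x)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(out_dir, ...)
  write_expression(report$study$expr, f("expression.tsv"),
                   groups_path = f("groups.tsv"))
  write_network_tsv(report$study$ppi, f("ppi_edges.tsv"))
  write_network_tsv(report$network$graph, f("network_edges.tsv"))
  write_sif(report$network$graph, f("network.sif"))
  write_gmt(report$study$pathways, f("pathways.gmt"))
  dd <- degree_distribution_table(report$network$graph)
  utils::write.table(data.frame(degree = names(dd), count = dd),
                     f("degree_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(report$categories$assignment),
               category = as.character(report$categories$assignment)),
    f("gene_categories.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in report$modules) {
    writeLines(m$genes, f(sprintf("module_%02d_genes.txt", m$id)))
    write_sif(m$graph, f(sprintf("module_%02d.sif", m$id)))
  }
  if (length(report$modules)) {
    utils::write.table(
      do.call(rbind, lapply(report$modules, function(m) {
        data.frame(module = m$id, size = m$size, density = m$density)
      })),
      f("module_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$expression$de_table, f("de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$enrichment)) {
    utils::write.table(report$enrichment, f("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
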