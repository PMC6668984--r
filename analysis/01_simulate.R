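#!/usr/bin/env Rscript
# Generate the synthetic study: expression (7 cases vs 7 controls), PPI
# overlay, immune/disease annotation sets and a pathway collection.

source("analysis/00_config.R")

study <- simulate_study(study_config())

write_expression(study$expr, file.path(RESULTS, "expression.tsv"),
                 groups_path = file.path(RESULTS, "groups.tsv"))
write_network_tsv(study$ppi, file.path(RESULTS, "ppi_edges.tsv"))
write_gmt(study$pathways, file.path(RESULTS, "pathways.gmt"))
writeLines(study$annotation$immune_genes,
           file.path(RESULTS, "immune_genes.txt"))
writeLines(study$annotation$disease_genes,
           file.path(RESULTS, "disease_genes.txt"))

cat(sprintf("expression: %d genes x %d samples (%d planted module genes)\n",
            nrow(study$expr$values), ncol(study$expr$values),
            sum(!is.na(study$truth$module_of))))
cat(sprintf("PPI overlay: %d nodes, %d edges\n",
            igraph::vcount(study$ppi), igraph::ecount(study$ppi)))
cat(sprintf("annotation: %d immune, %d disease genes\n",
            length(study$annotation$immune_genes),
            length(study$annotation$disease_genes)))
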