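#!/usr/bin/env Rscript
# Per-gene Welch tests, per-module co-expression fractions and the
# hypergeometric enrichment of differentially expressed genes in the
# mined modules.

source("analysis/00_config.R")

expr <- read_expression(file.path(RESULTS, "expression.tsv"),
                        file.path(RESULTS, "groups.tsv"))
net <- read_network_tsv(file.path(RESULTS, "network_edges.tsv"))
module_files <- sort(list.files(RESULTS, "module_.._genes\\.txt",
                                full.names = TRUE))

de <- per_gene_t_test(expr)
utils::write.table(de, file.path(RESULTS, "de_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
background <- igraph::V(net)$name
de_genes <- intersect(de$gene[de$p < 0.05], background)
cat(sprintf("%d of %d genes differentially expressed at p < 0.05 (%d in network)\n",
            sum(de$p < 0.05), nrow(de), length(de_genes)))

rows <- NULL
for (mf in module_files) {
  id <- as.integer(sub(".*module_(\\d+)_genes\\.txt", "\\1", mf))
  genes <- readLines(mf)
  frac <- pairwise_coexpr_fraction(subset_genes(expr, genes),
                                   thresholds = c(0.5, 0.7))
  sub_de <- de[de$gene %in% genes, ]
  enr <- module_de_enrichment(de_genes, genes, background)
  rows <- rbind(rows, data.frame(
    module = id, size = length(genes),
    frac_gt_0.5 = round(frac[["0.5"]], 3),
    frac_gt_0.7 = round(frac[["0.7"]], 3),
    n_de = sum(sub_de$p < 0.05),
    direction = sign(sum(sign(sub_de$direction))),
    de_enrichment_p = signif(enr$p, 4)))
}
utils::write.table(rows, file.path(RESULTS, "module_expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("per-module expression summary:\n")
print(rows)

all_module_genes <- unique(unlist(lapply(module_files, readLines)))
pooled <- module_de_enrichment(de_genes, all_module_genes, background)
cat(sprintf("DE genes vs all module genes: overlap %d/%d, hypergeometric p = %.3g\n",
            pooled$overlap, pooled$set_size, pooled$p))
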