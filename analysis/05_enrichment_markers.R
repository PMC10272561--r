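#!/usr/bin/env Rscript
# Stage 5 — functional enrichment and subtype markers.
#
# Over-representation of the trait-leading module's genes against the
# pathway collection (BH-adjusted hypergeometric enrichment at 0.05), then
# cluster-vs-rest marker calling on the cells (avg log2FC > 0.5, adjusted
# p < 0.05) and Fisher overlap of module genes with each subtype's markers.

suppressMessages(library(coexscreen))

inp <- "results/study/synthetic"
mods <- "results/study/modules"
out <- "results/study/enrich"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

asg <- utils::read.delim(file.path(mods, "module_assignment.tsv"))
trait_cor <- utils::read.delim(file.path(mods, "module_trait_correlation.tsv"))
top_module <- trait_cor$module[1]
genes <- asg$gene[asg$module == top_module]
universe <- asg$gene
pathways <- read_gmt(file.path(inp, "pathways.gmt"))

enr <- ora_enrichment(genes, pathways, universe)
message(sprintf("%d significant pathway(s); top: %s (p_adj = %.3g)",
                sum(enr$significant), enr$pathway[1], enr$p_adj[1]))
utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cells <- read_counts_mtx(file.path(inp, "counts"))
norm <- lognormalize(cells$counts)
markers <- marker_genes(norm, cells$annotations$cell_type)
message(sprintf("marker calls per subtype: %s",
                paste(capture.output(print(table(
                  markers$cluster[markers$pass]))), collapse = " ")))
utils::write.table(markers, file.path(out, "markers.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# module genes vs subtype markers, universe = genes present in both views
uni2 <- rownames(norm)
mod_in_cells <- intersect(genes, uni2)
ov <- do.call(rbind, lapply(unique(cells$annotations$cell_type), function(ct) {
  mk <- markers$gene[markers$cluster == ct & markers$pass]
  f <- fisher_overlap(mod_in_cells, mk, uni2)
  data.frame(cell_type = ct, n_markers = length(mk), overlap = f$overlap,
             odds_ratio = f$odds_ratio, p = f$p)
}))
ov$p_adj <- bh_adjust(ov$p)
ov <- ov[order(ov$p_adj), ]
message("module-marker overlap by subtype:")
print(ov, row.names = FALSE)
utils::write.table(ov, file.path(out, "module_marker_overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
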