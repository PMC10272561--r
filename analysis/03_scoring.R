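#!/usr/bin/env Rscript
# Stage 3 — module activity scores.
#
# ssGSEA-style score of the trait-leading module per bulk sample, the
# bin-controlled additive score per cell on the log-normalized counts, and
# a pseudo-bulk summary scored the same way as bulk.

suppressMessages(library(coexscreen))

inp <- "results/study/synthetic"
mods <- "results/study/modules"
out <- "results/study/scores"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

expr <- read_expression_tsv(file.path(inp, "expression.tsv"))
trait <- read_trait_tsv(file.path(inp, "trait.tsv"))
asg <- utils::read.delim(file.path(mods, "module_assignment.tsv"))
trait_cor <- utils::read.delim(file.path(mods, "module_trait_correlation.tsv"))
top_module <- trait_cor$module[1]
genes <- asg$gene[asg$module == top_module]
message(sprintf("scoring module %s (%d genes)", top_module, length(genes)))

bulk_score <- ssgsea_score(expr, genes)
w <- wilcoxon_two_group(bulk_score, ifelse(trait[names(bulk_score)] == 1,
                                           "case", "control"))
message(sprintf("bulk score case vs control: Wilcoxon p = %.3g (means %.3f / %.3f)",
                w$p, mean(bulk_score[trait == 1]), mean(bulk_score[trait == 0])))

cells <- read_counts_mtx(file.path(inp, "counts"))
norm <- lognormalize(cells$counts)
cell_score <- additive_module_score(norm, genes,
                                    seed = derive_seed(seed, "additive_score"))
by_type <- sort(tapply(cell_score, cells$annotations$cell_type, mean),
                decreasing = TRUE)
message("mean additive score by subtype (descending): ",
        paste(sprintf("%s=%.3f", names(by_type), by_type), collapse = ", "))

pb <- pseudobulk(cells$counts, cells$annotations$sample)
pb_score <- ssgsea_score(log1p(pb), genes)

tsv <- function(df, name) utils::write.table(
  df, file.path(out, name), sep = "\t", quote = FALSE, row.names = FALSE
)
tsv(data.frame(sample = names(bulk_score), score = bulk_score,
               trait = trait[names(bulk_score)]), "bulk_module_score.tsv")
tsv(data.frame(cells$annotations, score = cell_score), "cell_module_score.tsv")
tsv(data.frame(sample = names(pb_score), score = pb_score),
    "pseudobulk_module_score.tsv")
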