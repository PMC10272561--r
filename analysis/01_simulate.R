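#!/usr/bin/env Rscript
# Stage 1 — simulate the study's inputs.
#
# Emulates the data the analysis chain expects: a case/control bulk
# expression matrix with four planted co-expression modules (one carrying
# the trait effect), a scale-free PPI edge list in the STRING dialect, a
# drug-target table with 20 drugs planted near the trait module's future
# hubs plus 180 null drugs, cell-type-structured counts in which one
# subtype over-expresses the planted module, and a pathway collection with
# one set per planted module.

suppressMessages(library(coexscreen))

seed <- 1
out <- "results/study/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bulk <- generate_bulk_expression(module_plant_spec(seed = derive_seed(seed, "simulate")))
message(sprintf("bulk: %d genes x %d samples (%d cases / %d controls)",
                nrow(bulk$expr), ncol(bulk$expr), sum(bulk$trait),
                sum(bulk$trait == 0)))

net <- generate_ppi_network(network_plant_spec(seed = derive_seed(seed, "network")))
g <- igraph::graph_from_data_frame(net[, 1:2], directed = FALSE)
message(sprintf("network: %d nodes, %d scored edges",
                igraph::vcount(g), nrow(net)))

trait_genes <- names(bulk$truth$module)[
  bulk$truth$module == bulk$truth$trait_module]
planted_hubs <- intersect(
  bulk$truth$top_loading_genes[[bulk$truth$trait_module]],
  igraph::V(g)$name
)[1:10]
drugs <- generate_drug_table(
  drug_plant_spec(seed = derive_seed(seed, "drugs")), net, planted_hubs
)
message(sprintf("drugs: %d planted near the trait module, %d null",
                sum(drugs$truth), sum(!drugs$truth)))

cells <- generate_counts(
  cell_population_spec(module_shift = 4, seed = derive_seed(seed, "cells")),
  module_genes = trait_genes
)
message(sprintf("cells: %d genes x %d cells in %d subtypes",
                nrow(cells$counts), ncol(cells$counts),
                length(unique(cells$annotations$cell_type))))

pathways <- generate_pathways(bulk$truth, rownames(bulk$expr),
                              seed = derive_seed(seed, "pathways"))

write_expression_tsv(bulk$expr, file.path(out, "expression.tsv"))
write_trait_tsv(bulk$trait, file.path(out, "trait.tsv"))
write_string_edges(net, file.path(out, "ppi_edges.tsv"))
write_drug_table(drugs$drugs, file.path(out, "drug_targets.tsv"))
write_counts_mtx(cells$counts, file.path(out, "counts"), cells$annotations)
write_gmt(pathways, file.path(out, "pathways.gmt"))
jsonlite::write_json(
  list(module = as.list(bulk$truth$module),
       trait_module = bulk$truth$trait_module,
       planted_hubs = planted_hubs,
       planted_drugs = names(drugs$truth)[drugs$truth]),
  file.path(out, "truth.json"), auto_unbox = TRUE
)
message("inputs written under ", out)
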