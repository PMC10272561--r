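# End-to-end orchestration: a serializable configuration object, stage
# drivers, a hash-recorded manifest, and a plain-text report. Mirrors the
# workflow shape: simulate -> modules -> score -> classify -> enrich ->
# markers -> proximity -> report.

#' Pipeline configuration
#'
#' All stage parameters with their study defaults (top-variable 5000,
#' scale-free fit target 0.9, merge height 0.1, max module size 1000, 10
#' hubs, 3x5-fold CV, combined-score threshold 600, pChEMBL 6, 1000
#' backgrounds, top 20 report) plus a master seed fanned out per stage. The
#' `simulate` block holds the synthetic-data generators' arguments; set
#' `stages` to switch stages off.
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param seed Master seed.
#' @param simulate,modules,score,classify,enrich,markers,proximity Named
#'   lists of per-stage parameter overrides.
#' @param stages Character vector of enabled stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = list(),
                            modules = list(), score = list(),
                            classify = list(), enrich = list(),
                            markers = list(), proximity = list(),
                            stages = c("simulate", "modules", "score",
                                       "classify", "enrich", "markers",
                                       "proximity", "report")) {
  merge_defaults <- function(defaults, overrides) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) > 0) {
      stop_invalid("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    # NULL overrides mean "keep the default" (YAML round-trips drop nulls)
    overrides <- overrides[!vapply(overrides, is.null, logical(1))]
    utils::modifyList(defaults, overrides)
  }
  cfg <- list(
    out_dir = out_dir,
    seed = assert_count(seed, "seed", min = 0),
    stages = stages,
    simulate = merge_defaults(list(
      n_modules = 4, genes_per_module = 50, n_background_genes = 200,
      n_cases = 100, n_controls = 100, within_module_loading = 0.8,
      loading_jitter = 0.2, trait_effect = 0.8, noise_sd = 0.6,
      network_nodes = 500, edges_per_new_node = 2,
      n_null_drugs = 180, n_planted_drugs = 20, planting_radius = 1,
      cells_per_type = 250, n_random_pathways = 20
    ), simulate),
    modules = merge_defaults(list(
      top_variable = 5000, powers = 1:12, r2_target = 0.9,
      outlier_height = NULL, network_type = "unsigned",
      min_module_size = 30, cut_height = NULL, merge_cut_height = 0.1,
      max_module_size = 1000, n_hubs = 10
    ), modules),
    score = merge_defaults(list(alpha = 0.25, n_bins = 24, n_ctrl = 100), score),
    classify = merge_defaults(list(folds = 5, replicates = 3), classify),
    enrich = merge_defaults(list(alpha = 0.05), enrich),
    markers = merge_defaults(list(lfc_threshold = 0.5, alpha = 0.05), markers),
    proximity = merge_defaults(list(
      score_threshold = 600, pchembl_min = 6, n_background = 1000, top_k = 20
    ), proximity)
  )
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the configuration object.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = raw$out_dir, seed = raw$seed, stages = unlist(raw$stages),
    simulate = raw$simulate, modules = raw$modules, score = raw$score,
    classify = raw$classify, enrich = raw$enrich, markers = raw$markers,
    proximity = raw$proximity
  )
}

log_line <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = state$log, append = TRUE)
}

record_outputs <- function(state, stage, params, files, seed = NULL,
                           note = NULL) {
  state$manifest[[stage]] <- list(
    stage = stage,
    parameters = params,
    seed = seed,
    note = note,
    outputs = as.list(tools::md5sum(files)),
    elapsed_s = round(as.numeric(Sys.time()) - state$t0, 2)
  )
  state
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in order, writing every stage's tables as TSV
#' under `config$out_dir` together with a `manifest.json` recording stage
#' parameters, sub-seeds and the MD5 hash of every output file, and a run
#' log. Re-running with the same configuration and seed reproduces every
#' table byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The run directory, invisibly; the manifest is also returned as
#'   attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a pipeline_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(
    manifest = list(), t0 = as.numeric(Sys.time()),
    log = file.path(config$out_dir, "run.log")
  )
  cat("", file = state$log)
  log_line(state, "pipeline start; master seed ", config$seed)
  write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))

  env <- new.env(parent = emptyenv())
  for (stage in c("simulate", "modules", "score", "classify", "enrich",
                  "markers", "proximity", "report")) {
    if (!stage %in% config$stages) {
      state$manifest[[stage]] <- list(stage = stage, note = "skipped")
      log_line(state, "stage ", stage, ": skipped")
      next
    }
    state <- tryCatch(
      switch(stage,
        simulate = stage_simulate(config, state, env),
        modules = stage_modules(config, state, env),
        score = stage_score(config, state, env),
        classify = stage_classify(config, state, env),
        enrich = stage_enrich(config, state, env),
        markers = stage_markers(config, state, env),
        proximity = stage_proximity(config, state, env),
        report = stage_report(config, state, env)
      ),
      error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  jsonlite::write_json(state$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(state, "pipeline done")
  invisible(structure(config$out_dir, manifest = state$manifest))
}

stage_simulate <- function(config, state, env) {
  p <- config$simulate
  d <- file.path(config$out_dir, "synthetic")
  dir.create(d, showWarnings = FALSE)
  seed <- derive_seed(config$seed, "simulate")

  bulk <- generate_bulk_expression(module_plant_spec(
    n_modules = p$n_modules, genes_per_module = p$genes_per_module,
    n_background_genes = p$n_background_genes, n_cases = p$n_cases,
    n_controls = p$n_controls, within_module_loading = p$within_module_loading,
    loading_jitter = p$loading_jitter, trait_effect = p$trait_effect,
    noise_sd = p$noise_sd, seed = seed
  ))
  universe <- rownames(bulk$expr)
  # default node symbols come from the same synthetic universe, so the
  # network overlaps the expression genes and extends beyond them
  net <- generate_ppi_network(
    network_plant_spec(n_nodes = p$network_nodes,
                       edges_per_new_node = p$edges_per_new_node,
                       seed = derive_seed(config$seed, "network"))
  )
  g <- igraph::graph_from_data_frame(net[, 1:2], directed = FALSE)
  hub_pool <- names(sort(igraph::degree(g), decreasing = TRUE))
  trait_genes <- names(bulk$truth$module)[
    bulk$truth$module == bulk$truth$trait_module]
  planted_hubs <- intersect(
    bulk$truth$top_loading_genes[[bulk$truth$trait_module]],
    igraph::V(g)$name
  )[1:10]
  drug <- generate_drug_table(
    drug_plant_spec(n_null_drugs = p$n_null_drugs,
                    n_planted_drugs = p$n_planted_drugs,
                    planting_radius = p$planting_radius,
                    seed = derive_seed(config$seed, "drugs")),
    net, planted_hubs
  )
  cells <- generate_counts(
    cell_population_spec(
      cell_types = stats::setNames(rep(p$cells_per_type, 4),
                                   c("Mic0", "Mic1", "Mic2", "Mic3")),
      module_shift = 4,
      seed = derive_seed(config$seed, "cells")
    ),
    module_genes = trait_genes
  )
  pathways <- generate_pathways(bulk$truth, universe,
                                n_random = p$n_random_pathways,
                                seed = derive_seed(config$seed, "pathways"))

  write_expression_tsv(bulk$expr, file.path(d, "expression.tsv"))
  write_trait_tsv(bulk$trait, file.path(d, "trait.tsv"))
  write_string_edges(net, file.path(d, "ppi_edges.tsv"))
  write_drug_table(drug$drugs, file.path(d, "drug_targets.tsv"))
  write_counts_mtx(cells$counts, file.path(d, "counts"), cells$annotations)
  write_gmt(pathways, file.path(d, "pathways.gmt"))
  jsonlite::write_json(
    list(module = as.list(bulk$truth$module),
         trait_module = bulk$truth$trait_module,
         planted_hubs = planted_hubs,
         planted_drugs = names(drug$truth)[drug$truth]),
    file.path(d, "truth.json"), auto_unbox = TRUE
  )
  env$bulk <- bulk
  env$edges <- net
  env$drugs <- drug
  env$cells <- cells
  env$pathways <- pathways
  files <- c(file.path(d, c("expression.tsv", "trait.tsv", "ppi_edges.tsv",
                            "drug_targets.tsv", "pathways.gmt", "truth.json")),
             file.path(d, "counts", c("matrix.mtx", "genes.tsv",
                                      "barcodes.tsv", "annotations.tsv")))
  log_line(state, "stage simulate: ", nrow(bulk$expr), " genes, ",
           ncol(bulk$expr), " samples, ", nrow(net), " edges, ",
           length(unique(drug$drugs$drug_id)), " drugs")
  record_outputs(state, "simulate", p, files, seed = seed)
}

stage_modules <- function(config, state, env) {
  p <- config$modules
  d <- file.path(config$out_dir, "modules")
  dir.create(d, showWarnings = FALSE)
  fit <- coexpression_chain(
    env$bulk$expr, env$bulk$trait, top_variable = p$top_variable,
    powers = p$powers, r2_target = p$r2_target,
    outlier_height = p$outlier_height, network_type = p$network_type,
    min_module_size = p$min_module_size, cut_height = p$cut_height,
    merge_cut_height = p$merge_cut_height,
    max_module_size = p$max_module_size, n_hubs = p$n_hubs
  )
  env$fit <- fit
  write_tsv(data.frame(gene = names(fit$assignment),
                       module = unname(fit$assignment)),
            file.path(d, "module_assignment.tsv"))
  write_tsv(data.frame(sample = rownames(fit$eigengenes), fit$eigengenes,
                       check.names = FALSE),
            file.path(d, "eigengenes.tsv"))
  write_tsv(data.frame(gene = rownames(fit$kme), fit$kme, check.names = FALSE),
            file.path(d, "kme.tsv"))
  write_tsv(fit$scan$table, file.path(d, "soft_threshold_scan.tsv"))
  write_tsv(fit$trait_cor, file.path(d, "module_trait_correlation.tsv"))
  hubs_df <- do.call(rbind, lapply(names(fit$hubs), function(m) {
    data.frame(module = m, rank = seq_along(fit$hubs[[m]]),
               gene = fit$hubs[[m]])
  }))
  write_tsv(hubs_df, file.path(d, "hub_genes.tsv"))
  files <- file.path(d, c("module_assignment.tsv", "eigengenes.tsv",
                          "kme.tsv", "soft_threshold_scan.tsv",
                          "module_trait_correlation.tsv", "hub_genes.tsv"))
  log_line(state, "stage modules: power ", fit$power, ", ",
           length(retained_modules(fit$assignment)), " retained modules; top trait module ",
           fit$trait_cor$module[1], " (r = ",
           round(fit$trait_cor$r[1], 3), ")")
  record_outputs(state, "modules", p, files)
}

stage_score <- function(config, state, env) {
  p <- config$score
  d <- file.path(config$out_dir, "scores")
  dir.create(d, showWarnings = FALSE)
  fit <- env$fit
  top_module <- fit$trait_cor$module[1]
  genes <- names(fit$assignment)[fit$assignment == top_module]
  bulk_score <- ssgsea_score(env$bulk$expr, genes, alpha = p$alpha)
  norm <- lognormalize(env$cells$counts)
  cell_score <- additive_module_score(
    norm, genes, n_bins = p$n_bins, n_ctrl = p$n_ctrl,
    seed = derive_seed(config$seed, "additive_score")
  )
  pb <- pseudobulk(env$cells$counts, env$cells$annotations$sample)
  pb_score <- ssgsea_score(log1p(pb), genes, alpha = p$alpha)
  env$top_module <- top_module
  env$norm <- norm
  env$cell_score <- cell_score
  write_tsv(data.frame(sample = names(bulk_score), score = bulk_score,
                       trait = env$bulk$trait[names(bulk_score)]),
            file.path(d, "bulk_module_score.tsv"))
  write_tsv(data.frame(env$cells$annotations, score = cell_score),
            file.path(d, "cell_module_score.tsv"))
  write_tsv(data.frame(sample = names(pb_score), score = pb_score),
            file.path(d, "pseudobulk_module_score.tsv"))
  files <- file.path(d, c("bulk_module_score.tsv", "cell_module_score.tsv",
                          "pseudobulk_module_score.tsv"))
  log_line(state, "stage score: module ", top_module, "; mean bulk score ",
           round(mean(bulk_score), 3))
  record_outputs(state, "score", p, files,
                 seed = derive_seed(config$seed, "additive_score"))
}

stage_classify <- function(config, state, env) {
  p <- config$classify
  d <- file.path(config$out_dir, "classify")
  dir.create(d, showWarnings = FALSE)
  plan <- cv_plan(k = p$folds, replicates = p$replicates,
                  seed = derive_seed(config$seed, "cv"))
  tab <- module_discrimination(env$fit, plan)
  env$auprc_table <- tab
  write_tsv(tab, file.path(d, "module_auprc.tsv"))
  best <- tab$module[1]
  feats <- t(env$fit$expr[env$fit$hubs[[best]], , drop = FALSE])
  fit <- logistic_fit(feats, env$fit$trait)
  pr <- auprc(predict(fit, feats), env$fit$trait)
  write_tsv(pr$points, file.path(d, "pr_curve_best_module.tsv"))
  log_line(state, "stage classify: best module ", best,
           " median AUPRC ", round(tab$median_auprc[1], 3))
  record_outputs(state, "classify", p,
                 file.path(d, c("module_auprc.tsv", "pr_curve_best_module.tsv")),
                 seed = plan$seed)
}

stage_enrich <- function(config, state, env) {
  p <- config$enrich
  d <- file.path(config$out_dir, "enrich")
  dir.create(d, showWarnings = FALSE)
  genes <- names(env$fit$assignment)[env$fit$assignment == env$top_module]
  universe <- rownames(env$bulk$expr)
  tab <- ora_enrichment(genes, env$pathways, universe, alpha = p$alpha)
  write_tsv(tab, file.path(d, "enrichment.tsv"))
  log_line(state, "stage enrich: ", sum(tab$significant),
           " significant pathway(s); top ", tab$pathway[1])
  record_outputs(state, "enrich", p, file.path(d, "enrichment.tsv"))
}

stage_markers <- function(config, state, env) {
  p <- config$markers
  d <- file.path(config$out_dir, "markers")
  dir.create(d, showWarnings = FALSE)
  ann <- env$cells$annotations
  tab <- marker_genes(env$norm, ann$cell_type,
                      lfc_threshold = p$lfc_threshold, alpha = p$alpha)
  write_tsv(tab, file.path(d, "markers.tsv"))
  module_genes_in_matrix <- intersect(
    names(env$fit$assignment)[env$fit$assignment == env$top_module],
    rownames(env$norm)
  )
  universe <- rownames(env$norm)
  overlaps <- do.call(rbind, lapply(unique(ann$cell_type), function(ct) {
    mk <- tab$gene[tab$cluster == ct & tab$pass]
    ov <- fisher_overlap(module_genes_in_matrix, mk, universe)
    data.frame(cell_type = ct, n_markers = length(mk), overlap = ov$overlap,
               odds_ratio = ov$odds_ratio, p = ov$p)
  }))
  overlaps$p_adj <- bh_adjust(overlaps$p)
  write_tsv(overlaps, file.path(d, "module_marker_overlap.tsv"))
  log_line(state, "stage markers: ", sum(tab$pass), " marker calls")
  record_outputs(state, "markers", p,
                 file.path(d, c("markers.tsv", "module_marker_overlap.tsv")))
}

stage_proximity <- function(config, state, env) {
  p <- config$proximity
  d <- file.path(config$out_dir, "proximity")
  dir.create(d, showWarnings = FALSE)
  g <- load_string_edges(env$edges, score_threshold = p$score_threshold)
  drugs <- filter_effective_targets(env$drugs$drugs, pchembl_min = p$pchembl_min)
  hubs <- env$fit$hubs[[env$top_module]]
  screen <- screen_drugs(g, drugs, hubs, n_background = p$n_background,
                         seed = derive_seed(config$seed, "proximity"),
                         top_k = p$top_k)
  env$screen <- screen
  write_tsv(screen$table, file.path(d, "proximity_screen.tsv"))
  write_tsv(top_drugs_report(screen), file.path(d, "top_drugs.tsv"))
  bg <- screen$backgrounds[[1]]
  chk <- gaussian_check(bg)
  write_tsv(data.frame(size = bg$size, mu = bg$mu, sigma = bg$sigma,
                       ks_statistic = chk$ks_statistic),
            file.path(d, "background_normality.tsv"))
  log_line(state, "stage proximity: ", nrow(screen$table), " drugs screened; ",
           "top drug ", screen$table$drug_id[1])
  record_outputs(state, "proximity", p,
                 file.path(d, c("proximity_screen.tsv", "top_drugs.tsv",
                                "background_normality.tsv")),
                 seed = derive_seed(config$seed, "proximity"))
}

stage_report <- function(config, state, env) {
  d <- config$out_dir
  lines <- c(
    "Synthetic study summary",
    "=======================",
    if (!is.null(env$fit)) c(
      sprintf("Soft power: %d (scale-free target %s)", env$fit$power,
              if (env$fit$scan$reached_target) "reached" else "not reached"),
      sprintf("Retained modules: %d",
              length(retained_modules(env$fit$assignment))),
      sprintf("Trait-leading module: %s (r = %.3f, p = %.3g)",
              env$fit$trait_cor$module[1], env$fit$trait_cor$r[1],
              env$fit$trait_cor$p[1])
    ),
    if (!is.null(env$auprc_table)) sprintf(
      "Best module by CV AUPRC: %s (median %.3f)",
      env$auprc_table$module[1], env$auprc_table$median_auprc[1]
    ),
    if (!is.null(env$screen)) sprintf(
      "Top proximity drug: %s (D = %.3f, p_adj = %.3g)",
      env$screen$table$drug_id[1], env$screen$table$proximity[1],
      env$screen$table$p_adj[1]
    )
  )
  writeLines(lines, file.path(d, "summary.txt"))
  log_line(state, "stage report: summary written")
  record_outputs(state, "report", list(), file.path(d, "summary.txt"))
}
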