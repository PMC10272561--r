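# Synthetic-data layer: planted co-expression modules, scale-free PPI
# networks, drug-target tables and cell-type-structured counts. These
# generators define the study conditions every downstream stage is tested
# against; all are deterministic given their spec seed.

#' Specification of a planted-module bulk expression design
#'
#' Case/control bulk expression under a latent-factor model: genes of module
#' m follow `x = l_g * f_m + noise`, with `f_m` standard normal per sample and
#' per-gene loadings `l_g` drawn uniformly from
#' `[within_module_loading - loading_jitter, within_module_loading + loading_jitter]`
#' (clipped to (0, 1]). Exactly one module is trait-associated: its factor is
#' shifted by `trait_effect` (in SD units of the factor) in case samples.
#' Background genes are pure noise at `noise_sd`.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per module.
#' @param n_background_genes Pure-noise genes.
#' @param n_cases,n_controls Sample sizes per group.
#' @param within_module_loading Central factor loading in (0, 1].
#' @param loading_jitter Half-width of the per-gene loading spread (>= 0);
#'   makes hub recovery meaningful by giving genes distinct true loadings.
#' @param trait_effect Case shift of the trait module's factor, in SD units.
#' @param noise_sd Residual (and background) standard deviation, > 0.
#' @param trait_module Index (1-based) of the trait-associated module.
#' @param seed Generator seed.
#' @return An object of class `module_plant_spec`.
#' @export
module_plant_spec <- function(n_modules = 4, genes_per_module = 50,
                              n_background_genes = 200, n_cases = 100,
                              n_controls = 100, within_module_loading = 0.8,
                              loading_jitter = 0.2, trait_effect = 0.8,
                              noise_sd = 0.6, trait_module = 1, seed = 1) {
  spec <- list(
    n_modules = assert_count(n_modules, "n_modules"),
    genes_per_module = assert_count(genes_per_module, "genes_per_module"),
    n_background_genes = assert_count(n_background_genes, "n_background_genes", min = 0),
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    within_module_loading = assert_number(within_module_loading,
      "within_module_loading", lower = 0, upper = 1, strict_lower = TRUE),
    loading_jitter = assert_number(loading_jitter, "loading_jitter", lower = 0, upper = 1),
    trait_effect = assert_number(trait_effect, "trait_effect"),
    noise_sd = assert_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE),
    trait_module = assert_count(trait_module, "trait_module"),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (spec$trait_module > spec$n_modules) {
    stop_invalid("`trait_module` must index one of the planted modules")
  }
  structure(spec, class = "module_plant_spec")
}

#' Generate case/control bulk expression with planted modules
#'
#' @param spec A [module_plant_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{expr}{genes x samples numeric matrix.}
#'     \item{trait}{named 0/1 vector aligned to samples (1 = case).}
#'     \item{truth}{list: `module` (gene -> `"module_<m>"` or `"background"`),
#'       `loadings` (named per-gene true loadings; 0 for background),
#'       `trait_module` label, `factors` (samples x modules latent factors),
#'       and `top_loading_genes` (per module, genes ordered by true loading).}
#'   }
#' @export
generate_bulk_expression <- function(spec) {
  if (!inherits(spec, "module_plant_spec")) {
    stop_invalid("`spec` must be a module_plant_spec")
  }
  n_mod_genes <- spec$n_modules * spec$genes_per_module
  n_genes <- n_mod_genes + spec$n_background_genes
  n_samples <- spec$n_cases + spec$n_controls
  genes <- synthetic_gene_symbols(n_genes)
  samples <- sprintf("S%04d", seq_len(n_samples))
  trait <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  names(trait) <- samples

  module_of <- c(
    rep(sprintf("module_%d", seq_len(spec$n_modules)), each = spec$genes_per_module),
    rep("background", spec$n_background_genes)
  )
  names(module_of) <- genes

  with_rng(spec$seed, {
    f <- matrix(stats::rnorm(n_samples * spec$n_modules), n_samples, spec$n_modules,
                dimnames = list(samples, sprintf("module_%d", seq_len(spec$n_modules))))
    f[, spec$trait_module] <- f[, spec$trait_module] + spec$trait_effect * trait
    loadings <- stats::runif(
      n_mod_genes,
      spec$within_module_loading - spec$loading_jitter,
      spec$within_module_loading + spec$loading_jitter
    )
    loadings <- pmin(pmax(loadings, 1e-3), 1)
    loadings <- c(loadings, rep(0, spec$n_background_genes))
    names(loadings) <- genes

    expr <- matrix(stats::rnorm(n_genes * n_samples, sd = spec$noise_sd),
                   n_genes, n_samples, dimnames = list(genes, samples))
    for (m in seq_len(spec$n_modules)) {
      idx <- (m - 1L) * spec$genes_per_module + seq_len(spec$genes_per_module)
      expr[idx, ] <- expr[idx, ] + outer(loadings[idx], f[, m])
    }
  })

  top_loading <- lapply(sprintf("module_%d", seq_len(spec$n_modules)), function(m) {
    g <- names(module_of)[module_of == m]
    g[order(-loadings[g], g)]
  })
  names(top_loading) <- sprintf("module_%d", seq_len(spec$n_modules))

  list(
    expr = expr,
    trait = trait,
    truth = list(
      module = module_of,
      loadings = loadings,
      trait_module = sprintf("module_%d", spec$trait_module),
      factors = f,
      top_loading_genes = top_loading
    )
  )
}

#' Specification of a synthetic scale-free PPI network
#'
#' Preferential-attachment (Barabasi-Albert) graph whose edges carry synthetic
#' combined scores drawn uniformly from an integer range, in the three-column
#' STRING dialect.
#'
#' @param n_nodes Number of nodes.
#' @param edges_per_new_node Attachment parameter m (>= 1, < `n_nodes`).
#' @param score_low,score_high Integer score range within \[0, 1000\].
#' @param seed Generator seed.
#' @return An object of class `network_plant_spec`.
#' @export
network_plant_spec <- function(n_nodes = 500, edges_per_new_node = 2,
                               score_low = 600, score_high = 999, seed = 1) {
  spec <- list(
    n_nodes = assert_count(n_nodes, "n_nodes"),
    edges_per_new_node = assert_count(edges_per_new_node, "edges_per_new_node"),
    score_low = assert_count(score_low, "score_low", min = 0),
    score_high = assert_count(score_high, "score_high", min = 0),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (spec$n_nodes <= spec$edges_per_new_node) {
    stop_invalid("`n_nodes` must exceed `edges_per_new_node`")
  }
  if (spec$score_low > spec$score_high || spec$score_high > 1000) {
    stop_invalid("score range must satisfy 0 <= score_low <= score_high <= 1000")
  }
  structure(spec, class = "network_plant_spec")
}

#' Generate a synthetic PPI edge table (STRING dialect)
#'
#' @param spec A [network_plant_spec()].
#' @param node_symbols Optional node labels (length `n_nodes`); defaults to the
#'   shared synthetic symbol universe so expression and network overlap.
#' @return A data.frame with columns `protein1`, `protein2`, `combined_score`;
#'   each undirected edge appears once.
#' @export
generate_ppi_network <- function(spec, node_symbols = NULL) {
  if (!inherits(spec, "network_plant_spec")) {
    stop_invalid("`spec` must be a network_plant_spec")
  }
  if (is.null(node_symbols)) {
    node_symbols <- synthetic_gene_symbols(spec$n_nodes)
  }
  if (length(node_symbols) != spec$n_nodes || anyDuplicated(node_symbols)) {
    stop_invalid("`node_symbols` must be `n_nodes` unique labels")
  }
  with_rng(spec$seed, {
    g <- igraph::sample_pa(spec$n_nodes, power = 1,
                           m = spec$edges_per_new_node, directed = FALSE)
    g <- igraph::simplify(g)
    ends <- igraph::as_edgelist(g, names = FALSE)
    scores <- sample(seq(spec$score_low, spec$score_high),
                     nrow(ends), replace = TRUE)
  })
  data.frame(
    protein1 = node_symbols[ends[, 1]],
    protein2 = node_symbols[ends[, 2]],
    combined_score = as.integer(scores),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic drug-target table
#'
#' Null drugs draw targets uniformly from network nodes; planted drugs draw
#' targets only from nodes within `planting_radius` hops of designated hub
#' nodes. Every target carries a Gaussian pChEMBL draw.
#'
#' @param n_null_drugs,n_planted_drugs Drug counts (>= 0).
#' @param targets_per_drug Length-2 integer vector `c(min, max)` targets per drug.
#' @param planting_radius Hop radius around hubs for planted drugs (>= 0).
#' @param pchembl_mean,pchembl_sd Gaussian potency parameters.
#' @param seed Generator seed.
#' @return An object of class `drug_plant_spec`.
#' @export
drug_plant_spec <- function(n_null_drugs = 180, n_planted_drugs = 20,
                            targets_per_drug = c(5, 50), planting_radius = 1,
                            pchembl_mean = 7, pchembl_sd = 1, seed = 1) {
  if (length(targets_per_drug) != 2) {
    stop_invalid("`targets_per_drug` must be c(min, max)")
  }
  spec <- list(
    n_null_drugs = assert_count(n_null_drugs, "n_null_drugs", min = 0),
    n_planted_drugs = assert_count(n_planted_drugs, "n_planted_drugs", min = 0),
    targets_min = assert_count(targets_per_drug[1], "targets_per_drug[1]"),
    targets_max = assert_count(targets_per_drug[2], "targets_per_drug[2]"),
    planting_radius = assert_count(planting_radius, "planting_radius", min = 0),
    pchembl_mean = assert_number(pchembl_mean, "pchembl_mean"),
    pchembl_sd = assert_number(pchembl_sd, "pchembl_sd", lower = 0),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (spec$targets_min > spec$targets_max) {
    stop_invalid("`targets_per_drug` must satisfy min <= max")
  }
  structure(spec, class = "drug_plant_spec")
}

#' Generate a synthetic drug-target table with planted proximal drugs
#'
#' @param spec A [drug_plant_spec()].
#' @param edges PPI edge table (STRING dialect data.frame) or an igraph object.
#' @param hub_nodes Node labels around which planted drugs draw their targets.
#' @return A list: `drugs` (data.frame `drug_id`, `drug_name`, `target_symbol`,
#'   `pchembl`) and `truth` (named logical, TRUE for planted drugs).
#' @export
generate_drug_table <- function(spec, edges, hub_nodes) {
  if (!inherits(spec, "drug_plant_spec")) {
    stop_invalid("`spec` must be a drug_plant_spec")
  }
  g <- if (inherits(edges, "igraph")) {
    edges
  } else {
    igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  }
  nodes <- igraph::V(g)$name
  missing <- setdiff(hub_nodes, nodes)
  if (length(missing) > 0) {
    stop_invalid("hub nodes absent from the network: ",
                 paste(missing, collapse = ", "))
  }
  eligible <- unique(names(unlist(
    igraph::ego(g, order = spec$planting_radius, nodes = hub_nodes)
  )))
  if (length(eligible) == 0) {
    stop_invalid("empty eligible neighborhood around hubs: ",
                 paste(hub_nodes, collapse = ", "))
  }
  eligible <- sort(eligible)

  n_drugs <- spec$n_null_drugs + spec$n_planted_drugs
  planted <- c(rep(FALSE, spec$n_null_drugs), rep(TRUE, spec$n_planted_drugs))
  ids <- sprintf("DRUG%04d", seq_len(n_drugs))
  names(planted) <- ids

  rows <- with_rng(spec$seed, {
    lapply(seq_len(n_drugs), function(i) {
      pool <- if (planted[i]) eligible else nodes
      k <- sample(seq(spec$targets_min, spec$targets_max), 1)
      k <- min(k, length(pool))
      targets <- sample(pool, k)
      data.frame(
        drug_id = ids[i],
        drug_name = sprintf("compound_%04d", i),
        target_symbol = targets,
        pchembl = round(stats::rnorm(k, spec$pchembl_mean, spec$pchembl_sd), 3),
        stringsAsFactors = FALSE
      )
    })
  })
  list(drugs = do.call(rbind, rows), truth = planted)
}

#' Specification of a cell-type-structured count matrix
#'
#' Negative-binomial counts with log-normal per-cell library-size factors.
#' Module genes are up-regulated by `module_shift` in one designated
#' module-active subtype, and additionally in cells from case samples.
#'
#' @param cell_types Named integer vector: cells per cell type / subtype
#'   (at least 2 types).
#' @param active_type Name of the module-active subtype (must be one of
#'   `names(cell_types)`).
#' @param n_samples Number of samples cells are drawn from; the first half are
#'   cases, the rest controls.
#' @param n_genes Total gene universe of the count matrix (module genes are a
#'   subset).
#' @param nb_dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   the per-cell library-size factor.
#' @param module_shift Multiplicative up-regulation of module genes (> 0;
#'   1 = no planted effect).
#' @param seed Generator seed.
#' @return An object of class `cell_population_spec`.
#' @export
cell_population_spec <- function(cell_types = c(Mic0 = 500, Mic1 = 500,
                                                Mic2 = 500, Mic3 = 500),
                                 active_type = "Mic1", n_samples = 8,
                                 n_genes = 300, nb_dispersion = 0.5,
                                 library_size_log_mean = 0,
                                 library_size_log_sd = 0.3,
                                 module_shift = 1, seed = 1) {
  if (length(cell_types) < 2 || is.null(names(cell_types)) ||
      anyDuplicated(names(cell_types))) {
    stop_invalid("`cell_types` must be >= 2 uniquely named counts")
  }
  for (i in seq_along(cell_types)) assert_count(cell_types[[i]], "cell_types[i]")
  if (!active_type %in% names(cell_types)) {
    stop_invalid("`active_type` must be one of names(cell_types)")
  }
  spec <- list(
    cell_types = vapply(cell_types, as.integer, integer(1)),
    active_type = active_type,
    n_samples = assert_count(n_samples, "n_samples", min = 2),
    n_genes = assert_count(n_genes, "n_genes"),
    nb_dispersion = assert_number(nb_dispersion, "nb_dispersion",
                                  lower = 0, strict_lower = TRUE),
    library_size_log_mean = assert_number(library_size_log_mean, "library_size_log_mean"),
    library_size_log_sd = assert_number(library_size_log_sd, "library_size_log_sd", lower = 0),
    module_shift = assert_number(module_shift, "module_shift",
                                 lower = 0, strict_lower = TRUE),
    seed = assert_count(seed, "seed", min = 0)
  )
  structure(spec, class = "cell_population_spec")
}

#' Generate cell-type-structured negative-binomial counts
#'
#' @param spec A [cell_population_spec()].
#' @param module_genes Nonempty character vector of planted-module genes; they
#'   are placed inside the matrix's gene universe.
#' @return A list: `counts` (sparse dgCMatrix genes x cells),
#'   `annotations` (data.frame `cell`, `cell_type`, `sample`, `group`).
#' @export
generate_counts <- function(spec, module_genes) {
  if (!inherits(spec, "cell_population_spec")) {
    stop_invalid("`spec` must be a cell_population_spec")
  }
  if (length(module_genes) == 0) stop_invalid("`module_genes` must be nonempty")
  module_genes <- unique(module_genes)
  if (length(module_genes) > spec$n_genes) {
    stop_invalid("`n_genes` must be >= length(module_genes)")
  }
  extra <- setdiff(
    synthetic_gene_symbols(spec$n_genes + length(module_genes), prefix = "CG"),
    module_genes
  )[seq_len(spec$n_genes - length(module_genes))]
  genes <- c(module_genes, extra)

  n_cells <- sum(spec$cell_types)
  cell_type <- rep(names(spec$cell_types), spec$cell_types)
  cells <- sprintf("CELL%05d", seq_len(n_cells))
  samples <- sprintf("SAMP%02d", seq_len(spec$n_samples))
  case_samples <- samples[seq_len(ceiling(spec$n_samples / 2))]

  with_rng(spec$seed, {
    cell_sample <- sample(samples, n_cells, replace = TRUE)
    is_case <- cell_sample %in% case_samples
    base_mean <- exp(stats::rnorm(spec$n_genes, mean = log(0.5), sd = 1))
    lib <- exp(stats::rnorm(n_cells, spec$library_size_log_mean,
                            spec$library_size_log_sd))
    shift <- matrix(1, spec$n_genes, n_cells)
    mod_idx <- seq_along(module_genes)
    shift[mod_idx, cell_type == spec$active_type] <- spec$module_shift
    shift[mod_idx, is_case] <- shift[mod_idx, is_case] * spec$module_shift
    mu <- (base_mean * shift) * rep(lib, each = spec$n_genes)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / spec$nb_dispersion),
      spec$n_genes, n_cells, dimnames = list(genes, cells)
    )
  })

  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    annotations = data.frame(
      cell = cells,
      cell_type = cell_type,
      sample = cell_sample,
      group = ifelse(cell_sample %in% case_samples, "case", "control"),
      stringsAsFactors = FALSE
    )
  )
}

#' Generate a synthetic pathway collection (GMT-style list)
#'
#' One planted pathway per true module (its member genes) plus random gene
#' sets from the universe; exercises over-representation analysis with known
#' ground truth.
#'
#' @param truth Truth component of [generate_bulk_expression()].
#' @param universe Gene universe to draw random pathways from.
#' @param n_random Number of random pathways.
#' @param random_size Size range of random pathways.
#' @param seed Seed.
#' @return Named list of character vectors.
#' @export
generate_pathways <- function(truth, universe, n_random = 20,
                              random_size = c(20, 60), seed = 1) {
  modules <- setdiff(unique(truth$module), "background")
  planted <- lapply(modules, function(m) names(truth$module)[truth$module == m])
  names(planted) <- paste0("planted_", modules)
  random <- with_rng(seed, {
    lapply(seq_len(n_random), function(i) {
      sample(universe, sample(seq(random_size[1], random_size[2]), 1))
    })
  })
  names(random) <- sprintf("random_pathway_%02d", seq_len(n_random))
  c(planted, random)
}
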