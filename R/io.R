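# Plain-text readers/writers for the pipeline's interchange formats:
# expression/trait TSV, GMT gene sets, STRING-dialect edge lists,
# drug-target tables and MTX count triplets.

#' Write / read a genes x samples expression matrix as TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param expr Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return `read_expression_tsv` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  assert_matrix_like(expr, "expr")
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene") {
    stop_invalid("expression TSV must have a leading `gene` column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  assert_matrix_like(m, "expression matrix")
  m
}

#' Write / read a per-sample binary trait vector as TSV
#'
#' Columns `sample`, `trait` (1 = case, 0 = control).
#'
#' @param trait Named 0/1 vector.
#' @param path File path.
#' @return `read_trait_tsv` returns a named integer vector.
#' @export
write_trait_tsv <- function(trait, path) {
  utils::write.table(
    data.frame(sample = names(trait), trait = as.integer(trait)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trait_tsv
#' @export
read_trait_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- as.integer(df$trait)
  names(out) <- df$sample
  if (!all(out %in% c(0L, 1L))) stop_invalid("trait values must be 0/1")
  out
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @return `read_gmt` returns a named list of unique gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop_invalid("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a STRING-dialect PPI edge table
#'
#' Columns `protein1`, `protein2`, `combined_score`.
#'
#' @param edges Data.frame in the STRING dialect.
#' @param path File path.
#' @export
write_string_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a drug-target table
#'
#' Columns `drug_id`, `drug_name`, `target_symbol`, `pchembl`.
#'
#' @param drugs Data.frame with the four columns above.
#' @param path File path.
#' @export
write_drug_table <- function(drugs, path) {
  keep <- c("drug_id", "drug_name", "target_symbol", "pchembl")
  utils::write.table(drugs[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_drug_table
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "target_symbol", "pchembl")
  if (!all(need %in% names(df))) {
    stop_invalid("drug table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write / read sparse counts as MTX plus label files
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and (optionally)
#' `annotations.tsv` into `dir`.
#'
#' @param counts Sparse genes x cells matrix.
#' @param dir Output directory.
#' @param annotations Optional per-cell annotation data.frame.
#' @return `read_counts_mtx` returns `list(counts, annotations)`.
#' @export
write_counts_mtx <- function(counts, dir, annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(annotations)) {
    utils::write.table(annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) {
    utils::read.delim(ann_path, stringsAsFactors = FALSE)
  }
  list(counts = counts, annotations = annotations)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
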