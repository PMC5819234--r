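#' Read a gene expression matrix from a tab-separated file
#'
#' The file must have genes as rows and samples as columns: the first column
#' holds gene identifiers and the header row holds sample identifiers.
#' Gene identifiers are opaque, case-sensitive strings; no symbol mapping is
#' attempted. Duplicate gene rows are collapsed by keeping the row with the
#' highest mean expression (a message reports how many rows were dropped).
#' Missing or non-numeric cells are rejected rather than imputed, because
#' silent imputation would change downstream correlations.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression matrix must have at least 2 samples")
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("non-numeric or missing expression value '%s' at gene '%s', sample '%s'",
                 vals[i, j], genes[i], colnames(vals)[j]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  if (anyDuplicated(genes)) {
    means <- rowMeans(num)
    # keep the highest-mean row per duplicated id (probe-collapse convention)
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    dropped <- nrow(num) - length(keep)
    num <- num[sort(keep), , drop = FALSE]
    message(sprintf("collapsed %d duplicate gene row(s), keeping highest-mean rows", dropped))
  }
  validate_expression(num)
  num
}

#' Validate an expression matrix
#'
#' Checks the container invariants assumed throughout the pipeline: unique
#' gene and sample identifiers, all-finite numeric values, and at least two
#' genes and two samples.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @return The matrix, invisibly.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (nrow(expr) < 2L) stop("expression matrix must have at least 2 genes")
  if (ncol(expr) < 2L) stop("expression matrix must have at least 2 samples")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (!all(is.finite(expr))) stop("expression matrix contains non-finite values")
  invisible(expr)
}

#' Read a sample annotation table
#'
#' Two-column tab-separated file with a header: sample id and phenotype
#' class. Every annotated sample must be present in the expression matrix
#' when one is supplied; unannotated expression samples are allowed (they are
#' simply excluded from GSEA).
#'
#' @param path Path to a tab-separated file with columns sample, class.
#' @param expr Optional expression matrix used for referential validation.
#' @return A data.frame with columns `sample_id` and `class_label`.
#' @export
read_annotation <- function(path, expr = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation file needs two columns: sample, class")
  ann <- data.frame(sample_id = df[[1L]], class_label = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotation")
  if (!is.null(expr)) {
    missing <- setdiff(ann$sample_id, colnames(expr))
    if (length(missing) > 0L)
      stop("annotated sample(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
  }
  ann
}

#' Read a gene set collection in GMT format
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`. Member lists
#' are deduplicated and empty trailing fields dropped.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids; each element
#'   carries its description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    name <- fields[[1L]]
    if (name %in% names(sets))
      stop("duplicate gene set name in GMT: ", name)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("GMT line %d ('%s') has no genes", i, name))
    attr(genes, "description") <- fields[[2L]]
    sets[[name]] <- genes
  }
  sets
}

#' Write a module assignment as a GMT gene set collection
#'
#' @param assignment Named character vector, gene id -> module label.
#' @param path Output file path.
#' @param include_uncorrelated Write the "Uncorrelated" pseudo-module too.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(assignment, path, include_uncorrelated = TRUE) {
  labs <- module_labels(assignment, include_uncorrelated = include_uncorrelated)
  lines <- vapply(labs, function(m) {
    genes <- sort(names(assignment)[assignment == m])
    paste(c(m, m, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-gene interaction edge list
#'
#' At least two tab-separated columns; the first two are gene identifiers.
#' A header line is auto-detected: when gene ids from the expression matrix
#' are supplied and neither field of the first row matches any of them, the
#' first row is treated as a header (the decision is reported). Self-loops
#' are removed and duplicate edges collapsed regardless of endpoint order.
#'
#' @param path Path to the interaction file.
#' @param known_genes Optional character vector of gene ids for header
#'   auto-detection.
#' @return A data.frame with character columns `gene_a`, `gene_b`
#'   (undirected, deduplicated edges).
#' @export
read_interactions <- function(path, known_genes = NULL) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("interaction file is empty; continuing without interactions")
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short) > 0L)
    stop(sprintf("interaction file line %d has fewer than 2 columns", short[1L]))
  first <- fields[[1L]]
  has_header <- FALSE
  if (!is.null(known_genes) && length(lines) > 1L) {
    has_header <- !(first[[1L]] %in% known_genes) && !(first[[2L]] %in% known_genes)
    if (has_header)
      message(sprintf("treating interaction file first row ('%s', '%s') as a header",
                      first[[1L]], first[[2L]]))
  }
  if (has_header) fields <- fields[-1L]
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  data.frame(gene_a = lo[!dup], gene_b = hi[!dup], stringsAsFactors = FALSE)
}

module_labels <- function(assignment, include_uncorrelated = FALSE) {
  labs <- unique(assignment)
  named <- labs[labs != "Uncorrelated"]
  # M1...Mk by numeric suffix
  named <- named[order(as.integer(sub("^M", "", named)))]
  if (include_uncorrelated && "Uncorrelated" %in% labs) c(named, "Uncorrelated") else named
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write all pipeline products to a directory
#'
#' Emits, depending on which stages ran: the gene-to-module assignment TSV,
#' the modules as a GMT collection, the beta-curve TSV, the gene filter TSV,
#' ORA and GSEA TSVs, the adjacency-based hub TSV, per-module interaction
#' node/edge TSVs, and a JSON run summary (selected beta, scale-free fit,
#' phi, module count, parameters, seed). Output is deterministic: fixed
#' column order and row ordering, no timestamps.
#'
#' @param result A pipeline result list, as produced by [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of file paths written (the manifest), invisibly
#'   also saved as `manifest.json`.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  files <- character()
  add <- function(name) files <<- c(files, name)

  if (!is.null(result$filter)) {
    write_tsv(result$filter$table, file.path(out_dir, "gene_filter.tsv"))
    add("gene_filter.tsv")
  }
  if (!is.null(result$beta_curve)) {
    write_tsv(result$beta_curve$points, file.path(out_dir, "beta_curve.tsv"))
    add("beta_curve.tsv")
  }
  if (!is.null(result$assignment)) {
    adf <- data.frame(gene = names(result$assignment),
                      module = unname(result$assignment),
                      stringsAsFactors = FALSE)
    adf <- adf[order(adf$module, adf$gene), ]
    write_tsv(adf, file.path(out_dir, "module_assignment.tsv"))
    add("module_assignment.tsv")
    write_gmt(result$assignment, file.path(out_dir, "modules.gmt"))
    add("modules.gmt")
  }
  if (!is.null(result$ora)) {
    write_tsv(result$ora, file.path(out_dir, "ora.tsv")); add("ora.tsv")
  }
  if (!is.null(result$gsea)) {
    write_tsv(result$gsea, file.path(out_dir, "gsea.tsv")); add("gsea.tsv")
  }
  if (!is.null(result$hubs)) {
    write_tsv(result$hubs, file.path(out_dir, "hubs.tsv")); add("hubs.tsv")
  }
  if (!is.null(result$module_graphs)) {
    nodes <- do.call(rbind, lapply(result$module_graphs, `[[`, "nodes"))
    edges <- do.call(rbind, lapply(result$module_graphs, `[[`, "edges"))
    write_tsv(nodes, file.path(out_dir, "interaction_nodes.tsv"))
    write_tsv(edges, file.path(out_dir, "interaction_edges.tsv"))
    add("interaction_nodes.tsv"); add("interaction_edges.tsv")
  }

  summary <- result$summary
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  add("summary.json")

  jsonlite::write_json(as.list(files), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  add("manifest.json")
  invisible(files)
}
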