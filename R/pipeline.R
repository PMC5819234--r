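#' Run the full co-expression module discovery pipeline
#'
#' Orchestrates every stage from a single expression matrix: optional
#' variance-stabilizing transformation, inverse-gamma variance filtering,
#' automatic soft-threshold selection, topological overlap, module
#' detection, and — as the optional inputs allow — over-representation
#' analysis, gene set enrichment analysis across phenotype classes, and
#' per-module interaction subnetworks. Skipped optional stages are logged,
#' never fatal; a run that finds no modules is still a valid run.
#'
#' @param expr Expression matrix (genes x samples) or path to a TSV file.
#' @param annotation Optional sample annotation (data.frame or TSV path);
#'   enables GSEA.
#' @param gene_sets Optional gene set collection (named list or GMT path);
#'   enables ORA.
#' @param interactions Optional interaction table (data.frame or TSV path);
#'   enables module interaction graphs.
#' @param out_dir Optional output directory; when given, all tables, the
#'   JSON summary and (unless `report = FALSE`) the HTML report are written.
#' @param filter_pval,low_mean_fraction Gene filter parameters (defaults
#'   0.1 and 0.25).
#' @param apply_vst Apply the NB variance-stabilizing transformation first
#'   (default FALSE; requires count-like non-negative data).
#' @param beta_grid,tau,epsilon,network_type,cor_method Soft-threshold
#'   selection parameters (defaults 1:20, 0.8, 0.1, "unsigned", "pearson").
#' @param force_beta Integer fallback power. Consulted when the
#'   stabilization criterion selects no beta (or always, if
#'   `force_beta_always = TRUE`); without it an unresolvable beta aborts the
#'   run.
#' @param force_beta_always Use `force_beta` unconditionally.
#' @param min_module_size Minimum module size (default 20).
#' @param merge_modules Merge modules with correlated eigengenes (default
#'   FALSE).
#' @param merge_threshold Eigengene correlation for merging (default 0.8).
#' @param n_perm GSEA permutations (default 1000).
#' @param seed Integer seed, required when GSEA runs; recorded in the
#'   summary.
#' @param report Render the HTML report when `out_dir` is given (default
#'   TRUE).
#' @param verbose Print progress messages.
#' @return List of class `coex_result`: `filter`, `beta_curve`,
#'   `assignment`, `eigengenes`, `hubs`, `ora`, `gsea`, `ces`,
#'   `module_graphs`, `summary`, plus `expr_filtered`.
#' @export
run_pipeline <- function(expr,
                         annotation = NULL, gene_sets = NULL, interactions = NULL,
                         out_dir = NULL,
                         filter_pval = 0.1, low_mean_fraction = 0.25,
                         apply_vst = FALSE,
                         beta_grid = 1:20, tau = 0.8, epsilon = 0.1,
                         network_type = "unsigned", cor_method = "pearson",
                         force_beta = NULL, force_beta_always = FALSE,
                         min_module_size = 20,
                         merge_modules = FALSE, merge_threshold = 0.8,
                         n_perm = 1000, seed = NULL,
                         report = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  if (is.character(expr)) expr <- read_expression(expr)
  validate_expression(expr)
  if (is.character(annotation)) annotation <- read_annotation(annotation, expr)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(interactions))
    interactions <- read_interactions(interactions, rownames(expr))

  vst_alpha <- NULL
  if (apply_vst) {
    say("applying variance-stabilizing transformation")
    expr <- coexmod::apply_vst(expr)
    vst_alpha <- attr(expr, "alpha")
    say(sprintf("  estimated dispersion alpha = %.4f", vst_alpha))
  }

  say("filtering genes (inverse-gamma variance model)")
  filt <- filter_genes(expr, filter_pval = filter_pval,
                       low_mean_fraction = low_mean_fraction)
  say(sprintf("  %d / %d genes selected", length(filt$selected), nrow(expr)))
  if (length(filt$selected) < max(3L, min_module_size))
    stop("too few genes pass the variance filter; relax --filter-pval")
  expr_f <- expr[filt$selected, , drop = FALSE]

  say("selecting soft-threshold beta")
  curve <- beta_curve(expr_f, beta_grid = beta_grid, tau = tau,
                      epsilon = epsilon, network_type = network_type,
                      cor_method = cor_method)
  beta <- curve$selected_beta
  beta_forced <- FALSE
  if (force_beta_always && !is.null(force_beta)) {
    beta <- as.integer(force_beta); beta_forced <- TRUE
  } else if (is.na(beta)) {
    if (!is.null(force_beta)) {
      beta <- as.integer(force_beta); beta_forced <- TRUE
      warning("no beta satisfied the stabilization criterion; using forced beta ",
              beta)
    } else {
      diag_df <- attr(curve$selected_beta, "diagnostic")
      stop("no beta satisfies the stabilization criterion ",
           "(max r2 = ", signif(max(curve$points$r2), 3),
           "); rerun with force_beta to override")
    }
  }
  say(sprintf("  beta = %d (phi = %.3f)", beta, curve$phi))

  adjacency <- correlation_adjacency(expr_f, beta = beta,
                                     network_type = network_type,
                                     cor_method = cor_method)
  say("computing topological overlap and clustering")
  tom <- tom_similarity(adjacency)
  dendro <- cluster_genes(tom)
  assignment <- cut_modules(dendro, 1 - tom, min_module_size = min_module_size)
  if (merge_modules && length(module_labels(assignment)) >= 2L)
    assignment <- merge_similar(expr_f, assignment,
                                merge_threshold = merge_threshold)
  mods <- module_labels(assignment)
  say(sprintf("  %d module(s) detected", length(mods)))

  eigengenes <- if (length(mods) > 0L) module_eigengenes(expr_f, assignment) else NULL
  hubs <- if (length(mods) > 0L) hub_genes(adjacency, assignment) else NULL

  ora_rows <- NULL; ces <- NULL
  if (!is.null(gene_sets) && length(mods) > 0L) {
    say("over-representation analysis")
    ora_rows <- ora(assignment, gene_sets, universe = rownames(expr_f))
    ces <- combined_enrichment_score(ora_rows, modules = mods)
  } else say("ORA skipped (no gene sets or no modules)")

  gsea_rows <- NULL
  if (!is.null(annotation) && length(mods) > 0L) {
    if (is.null(seed)) stop("GSEA requires a seed")
    say("gene set enrichment analysis across classes")
    rankings <- class_rankings(expr_f, annotation)
    gsea_rows <- gsea(rankings, assignment, n_perm = n_perm, seed = seed)
  } else say("GSEA skipped (no annotation or no modules)")

  graphs <- NULL
  if (!is.null(interactions) && length(mods) > 0L) {
    say("building module interaction graphs")
    graphs <- module_interaction_graph(assignment, interactions)
  } else say("interaction graphs skipped (no interactions or no modules)")

  summary <- list(
    n_genes_input = nrow(expr), n_samples = ncol(expr),
    n_genes_filtered = length(filt$selected),
    vst_alpha = vst_alpha,
    filter_pval = filter_pval, low_mean_fraction = low_mean_fraction,
    inverse_gamma_shape = filt$shape, inverse_gamma_scale = filt$scale,
    selected_beta = beta, beta_forced = beta_forced,
    r2_at_beta = curve$points$r2[match(beta, curve$points$beta)],
    phi = curve$phi, tau = tau, epsilon = epsilon,
    network_type = network_type, cor_method = cor_method,
    min_module_size = min_module_size,
    merge_modules = merge_modules,
    n_modules = length(mods),
    module_sizes = as.list(stats::setNames(
      vapply(mods, function(m) sum(assignment == m), integer(1)), mods)),
    n_uncorrelated = sum(assignment == "Uncorrelated"),
    ces = if (!is.null(ces)) ces$ces else NULL,
    n_perm = if (!is.null(gsea_rows)) n_perm else NULL,
    seed = seed)

  result <- structure(list(filter = filt, beta_curve = curve,
                           assignment = assignment, eigengenes = eigengenes,
                           hubs = hubs, ora = ora_rows, gsea = gsea_rows,
                           ces = ces, module_graphs = graphs,
                           summary = summary, expr_filtered = expr_f,
                           annotation = annotation),
                      class = "coex_result")

  if (!is.null(out_dir)) {
    say("writing results to ", out_dir)
    write_results(result, out_dir)
    if (report) render_report(result, out_dir)
  }
  result
}

#' @export
print.coex_result <- function(x, ...) {
  s <- x$summary
  cat("Co-expression module analysis\n")
  cat(sprintf("  genes: %d input, %d after filtering; samples: %d\n",
              s$n_genes_input, s$n_genes_filtered, s$n_samples))
  cat(sprintf("  soft-threshold beta = %d (R2 = %.3f, phi = %.3f)%s\n",
              s$selected_beta, s$r2_at_beta, s$phi,
              if (isTRUE(s$beta_forced)) " [forced]" else ""))
  cat(sprintf("  modules: %d named, %d genes uncorrelated\n",
              s$n_modules, s$n_uncorrelated))
  if (!is.null(s$ces)) cat(sprintf("  combined enrichment score: %.4g\n", s$ces))
  invisible(x)
}
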