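#' Over-representation analysis of modules against gene sets
#'
#' For each (module, gene set) pair, the upper-tail hypergeometric
#' probability of observing at least the witnessed overlap when `|module|`
#' genes are drawn without replacement from the universe of filtered genes,
#' of which `|set|` belong to the set. Gene sets are intersected with the
#' universe first; sets with empty intersection are skipped (with a
#' message). P-values are Benjamini-Hochberg adjusted within each module
#' across its gene sets, matching per-module enrichment bar plots. The
#' "Uncorrelated" pseudo-module is excluded.
#'
#' @param assignment Module assignment.
#' @param gene_sets Named list of gene id vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of gene ids (the filtered genes).
#' @return data.frame of class rows: module, gene_set, overlap, module_size,
#'   set_size, universe_size, p, p_adjust; sorted by module then adjusted p.
#' @export
ora <- function(assignment, gene_sets, universe) {
  mods <- module_labels(assignment)
  universe <- unique(universe)
  n_univ <- length(universe)
  sets <- lapply(gene_sets, intersect, universe)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty) > 0L) {
    message("gene set(s) with no universe overlap skipped: ",
            paste(empty, collapse = ", "))
    sets <- sets[lengths(sets) > 0L]
  }
  rows <- lapply(mods, function(m) {
    members <- intersect(names(assignment)[assignment == m], universe)
    df <- data.frame(
      module = m,
      gene_set = names(sets),
      overlap = vapply(sets, function(s) length(intersect(members, s)), integer(1)),
      module_size = length(members),
      set_size = lengths(sets),
      universe_size = n_univ,
      stringsAsFactors = FALSE, row.names = NULL)
    # P(X >= overlap), X ~ Hypergeometric(set_size successes, module_size draws)
    df$p <- stats::phyper(df$overlap - 1L, df$set_size,
                          n_univ - df$set_size, df$module_size,
                          lower.tail = FALSE)
    df$p_adjust <- stats::p.adjust(df$p, method = "BH")
    df[order(df$p_adjust, df$p, df$gene_set), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class gene scores from z-normalized expression
#'
#' Each gene is z-scored across all samples (mean 0, sd 1), then each
#' phenotype class gets one score per gene: the mean z over that class's
#' samples. Within a class, genes ordered by decreasing score form the
#' ranking used by [gsea()]. Because z-scores sum to zero over all samples,
#' the class-size-weighted mean of a gene's class scores is always zero: a
#' module elevated in one class is necessarily depressed in the others.
#'
#' @param expr Expression matrix restricted to the filtered genes.
#' @param annotation data.frame with `sample_id`, `class_label` (see
#'   [read_annotation()]).
#' @return Named list: class label -> named numeric vector of gene scores,
#'   sorted decreasing.
#' @export
class_rankings <- function(expr, annotation) {
  validate_expression(expr)
  annotation <- annotation[annotation$sample_id %in% colnames(expr), , drop = FALSE]
  z <- t(scale(t(expr)))
  z[!is.finite(z)] <- 0
  classes <- unique(annotation$class_label)
  out <- list()
  for (cl in classes) {
    samples <- annotation$sample_id[annotation$class_label == cl]
    if (length(samples) == 0L) {
      warning("class with no samples excluded: ", cl)
      next
    }
    score <- rowMeans(z[, samples, drop = FALSE])
    out[[cl]] <- sort(score, decreasing = TRUE)
  }
  out
}

# Weighted Kolmogorov-Smirnov enrichment score for one gene set against one
# decreasing-sorted score vector. Hit steps are proportional to |score|
# (weight exponent 1), miss steps are 1/(N - N_hit). The ES is the running
# sum's maximum deviation from zero (signed).
enrichment_score <- function(scores, hit_index) {
  n <- length(scores)
  n_hit <- length(hit_index)
  if (n_hit == 0L) return(0)
  if (n_hit >= n) stop("gene set must be a proper subset of the ranking")
  is_hit <- logical(n)
  is_hit[hit_index] <- TRUE
  w <- abs(scores)
  denom_hit <- sum(w[is_hit])
  steps <- ifelse(is_hit,
                  if (denom_hit > 0) w / denom_hit else 1 / n_hit,
                  -1 / (n - n_hit))
  if (denom_hit == 0) steps[is_hit] <- 1 / n_hit  # all-zero scores: unweighted KS
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' Gene set enrichment analysis of modules across phenotype classes
#'
#' Preranked GSEA with the co-expression modules as gene sets: for each
#' (module, class), the weighted Kolmogorov-Smirnov enrichment score (ES) of
#' the module genes in the class's score ranking (hit increments
#' proportional to |score|, miss increments 1/(N - N_hit)). The null is
#' built by drawing `n_perm` random gene sets of the same size (gene-label
#' permutation); the nominal p is the fraction of same-sign permuted ES at
#' least as extreme, with a +1 continuity correction, and NES is the ES
#' divided by the mean |permuted ES| of the same sign. BH adjustment is
#' applied across all (module, class) pairs. A positive NES means the
#' module's genes sit atop the class ranking: the module is induced in that
#' class.
#'
#' @param rankings Output of [class_rankings()].
#' @param assignment Module assignment.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation null (required, so runs are
#'   reproducible bit for bit).
#' @return data.frame: module, class, es, nes, p, p_adjust.
#' @export
gsea <- function(rankings, assignment, n_perm = 1000, seed) {
  if (missing(seed)) stop("gsea requires an explicit seed")
  mods <- module_labels(assignment)
  mods <- Filter(function(m) sum(assignment == m) >= 2L, mods)
  if (length(mods) == 0L) stop("no module with >= 2 ranked genes")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rows <- list()
  for (cl in names(rankings)) {
    scores <- rankings[[cl]]
    ranked_genes <- names(scores)
    for (m in mods) {
      members <- intersect(names(assignment)[assignment == m], ranked_genes)
      if (length(members) < 2L) next
      hit <- match(members, ranked_genes)
      es <- enrichment_score(scores, hit)
      perm_es <- vapply(seq_len(n_perm), function(i) {
        enrichment_score(scores, sample.int(length(scores), length(hit)))
      }, numeric(1))
      same <- perm_es[sign(perm_es) == sign(es)]
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, class = cl, es = es, nes = nes, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Combined enrichment score
#'
#' Condenses a run's over-representation results into a single number: per
#' named module take the minimum BH-adjusted ORA p-value (1 when the module
#' has no rows), then take the geometric mean across modules. The lower the
#' CES, the more enriched the modules; 1 means no module is enriched at
#' all. This summary is an approximation chosen for its monotonicity: it
#' strictly decreases whenever any module's best adjusted p-value improves.
#'
#' @param ora_rows Output of [ora()].
#' @param modules Optional character vector of module labels to summarize
#'   (defaults to the modules present in `ora_rows`).
#' @return List: `ces` in (0, 1], `module_minima` (named numeric).
#' @export
combined_enrichment_score <- function(ora_rows, modules = NULL) {
  if (is.null(modules)) modules <- unique(ora_rows$module)
  minima <- vapply(modules, function(m) {
    p <- ora_rows$p_adjust[ora_rows$module == m]
    if (length(p) == 0L) 1 else min(p)
  }, numeric(1))
  list(ces = exp(mean(log(minima))), module_minima = minima)
}
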