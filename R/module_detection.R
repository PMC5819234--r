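#' Hierarchical clustering of genes on topological overlap dissimilarity
#'
#' Average-linkage agglomerative clustering on `1 - TOM`. Deterministic
#' given the input matrix.
#'
#' @param tom TOM similarity matrix.
#' @return An `hclust` dendrogram over the genes.
#' @export
cluster_genes <- function(tom) {
  if (nrow(tom) < 2L) stop("need at least 2 genes to cluster")
  d <- stats::as.dist(1 - tom)
  stats::hclust(d, method = "average")
}

#' Cut a gene dendrogram into co-expression modules
#'
#' An adaptive cut with a silhouette criterion: every distinct merge height
#' of the dendrogram is a candidate (downsampled to at most 120 for large
#' trees), and each candidate partition is scored by the summed silhouette
#' width of the genes inside its qualifying clusters (clusters with at
#' least `min_module_size` members) — for each such gene,
#' `(b - a) / max(a, b)` with `a` the mean dissimilarity to its own cluster
#' and `b` the mean dissimilarity to everything else. The best-scoring
#' height wins: loose agglomerates of uncorrelated genes contribute nothing
#' to the score, so the chosen partition contains exactly the well-separated
#' modules. Genes outside qualifying clusters are labeled "Uncorrelated",
#' then a PAM-like refinement (iterated to a fixed point) reassigns each
#' unlabeled gene to the module minimizing its average dissimilarity,
#' provided the gene's separation margin — its average dissimilarity to the
#' rest of the network minus its average dissimilarity to that module — is
#' at least `margin_frac` of the module members' own median margin. The
#' gate is self-calibrating: genes merely equidistant from everything (the
#' uncorrelated background) have margins near zero and are never absorbed.
#' Final module labels are M1..Mk by decreasing size.
#'
#' @param dendro `hclust` object from [cluster_genes()].
#' @param dissimilarity The `1 - TOM` dissimilarity matrix the dendrogram
#'   was built on.
#' @param min_module_size Minimum genes per named module (default 20).
#' @param margin_frac Fraction of the median member margin an unlabeled
#'   gene must reach to join a module (default 0.25).
#' @return Named character vector of class `coex_assignment`: gene id ->
#'   module label ("M1".."Mk" or "Uncorrelated"); attribute `"cut_height"`.
#' @export
cut_modules <- function(dendro, dissimilarity, min_module_size = 20,
                        margin_frac = 0.25) {
  genes <- dendro$labels
  n <- length(genes)
  all_uncorrelated <- function() {
    out <- stats::setNames(rep("Uncorrelated", n), genes)
    structure(out, class = "coex_assignment", cut_height = NA_real_)
  }
  if (min_module_size > n) {
    warning("min_module_size exceeds gene count; all genes labeled Uncorrelated")
    return(all_uncorrelated())
  }
  D <- as.matrix(dissimilarity)[genes, genes]
  heights <- sort(unique(dendro$height))
  counts <- vapply(heights, function(h) {
    sum(table(stats::cutree(dendro, h = h)) >= min_module_size)
  }, integer(1))
  if (all(counts == 0L)) {
    warning("no cluster reaches min_module_size; all genes labeled Uncorrelated")
    return(all_uncorrelated())
  }
  cand <- heights[counts >= 1L]
  if (length(cand) > 120L)
    cand <- cand[unique(round(seq(1L, length(cand), length.out = 120L)))]
  row_tot <- rowSums(D)
  best_q <- -Inf; best_h <- cand[1L]
  for (h in cand) {
    cl <- stats::cutree(dendro, h = h)
    sizes <- table(cl)
    big <- as.integer(names(sizes)[sizes >= max(min_module_size, 2L) &
                                     sizes < n])
    if (length(big) == 0L) next
    q <- 0
    for (j in big) {
      mem <- cl == j
      sz <- sum(mem)
      within <- rowSums(D[mem, mem, drop = FALSE])
      a <- within / (sz - 1L)
      b <- (row_tot[mem] - within) / (n - sz)
      q <- q + sum((b - a) / pmax(a, b, .Machine$double.eps))
    }
    if (q > best_q) { best_q <- q; best_h <- h }
  }
  best_cl <- stats::cutree(dendro, h = best_h)
  sizes <- table(best_cl)
  keep_ids <- names(sizes)[sizes >= min_module_size]
  labels <- ifelse(best_cl %in% as.integer(keep_ids),
                   paste0("C", best_cl), "Uncorrelated")
  names(labels) <- genes

  labels <- pam_refine(labels, D, margin_frac = margin_frac)
  # refinement may shrink a module below the size floor; such remnants are
  # not modules
  small <- names(which(table(labels[labels != "Uncorrelated"]) < min_module_size))
  labels[labels %in% small] <- "Uncorrelated"
  out <- renumber_modules(labels)
  structure(out, class = "coex_assignment", cut_height = best_h)
}

# Iterated margin-gated refinement, applied symmetrically. A gene's
# separation margin for a module is its average dissimilarity to the rest
# of the network minus its average dissimilarity to that module's members.
# Per iteration: members whose margin falls below margin_frac times the
# module's median member margin are demoted to "Uncorrelated" (they were
# agglomeration accidents), then each unlabeled gene joins its nearest
# module when its margin clears the same threshold. Background genes are
# roughly equidistant from everything, so their margins sit near zero and
# the gate never admits them.
pam_refine <- function(labels, dissimilarity, margin_frac = 0.25,
                       max_iter = 20L) {
  nms <- names(labels)
  for (it in seq_len(max_iter)) {
    mods <- setdiff(unique(labels), "Uncorrelated")
    if (length(mods) == 0L) break
    thr <- vapply(mods, function(m) {
      mem <- nms[labels == m]
      oth <- setdiff(nms, mem)
      d_own <- rowSums(dissimilarity[mem, mem, drop = FALSE]) /
        (length(mem) - 1L)
      d_out <- rowMeans(dissimilarity[mem, oth, drop = FALSE])
      margin_frac * stats::median(d_out - d_own)
    }, numeric(1))
    changed <- FALSE
    for (m in mods) {
      mem <- nms[labels == m]
      if (length(mem) < 3L) next
      d_own <- rowSums(dissimilarity[mem, mem, drop = FALSE]) /
        (length(mem) - 1L)
      d_out <- rowMeans(dissimilarity[mem, setdiff(nms, mem), drop = FALSE])
      weak <- mem[(d_out - d_own) < thr[m]]
      if (length(weak) > 0L) {
        labels[weak] <- "Uncorrelated"
        changed <- TRUE
      }
    }
    mods <- setdiff(unique(labels), "Uncorrelated")
    for (g in nms[labels == "Uncorrelated"]) {
      if (length(mods) == 0L) break
      d_mod <- vapply(mods, function(m)
        mean(dissimilarity[g, nms[labels == m]]), numeric(1))
      best <- which.min(d_mod)
      d_out <- mean(dissimilarity[g, setdiff(nms[labels != mods[best]], g)])
      if (d_out - d_mod[best] > thr[mods[best]]) {
        labels[g] <- mods[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

# Relabel modules M1..Mk by decreasing size (ties by current label order);
# "Uncorrelated" is preserved.
renumber_modules <- function(labels) {
  mods <- setdiff(unique(labels), "Uncorrelated")
  if (length(mods) == 0L) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, match(mods, mods))]
  map <- stats::setNames(paste0("M", seq_along(ord)), ord)
  out <- ifelse(labels == "Uncorrelated", "Uncorrelated", map[labels])
  stats::setNames(unname(out), names(labels))
}

#' Module eigengenes
#'
#' The eigengene of a module is the unit-norm first principal component of
#' the module's standardized expression across samples: one score per
#' sample summarizing the module's activity. The sign is oriented so the
#' eigengene correlates non-negatively with the module's mean expression
#' profile. A single-gene module's eigengene is that gene's standardized
#' profile (unit-normed), with variance explained 1.
#'
#' @param expr Expression matrix covering at least the assigned genes.
#' @param assignment Module assignment from [cut_modules()].
#' @return List per named module: `eigengene` (numeric vector over samples),
#'   `var_explained` in [0, 1].
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- module_labels(assignment)
  if (length(mods) == 0L) stop("no named modules")
  out <- lapply(mods, function(m) {
    members <- names(assignment)[assignment == m]
    x <- expr[members, , drop = FALSE]
    xs <- t(scale(t(x)))                     # standardize each gene
    xs[!is.finite(xs)] <- 0                  # constant genes contribute nothing
    sv <- svd(xs, nu = 0, nv = 1)
    eig <- sv$v[, 1L]
    ve <- sv$d[1L]^2 / sum(sv$d^2)
    mean_prof <- colMeans(xs)
    if (sum(eig * mean_prof) < 0) eig <- -eig
    names(eig) <- colnames(expr)
    list(eigengene = eig, var_explained = ve)
  })
  stats::setNames(out, mods)
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair whose eigengene correlation is highest,
#' as long as it strictly exceeds `merge_threshold`, recomputing eigengenes
#' after each merge. Never increases the module count and is idempotent once
#' no pair exceeds the threshold. Off by default in the pipeline.
#'
#' @param expr Expression matrix.
#' @param assignment Module assignment.
#' @param merge_threshold Eigengene correlation above which two modules are
#'   considered the same (default 0.8; threshold 1 never merges).
#' @return Updated assignment, relabeled by size.
#' @export
merge_similar <- function(expr, assignment, merge_threshold = 0.8) {
  labels <- stats::setNames(as.character(assignment), names(assignment))
  repeat {
    mods <- setdiff(unique(labels), "Uncorrelated")
    if (length(mods) < 2L) break
    eg <- module_eigengenes(expr, structure(labels, class = "coex_assignment"))
    em <- vapply(mods, function(m) eg[[m]]$eigengene,
                 numeric(length(eg[[1L]]$eigengene)))
    cc <- stats::cor(em)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (max(cc) <= merge_threshold) break
    from <- mods[max(best)]; to <- mods[min(best)]
    labels[labels == from] <- to
  }
  structure(renumber_modules(labels), class = "coex_assignment",
            cut_height = attr(assignment, "cut_height"))
}

#' Intramodular hub genes
#'
#' Ranks each module's genes by intramodular connectivity — the sum of
#' soft-thresholded adjacency to the other module members — and returns the
#' `top_n` most connected genes per module (the network hubs). Ties are
#' broken alphabetically by gene id.
#'
#' @param adjacency Adjacency matrix at the selected beta.
#' @param assignment Module assignment.
#' @param top_n Hubs per module (default 10).
#' @return data.frame: module, rank, gene, connectivity.
#' @export
hub_genes <- function(adjacency, assignment, top_n = 10) {
  mods <- module_labels(assignment)
  rows <- lapply(mods, function(m) {
    members <- sort(names(assignment)[assignment == m])
    a <- adjacency[members, members, drop = FALSE]
    k <- rowSums(a) - diag(a)
    ord <- order(-k, members)
    take <- utils::head(ord, top_n)
    data.frame(module = m, rank = seq_along(take), gene = members[take],
               connectivity = unname(k[take]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
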