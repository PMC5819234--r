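#' Simulate a modular expression matrix with planted co-expression modules
#'
#' A single-factor model per module: each module m has a latent factor per
#' sample, standard normal plus a class-specific activity shift (in sd
#' units), and each member gene is `loading * factor + noise_sd * N(0,1)`.
#' Background genes are independent standard normal noise. The expected
#' within-module gene-gene correlation is
#' `loading^2 / (loading^2 + noise_sd^2)`, which makes adjacency, TOM and
#' eigengene behavior checkable in closed form; the class shifts give GSEA
#' a planted direction of module activity. Deterministic per seed.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per module.
#' @param n_background_genes Uncorrelated background genes.
#' @param samples_per_class Named integer vector: class label -> sample
#'   count (or a single unnamed count for one class "all").
#' @param loading Factor loading lambda (>= 0) shared by module genes.
#' @param noise_sd Residual noise sd sigma (>= 0).
#' @param class_shifts Optional matrix or data.frame of activity shifts,
#'   modules x classes (sd units); 0 when absent.
#' @param seed Integer seed (mandatory).
#' @return List: `expr` (matrix), `truth` (named vector gene -> "M<i>" or
#'   "Uncorrelated"), `annotation` (data.frame sample_id, class_label),
#'   `factors` (matrix modules x samples, the latent factors).
#' @export
simulate_modular_expression <- function(n_modules = 5, genes_per_module = 50,
                                        n_background_genes = 250,
                                        samples_per_class = c(control = 20, disease = 20),
                                        loading = 0.9, noise_sd = 0.5,
                                        class_shifts = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(loading >= 0, noise_sd >= 0, n_modules >= 1, genes_per_module >= 1)
  if (is.null(names(samples_per_class)))
    names(samples_per_class) <- if (length(samples_per_class) == 1L) "all"
                                else paste0("class", seq_along(samples_per_class))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  classes <- rep(names(samples_per_class), samples_per_class)
  n_samples <- length(classes)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  annotation <- data.frame(sample_id = sample_ids, class_label = classes,
                           stringsAsFactors = FALSE)

  shifts <- matrix(0, n_modules, length(samples_per_class),
                   dimnames = list(paste0("M", seq_len(n_modules)),
                                   names(samples_per_class)))
  if (!is.null(class_shifts)) {
    class_shifts <- as.matrix(class_shifts)
    shifts[rownames(class_shifts), colnames(class_shifts)] <- class_shifts
  }

  factors <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  factors <- factors + shifts[, classes, drop = FALSE]
  rownames(factors) <- paste0("M", seq_len(n_modules))
  colnames(factors) <- sample_ids

  n_mod_genes <- n_modules * genes_per_module
  gene_ids <- c(sprintf("MOD%d_G%03d",
                        rep(seq_len(n_modules), each = genes_per_module),
                        rep(seq_len(genes_per_module), n_modules)),
                sprintf("BG_G%04d", seq_len(n_background_genes)))
  truth <- stats::setNames(
    c(rep(paste0("M", seq_len(n_modules)), each = genes_per_module),
      rep("Uncorrelated", n_background_genes)), gene_ids)

  expr <- matrix(0, length(gene_ids), n_samples,
                 dimnames = list(gene_ids, sample_ids))
  for (m in seq_len(n_modules)) {
    idx <- (m - 1L) * genes_per_module + seq_len(genes_per_module)
    noise <- matrix(stats::rnorm(genes_per_module * n_samples),
                    genes_per_module, n_samples)
    expr[idx, ] <- loading * matrix(factors[m, ], genes_per_module,
                                    n_samples, byrow = TRUE) + noise_sd * noise
  }
  if (n_background_genes > 0L) {
    expr[n_mod_genes + seq_len(n_background_genes), ] <-
      stats::rnorm(n_background_genes * n_samples)
  }
  list(expr = expr, truth = truth, annotation = annotation, factors = factors)
}

#' Simulate negative-binomial count data with a quadratic mean-variance law
#'
#' Gene means are log-uniform over `mean_range`; counts are drawn with
#' variance `mu + alpha * mu^2` (`alpha = 0` gives Poisson counts).
#' Deterministic per seed. Used to exercise the variance-stabilizing
#' transformation and the dispersion estimator.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param mean_range Length-2 range of gene means (default c(5, 5000),
#'   spanning typical RNA-seq expression depth).
#' @param alpha NB dispersion (>= 0).
#' @param seed Integer seed (mandatory).
#' @return Count matrix (genes x samples) with attribute `"true_means"`.
#' @export
simulate_nb_counts <- function(n_genes = 2000, n_samples = 30,
                               mean_range = c(5, 5000), alpha = 0.2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(alpha >= 0, length(mean_range) == 2L, all(mean_range > 0))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  mu <- exp(stats::runif(n_genes, log(mean_range[1L]), log(mean_range[2L])))
  counts <- if (alpha > 0) {
    matrix(stats::rnbinom(n_genes * n_samples, size = 1 / alpha,
                          mu = rep(mu, n_samples)), n_genes, n_samples)
  } else {
    matrix(stats::rpois(n_genes * n_samples, lambda = rep(mu, n_samples)),
           n_genes, n_samples)
  }
  dimnames(counts) <- list(sprintf("G%05d", seq_len(n_genes)),
                           sprintf("S%03d", seq_len(n_samples)))
  attr(counts, "true_means") <- mu
  counts
}

#' Simulate a gene-gene interaction table from a planted module structure
#'
#' Each same-module gene pair receives an edge with probability `within_p`,
#' each cross-module (or background-touching) pair with `between_p`.
#' Deterministic per seed.
#'
#' @param truth Named vector gene -> module label (as from
#'   [simulate_modular_expression()]).
#' @param within_p,between_p Edge probabilities in [0, 1].
#' @param seed Integer seed (mandatory).
#' @return data.frame `gene_a`, `gene_b` (undirected, deduplicated).
#' @export
simulate_interactions <- function(truth, within_p = 0.2, between_p = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(within_p >= 0, within_p <= 1, between_p >= 0, between_p <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  genes <- names(truth)
  pairs <- utils::combn(genes, 2)
  same <- truth[pairs[1L, ]] == truth[pairs[2L, ]] &
    truth[pairs[1L, ]] != "Uncorrelated"
  p <- ifelse(same, within_p, between_p)
  keep <- stats::runif(ncol(pairs)) < p
  a <- pairs[1L, keep]; b <- pairs[2L, keep]
  data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b), stringsAsFactors = FALSE)
}
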