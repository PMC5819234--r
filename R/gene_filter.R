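#' Estimate a common negative-binomial dispersion from count data
#'
#' Assumes counts with a quadratic mean-variance relation
#' `Var = mu + alpha * mu^2` and estimates the single dispersion `alpha` by
#' least-squares regression of (variance - mean) on mean^2 across genes,
#' clamped at zero. A per-gene dispersion would be far noisier at typical
#' sample sizes; the common-alpha fit is what the variance-stabilizing
#' transformation needs.
#'
#' @param expr Non-negative count-like expression matrix (genes x samples).
#' @return Estimated dispersion alpha (>= 0).
#' @export
estimate_dispersion <- function(expr) {
  validate_expression(expr)
  if (any(expr < 0)) stop("negative values: data is not count-like; disable VST")
  if (ncol(expr) < 3L) stop("dispersion estimation needs at least 3 samples")
  m <- rowMeans(expr)
  v <- apply(expr, 1L, stats::var)
  fit <- stats::lm.fit(x = cbind(m^2), y = v - m)
  max(0, unname(fit$coefficients[1L]))
}

#' Variance-stabilizing transformation for negative-binomial counts
#'
#' Estimates the common dispersion `alpha` (see [estimate_dispersion()]) and
#' applies the closed-form NB variance-stabilizing transformation
#' `x -> (2/sqrt(alpha)) * asinh(sqrt(alpha * x))`, which reduces to the
#' Poisson transform `x -> 2*sqrt(x)` as `alpha -> 0`. After the transform
#' the per-gene variance is approximately constant in the mean, so the
#' variance filter no longer preferentially keeps high-mean genes.
#'
#' @param expr Non-negative count-like expression matrix.
#' @param alpha Optional dispersion; estimated from the data when `NULL`.
#' @return Transformed matrix with attribute `"alpha"` holding the
#'   dispersion used.
#' @export
apply_vst <- function(expr, alpha = NULL) {
  validate_expression(expr)
  if (any(expr < 0)) stop("negative values: data is not count-like; disable VST")
  if (is.null(alpha)) alpha <- estimate_dispersion(expr)
  if (alpha < 0) stop("alpha must be non-negative")
  out <- if (alpha > 0) (2 / sqrt(alpha)) * asinh(sqrt(alpha * expr)) else 2 * sqrt(expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "alpha") <- alpha
  out
}

# Gamma MLE via the standard log-moment profile equation:
# log(shape) - digamma(shape) = log(mean(x)) - mean(log(x)).
# Returns NULL when the equation cannot be solved (degenerate input).
fit_gamma_mle <- function(x) {
  if (any(x <= 0)) return(NULL)
  s <- log(mean(x)) - mean(log(x))
  if (!is.finite(s) || s <= 0) return(NULL)
  f <- function(a) log(a) - digamma(a) - s
  # log(a) - digamma(a) is decreasing in a, from +Inf to 0
  lo <- 1e-8; hi <- 1e8
  if (f(hi) > 0 || f(lo) < 0) return(NULL)
  root <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                   error = function(e) NULL)
  if (is.null(root)) return(NULL)
  list(shape = root, rate = root / mean(x))
}

#' Fit an inverse-gamma distribution to a sample
#'
#' Maximum likelihood, using the identity that `X ~ InvGamma(shape, scale)`
#' iff `1/X ~ Gamma(shape, rate = scale)`. Falls back to moment matching
#' (with a message) when the MLE profile equation has no solution.
#'
#' @param x Positive sample values.
#' @return List with `shape`, `scale` and `method` ("mle" or "moments").
#' @export
fit_inverse_gamma <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 3L) stop("too few positive values to fit an inverse gamma")
  if (stats::sd(x) == 0) stop("variance distribution degenerate")
  fit <- fit_gamma_mle(1 / x)
  if (!is.null(fit)) {
    return(list(shape = fit$shape, scale = fit$rate, method = "mle"))
  }
  message("inverse-gamma MLE did not converge; falling back to moment matching")
  m <- mean(x); s2 <- stats::var(x)
  shape <- m^2 / s2 + 2
  scale <- m * (shape - 1)
  list(shape = shape, scale = scale, method = "moments")
}

#' Upper-tail probability under an inverse-gamma distribution
#'
#' `P(X >= q)` for `X ~ InvGamma(shape, scale)`, computed as
#' `P(1/X <= 1/q)` under the corresponding gamma distribution.
#'
#' @param q Quantiles (positive).
#' @param shape,scale Inverse-gamma parameters.
#' @return Upper-tail probabilities.
#' @export
pinvgamma_upper <- function(q, shape, scale) {
  stats::pgamma(1 / q, shape = shape, rate = scale, lower.tail = TRUE)
}

#' Select genes by inverse-gamma variance filtering
#'
#' The unsupervised gene selection step: (1) remove the `low_mean_fraction`
#' of genes with lowest mean expression; (2) compute the unbiased sample
#' variance of each remaining gene; (3) fit an inverse-gamma distribution to
#' the variances by maximum likelihood; (4) assign each gene the upper-tail
#' probability of its variance under the fitted distribution; (5) keep genes
#' with p below `filter_pval`. High-variance genes are the informative ones
#' for co-expression, so the upper tail is selected. Zero-variance genes are
#' excluded from the fit and never selected (their correlations are
#' undefined downstream).
#'
#' Filtering on variance rather than on differential expression preserves
#' the scale-free topology assumption of the downstream network.
#'
#' @param expr Expression matrix (genes x samples), VST-transformed first if
#'   the data are raw counts.
#' @param filter_pval Upper-tail probability cutoff, default 0.1.
#' @param low_mean_fraction Fraction of lowest-mean genes removed before the
#'   fit, default 0.25.
#' @return List of class `coex_filter`: `table` (data.frame gene, mean,
#'   variance, p, selected), `selected` (character vector of gene ids),
#'   `shape`, `scale`, `method`.
#' @export
filter_genes <- function(expr, filter_pval = 0.1, low_mean_fraction = 0.25) {
  validate_expression(expr)
  stopifnot(filter_pval > 0, filter_pval < 1,
            low_mean_fraction >= 0, low_mean_fraction < 1)
  if (ncol(expr) < 3L) stop("variance filtering needs at least 3 samples")
  means <- rowMeans(expr)
  vars <- apply(expr, 1L, stats::var)

  n_remove <- floor(low_mean_fraction * nrow(expr))
  survived <- rep(TRUE, nrow(expr))
  if (n_remove > 0L) {
    # ties broken by gene order for determinism
    survived[order(means, seq_along(means))[seq_len(n_remove)]] <- FALSE
  }
  if (sum(survived) < 20L)
    stop("fewer than 20 genes remain after low-mean removal; fit not meaningful")

  fit_vars <- vars[survived & vars > 0]
  if (length(unique(fit_vars)) < 2L) stop("variance distribution degenerate")
  fit <- fit_inverse_gamma(fit_vars)

  p <- rep(NA_real_, nrow(expr))
  pos <- survived & vars > 0
  p[pos] <- pinvgamma_upper(vars[pos], fit$shape, fit$scale)
  selected <- pos & !is.na(p) & p < filter_pval

  table <- data.frame(gene = rownames(expr), mean = means, variance = vars,
                      p = p, selected = selected, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(table = table,
                 selected = rownames(expr)[selected],
                 shape = fit$shape, scale = fit$scale, method = fit$method,
                 filter_pval = filter_pval,
                 low_mean_fraction = low_mean_fraction),
            class = "coex_filter")
}
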