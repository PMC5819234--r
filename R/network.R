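#' Soft-thresholded correlation adjacency
#'
#' Computes the pairwise gene correlation matrix and raises it to the power
#' `beta` after the network-type scaling: unsigned networks use `|r|^beta`,
#' signed networks rescale correlations from [-1, 1] into [0, 1] first,
#' `((1 + r)/2)^beta`. The diagonal is stored as 1 but is excluded from all
#' connectivity sums downstream.
#'
#' @param expr Expression matrix (genes x samples); zero-variance genes must
#'   have been removed upstream.
#' @param beta Soft-thresholding power (integer >= 1).
#' @param network_type "unsigned" (default) or "signed".
#' @param cor_method "pearson" (default) or "spearman".
#' @param cor_matrix Optional precomputed gene-gene correlation matrix; when
#'   supplied, `expr` is ignored. Used to power the same base correlations
#'   across a beta grid.
#' @return Symmetric adjacency matrix with entries in [0, 1], diagonal 1.
#' @export
correlation_adjacency <- function(expr = NULL, beta, network_type = "unsigned",
                                  cor_method = "pearson", cor_matrix = NULL) {
  if (beta < 1) stop("beta must be >= 1")
  network_type <- match.arg(network_type, c("unsigned", "signed"))
  if (is.null(cor_matrix)) {
    validate_expression(expr)
    if (ncol(expr) < 3L) stop("correlation needs at least 3 samples")
    cor_matrix <- stats::cor(t(expr), method = cor_method)
  }
  a <- if (network_type == "unsigned") abs(cor_matrix)^beta
       else ((1 + cor_matrix) / 2)^beta
  diag(a) <- 1
  a
}

connectivity <- function(adjacency) {
  rowSums(adjacency) - diag(adjacency)
}

#' Scale-free topology fit index of a network
#'
#' Bins the node connectivities into `n_bins` equal-width bins, regresses
#' log10(bin frequency) on log10(mean bin connectivity) over non-empty bins,
#' and returns the signed fit index `-sign(slope) * R^2`, so that only
#' decaying (power-law-like) degree distributions score high. Plain R^2
#' would also reward increasing degree distributions; the signed form is
#' strictly more conservative.
#'
#' @param adjacency Adjacency matrix, or a numeric vector of connectivities.
#' @param n_bins Number of equal-width histogram bins (default 10).
#' @return List of class `scale_free_point`: `r2` in [-1, 1],
#'   `mean_connectivity`, `slope`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- if (is.matrix(adjacency)) connectivity(adjacency) else as.numeric(adjacency)
  if (length(k) < 2L) stop("need at least 2 nodes")
  mean_k <- mean(k)
  if (length(unique(k)) == 1L) {
    warning("all connectivities equal; scale-free fit undefined, r2 set to 0")
    return(structure(list(r2 = 0, mean_connectivity = mean_k, slope = NA_real_),
                     class = "scale_free_point"))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  bin_mean <- vapply(seq_len(n_bins),
                     function(i) mean(k[as.integer(bin) == i]), numeric(1))
  keep <- freq > 0 & bin_mean > 0
  if (sum(keep) < 2L) {
    warning("fewer than 2 usable connectivity bins; r2 set to 0")
    return(structure(list(r2 = 0, mean_connectivity = mean_k, slope = NA_real_),
                     class = "scale_free_point"))
  }
  x <- log10(bin_mean[keep])
  y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- -sign(slope) * summary(fit)$r.squared
  if (!is.finite(r2)) {
    # constant bin frequencies (or a flat fit): no evidence either way
    warning("degenerate degree histogram; r2 set to 0")
    r2 <- 0
  }
  structure(list(r2 = r2, mean_connectivity = mean_k, slope = slope),
            class = "scale_free_point")
}

#' Scale-free fit curve over a grid of soft-thresholding powers
#'
#' Computes the base correlation matrix once and powers it per beta, giving
#' one scale-free fit point per grid value, then fills in the stability
#' statistic phi and the automatically selected beta.
#'
#' @param expr Filtered expression matrix.
#' @param beta_grid Ordered integer grid of candidate powers (default 1:20).
#' @param tau R^2 threshold a candidate must exceed (default 0.8).
#' @param epsilon Stabilization tolerance on R^2 differences (default 0.1).
#' @param network_type,cor_method Passed to [correlation_adjacency()].
#' @param n_bins Passed to [scale_free_fit()].
#' @return List of class `beta_curve`: `points` (data.frame beta, r2,
#'   mean_connectivity), `selected_beta` (NA when no candidate qualifies),
#'   `phi`, plus the parameters used.
#' @export
beta_curve <- function(expr, beta_grid = 1:20, tau = 0.8, epsilon = 0.1,
                       network_type = "unsigned", cor_method = "pearson",
                       n_bins = 10) {
  stopifnot(length(beta_grid) >= 1L, all(beta_grid >= 1),
            !is.unsorted(beta_grid, strictly = TRUE),
            tau > 0, tau < 1, epsilon > 0)
  validate_expression(expr)
  base_cor <- stats::cor(t(expr), method = cor_method)
  pts <- lapply(beta_grid, function(b) {
    a <- correlation_adjacency(beta = b, network_type = network_type,
                               cor_matrix = base_cor)
    scale_free_fit(a, n_bins = n_bins)
  })
  points <- data.frame(beta = beta_grid,
                       r2 = vapply(pts, `[[`, numeric(1), "r2"),
                       mean_connectivity = vapply(pts, `[[`, numeric(1),
                                                  "mean_connectivity"))
  curve <- structure(list(points = points, selected_beta = NA_integer_,
                          phi = NA_real_, tau = tau, epsilon = epsilon,
                          network_type = network_type,
                          cor_method = cor_method),
                     class = "beta_curve")
  curve$phi <- phi_statistic(curve)
  curve$selected_beta <- select_beta(curve, tau = tau, epsilon = epsilon)
  curve
}

#' Select the soft-thresholding power by suffix stabilization
#'
#' Accepts the smallest grid beta whose R^2 exceeds `tau` AND whose suffix
#' of R^2 values (from that beta to the end of the grid, or over a window of
#' `window` grid points) varies by less than `epsilon` across all pairs: the
#' curve must have stabilized, so no significant gain in scale-freeness is
#' left on the table. With `epsilon = Inf` this reduces exactly to the plain
#' "first beta with R^2 > tau" rule.
#'
#' @param curve A `beta_curve`, or a numeric vector of R^2 values (the grid
#'   is then taken as their positions).
#' @param tau R^2 threshold (default taken from the curve, else 0.8).
#' @param epsilon Stabilization tolerance (default from the curve, else 0.1).
#' @param window Number of grid points in the stabilization window;
#'   `Inf` (default) uses the full suffix.
#' @return Selected beta (integer), or `NA` when no beta qualifies; in that
#'   case attribute `"diagnostic"` holds, per above-threshold candidate, the
#'   maximum R^2 spread of its suffix.
#' @export
select_beta <- function(curve, tau = NULL, epsilon = NULL, window = Inf) {
  if (inherits(curve, "beta_curve")) {
    r2 <- curve$points$r2
    grid <- curve$points$beta
    if (is.null(tau)) tau <- curve$tau
    if (is.null(epsilon)) epsilon <- curve$epsilon
  } else {
    r2 <- as.numeric(curve)
    grid <- seq_along(r2)
  }
  if (is.null(tau)) tau <- 0.8
  if (is.null(epsilon)) epsilon <- 0.1
  n <- length(r2)
  spreads <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.finite(r2[i]) || r2[i] <= tau) next
    j <- if (is.finite(window)) min(n, i + window - 1L) else n
    suffix <- r2[i:j]
    spreads[i] <- max(suffix) - min(suffix)   # max pairwise |difference|
    if (spreads[i] < epsilon) return(grid[i])
  }
  diag_df <- data.frame(beta = grid, r2 = r2, suffix_spread = spreads)
  structure(NA_integer_, diagnostic = diag_df)
}

#' Stability statistic phi of a beta x R^2 curve
#'
#' The trapezoidal area under the curve of `max(R^2, 0)` over the beta grid,
#' divided by the area of the enclosing rectangle (grid span x 1, the
#' highest attainable R^2). Values near 1 indicate that the network topology
#' converges sharply to a scale-free degree distribution; low values flag
#' unstable curves, typically from too few samples. A single-point grid
#' returns that point's R^2 clamped into [0, 1].
#'
#' @param curve A `beta_curve`, or a data.frame with columns beta and r2.
#' @return phi in [0, 1].
#' @export
phi_statistic <- function(curve) {
  pts <- if (inherits(curve, "beta_curve")) curve$points else curve
  stopifnot(nrow(pts) >= 1L)
  y <- pmax(pts$r2, 0)
  x <- pts$beta
  if (length(x) == 1L) return(min(1, y[1L]))
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc / (x[length(x)] - x[1L])
}

#' Topological overlap matrix
#'
#' `TOM[i,j] = (l[i,j] + a[i,j]) / (min(k[i], k[j]) + 1 - a[i,j])` where
#' `l[i,j] = sum_u a[i,u] a[u,j]` over `u != i, j` counts shared neighbors
#' and `k` is connectivity (diagonal excluded). Two genes are topologically
#' similar when they are directly connected and share neighbors; TOM is the
#' similarity fed to hierarchical clustering for module detection.
#'
#' @param adjacency Symmetric adjacency matrix, entries in [0, 1].
#' @return TOM matrix: symmetric, diagonal 1, entries in [0, 1].
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                     # l[i,j] includes no u==i or u==j terms: diag(a)=0
  n <- nrow(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}
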