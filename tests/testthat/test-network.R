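test_that("adjacency applies the signed/unsigned scaling before powering", {
  r <- matrix(c(1, -0.8, -0.8, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  un <- correlation_adjacency(beta = 2, cor_matrix = r)
  expect_equal(un["a", "b"], 0.64)
  si <- correlation_adjacency(beta = 2, network_type = "signed", cor_matrix = r)
  expect_equal(si["a", "b"], 0.01)
  b1 <- correlation_adjacency(beta = 1, cor_matrix = r)
  expect_equal(b1["a", "b"], 0.8)
  expect_error(correlation_adjacency(beta = 0, cor_matrix = r), "beta")
})

test_that("scale-free fit scores power-law connectivity high and Poisson low", {
  set.seed(13)
  # discrete power law p(k) ~ k^-1.5 on 1..1000
  support <- 1:1000
  p <- support^-1.5
  k_pl <- sample(support, 2000, replace = TRUE, prob = p)
  fit_pl <- scale_free_fit(k_pl)
  expect_gt(fit_pl$r2, 0.8)
  expect_equal(fit_pl$r2, brute_scale_free_r2(k_pl), tolerance = 1e-10)

  k_pois <- rpois(2000, 20)
  fit_pois <- scale_free_fit(k_pois)
  expect_lt(fit_pois$r2, fit_pl$r2)
  expect_equal(fit_pois$r2, brute_scale_free_r2(k_pois), tolerance = 1e-10)

  expect_warning(flat <- scale_free_fit(rep(3, 50)), "equal")
  expect_equal(flat$r2, 0)
})

test_that("beta selection follows exhaustive suffix enumeration", {
  r2 <- c(0.30, 0.70, 0.82, 0.90, 0.95, 0.96, 0.96, 0.96)
  expect_equal(select_beta(r2, tau = 0.8, epsilon = 0.05), 5L)
  expect_equal(select_beta(r2, tau = 0.8, epsilon = Inf), 3L)
  expect_equal(brute_select_beta(r2, 0.8, 0.05), 5L)
  # property: agrees with the oracle on random curves
  set.seed(99)
  for (i in 1:50) {
    rr <- sort(runif(10, 0, 1))
    eps <- runif(1, 0.01, 0.3)
    expect_equal(select_beta(rr, tau = 0.5, epsilon = eps),
                 brute_select_beta(rr, 0.5, eps))
  }
  # constant curve above tau picks the first grid value
  expect_equal(select_beta(rep(0.9, 6), tau = 0.8, epsilon = 0.05), 1L)
  # all below tau: none, with diagnostics
  none <- select_beta(rep(0.5, 6), tau = 0.8, epsilon = 0.05)
  expect_true(is.na(none))
  expect_s3_class(attr(none, "diagnostic"), "data.frame")
})

test_that("phi is the normalized area under the clamped r2 curve", {
  grid <- 1:20
  expect_equal(phi_statistic(data.frame(beta = grid, r2 = rep(1, 20))), 1)
  expect_equal(phi_statistic(data.frame(beta = grid,
                                        r2 = seq(0, 1, length.out = 20))), 0.5)
  expect_equal(phi_statistic(data.frame(beta = grid, r2 = rep(0.8, 20))), 0.8)
  # negative r2 is clamped at zero so phi stays in [0, 1]
  expect_equal(phi_statistic(data.frame(beta = 1:3, r2 = c(-1, -1, -1))), 0)
  # single-point grid: the clamped r2 itself
  expect_equal(phi_statistic(data.frame(beta = 5, r2 = 0.7)), 0.7)
})

test_that("TOM matches the brute-force closed form", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  t3 <- tom_similarity(a3)
  expect_equal(t3[lower.tri(t3)], rep(0.5, 3))
  # zero adjacency: identity pattern
  z <- diag(4)
  expect_equal(tom_similarity(z), diag(4), ignore_attr = TRUE)
  # complete graph: all off-diagonal 1
  cg <- matrix(1, 5, 5)
  expect_true(all(tom_similarity(cg) == 1))
  set.seed(2024)
  for (i in 1:20) {
    a <- random_adjacency(10)
    expect_equal(unname(tom_similarity(a)), brute_tom(a), tolerance = 1e-12)
  }
  asym <- matrix(runif(9), 3)
  expect_error(tom_similarity(asym), "symmetric")
})

test_that("beta curve rises to a plateau on modular data, stays low when permuted", {
  sim <- simulate_modular_expression(n_modules = 5, genes_per_module = 50,
                                     n_background_genes = 250,
                                     samples_per_class = c(all = 40),
                                     loading = 0.9, noise_sd = 0.5, seed = 42)
  curve <- beta_curve(sim$expr, beta_grid = 1:20)
  # mean connectivity weakly decreasing in beta
  expect_true(all(diff(curve$points$mean_connectivity) <= 1e-9))
  expect_gt(max(curve$points$r2), 0.8)
  # each point equals an independent recomputation
  base_cor <- cor(t(sim$expr))
  for (b in c(1, 6, 12, 20)) {
    a <- correlation_adjacency(beta = b, cor_matrix = base_cor)
    expect_equal(curve$points$r2[curve$points$beta == b],
                 scale_free_fit(a)$r2)
  }
  # permuting each gene's samples destroys the planted structure: at low to
  # moderate powers the permuted fit stays below the planted curve, and the
  # curve-wide stability statistic phi drops (at very high powers pure noise
  # correlations also produce heavy-tailed connectivity, so the comparison
  # is only meaningful before that regime)
  set.seed(18)
  perm <- t(apply(sim$expr, 1, sample))
  dimnames(perm) <- dimnames(sim$expr)
  curve_p <- beta_curve(perm, beta_grid = 1:20)
  low <- curve$points$beta <= 7
  expect_lt(max(curve_p$points$r2[low]), max(curve$points$r2[low]))
  expect_lt(curve_p$phi, curve$phi)
})

test_that("adjacency and TOM are permutation-equivariant under gene reordering", {
  sim <- simulate_modular_expression(n_modules = 2, genes_per_module = 15,
                                     n_background_genes = 5,
                                     samples_per_class = c(all = 20), seed = 4)
  a <- correlation_adjacency(sim$expr, beta = 4)
  tom <- tom_similarity(a)
  set.seed(5)
  ord <- sample(nrow(sim$expr))
  a2 <- correlation_adjacency(sim$expr[ord, ], beta = 4)
  expect_equal(a2, a[ord, ord])
  expect_equal(tom_similarity(a2), tom[ord, ord])
})
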