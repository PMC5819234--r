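block_tom <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  tom <- matrix(between, n, n)
  for (b in seq_along(sizes)) tom[lab == b, lab == b] <- within
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tom
}

test_that("clustering separates perfect blocks at the top split", {
  tom <- block_tom(c(10, 10))
  dend <- cluster_genes(tom)
  cl <- cutree(dend, k = 2)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])
  # merge heights of average linkage are weakly increasing (no inversions)
  set.seed(6)
  a <- random_adjacency(20)
  rt <- (a + t(a)) / 2; diag(rt) <- 1
  d2 <- cluster_genes(rt)
  expect_true(all(diff(d2$height) >= -1e-12))
})

test_that("zero-noise planted blocks are recovered exactly", {
  tom <- block_tom(c(100, 100))
  assignment <- cut_modules(cluster_genes(tom), 1 - tom)
  expect_setequal(unique(assignment), c("M1", "M2"))
  expect_equal(sort(as.integer(table(assignment))), c(100L, 100L))
  expect_equal(mclust::adjustedRandIndex(assignment,
                                         rep(c("A", "B"), each = 100)), 1)
})

test_that("planted factor modules are recovered with background left out", {
  sim <- simulate_modular_expression(n_modules = 5, genes_per_module = 50,
                                     n_background_genes = 250,
                                     samples_per_class = c(all = 40),
                                     loading = 0.9, noise_sd = 0.5, seed = 42)
  curve <- beta_curve(sim$expr)
  beta <- curve$selected_beta
  expect_false(is.na(beta))
  a <- correlation_adjacency(sim$expr, beta = beta)
  tom <- tom_similarity(a)
  assignment <- cut_modules(cluster_genes(tom), 1 - tom)
  ari <- mclust::adjustedRandIndex(assignment, sim$truth)
  expect_gte(ari, 0.9)
  bg <- names(sim$truth)[sim$truth == "Uncorrelated"]
  expect_gt(mean(assignment[bg] == "Uncorrelated"), 0.5)
  # labels partition the genes, renumbered by size
  sizes <- table(assignment[assignment != "Uncorrelated"])
  mods <- paste0("M", seq_along(sizes))
  expect_setequal(names(sizes), mods)
  expect_true(all(diff(sizes[mods]) <= 0))
})

test_that("undersized inputs yield all-Uncorrelated with a warning", {
  tom <- block_tom(c(12, 13), within = 0.9)
  expect_warning(a <- cut_modules(cluster_genes(tom), 1 - tom,
                                  min_module_size = 30), "Uncorrelated")
  expect_true(all(a == "Uncorrelated"))
})

test_that("eigengenes summarize module expression", {
  n_s <- 12
  profile <- sin(seq_len(n_s))
  set.seed(40)
  expr <- rbind(matrix(profile, 4, n_s, byrow = TRUE),
                matrix(rnorm(2 * n_s, sd = 0.1), 2, n_s))
  dimnames(expr) <- list(paste0("g", 1:6), paste0("s", 1:n_s))
  assignment <- stats::setNames(c(rep("M1", 4), rep("Uncorrelated", 2)),
                                rownames(expr))
  eg <- module_eigengenes(expr, assignment)
  # identical member genes: eigengene proportional to common profile, VE = 1
  expect_equal(eg$M1$var_explained, 1)
  expect_gt(abs(cor(eg$M1$eigengene, profile)), 0.999)
  # orientation: non-negative correlation with module mean expression
  expect_gte(cor(eg$M1$eigengene, rowMeans(scale(t(expr[1:4, ])))), 0)

  # factor-model module tracks the latent factor
  sim <- simulate_modular_expression(n_modules = 1, genes_per_module = 40,
                                     n_background_genes = 0,
                                     samples_per_class = c(all = 30),
                                     loading = 0.8, noise_sd = 0.6, seed = 8)
  ass <- stats::setNames(rep("M1", 40), rownames(sim$expr))
  eg2 <- module_eigengenes(sim$expr, ass)
  expect_gt(abs(cor(eg2$M1$eigengene, sim$factors[1, ])), 0.9)
})

test_that("merging collapses duplicate modules and respects the threshold", {
  sim <- simulate_modular_expression(n_modules = 2, genes_per_module = 30,
                                     n_background_genes = 0,
                                     samples_per_class = c(all = 25),
                                     loading = 0.9, noise_sd = 0.3, seed = 9)
  # split the single real structure artificially: relabel module M1 genes
  # into two fake modules sharing the same factor
  expr <- sim$expr[1:30, ]
  ass <- stats::setNames(rep(c("M1", "M2"), each = 15), rownames(expr))
  class(ass) <- "coex_assignment"
  merged <- merge_similar(expr, ass, merge_threshold = 0.8)
  expect_equal(length(unique(merged)), 1L)
  # orthogonal modules stay apart
  ass2 <- stats::setNames(c(rep("M1", 30), rep("M2", 30)),
                          rownames(sim$expr))
  class(ass2) <- "coex_assignment"
  merged2 <- merge_similar(sim$expr, ass2, merge_threshold = 0.8)
  expect_equal(length(unique(merged2)), 2L)
  # threshold 1 never merges
  merged3 <- merge_similar(expr, ass, merge_threshold = 1)
  expect_equal(length(unique(merged3)), 2L)
})

test_that("hub ranking finds the star center and is order-invariant", {
  genes <- paste0("g", 1:6)
  a <- matrix(0.1, 6, 6, dimnames = list(genes, genes))
  a[1, ] <- a[, 1] <- 0.9     # star center
  diag(a) <- 1
  ass <- stats::setNames(rep("M1", 6), genes)
  hubs <- hub_genes(a, ass, top_n = 10)
  expect_equal(hubs$gene[1], "g1")
  expect_equal(nrow(hubs), 6L)       # fewer members than top_n: all returned
  # permuting gene order leaves the ranking unchanged
  set.seed(10)
  ord <- sample(6)
  hubs2 <- hub_genes(a[ord, ord], ass[ord], top_n = 10)
  expect_equal(hubs2$gene, hubs$gene)
  expect_equal(hubs2$connectivity, hubs$connectivity)
  # default returns at most ten per module
  big <- paste0("h", sprintf("%02d", 1:15))
  ab <- matrix(0.2, 15, 15, dimnames = list(big, big)); diag(ab) <- 1
  hb <- hub_genes(ab, stats::setNames(rep("M1", 15), big))
  expect_lte(nrow(hb), 10L)
})
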