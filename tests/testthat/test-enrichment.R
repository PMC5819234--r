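test_that("ORA p-values equal exhaustive combinatorial enumeration", {
  # spec-level example: universe 100, module 10, set 5, overlap 4
  universe <- paste0("g", 1:100)
  module_genes <- universe[1:10]
  set_genes <- c(universe[1:4], universe[50])
  assignment <- stats::setNames(
    ifelse(universe %in% module_genes, "M1", "Uncorrelated"), universe)
  rows <- ora(assignment, list(S = set_genes), universe)
  expect_equal(rows$overlap, 4L)
  expect_equal(rows$p, brute_hyper_upper(4, K = 5, N = 100, n_draw = 10),
               tolerance = 1e-12)

  # overlap 0 gives p = 1; module == universe gives p = 1
  rows0 <- ora(assignment, list(S0 = universe[90:95]), universe)
  expect_equal(rows0$p, 1)
  all_mod <- stats::setNames(rep("M1", 100), universe)
  rows_all <- ora(all_mod, list(S = set_genes), universe)
  expect_equal(rows_all$p, 1)

  # random configurations on small universes vs the enumeration oracle
  set.seed(31)
  for (i in 1:100) {
    N <- sample(5:30, 1)
    univ <- paste0("u", 1:N)
    K <- sample(1:N, 1); n_draw <- sample(1:N, 1)
    mod <- sample(univ, n_draw); gs <- sample(univ, K)
    ass <- stats::setNames(ifelse(univ %in% mod, "M1", "Uncorrelated"), univ)
    r <- ora(ass, list(S = gs), univ)
    expect_equal(r$p, brute_hyper_upper(r$overlap, K, N, n_draw),
                 tolerance = 1e-12)
  }
})

test_that("ORA adjusts within module and sorts by adjusted p", {
  universe <- paste0("g", 1:60)
  ass <- stats::setNames(rep(c("M1", "M2", "Uncorrelated"), each = 20), universe)
  sets <- list(A = universe[1:10], B = universe[21:30], C = universe[41:50])
  rows <- ora(ass, sets, universe)
  expect_false("Uncorrelated" %in% rows$module)
  for (m in unique(rows$module)) {
    sub <- rows[rows$module == m, ]
    expect_equal(sub$p_adjust, p.adjust(sub$p, "BH"))
    expect_true(all(sub$p_adjust >= sub$p - 1e-15))
    expect_true(all(diff(sub$p_adjust) >= -1e-15))
  }
})

test_that("class rankings are zero-sum z-score means with planted direction", {
  sim <- simulate_modular_expression(
    n_modules = 2, genes_per_module = 20, n_background_genes = 40,
    samples_per_class = c(control = 15, disease = 15),
    class_shifts = matrix(c(0, 2), 1, 2,
                          dimnames = list("M1", c("control", "disease"))),
    seed = 33)
  rk <- class_rankings(sim$expr, sim$annotation)
  expect_setequal(names(rk), c("control", "disease"))
  # class-size-weighted mean of each gene's scores is zero
  w <- table(sim$annotation$class_label)
  for (g in rownames(sim$expr)) {
    expect_equal(sum(rk$control[g] * w[["control"]],
                     rk$disease[g] * w[["disease"]]) / sum(w), 0,
                 tolerance = 1e-12)
  }
  # scores sorted decreasing within each class
  expect_true(all(diff(rk$disease) <= 0))
  # genes elevated in "disease" score positive there, negative in control
  m1 <- names(sim$truth)[sim$truth == "M1"]
  expect_true(all(rk$disease[m1] > 0))
  expect_true(all(rk$control[m1] < 0))
  # single-class annotation: all scores ~ 0
  ann1 <- sim$annotation; ann1$class_label <- "only"
  rk1 <- class_rankings(sim$expr, ann1)
  expect_lt(max(abs(rk1$only)), 1e-12)
})

test_that("enrichment score matches the brute-force running sum", {
  set.seed(41)
  for (i in 1:50) {
    scores <- sort(rnorm(100), decreasing = TRUE)
    names(scores) <- paste0("g", 1:100)
    hit <- sort(sample(100, sample(3:20, 1)))
    es <- coexmod:::enrichment_score(scores, hit)
    expect_equal(es, brute_es(scores, hit), tolerance = 1e-12)
  }
  # genes at the very top give the maximal positive ES over placements
  scores <- sort(abs(rnorm(100)) + 0.1, decreasing = TRUE)
  k <- 10
  es_top <- coexmod:::enrichment_score(scores, 1:k)
  expect_gt(es_top, 0)
  for (i in 1:30) {
    other <- sort(sample(100, k))
    expect_lte(coexmod:::enrichment_score(scores, other), es_top + 1e-12)
  }
  # equal |scores| reduce to the classic unweighted KS running sum; this
  # placement ties the positive and negative extrema at |ES| = 0.5
  flat <- rep(1, 50); names(flat) <- paste0("g", 1:50)
  hit <- c(1:5, 46:50)
  expect_equal(abs(coexmod:::enrichment_score(flat, hit)),
               abs(brute_es(flat, hit)))
  hit2 <- c(1:5, 26:30)
  expect_equal(coexmod:::enrichment_score(flat, hit2), brute_es(flat, hit2))
  # a set covering the whole ranking is rejected
  expect_error(coexmod:::enrichment_score(flat, 1:50), "proper subset")
})

test_that("gsea flags the planted class-active module with a reproducible null", {
  sim <- simulate_modular_expression(
    n_modules = 3, genes_per_module = 30, n_background_genes = 90,
    samples_per_class = c(control = 15, disease = 15),
    class_shifts = matrix(c(0, 1), 1, 2,
                          dimnames = list("M1", c("control", "disease"))),
    seed = 51)
  rk <- class_rankings(sim$expr, sim$annotation)
  ass <- structure(sim$truth, class = "coex_assignment")
  res <- gsea(rk, ass, n_perm = 500, seed = 77)
  m1d <- res[res$module == "M1" & res$class == "disease", ]
  m1c <- res[res$module == "M1" & res$class == "control", ]
  expect_gt(m1d$nes, 0)
  expect_lt(m1c$nes, 0)
  expect_lt(m1d$p_adjust, 0.05)
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$p_adjust >= res$p - 1e-15))
  # bit-for-bit reproducible under the same seed
  res2 <- gsea(rk, ass, n_perm = 500, seed = 77)
  expect_identical(res, res2)
  res3 <- gsea(rk, ass, n_perm = 500, seed = 78)
  expect_false(identical(res$p, res3$p))
})

test_that("gsea ES agrees with an established preranked implementation", {
  set.seed(61)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- paste0("g", 1:200)
  for (i in 1:10) {
    hit <- sort(sample(200, 15))
    mine <- coexmod:::enrichment_score(scores, hit)
    ref <- fgsea::calcGseaStat(scores, selectedStats = hit, gseaParam = 1,
                               scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("combined enrichment score is the geometric mean of module minima", {
  rows <- data.frame(module = c("M1", "M1", "M2"),
                     gene_set = c("A", "B", "A"),
                     p_adjust = c(0.01, 0.5, 1))
  ces <- combined_enrichment_score(rows)
  expect_equal(ces$ces, sqrt(0.01 * 1))
  expect_equal(unname(ces$module_minima), c(0.01, 1))
  # single module
  expect_equal(combined_enrichment_score(rows[rows$module == "M1", ])$ces, 0.01)
  # no enrichment at all
  none <- data.frame(module = "M1", gene_set = "A", p_adjust = 1)
  expect_equal(combined_enrichment_score(none)$ces, 1)
  # strictly decreases when any module's minimum improves
  better <- rows; better$p_adjust[3] <- 0.2
  expect_lt(combined_enrichment_score(better)$ces, ces$ces)
})
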