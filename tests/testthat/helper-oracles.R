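# Independent brute-force oracles used across tests. These deliberately use
# naive loops / direct combinatorics so they share no code path with the
# package implementations they check.

# Triple-loop topological overlap
brute_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Upper-tail hypergeometric probability by direct combinatorial summation:
# P(X >= x) drawing n_draw from N with K successes.
brute_hyper_upper <- function(x, K, N, n_draw) {
  hi <- min(K, n_draw)
  lo <- max(x, 0, n_draw + K - N)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(i)
    choose(K, i) * choose(N - K, n_draw - i), numeric(1))) / choose(N, n_draw)
}

# Running-sum weighted KS enrichment score, step by step.
brute_es <- function(scores, hit_index) {
  scores <- unname(scores)
  n <- length(scores)
  nh <- length(hit_index)
  denom <- sum(abs(scores[hit_index]))
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_index) {
      running <- running + (if (denom > 0) abs(scores[i]) / denom else 1 / nh)
    } else {
      running <- running - 1 / (n - nh)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Log-log regression on a binned degree histogram, written independently.
brute_scale_free_r2 <- function(k, n_bins = 10) {
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  idx <- findInterval(k, br, rightmost.closed = TRUE, all.inside = TRUE)
  xs <- ys <- numeric(0)
  for (b in seq_len(n_bins)) {
    kk <- k[idx == b]
    if (length(kk) == 0 || mean(kk) <= 0) next
    xs <- c(xs, log10(mean(kk)))
    ys <- c(ys, log10(length(kk)))
  }
  fit <- lm(ys ~ xs)
  unname(-sign(coef(fit)[2]) * summary(fit)$r.squared)
}

# First-beta-whose-suffix-stabilizes rule by exhaustive suffix enumeration.
brute_select_beta <- function(r2, tau, eps) {
  n <- length(r2)
  for (i in seq_len(n)) {
    if (r2[i] <= tau) next
    ok <- TRUE
    for (j in i:n) for (l in i:n)
      if (abs(r2[j] - r2[l]) >= eps) ok <- FALSE
    if (ok) return(i)
  }
  NA_integer_
}

random_adjacency <- function(n) {
  m <- matrix(runif(n * n), n)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  a
}
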