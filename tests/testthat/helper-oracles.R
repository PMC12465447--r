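# independent oracles used across tests; each is intentionally the
# simplest correct computation, never sharing code with the implementation

# symmetric Sinkhorn-Knopp scaling: fixed point x with x_i (A x)_i = 1
sinkhornOracle <- function(A, tol = 1e-12, maxit = 100000L) {
  x <- rep(1, nrow(A))
  for (k in seq_len(maxit)) {
    xn <- sqrt(x / as.numeric(A %*% x))
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  x
}

# brute-force nearest interval by edge distance, smaller start wins ties
nearestOracle <- function(qs, qe, fs, fe) {
  best <- NA_integer_; bestd <- Inf
  for (k in seq_along(fs)) {
    d <- if (qe < fs[k]) fs[k] - qe - 1
    else if (fe[k] < qs) qs - fe[k] - 1
    else 0
    if (d < bestd || (d == bestd && !is.na(best) && fs[k] < fs[best])) {
      best <- k; bestd <- d
    }
  }
  list(index = best, distance = bestd)
}

# exhaustive two-sided sign-test p over all 2^n sign patterns
signTestOracle <- function(k, n) {
  patterns <- expand.grid(rep(list(c(-1, 1)), n))
  sums <- abs(rowSums(patterns))
  mean(sums >= abs(2 * k - n))
}

# brute-force BH step-up
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, 0)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# Monte-Carlo permutation p-values for a grouped statistic; returns both
# tail conventions P(T >= obs) and P(T > obs) so a continuous
# approximation can be checked against the discrete null's bracket
permutationOracle <- function(groups, statFun, B = 10000L, seed = 99L) {
  set.seed(seed)
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  obs <- statFun(groups)
  geq <- gt <- 0L
  for (b in seq_len(B)) {
    perm <- sample(pooled)
    gs <- split(perm, rep(seq_along(sizes), sizes))
    s <- statFun(gs)
    if (s >= obs - 1e-12) geq <- geq + 1L
    if (s > obs + 1e-12) gt <- gt + 1L
  }
  list(geq = (geq + 1) / (B + 1), gt = (gt + 1) / (B + 1))
}

moodsStat <- function(groups) {
  unname(moodsMedianTest(groups)$statistic)
}

kruskalStat <- function(groups) {
  unname(kruskalDunn(groups)$kruskal$statistic)
}

# dense contact matrix wrapped as a ContactMatrix for unit tests
cmFromDense <- function(m, binSize = 1000L, chrom = "chrT") {
  n <- nrow(m)
  grid <- BinGrid(binSize, setNames(as.numeric(n * binSize), chrom))
  new("ContactMatrix", chrom = chrom, grid = grid,
      counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
      weights = rep(NA_real_, n), krConverged = NA, krIterations = 0L)
}

randomSymmetricPositive <- function(n) {
  a <- matrix(runif(n * n, 0.2, 2), n)
  (a + t(a)) / 2
}
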