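test_that("sign test reproduces closed forms and the exhaustive enumeration for n <= 12", {
  expect_equal(signTest(rep(1, 10))$p.value, 2 * (1 / 2)^10)      # 0.001953125
  expect_equal(signTest(c(rep(1, 8), rep(-1, 2)))$p.value, 0.109375)
  expect_equal(signTest(c(rep(1, 5), rep(-1, 5)))$p.value, 1)     # capped at centre
  for (n in c(3, 7, 12)) {
    for (k in 0:n) {
      d <- c(rep(1, k), rep(-1, n - k))
      expect_equal(signTest(d)$p.value, signTestOracle(k, n),
                   tolerance = 1e-12, label = sprintf("n=%d k=%d", n, k))
    }
  }
  # zeros are dropped from n_effective; all-zero input flags a missing p
  st <- signTest(c(0, 0, 1, 1, -1))
  expect_equal(st$n.effective, 3L)
  z <- signTest(c(0, 0))
  expect_true(is.na(z$p.value))
  # cross-check against the binomial-test reference
  expect_equal(signTest(c(rep(1, 9), rep(-1, 3)))$p.value,
               stats::binom.test(9, 12)$p.value, tolerance = 1e-12)
})

test_that("Mood's median test matches the hand-computed 2x2 chi-square", {
  r <- moodsMedianTest(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(r$statistic), 6)       # table [[0,3],[3,0]], no correction
  expect_equal(unname(r$parameter), 1L)
  expect_equal(r$p.value, pchisq(6, 1, lower.tail = FALSE))
  same <- moodsMedianTest(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
})

test_that("Mood's p-value is calibrated against a permutation oracle", {
  # the permutation null of the median dichotomy is discrete, so the
  # chi-square p must land inside the [P(T > obs), P(T >= obs)] bracket
  # (up to Monte-Carlo error), and close the bracket as n grows
  set.seed(67)
  mc <- 0.02
  for (shift in c(0, 0.8)) {
    g1 <- rnorm(15); g2 <- rnorm(15, shift)
    p_chi <- moodsMedianTest(list(g1, g2))$p.value
    o <- permutationOracle(list(g1, g2), moodsStat, B = 10000L)
    expect_gte(p_chi, o$gt - mc)
    expect_lte(p_chi, o$geq + mc)
  }
  g1 <- rnorm(60); g2 <- rnorm(60, 0.5)
  p_chi <- moodsMedianTest(list(g1, g2))$p.value
  o <- permutationOracle(list(g1, g2), moodsStat, B = 10000L)
  expect_lt(abs(p_chi - (o$geq + o$gt) / 2), 0.05)
})

test_that("pairwise Mood's comparisons feed BH-adjusted p-values", {
  set.seed(71)
  ctrl <- rnorm(20)
  gs <- list(a = rnorm(20, 2), b = rnorm(20), c = rnorm(20, 1))
  tab <- pairwiseMoodsVsControl(gs, ctrl)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$p.adjusted, bhAdjust(tab$p.value))
  expect_true(all(tab$p.adjusted >= tab$p.value - 1e-12))
})

test_that("BH adjustment equals brute-force step-up and the reference implementation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bhAdjust(0.7), 0.7)
  set.seed(73)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))^2
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_false(is.unsorted(q[order(p)]))
  }
})

test_that("pooled-variance t-test agrees with the reference on random samples", {
  set.seed(79)
  for (rep in 1:100) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = 1)
    r <- twoSampleT(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(r$statistic), unname(ref$statistic), tolerance = 1e-8)
    expect_equal(r$p.value, ref$p.value, tolerance = 1e-8)
  }
  a <- rnorm(10); b <- rnorm(10)
  rp <- twoSampleT(a, b, paired = TRUE)
  refp <- t.test(a, b, paired = TRUE)
  expect_equal(rp$p.value, refp$p.value, tolerance = 1e-10)
  # degenerate cases
  expect_equal(twoSampleT(1:4 * 0, 1:4 * 0)$p.value, 1)
  deg <- twoSampleT(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(deg$p.value, 0)
  expect_match(deg$notes, "zero")
})

test_that("Kruskal-Wallis H matches the hand rank-sum computation and the reference", {
  r <- kruskalDunn(list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22)))
  expect_equal(unname(r$kruskal$statistic), 7.2)   # 12/(9*10)*(6^2+15^2+24^2)/3 - 30
  expect_equal(unname(r$kruskal$parameter), 2L)
  ident <- kruskalDunn(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(unname(ident$kruskal$statistic), 0)
  expect_equal(ident$kruskal$p.value, 1)
  set.seed(83)
  for (rep in 1:20) {
    gs <- lapply(1:3, function(i) round(rnorm(sample(4:12, 1), i / 2), 1))  # with ties
    r <- kruskalDunn(gs)
    ref <- kruskal.test(gs)
    expect_equal(unname(r$kruskal$statistic), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$kruskal$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis p sits within Monte-Carlo error of a permutation oracle at small n", {
  set.seed(89)
  gs <- list(rnorm(6), rnorm(6, 1), rnorm(6, 0.5))
  p_chi <- kruskalDunn(gs)$kruskal$p.value
  o <- permutationOracle(gs, kruskalStat, B = 10000L)
  expect_gte(p_chi, o$gt - 0.04)
  expect_lte(p_chi, o$geq + 0.04)
})

test_that("Dunn's post hoc z-statistics are BH-adjusted and directionally sane", {
  set.seed(97)
  gs <- list(low = rnorm(12), mid = rnorm(12, 1), high = rnorm(12, 3))
  d <- kruskalDunn(gs)$dunn
  expect_equal(nrow(d), 3L)
  expect_equal(d$p.adjusted, bhAdjust(d$p.value))
  # low vs high must be the most extreme comparison
  z13 <- abs(d$z[d$group1 == 1 & d$group2 == 3])
  expect_true(all(z13 >= abs(d$z) - 1e-12))
  expect_lt(d$p.value[d$group1 == 1 & d$group2 == 3], 0.01)
})

test_that("correlation t-test follows the closed form and flags degeneracies", {
  x <- 1:12
  set.seed(101)
  # construct data with an exact target correlation via projection
  y0 <- rnorm(12)
  y <- scale(x)[, 1] * 0.5 + sqrt(1 - 0.25) * scale(resid(lm(y0 ~ x)))[, 1]
  r <- correlationTTest(x, y)
  expect_equal(unname(r$estimate), 0.5, tolerance = 1e-10)
  expect_equal(unname(r$statistic), 0.5 * sqrt(10 / 0.75), tolerance = 1e-10)
  ref <- cor.test(x, y)
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)

  exact <- correlationTTest(1:10, 2 * (1:10) + 1)
  expect_equal(exact$p.value, 0)
  expect_match(exact$notes, "exact linear fit")
  flat <- correlationTTest(1:10, rep(3, 10))
  expect_equal(unname(flat$estimate), 0)
  expect_equal(flat$p.value, 1)
  expect_warning(two <- correlationTTest(c(1, 2), c(5, 9)), "zero degrees")
  expect_true(is.na(two$p.value))
})

test_that("sign and Mood's tests hold their nominal type-I error under null simulation", {
  set.seed(103)
  B <- 10000L
  rejS <- rejM <- 0L
  for (b in seq_len(B)) {
    d <- rnorm(20)
    if (signTest(d)$p.value < 0.05) rejS <- rejS + 1L
  }
  for (b in seq_len(B)) {
    if (moodsMedianTest(list(rnorm(15), rnorm(15)))$p.value < 0.05) rejM <- rejM + 1L
  }
  slack <- 2.6 * sqrt(0.05 * 0.95 / B)
  expect_lte(rejS / B, 0.05 + slack)
  expect_lte(rejM / B, 0.05 + slack)
})
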