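test_that("the leading eigenvector resolves a two-block checkerboard exactly", {
  cc <- rbind(cbind(matrix(1, 10, 10), matrix(-1, 10, 10)),
              cbind(matrix(-1, 10, 10), matrix(1, 10, 10)))
  v <- compartmentEigenvector(cc)
  expect_equal(abs(v), rep(1 / sqrt(20), 20), tolerance = 1e-9)
  expect_true(all(sign(v[1:10]) == sign(v[1])))
  expect_true(all(sign(v[11:20]) == -sign(v[1])))
})

test_that("power iteration agrees with a dense eigensolver oracle", {
  set.seed(19)
  for (rep in 1:5) {
    x <- matrix(rnorm(30 * 60), 30)
    cc <- cor(t(x))                       # correlation-structured symmetric input
    v <- compartmentEigenvector(cc)
    e <- eigen(cc, symmetric = TRUE)
    vref <- e$vectors[, which.max(abs(e$values))]
    expect_gt(abs(sum(v * vref)), 1 - 1e-8)
  }
  # generic symmetric matrix, possibly negative dominant eigenvalue
  s <- matrix(rnorm(900), 30); s <- (s + t(s)) / 2
  v <- compartmentEigenvector(s)
  e <- eigen(s, symmetric = TRUE)
  vref <- e$vectors[, which.max(abs(e$values))]
  expect_gt(abs(sum(v * vref)), 1 - 1e-8)
})

test_that("eigenvector handles flat, masked, and tiny inputs", {
  flat <- matrix(1, 8, 8)
  v <- compartmentEigenvector(flat)
  expect_equal(v, rep(1 / sqrt(8), 8), tolerance = 1e-9)

  cc <- cor(t(matrix(rnorm(10 * 40), 10)))
  cc[4, ] <- NA; cc[, 4] <- NA
  v2 <- compartmentEigenvector(cc)
  expect_true(is.na(v2[4]))
  expect_equal(sum(v2^2, na.rm = TRUE), 1, tolerance = 1e-9)

  tiny <- matrix(NA_real_, 5, 5); tiny[1:2, 1:2] <- 1
  expect_true(all(is.na(compartmentEigenvector(tiny))))
})

test_that("eigenvector commutes with permutation of the correlation matrix", {
  set.seed(29)
  cc <- cor(t(matrix(rnorm(25 * 50), 25)))
  v <- compartmentEigenvector(cc)
  p <- sample(25)
  vp <- compartmentEigenvector(cc[p, p])
  # up to global sign, permuted scores match
  expect_gt(abs(sum(vp * v[p])), 1 - 1e-8)
})

test_that("orientation follows the active-minus-repressive rank evidence", {
  grid <- BinGrid(25000, c(chr1 = 250000))
  sc <- c(0.5, 0.4, 0.3, -0.2, -0.3, -0.4, 0.2, 0.3, -0.1, -0.2)
  act <- list(chr1 = as.numeric(sc > 0) * 10)
  rep9 <- list(chr1 = as.numeric(sc < 0) * 10)
  # already aligned: unchanged
  p1 <- orientEigenvector(list(chr1 = sc), act, rep9, grid)
  expect_equal(p1@scores$chr1, sc)
  expect_gte(p1@orientationEvidence[["chr1"]], 0)
  # anti-correlated: flipped
  p2 <- orientEigenvector(list(chr1 = -sc), act, rep9, grid)
  expect_equal(p2@scores$chr1, sc)
  # zero-variance evidence: unresolved, no flip
  expect_warning(
    p3 <- orientEigenvector(list(chr1 = sc), list(chr1 = rep(1, 10)),
                            list(chr1 = rep(1, 10)), grid),
    "unresolved")
  expect_true(is.na(p3@orientationEvidence[["chr1"]]))
})

test_that("delta scores subtract unit-normalised profiles with NA propagation", {
  grid <- BinGrid(25000, c(chr1 = 125000))
  mk <- function(s) new("CompartmentProfile", grid = grid,
                        scores = list(chr1 = s),
                        orientationEvidence = c(chr1 = 0.9), oriented = TRUE)
  s <- c(0.6, -0.2, 0.5, NA, 0.1)
  expect_equal(deltaScores(mk(s), mk(s))$chr1, c(0, 0, 0, NA, 0))
  a <- mk(c(1, 1, 1, 1, NA)); b <- mk(c(2, 2, 2, 2, NA))  # same direction, diff scale
  expect_equal(deltaScores(a, b)$chr1, c(0, 0, 0, 0, NA), tolerance = 1e-12)
})

test_that("ranking and grouping partitions A bins into ordered sets with remainder", {
  grid <- BinGrid(25000, c(chr1 = 25000 * 1300))
  set.seed(37)
  control <- runif(1300, -1, 1)
  control[1:1200] <- abs(control[1:1200])      # exactly 1200 A bins
  control[1201:1300] <- -abs(control[1201:1300])
  delta <- rnorm(1300, 0, 0.1)
  prof <- new("CompartmentProfile", grid = grid,
              scores = list(chr1 = control / sqrt(sum(control^2))),
              orientationEvidence = c(chr1 = 0.8), oriented = TRUE)
  g <- rankAndGroup(list(chr1 = delta), prof, 500L)
  expect_equal(as.integer(table(g@bins$group)), c(500L, 500L, 200L))
  expect_false(is.unsorted(g@bins$delta))
  # concatenated groups reproduce the sorted list exactly, nothing lost
  expect_setequal(g@bins$bin, 1:1200)
  # small case with remainder
  prof2 <- new("CompartmentProfile", grid = BinGrid(25000, c(chr1 = 25000 * 7)),
               scores = list(chr1 = rep(0.3, 7)),
               orientationEvidence = c(chr1 = 0.8), oriented = TRUE)
  g2 <- rankAndGroup(list(chr1 = rnorm(7)), prof2, 3L)
  expect_equal(as.integer(table(g2@bins$group)), c(3L, 3L, 1L))
  # ties in delta broken by bin index
  g3 <- rankAndGroup(list(chr1 = rep(0, 7)), prof2, 3L)
  expect_equal(g3@bins$bin, 1:7)
  # no A bins -> empty
  prof3 <- new("CompartmentProfile", grid = BinGrid(25000, c(chr1 = 25000 * 4)),
               scores = list(chr1 = rep(-0.5, 4)),
               orientationEvidence = c(chr1 = 0.8), oriented = TRUE)
  expect_equal(nrow(rankAndGroup(list(chr1 = rnorm(4)), prof3)@bins), 0L)
})

test_that("group expression feature uses nearest eligible protein-coding gene", {
  grid <- BinGrid(25000, c(chr1 = 250000))
  prof <- new("CompartmentProfile", grid = grid,
              scores = list(chr1 = rep(0.3, 10)),
              orientationEvidence = c(chr1 = 0.9), oriented = TRUE)
  g <- rankAndGroup(list(chr1 = seq(-0.5, 0.4, 0.1)), prof, 5L)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1), c(250000, 250000)),
                                  strand = "+")
  genes$gene_id <- c("gIn", "gOut")
  genes$biotype <- "protein_coding"
  genes$tss <- 1
  genes$log2cpm <- c(3, 0)      # log2 CPM 0 is excluded (must be > 0)
  genes$log2fc <- c(-2, 5)
  fe <- groupFeatureExpression(g, genes)
  expect_equal(fe$mean_log2fc, c(-2, -2))   # every bin inside gIn; gOut ineligible
  expect_equal(fe$n, c(5L, 5L))
})

test_that("genic fraction counts expressed-gene overlap and matches a scan oracle", {
  grid <- BinGrid(25000, c(chr1 = 250000))
  prof <- new("CompartmentProfile", grid = grid,
              scores = list(chr1 = rep(0.3, 10)),
              orientationEvidence = c(chr1 = 0.9), oriented = TRUE)
  g <- rankAndGroup(list(chr1 = 1:10 / 100), prof, 10L)
  set.seed(43)
  gs <- sort(sample.int(240000, 6)); ge <- gs + sample.int(30000, 6)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, ge), strand = "+")
  genes$gene_id <- paste0("g", 1:6); genes$biotype <- "protein_coding"
  genes$tss <- gs; genes$log2cpm <- 2; genes$log2fc <- 0
  gf <- groupFeatureGenicFraction(g, genes)
  # brute-force per-bin overlap scan
  overlap <- vapply(g@bins$bin, function(b) {
    bs <- (b - 1) * 25000 + 1; be <- b * 25000
    any(ge >= bs & gs <= be)
  }, TRUE)
  expect_equal(gf$genic_fraction, mean(overlap))
  expect_true(gf$genic_fraction >= 0 && gf$genic_fraction <= 1)
})

test_that("peak distance feature excludes genic and promoter-proximal peaks first", {
  grid <- BinGrid(25000, c(chr1 = 250000))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, 150000),
                                  strand = "+")
  genes$gene_id <- "g1"; genes$biotype <- "protein_coding"
  genes$tss <- 100000; genes$log2cpm <- 2; genes$log2fc <- 0
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(120000, 99700, 20000), c(121000, 99900, 21000)), signal = 1)
  surv <- intergenicPeaks(peaks, genes, 500L)
  # genic peak and the peak 100-300 bp upstream of the TSS are removed
  expect_length(surv, 1)
  expect_equal(GenomicRanges::start(surv), 20000)
  prof <- new("CompartmentProfile", grid = grid,
              scores = list(chr1 = rep(0.3, 10)),
              orientationEvidence = c(chr1 = 0.9), oriented = TRUE)
  g <- rankAndGroup(list(chr1 = 1:10 / 100), prof, 10L)
  pd <- groupFeaturePeakDistance(g, peaks, genes, 500L)
  # per-bin edge distance to the only surviving peak [20000,21000]
  d <- vapply(g@bins$bin, function(b) {
    bs <- (b - 1) * 25000 + 1; be <- b * 25000
    if (21000 >= bs && 20000 <= be) 0 else if (bs > 21000) bs - 21000 - 1 else 20000 - be - 1
  }, 0)
  expect_equal(pd$mean_distance, mean(d))
})

test_that("interval scores are length-weighted over overlapped bins", {
  grid <- BinGrid(100, c(chr1 = 1000))
  prof <- new("CompartmentProfile", grid = grid,
              scores = list(chr1 = c(1, 3, NA, 7, 9, 11, 13, 15, 17, 19) / 10),
              orientationEvidence = c(chr1 = 1), oriented = TRUE)
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  expect_equal(scoreAtIntervals(prof, gr(110, 150)), 0.3)          # inside bin 2
  expect_equal(scoreAtIntervals(prof, gr(51, 150)), 0.2)           # equal halves of bins 1-2
  expect_true(is.na(scoreAtIntervals(prof, gr(201, 290))))         # only a missing bin
  # per-base oracle on an interval straddling bins with a missing one
  iv <- gr(151, 420)
  base_scores <- prof@scores$chr1[((151:420) - 1) %/% 100 + 1]
  expect_equal(scoreAtIntervals(prof, iv), mean(base_scores, na.rm = TRUE))
})
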