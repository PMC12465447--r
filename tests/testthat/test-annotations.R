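test_that("chrom.sizes parsing preserves order and rejects bad input", {
  f <- withr::local_tempfile(lines = c("chr1\t20000000", "chr2 5000000"))
  cs <- readChromSizes(f)
  expect_identical(names(cs), c("chr1", "chr2"))
  expect_equal(unname(cs), c(2e7, 5e6))

  empty <- withr::local_tempfile(lines = character())
  expect_warning(cs0 <- readChromSizes(empty), "empty")
  expect_length(cs0, 0)

  dup <- withr::local_tempfile(lines = c("chr1 100", "chr1 200"))
  expect_error(readChromSizes(dup), "duplicate")
  neg <- withr::local_tempfile(lines = "chr1\t-5")
  expect_error(readChromSizes(neg), "non-positive")
})

test_that("BED reader keeps records as-is, converts coordinates, skips unknown chroms", {
  f <- withr::local_tempfile(lines = c(
    "chr1\t100\t200\tp1\t7",
    "chr1\t150\t300\tp2\t3",
    "chrUn\t0\t10\tp3\t1"))
  expect_warning(p <- readBed(f, chromSizes = c(chr1 = 1e6), mark = "H3K27ac"),
                 "1 BED record")
  expect_length(p, 2)                       # no auto-merge of overlaps
  expect_equal(GenomicRanges::start(p), c(101, 151))  # 0-based -> 1-based
  expect_equal(GenomicRanges::end(p), c(200, 300))
  expect_equal(p$signal, c(7, 3))
  expect_identical(S4Vectors::metadata(p)$mark, "H3K27ac")

  bad <- withr::local_tempfile(lines = "chr1\t200\t100")
  expect_error(readBed(bad), "start >= end")
})

test_that("interval distance follows edge-gap semantics", {
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  # half-open [100,200) vs [150,300) -> 1-based closed [101,200] vs [151,300]
  expect_equal(intervalDistance(gr(101, 200), gr(151, 300)), 0)   # overlap
  expect_equal(intervalDistance(gr(101, 200), gr(501, 600)), 300) # gap
  expect_equal(intervalDistance(gr(101, 200), gr(201, 300)), 0)   # abutting
  other <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 10))
  expect_true(is.na(intervalDistance(gr(1, 10), other)))
})

test_that("interval distance is symmetric and satisfies the triangle inequality", {
  set.seed(5)
  n <- 60
  s <- sample.int(1e5, n); w <- sample.int(5000, n)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + w))
  idx <- cbind(sample.int(n, 200, TRUE), sample.int(n, 200, TRUE),
               sample.int(n, 200, TRUE))
  dAB <- intervalDistance(gr[idx[, 1]], gr[idx[, 2]])
  dBA <- intervalDistance(gr[idx[, 2]], gr[idx[, 1]])
  dBC <- intervalDistance(gr[idx[, 2]], gr[idx[, 3]])
  dAC <- intervalDistance(gr[idx[, 1]], gr[idx[, 3]])
  expect_equal(dAB, dBA)
  expect_true(all(dAC <= dAB + dBC + (w[idx[, 2]] + 1)))  # via B's extent
})

test_that("nearestFeature matches an exhaustive scan with lower-start tie-break", {
  # spec example: query [0,25000) with genes at [30000,60000) and [100000,120000)
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 25000))
  feats <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(30001, 100001), c(60000, 120000)))
  nf <- nearestFeature(q, feats)
  expect_equal(nf$feature, 1L)
  expect_equal(nf$distance, 5000)

  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(35000, 36000))
  expect_equal(nearestFeature(inside, feats)$distance, 0)

  # equidistant features -> lower start
  q2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100))
  eq <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(6001, 3200), c(6500, 4099)))
  expect_equal(nearestFeature(q2, eq)$feature, 2L)  # both 900 away; start 3200 wins

  # 1000 random queries against the linear-scan oracle
  set.seed(11)
  fs <- sort(sample.int(5e5, 300)); fe <- fs + sample.int(3000, 300)
  fgr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(fs, fe))
  qs <- sample.int(5e5, 1000); qe <- qs + sample.int(2000, 1000)
  qgr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(qs, qe))
  nf <- nearestFeature(qgr, fgr)
  for (i in sample.int(1000, 60)) {  # spot-check a random subset densely
    o <- nearestOracle(qs[i], qe[i], fs, fe)
    expect_equal(nf$distance[i], o$distance)
    expect_equal(GenomicRanges::start(fgr)[nf$feature[i]], fs[o$index])
  }
  # and the full set agrees on distances
  alld <- vapply(seq_len(1000), function(i) nearestOracle(qs[i], qe[i], fs, fe)$distance, 0)
  expect_equal(nf$distance, alld)
})

test_that("nearestFeature respects the filter predicate and missing results", {
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500), c(200, 600)))
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 310))
  nf <- nearestFeature(q, feats, filter = c(FALSE, TRUE))
  expect_equal(nf$feature, 2L)
  nf2 <- nearestFeature(q, feats, filter = c(FALSE, FALSE))
  expect_true(is.na(nf2$feature) && is.na(nf2$distance))
})

test_that("peak merging coalesces overlap and abutment, and is idempotent and commutative", {
  gr <- function(s, e, mark = "H3K27ac") {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    S4Vectors::metadata(g)$mark <- mark
    g
  }
  m <- mergePeaks(gr(101, 200), gr(151, 300))
  expect_equal(c(GenomicRanges::start(m), GenomicRanges::end(m)), c(101, 300))
  m2 <- mergePeaks(gr(1, 50), gr(101, 150))
  expect_length(m2, 2)
  m3 <- mergePeaks(gr(1, 100), gr(101, 200))   # abutting halves coalesce
  expect_length(m3, 1)
  expect_error(mergePeaks(gr(1, 10), gr(1, 10, mark = "CTCF")), "different marks")

  set.seed(21)
  sa <- sort(sample.int(1e4, 20)); sb <- sort(sample.int(1e4, 20))
  a <- gr(sa, sa + sample.int(500, 20, TRUE))
  b <- gr(sb, sb + sample.int(700, 20, TRUE))
  ab <- mergePeaks(a, b); ba <- mergePeaks(b, a)
  expect_identical(GenomicRanges::start(ab), GenomicRanges::start(ba))
  again <- mergePeaks(ab, ab)
  expect_identical(GenomicRanges::ranges(again), GenomicRanges::ranges(ab))
  expect_lte(sum(GenomicRanges::width(ab)),
             sum(GenomicRanges::width(a)) + sum(GenomicRanges::width(b)))
})

test_that("gene table parsing derives strand-aware TSS and promoter windows", {
  f <- withr::local_tempfile(lines = c(
    "gene_id\tchrom\tstart\tend\tstrand\tbiotype",
    "gA\tchr1\t1000\t2000\t+\tprotein_coding",
    "gB\tchr1\t5000\t9000\t-\tprotein_coding"))
  g <- readGeneTable(f)
  expect_equal(g$tss, c(1000, 9000))
  up <- promoterUpstream(g, 500)
  expect_equal(GenomicRanges::start(up), c(500, 9000))
  expect_equal(GenomicRanges::end(up), c(1000, 9500))
})

test_that("bin grids round-trip positions and truncate the last bin", {
  grid <- BinGrid(25000, c(chr1 = 90000))
  expect_equal(nBins(grid, "chr1"), 4L)
  expect_equal(binIndex(grid, "chr1", c(1, 25000, 25001, 90000)), c(1, 1, 2, 4))
  br <- binRanges(grid, "chr1")
  expect_equal(GenomicRanges::end(br)[4], 90000)  # truncated
  st <- binStarts(grid, "chr1")
  expect_equal(binIndex(grid, "chr1", st), 1:4)   # round-trip
  expect_error(binIndex(grid, "chr1", 90001), "beyond chromosome")
})
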