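# shared synthetic fixtures, built once per test run and cached

.fixtureCache <- new.env(parent = emptyenv())

# full default-condition fixture processed through the pipeline stages
# used by the compartment / local-interaction acceptance checks
mainFixture <- function() {
  if (!is.null(.fixtureCache$main)) return(.fixtureCache$main)
  dir <- file.path(tempdir(), "cohesinHiC_main_fixture")
  fx <- simulateFixture(dir, syntheticConfig(seed = 1))
  cs <- readChromSizes(fx$paths$chrom_sizes)
  gridL <- BinGrid(5000, cs)
  gridC <- BinGrid(25000, cs)
  proc <- function(path) {
    flt <- filterPairs(readPairs(path, cs))
    list(local = lapply(binPairs(flt$pairs, gridL)$matrices, krBalance),
         compartment = lapply(binPairs(flt$pairs, gridC)$matrices, krBalance),
         report = flt$report)
  }
  mats <- list(control = proc(fx$paths$pairs_control),
               cko = proc(fx$paths$pairs_cko))
  act <- binnedPeakDensity(fx$annotation$peaks$H3K27ac, gridC)
  rep9 <- binnedPeakDensity(fx$annotation$peaks$H3K9me3, gridC)
  profiles <- lapply(mats, function(m)
    compartmentProfile(m$compartment, act, rep9))
  delta <- deltaScores(profiles$control, profiles$cko)
  genes <- fx$annotation$genes
  idx <- match(genes$gene_id, fx$expression$gene_id)
  genes$log2cpm <- fx$expression$log2cpm[idx]
  genes$log2fc <- fx$expression$log2fc[idx]
  .fixtureCache$main <- list(
    fx = fx, cs = cs, gridL = gridL, gridC = gridC, mats = mats,
    profiles = profiles, delta = delta, genes = genes,
    manifest = fx$annotation$manifest, peaks = fx$annotation$peaks)
  .fixtureCache$main
}

# distance-dependence fixtures: flips planted only at distal enhancers,
# or uniformly across enhancers, 60 target genes
distanceFixture <- function(mode) {
  key <- paste0("dist_", mode)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  cfg <- syntheticConfig(seed = 1, n_target_genes = 60L, n_other_genes = 40L,
                         flip_mode = mode)
  dir <- file.path(tempdir(), paste0("cohesinHiC_fx_", mode))
  fx <- simulateFixture(dir, cfg)
  cs <- readChromSizes(fx$paths$chrom_sizes)
  gridC <- BinGrid(25000, cs)
  proc <- function(path)
    lapply(binPairs(filterPairs(readPairs(path, cs))$pairs, gridC)$matrices,
           krBalance)
  act <- binnedPeakDensity(fx$annotation$peaks$H3K27ac, gridC)
  rep9 <- binnedPeakDensity(fx$annotation$peaks$H3K9me3, gridC)
  profiles <- list(
    control = compartmentProfile(proc(fx$paths$pairs_control), act, rep9),
    cko = compartmentProfile(proc(fx$paths$pairs_cko), act, rep9))
  delta <- deltaScores(profiles$control, profiles$cko)
  genes <- fx$annotation$genes
  enh <- classifyEnhancers(fx$annotation$peaks$H3K27ac,
                           fx$annotation$peaks$H3K4me3, genes)
  res <- enhancerDistanceVsDeltaScore(genes[genes$class == "target"], enh,
                                      genes, delta, gridC)
  .fixtureCache[[key]] <- list(fx = fx, delta = delta, result = res)
  .fixtureCache[[key]]
}

# hand-enumerable gene/peak layout used by exactness tests: coordinates
# chosen so every enhancer call and flank assignment is checkable by eye
handLayout <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(10000, 60000, 200000, 400000, 520000),
                     end = c(30000, 90000, 260000, 470000, 560000)),
    strand = c("+", "-", "+", "+", "-"))
  genes$gene_id <- paste0("g", 1:5)
  genes$biotype <- c("protein_coding", "protein_coding", "protein_coding",
                     "other", "protein_coding")
  genes$tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                      GenomicRanges::end(genes), GenomicRanges::start(genes))
  genes
}
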