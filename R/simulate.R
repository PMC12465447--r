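#' Default configuration of the synthetic fixture generator
#'
#' The defaults define the standard desk-scale study conditions: one
#' 20 Mb chromosome, 25 Kb compartment bins, 50 cohesin target genes with
#' planted intergenic enhancer clusters (distances in [20, 400] Kb,
#' right-skewed as enhancer-gene distances are), 60 further active genes,
#' 10 lowly expressed genes inside B blocks, 30 planted A->B compartment
#' flips at intergenic enhancer bins, loop depletion factor 0.5 at target
#' genes, power-law contact decay (alpha = 1), compartment strength
#' kappa = 0.6, loop/TAD boost 3x, and 2e6 sampled contact pairs.
#'
#' @param ... overrides for any default entry.
#' @return named list of generator parameters.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    chrom_sizes = c(chr1 = 20e6),
    bin_size_compartment = 25000L,
    bin_size_local = 5000L,
    n_target_genes = 50L,
    n_other_genes = 60L,
    n_b_genes = 10L,
    gene_length_range = c(30000, 80000),
    other_gene_length_range = c(20000, 80000),
    genes_per_a_segment = c(2L, 5L),
    b_segment_bins = c(6L, 12L),
    enhancer_dist_range = c(20000, 400000),
    enhancer_dist_shape = c(1, 3),  # Beta shape: right-skewed distances
    enhancer_width = 1500,
    n_flips = 30L,
    flip_mode = "enhancer",   # "enhancer" | "distal_only" | "uniform"
    distal_cutoff = 100000,
    loop_boost = 3,
    depletion_factor = 0.5,
    kappa = 0.6,
    alpha = 1.0,
    n_pairs = 2e6,
    short_pair_rate = 0.002,
    duplicate_rate = 0.001,
    n_reps = 3L,
    dispersion = 0.05,
    expr_library_size = 1e6,
    target_log2fc_range = c(-2.5, -1),
    n_up_genes = 15L,
    up_log2fc = 1)
  utils::modifyList(cfg, list(...))
}

#' Simulate a genome annotation with planted regulatory layout
#'
#' Lays out alternating A/B compartment segments on each chromosome
#' (segment boundaries snapped to the compartment bin size so every bin
#' has a definite sign): A segments hold gene cassettes - target genes
#' preceded by an intergenic enhancer flank, plus ordinary genes - and B
#' segments are gene deserts tiled by H3K9me3, with a few lowly expressed
#' genes. Generates matched ChIP peak sets (H3K4me3 at TSSs, H3K27ac at
#' promoters and enhancers, RAD21 at target promoters/enhancers, CTCF at
#' segment boundaries, H3K9me3 over B blocks) and the [TruthManifest].
#'
#' @param config list from [syntheticConfig()].
#' @return list with `genes` (GRanges), `peaks` (named list of GRanges),
#'   `chromSizes`, `manifest` ([TruthManifest]), `config`.
#' @export
simulateAnnotation <- function(config = syntheticConfig()) {
  set.seed(config$seed %% .Machine$integer.max)
  bw <- config$bin_size_compartment
  snapUp <- function(x) ceiling(x / bw) * bw
  geneRows <- list(); enhRows <- list(); segRows <- list()
  signList <- list()
  nT <- config$n_target_genes; nO <- config$n_other_genes
  for (ch in names(config$chrom_sizes)) {
    L <- config$chrom_sizes[[ch]]
    nbin <- as.integer(ceiling(L / bw))
    # draw the gene slots for this chromosome (single-chromosome default
    # gets everything; multi-chromosome configs split proportionally)
    frac <- L / sum(config$chrom_sizes)
    nTc <- round(nT * frac); nOc <- round(nO * frac)
    slots <- sample(c(rep("target", nTc), rep("other", nOc)))
    # draw cassette dimensions up front so the layout can be rescaled to fit
    slotGap <- runif(length(slots), 5000, 20000)
    slotLen <- ifelse(slots == "target",
                      runif(length(slots), config$gene_length_range[1],
                            config$gene_length_range[2]),
                      runif(length(slots), config$other_gene_length_range[1],
                            config$other_gene_length_range[2]))
    dr <- config$enhancer_dist_range
    slotFlank <- ifelse(slots == "target",
                        dr[1] + (dr[2] - dr[1]) *
                          rbeta(length(slots), config$enhancer_dist_shape[1],
                                config$enhancer_dist_shape[2]) + 5000,
                        0)
    nSeg <- ceiling(length(slots) / mean(config$genes_per_a_segment))
    bSegLen <- sample(config$b_segment_bins[1]:config$b_segment_bins[2],
                      nSeg + 1L, replace = TRUE) * bw
    need <- sum(slotGap + slotLen + slotFlank) + sum(bSegLen) + bw * nSeg
    budget <- 0.98 * L
    if (need > budget) {
      # shrink flanks, gaps and B segments (never gene bodies) to fit
      sc <- (budget - sum(slotLen) - bw * nSeg) /
        (sum(slotGap + slotFlank) + sum(bSegLen))
      if (sc <= 0) stop("chromosome too small for the requested gene layout")
      slotGap <- slotGap * sc
      slotFlank <- pmax(slotFlank * sc, ifelse(slots == "target", dr[1] + 5000, 0))
      bSegLen <- pmax(round(bSegLen * sc / bw), 2) * bw
    }
    cursor <- 0
    slotIdx <- 0L
    segId <- 0L
    sign <- rep(-1, nbin)
    while (slotIdx < length(slots) && cursor < L - 2 * bw) {
      segId <- segId + 1L
      # B segment first
      bLen <- bSegLen[min(segId, length(bSegLen))]
      bStart <- cursor + 1
      cursor <- min(cursor + bLen, L)
      segRows[[length(segRows) + 1L]] <-
        data.frame(chrom = ch, start = bStart, end = cursor, type = "B")
      if (slotIdx >= length(slots)) break
      # A segment with 2-5 cassettes
      kGenes <- sample(config$genes_per_a_segment[1]:config$genes_per_a_segment[2], 1)
      aStart <- cursor + 1
      for (k in seq_len(kGenes)) {
        if (slotIdx >= length(slots)) break
        slotIdx <- slotIdx + 1L
        gStart <- cursor + slotGap[slotIdx] + slotFlank[slotIdx]
        gEnd <- gStart + slotLen[slotIdx]
        if (gEnd > L - 2 * bw) { slotIdx <- slotIdx - 1L; break }
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          chrom = ch, start = round(gStart), end = round(gEnd),
          strand = sample(c("+", "-"), 1),
          type = slots[slotIdx], segment = segId)
        if (slots[slotIdx] == "target") {
          gi <- length(geneRows)
          nEnh <- 1L + stats::rbinom(1, 1, 0.5)
          dmax <- slotFlank[slotIdx] - 5000
          dists <- if (nEnh == 1L) dmax else c(dmax, max(dr[1], dmax * runif(1, 0.3, 0.8)))
          for (dd in dists) {
            mid <- round(gStart - dd)
            enhRows[[length(enhRows) + 1L]] <- data.frame(
              chrom = ch, gene_row = gi,
              start = round(mid - config$enhancer_width / 2),
              end = round(mid + config$enhancer_width / 2),
              distance = round(dd))
          }
        }
        cursor <- gEnd
      }
      cursor <- min(snapUp(cursor + 5000), L)
      segRows[[length(segRows) + 1L]] <-
        data.frame(chrom = ch, start = aStart, end = cursor, type = "A")
      aBins <- (floor((aStart - 1) / bw) + 1L):min(ceiling(cursor / bw), nbin)
      sign[aBins] <- 1
    }
    signList[[ch]] <- sign
  }
  genesDf <- do.call(rbind, geneRows)
  if (is.null(genesDf)) stop("no genes could be placed; enlarge the chromosome")
  genesDf$gene_id <- sprintf("gene%03d", seq_len(nrow(genesDf)))
  enhDf <- do.call(rbind, enhRows)
  if (is.null(enhDf))
    enhDf <- data.frame(chrom = character(), gene_row = integer(),
                        start = numeric(), end = numeric(),
                        distance = numeric())
  enhDf$gene_id <- genesDf$gene_id[enhDf$gene_row]
  segDf <- do.call(rbind, segRows)
  # a few lowly expressed genes inside B segments
  bSegs <- segDf[segDf$type == "B" & (segDf$end - segDf$start) > 80000, ]
  nB <- min(config$n_b_genes, nrow(bSegs))
  if (nB > 0) {
    pick <- sample(nrow(bSegs), nB)
    bGenes <- data.frame(
      chrom = bSegs$chrom[pick],
      start = round(bSegs$start[pick] + 10000),
      end = round(pmin(bSegs$start[pick] + 10000 +
                         runif(nB, 30000, 60000), bSegs$end[pick] - 5000)),
      strand = sample(c("+", "-"), nB, replace = TRUE),
      type = "b_gene", segment = NA_integer_,
      gene_id = sprintf("bgene%02d", seq_len(nB)))
    genesDf <- rbind(genesDf, bGenes)
  }
  genesDf$biotype <- ifelse(genesDf$type == "other" &
                              seq_len(nrow(genesDf)) %% 10 == 0,
                            "other", "protein_coding")
  genes <- GenomicRanges::GRanges(genesDf$chrom,
                                  IRanges::IRanges(genesDf$start, genesDf$end),
                                  strand = genesDf$strand)
  genes$gene_id <- genesDf$gene_id
  genes$biotype <- genesDf$biotype
  genes$class <- genesDf$type
  genes$tss <- ifelse(genesDf$strand == "-", genesDf$end, genesDf$start)
  ord <- order(genesDf$chrom, genesDf$start)
  genes <- genes[ord]

  peaks <- buildPeakSets(genes, enhDf, segDf, config)

  # planted A->B flips at intergenic enhancer bins
  enhMid <- (enhDf$start + enhDf$end) %/% 2
  enhBin <- floor((enhMid - 1) / bw) + 1L
  enhTab <- data.frame(chrom = enhDf$chrom, bin = enhBin,
                       distance = enhDf$distance)
  flips <- switch(config$flip_mode,
    enhancer = {
      u <- unique(enhTab[, c("chrom", "bin")])
      if (nrow(u)) u[sample(nrow(u), min(config$n_flips, nrow(u))), ] else u
    },
    distal_only = unique(enhTab[enhTab$distance > config$distal_cutoff,
                                c("chrom", "bin")]),
    uniform = {
      nDistal <- nrow(unique(enhTab[enhTab$distance > config$distal_cutoff,
                                    c("chrom", "bin")]))
      u <- unique(enhTab[, c("chrom", "bin")])
      u[sample(nrow(u), min(nDistal, nrow(u))), ]
    },
    stop("unknown flip_mode: ", config$flip_mode))
  rownames(flips) <- NULL
  ckoSign <- signList
  for (r in seq_len(nrow(flips)))
    ckoSign[[flips$chrom[r]]][flips$bin[r]] <- -1

  targets <- genesDf$gene_id[genesDf$type == "target"]
  nonTarget <- genesDf$gene_id[genesDf$type == "other"]
  upPick <- sample(nonTarget, min(config$n_up_genes, length(nonTarget)))
  de <- rbind(
    data.frame(gene_id = targets,
               log2fc = runif(length(targets), config$target_log2fc_range[1],
                              config$target_log2fc_range[2])),
    data.frame(gene_id = upPick,
               log2fc = rep(config$up_log2fc, length(upPick))))
  manifest <- new("TruthManifest",
                  compartmentSign = list(control = signList, cko = ckoSign),
                  flippedBins = flips,
                  loopDepletedGenes = data.frame(
                    gene_id = targets,
                    depletion = rep(config$depletion_factor, length(targets))),
                  deGenes = de,
                  enhancerLayout = data.frame(
                    gene_id = enhDf$gene_id, chrom = enhDf$chrom,
                    start = enhDf$start, end = enhDf$end,
                    distance = enhDf$distance),
                  binSize = as.integer(bw),
                  seed = as.integer(config$seed))
  list(genes = genes, peaks = peaks, chromSizes = config$chrom_sizes,
       manifest = manifest, segments = segDf, config = config)
}

# ChIP peak sets implied by the planted layout
buildPeakSets <- function(genes, enhDf, segDf, config) {
  gr <- function(df, sig, mark) {
    g <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                signal = sig)
    g <- GenomicRanges::sort(g, ignore.strand = TRUE)
    S4Vectors::metadata(g)$mark <- mark
    g
  }
  expressedTss <- genes$tss[genes$class != "b_gene"]
  tssCh <- as.character(GenomeInfoDb::seqnames(genes))[genes$class != "b_gene"]
  k4 <- data.frame(chrom = tssCh, start = pmax(1, expressedTss - 750),
                   end = expressedTss + 750)
  prom <- data.frame(chrom = tssCh, start = pmax(1, expressedTss - 1000),
                     end = expressedTss + 1000)
  k27 <- rbind(prom, enhDf[, c("chrom", "start", "end")])
  isTarget <- genes$class == "target"
  rad21 <- rbind(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes))[isTarget],
               start = pmax(1, genes$tss[isTarget] - 400),
               end = genes$tss[isTarget] + 400),
    enhDf[, c("chrom", "start", "end")])
  bounds <- unique(data.frame(chrom = segDf$chrom,
                              pos = c(segDf$start, segDf$end)))
  ctcf <- data.frame(chrom = bounds$chrom, start = pmax(1, bounds$pos - 250),
                     end = bounds$pos + 250)
  bseg <- segDf[segDf$type == "B", ]
  k9 <- data.frame(chrom = bseg$chrom, start = bseg$start, end = bseg$end)
  list(
    H3K4me3 = gr(k4, runif(nrow(k4), 5, 15), "H3K4me3"),
    H3K27ac = gr(k27, runif(nrow(k27), 5, 20), "H3K27ac"),
    RAD21 = gr(rad21, runif(nrow(rad21), 3, 12), "RAD21"),
    CTCF = gr(ctcf, runif(nrow(ctcf), 5, 15), "CTCF"),
    H3K9me3 = gr(k9, runif(nrow(k9), 3, 8), "H3K9me3"))
}

#' Simulate a Hi-C valid-pairs file for one condition
#'
#' Contact probability at the 5 Kb bin level is
#' `P(i,j) propto (1 + |i-j|)^(-alpha) * (1 + kappa * c_i * c_j) * L(i,j)`
#' with compartment signs `c` taken from the manifest for the requested
#' condition, and a loop/TAD factor `L` boosting bin pairs within target
#' gene bodies and promoter-enhancer pairs (boost reduced by the
#' depletion factor in the cKO condition). Pairs are sampled to the
#' requested depth with positions uniform within bins; a small rate of
#' sub-1 Kb and duplicate pairs is injected to exercise the filters.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param condition "control" or "cko".
#' @param path output pairs file path.
#' @param nPairs sampling depth (default from the annotation's config).
#' @param seed RNG seed for this stream.
#' @return invisibly, the pairs data.table that was written.
#' @export
simulateContacts <- function(annotation, condition = c("control", "cko"),
                             path, nPairs = NULL, seed = NULL) {
  condition <- match.arg(condition)
  cfg <- annotation$config
  manifest <- annotation$manifest
  if (is.null(nPairs)) nPairs <- cfg$n_pairs
  if (is.null(seed)) seed <- cfg$seed + ifelse(condition == "control", 101L, 202L)
  set.seed(seed %% .Machine$integer.max)
  bw5 <- cfg$bin_size_local
  bwC <- manifest@binSize
  expand <- bwC / bw5
  genes <- annotation$genes
  enh <- manifest@enhancerLayout
  depl <- manifest@loopDepletedGenes
  chunks <- list()
  alloc <- round(nPairs * annotation$chromSizes / sum(annotation$chromSizes))
  for (ch in names(annotation$chromSizes)) {
    L <- annotation$chromSizes[[ch]]
    n5 <- as.integer(ceiling(L / bw5))
    signC <- manifest@compartmentSign[[condition]][[ch]]
    c5 <- rep(signC, each = expand)[seq_len(n5)]
    # flat upper-triangle enumeration, column-major: idx = j(j-1)/2 + i
    jj <- rep.int(seq_len(n5), seq_len(n5))
    ii <- sequence(seq_len(n5))
    p <- (1 + (jj - ii))^(-cfg$alpha) * (1 + cfg$kappa * c5[ii] * c5[jj])
    off <- as.numeric(seq_len(n5)) * (seq_len(n5) - 1) / 2
    flatIdx <- function(i, j) off[j] + i  # requires i <= j
    boost <- rep(1, length(p))
    onCh <- as.character(GenomeInfoDb::seqnames(genes)) == ch
    for (g in which(onCh & genes$class == "target")) {
      gid <- genes$gene_id[g]
      fac <- cfg$loop_boost
      if (condition == "cko" && gid %in% depl$gene_id)
        fac <- max(1, fac * depl$depletion[match(gid, depl$gene_id)])
      b1 <- (GenomicRanges::start(genes)[g] - 1) %/% bw5 + 1
      b2 <- min((GenomicRanges::end(genes)[g] - 1) %/% bw5 + 1, n5)
      gb <- b1:b2
      pr <- expand.grid(i = gb, j = gb)
      pr <- pr[pr$i <= pr$j, ]
      boost[flatIdx(pr$i, pr$j)] <- fac
      # promoter-enhancer pairs
      pBin <- (genes$tss[g] - 1) %/% bw5 + 1
      eRows <- enh[enh$gene_id == gid, , drop = FALSE]
      if (nrow(eRows)) {
        eBin <- pmin(((eRows$start + eRows$end) %/% 2 - 1) %/% bw5 + 1, n5)
        lo <- pmin(pBin, eBin); hi <- pmax(pBin, eBin)
        boost[flatIdx(lo, hi)] <- fac
      }
    }
    p <- p * boost
    k <- alloc[[ch]]
    if (k == 0) next
    draw <- sample.int(length(p), k, replace = TRUE, prob = p)
    j <- findInterval(draw - 0.5, off)
    i <- as.integer(draw - off[j])
    pos1 <- pmin((i - 1) * bw5 + floor(runif(k) * bw5) + 1, L)
    pos2 <- pmin((j - 1) * bw5 + floor(runif(k) * bw5) + 1, L)
    swap <- pos1 > pos2
    tmp <- pos1[swap]; pos1[swap] <- pos2[swap]; pos2[swap] <- tmp
    dt <- data.table::data.table(
      chrom1 = ch, pos1 = pos1, chrom2 = ch, pos2 = pos2,
      strand1 = sample(c("+", "-"), k, replace = TRUE),
      strand2 = sample(c("+", "-"), k, replace = TRUE))
    # injected sub-1Kb and duplicate pairs (removed by filterPairs)
    nShort <- round(k * cfg$short_pair_rate)
    if (nShort > 0) {
      sp <- pmin(floor(runif(nShort) * (L - 2000)) + 1, L)
      dt <- rbind(dt, data.table::data.table(
        chrom1 = ch, pos1 = sp, chrom2 = ch,
        pos2 = sp + floor(runif(nShort) * 999),
        strand1 = "+", strand2 = "-"))
    }
    nDup <- round(k * cfg$duplicate_rate)
    if (nDup > 0) dt <- rbind(dt, dt[sample(.N, nDup)])
    chunks[[ch]] <- dt
  }
  pairs <- data.table::rbindlist(chunks)
  pairs <- pairs[sample(.N)]  # shuffle: binning must be order-independent
  writePairsFile(pairs, path, annotation$chromSizes)
  invisible(pairs)
}

#' Write a pairs table in 4DN pairs text format
#'
#' @param pairs data.table with chrom1, pos1, chrom2, pos2, strand1,
#'   strand2.
#' @param path output path.
#' @param chromSizes named chromosome length vector for the header.
#' @export
writePairsFile <- function(pairs, path, chromSizes) {
  hdr <- c("## pairs format v1.0",
           "#shape: upper triangle",
           sprintf("#chromsize: %s %d", names(chromSizes), chromSizes),
           "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  writeLines(hdr, path)
  out <- data.table::data.table(readID = ".", pairs[, c(
    "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")])
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Simulate negative-binomial expression counts for both conditions
#'
#' Gene means are tied to compartment (active A genes high, B-block genes
#' low, a few near-zero to exercise the expression filter); the
#' manifest's true log2 fold changes are applied to the cKO means.
#' Observed CPM and log2FC columns are emitted alongside the counts.
#'
#' @param annotation output of [simulateAnnotation()].
#' @param nReps replicates per condition (default from config).
#' @param dispersion NB dispersion (default from config; 0 = Poisson).
#' @param seed RNG seed.
#' @return data.frame with gene_id, per-replicate counts for both
#'   conditions, cpm_ctrl, cpm_cko, log2cpm (control), log2fc (observed).
#' @export
simulateExpression <- function(annotation, nReps = NULL, dispersion = NULL,
                               seed = NULL) {
  cfg <- annotation$config
  if (is.null(nReps)) nReps <- cfg$n_reps
  if (is.null(dispersion)) dispersion <- cfg$dispersion
  if (is.null(seed)) seed <- cfg$seed + 303L
  set.seed(seed %% .Machine$integer.max)
  genes <- annotation$genes
  de <- annotation$manifest@deGenes
  nG <- length(genes)
  mu <- exp(rnorm(nG, log(300), 0.6))
  isB <- genes$class == "b_gene"
  mu[isB] <- exp(rnorm(sum(isB), log(5), 0.5))
  # half the B-block genes near-silent: control log2 CPM <= 0
  silent <- which(isB)[seq_len(ceiling(sum(isB) / 2))]
  mu[silent] <- 0.02
  lfc <- rep(0, nG)
  hit <- match(de$gene_id, genes$gene_id)
  lfc[hit] <- de$log2fc
  drawMat <- function(m) {
    sapply(seq_len(nReps), function(r) {
      if (dispersion <= 0) rpois(nG, m) else rnbinom(nG, mu = m, size = 1 / dispersion)
    })
  }
  ctrl <- drawMat(mu)
  cko <- drawMat(mu * 2^lfc)
  # CPM against the nominal whole-transcriptome depth: the simulated genes
  # cover only a small genomic region, so their own count total is not a
  # meaningful library size
  cpm <- function(m) m / (cfg$expr_library_size %||% 1e6) * 1e6
  cpmC <- rowMeans(cpm(ctrl)); cpmK <- rowMeans(cpm(cko))
  out <- data.frame(gene_id = genes$gene_id)
  for (r in seq_len(nReps)) out[[sprintf("ctrl_%d", r)]] <- ctrl[, r]
  for (r in seq_len(nReps)) out[[sprintf("cko_%d", r)]] <- cko[, r]
  out$cpm_ctrl <- cpmC
  out$cpm_cko <- cpmK
  out$log2cpm <- log2(cpmC)
  out$log2fc <- log2((cpmK + 0.5) / (cpmC + 0.5))
  out
}

#' Simulate a two-channel 3D FISH volume with planted probe spots
#'
#' Gaussian blobs at a requested physical separation on an anisotropic
#' voxel grid (0.3 um optical sections by default), with Poisson noise at
#' a requested signal-to-noise ratio (peak amplitude over background
#' noise standard deviation).
#'
#' @param separationUm planted probe separation in um.
#' @param snr signal-to-noise ratio, default 5.
#' @param dims volume dimensions (z, y, x), default c(26, 64, 64).
#' @param spacing voxel size (z, y, x) um, default c(0.3, 0.1, 0.1).
#' @param blobSigmaUm physical blob sigma, default 0.25.
#' @param background mean background level (counts), default 20.
#' @param seed RNG seed.
#' @return list with `volA`, `volB` (arrays), `truthA`, `truthB`
#'   (centroids in um), `spacing`, `separation`.
#' @export
simulateFishVolume <- function(separationUm, snr = 5,
                               dims = c(26L, 64L, 64L),
                               spacing = c(0.3, 0.1, 0.1),
                               blobSigmaUm = 0.25, background = 20,
                               seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  ext <- (dims - 1) * spacing
  margin <- 3 * blobSigmaUm
  repeat {
    a <- margin + runif(3) * (ext - 2 * margin)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    b <- a + separationUm * u
    if (all(b >= margin & b <= ext - margin)) break
  }
  amp <- snr * sqrt(background)
  render <- function(centre) {
    zs <- (seq_len(dims[1]) - 1) * spacing[1]
    ys <- (seq_len(dims[2]) - 1) * spacing[2]
    xs <- (seq_len(dims[3]) - 1) * spacing[3]
    gz <- exp(-(zs - centre[1])^2 / (2 * blobSigmaUm^2))
    gy <- exp(-(ys - centre[2])^2 / (2 * blobSigmaUm^2))
    gx <- exp(-(xs - centre[3])^2 / (2 * blobSigmaUm^2))
    blob <- outer(gz, outer(gy, gx))
    arr <- background + amp * array(blob, dims)
    array(rpois(length(arr), arr), dims)
  }
  list(volA = render(a), volB = render(b), truthA = a, truthB = b,
       spacing = spacing, separation = separationUm)
}

#' Generate and write a complete synthetic fixture
#'
#' Writes chrom.sizes, the gene table, per-mark BED peak files, the
#' expression table, both conditions' pairs files and the truth manifest
#' (JSON) into a directory.
#'
#' @param dir output directory (created if needed).
#' @param config list from [syntheticConfig()].
#' @return list with all in-memory objects and a `paths` list.
#' @export
simulateFixture <- function(dir, config = syntheticConfig()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulateAnnotation(config)
  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genes = file.path(dir, "genes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    pairs_control = file.path(dir, "control.pairs"),
    pairs_cko = file.path(dir, "cko.pairs"),
    manifest = file.path(dir, "manifest.json"))
  writeLines(sprintf("%s\t%d", names(ann$chromSizes), ann$chromSizes),
             paths$chrom_sizes)
  gdf <- data.frame(gene_id = ann$genes$gene_id,
                    chrom = as.character(GenomeInfoDb::seqnames(ann$genes)),
                    start = GenomicRanges::start(ann$genes),
                    end = GenomicRanges::end(ann$genes),
                    strand = as.character(GenomicRanges::strand(ann$genes)),
                    biotype = ann$genes$biotype,
                    class = ann$genes$class)
  data.table::fwrite(gdf, paths$genes, sep = "\t")
  for (mark in names(ann$peaks)) {
    p <- ann$peaks[[mark]]
    paths[[paste0("peaks_", mark)]] <- file.path(dir, sprintf("%s.bed", mark))
    data.table::fwrite(data.table::data.table(
      chrom = as.character(GenomeInfoDb::seqnames(p)),
      start = GenomicRanges::start(p) - 1L,
      end = GenomicRanges::end(p),
      name = sprintf("%s_%d", mark, seq_along(p)),
      signal = p$signal), paths[[paste0("peaks_", mark)]],
      sep = "\t", col.names = FALSE)
  }
  expr <- simulateExpression(ann)
  data.table::fwrite(expr, paths$expression, sep = "\t")
  simulateContacts(ann, "control", paths$pairs_control)
  simulateContacts(ann, "cko", paths$pairs_cko)
  writeTruthManifest(ann$manifest, paths$manifest)
  list(annotation = ann, expression = expr, manifest = ann$manifest,
       paths = paths)
}

#' Serialise / restore a truth manifest as JSON
#'
#' @param manifest a [TruthManifest].
#' @param path JSON path.
#' @export
writeTruthManifest <- function(manifest, path) {
  jsonlite::write_json(list(
    bin_size = manifest@binSize, seed = manifest@seed,
    compartment_sign = manifest@compartmentSign,
    flipped_bins = manifest@flippedBins,
    loop_depleted_genes = manifest@loopDepletedGenes,
    de_genes = manifest@deGenes,
    enhancer_layout = manifest@enhancerLayout),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TruthManifest",
      compartmentSign = lapply(j$compartment_sign, function(cond)
        lapply(cond, as.numeric)),
      flippedBins = as.data.frame(j$flipped_bins),
      loopDepletedGenes = as.data.frame(j$loop_depleted_genes),
      deGenes = as.data.frame(j$de_genes),
      enhancerLayout = as.data.frame(j$enhancer_layout),
      binSize = as.integer(j$bin_size), seed = as.integer(j$seed))
}
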