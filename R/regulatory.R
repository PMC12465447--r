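#' Rule-based enhancer classification
#'
#' H3K27ac peaks more than `minDistal` bp (edge distance, strict) from
#' every H3K4me3-bound TSS are classified as enhancers. A TSS counts as
#' H3K4me3-bound when its symmetric +/- `tssHalfWindow` window overlaps an
#' H3K4me3 peak. Each enhancer is additionally flagged intergenic when it
#' overlaps no gene body.
#'
#' @param h3k27ac GRanges of H3K27ac peaks.
#' @param h3k4me3 GRanges of H3K4me3 peaks (empty set: every H3K27ac peak
#'   is called an enhancer, with a warning).
#' @param genes gene GRanges (with `tss`).
#' @param minDistal strict distance threshold in bp, default 2000.
#' @param tssHalfWindow TSS promoter half-width in bp, default 1000.
#' @return GRanges of enhancer calls with metadata columns
#'   `distance_to_tss` (bp to the nearest bound TSS, `NA` if none) and
#'   `is_intergenic`.
#' @export
classifyEnhancers <- function(h3k27ac, h3k4me3, genes,
                              minDistal = 2000L, tssHalfWindow = 1000L) {
  tss <- tssRanges(genes)
  boundTss <- if (length(h3k4me3) == 0L) tss[0] else
    tss[IRanges::overlapsAny(tssWindows(genes, tssHalfWindow), h3k4me3,
                                   ignore.strand = TRUE)]
  if (length(boundTss) == 0L) {
    if (length(h3k4me3) == 0L)
      warning("empty H3K4me3 peak set: all H3K27ac peaks classified as enhancers")
    dist <- rep(NA_real_, length(h3k27ac))
    keep <- rep(TRUE, length(h3k27ac))
  } else {
    nf <- nearestFeature(h3k27ac, boundTss)
    dist <- nf$distance
    # no bound TSS on that chromosome => distal by definition
    keep <- is.na(dist) | dist > minDistal
  }
  enh <- h3k27ac[keep]
  enh$distance_to_tss <- dist[keep]
  enh$is_intergenic <- !IRanges::overlapsAny(enh, genes, ignore.strand = TRUE)
  enh
}

#' Intergenic enhancers flanking a gene
#'
#' Returns the intergenic enhancers located between the gene's body and
#' the nearest protein-coding gene body on each side, i.e. within the two
#' immediately flanking intergenic regions. Enhancers beyond an
#' intervening protein-coding gene (or inside any gene body) are
#' excluded.
#'
#' @param gene GRanges of length 1 (the gene under test).
#' @param enhancers enhancer GRanges from [classifyEnhancers()].
#' @param genes full gene GRanges (used to find flanking protein-coding
#'   neighbours).
#' @return GRanges subset of `enhancers` assigned to this gene, with a
#'   `flank` column ("left"/"right") and `gene_distance` (edge distance
#'   from the gene body to the enhancer midpoint, bp).
#' @export
intergenicEnhancersForGene <- function(gene, enhancers, genes) {
  ch <- as.character(GenomeInfoDb::seqnames(gene))[1]
  gs <- GenomicRanges::start(gene)[1]; ge <- GenomicRanges::end(gene)[1]
  pc <- genes[genes$biotype == "protein_coding" &
                as.character(GenomeInfoDb::seqnames(genes)) == ch]
  gid <- if (!is.null(gene$gene_id)) gene$gene_id[1] else NA_character_
  if (!is.na(gid)) pc <- pc[pc$gene_id != gid]
  other_s <- GenomicRanges::start(pc); other_e <- GenomicRanges::end(pc)
  leftEdge <- suppressWarnings(max(other_e[other_e < gs]))
  if (!is.finite(leftEdge)) leftEdge <- 0
  rightEdge <- suppressWarnings(min(other_s[other_s > ge]))
  if (!is.finite(rightEdge)) rightEdge <- Inf
  onChr <- as.character(GenomeInfoDb::seqnames(enhancers)) == ch
  inter <- onChr & enhancers$is_intergenic
  es <- GenomicRanges::start(enhancers); ee <- GenomicRanges::end(enhancers)
  leftFlank <- inter & es > leftEdge & ee < gs
  rightFlank <- inter & es > ge & ee < rightEdge
  sel <- which(leftFlank | rightFlank)
  out <- enhancers[sel]
  out$flank <- ifelse(leftFlank[sel], "left", "right")
  mid <- (GenomicRanges::start(out) + GenomicRanges::end(out)) %/% 2
  out$gene_distance <- ifelse(out$flank == "left", gs - mid, mid - ge)
  out
}

#' Distance from a gene to its most distal intergenic enhancer
#'
#' Maximum over the gene's assigned intergenic enhancers of the edge
#' distance from the gene body to the enhancer midpoint.
#'
#' @param enhancers GRanges from [intergenicEnhancersForGene()] (carries
#'   `gene_distance`).
#' @return list with `distance` (bp, `NA` when no enhancer) and `index`
#'   (which enhancer is the most distal).
#' @export
mostDistalEnhancerDistance <- function(enhancers) {
  if (length(enhancers) == 0L) return(list(distance = NA_real_, index = NA_integer_))
  i <- which.max(enhancers$gene_distance)
  list(distance = as.numeric(enhancers$gene_distance[i]), index = i)
}

#' ChIP-seq read density over promoter regions
#'
#' Promoter regions are merged H3K27ac peaks overlapping an H3K4me3-bound
#' TSS. Density is the library-size-normalised coverage summed over the
#' region divided by region length, in reads per kilobase per million
#' (RPKM-style): `sum(coverage) * 1e9 / (L * librarySize)`.
#'
#' @param coverage named list chromosome -> per-base numeric coverage
#'   vector, or an `RleList` (as from `GenomicRanges::coverage`).
#' @param regions GRanges of promoter regions (see
#'   [promoterRegions()]).
#' @param librarySize total input reads.
#' @return numeric per-region density.
#' @export
promoterDensity <- function(coverage, regions, librarySize) {
  if (librarySize <= 0) stop("librarySize must be positive")
  vapply(seq_along(regions), function(i) {
    ch <- as.character(GenomeInfoDb::seqnames(regions))[i]
    cov <- coverage[[ch]]
    if (is.null(cov)) return(NA_real_)
    st <- GenomicRanges::start(regions)[i]; en <- GenomicRanges::end(regions)[i]
    en <- min(en, length(cov))
    s <- sum(as.numeric(cov[st:en]))
    L <- GenomicRanges::width(regions)[i]
    s * 1e9 / (L * librarySize)
  }, 0)
}

#' @describeIn promoterDensity merged H3K27ac peaks (two stages)
#'   overlapping an H3K4me3-bound TSS.
#' @param h3k27acA,h3k27acB H3K27ac peak GRanges from the two stages to
#'   merge.
#' @param h3k4me3 H3K4me3 peak GRanges.
#' @param genes gene GRanges.
#' @param tssHalfWindow promoter half-width for TSS binding, default 1000.
#' @export
promoterRegions <- function(h3k27acA, h3k27acB, h3k4me3, genes,
                            tssHalfWindow = 1000L) {
  merged <- mergePeaks(h3k27acA, h3k27acB)
  boundTss <- tssRanges(genes)[IRanges::overlapsAny(
    tssWindows(genes, tssHalfWindow), h3k4me3, ignore.strand = TRUE)]
  merged[IRanges::overlapsAny(merged, boundTss, ignore.strand = TRUE)]
}

#' Distal-enhancer distance versus compartment score change
#'
#' For each (downregulated) gene: the distance to its most distal
#' intergenic enhancer and the compartment score change of that enhancer
#' (length-weighted over the delta profile). Returns the per-gene records
#' with the Pearson correlation and its t-test across genes.
#'
#' @param genesDown GRanges of the genes to analyse (with `gene_id`).
#' @param enhancers GRanges from [classifyEnhancers()].
#' @param genes full gene GRanges.
#' @param delta named list from [deltaScores()].
#' @param grid the compartment [BinGrid].
#' @return list with `records` (data.frame gene_id, distance,
#'   delta_score) and `test` (the correlation t-test, see
#'   [correlationTTest()]).
#' @export
enhancerDistanceVsDeltaScore <- function(genesDown, enhancers, genes,
                                         delta, grid) {
  recs <- lapply(seq_along(genesDown), function(i) {
    g <- genesDown[i]
    enh <- intergenicEnhancersForGene(g, enhancers, genes)
    md <- mostDistalEnhancerDistance(enh)
    if (is.na(md$distance)) return(NULL)
    ds <- scoreAtIntervals(delta, enh[md$index], grid = grid)
    data.frame(gene_id = g$gene_id, distance = md$distance, delta_score = ds)
  })
  records <- do.call(rbind, recs)
  if (is.null(records) || nrow(records) < 3L ||
      !any(complete.cases(records[, c("distance", "delta_score")]))) {
    return(list(records = records, test = NULL))
  }
  test <- correlationTTest(records$distance, records$delta_score)
  list(records = records, test = test)
}
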