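#' Mean balanced interaction across a transcript's 5 Kb bins
#'
#' The local gene-body interaction statistic: the mean of the balanced
#' contact entries over all unordered pairs (i < j) of bins spanning the
#' transcript (every bin overlapping its interval). Transcripts contained
#' in a single bin fall back to that bin's diagonal entry. Pairs touching
#' masked bins are excluded from the mean; the diagonal is excluded for
#' multi-bin transcripts (configurable).
#'
#' @param x a KR-balanced [ContactMatrix] (5 Kb grid in the standard
#'   analysis).
#' @param transcript a GRanges of length 1 (or chrom/start/end given
#'   separately via a 1-row data.frame).
#' @param includeDiagonal include diagonal entries for multi-bin
#'   transcripts, default FALSE.
#' @return list with `score` (mean balanced interaction, `NA` when every
#'   constituent pair is masked), `n_bins` (bins spanning the transcript).
#' @export
geneBodyInteraction <- function(x, transcript, includeDiagonal = FALSE) {
  stopifnot(methods::is(x, "ContactMatrix"))
  ch <- as.character(GenomeInfoDb::seqnames(transcript))[1]
  if (!identical(ch, x@chrom))
    stop("transcript chromosome ", ch, " does not match matrix chromosome ", x@chrom)
  w <- balancingWeights(x)
  if (all(is.na(w))) stop("balance the matrix before scoring transcripts")
  grid <- x@grid
  b1 <- binIndex(grid, ch, GenomicRanges::start(transcript)[1])
  b2 <- binIndex(grid, ch, min(GenomicRanges::end(transcript)[1],
                               chromSizes(grid)[[ch]]))
  bins <- b1:b2
  nb <- length(bins)
  wb <- w[bins]
  sub <- as.matrix(contactCounts(x)[bins, bins, drop = FALSE])
  bal <- sub * outer(wb, wb)
  if (nb == 1L) {
    score <- if (is.na(wb)) NA_real_ else bal[1, 1]
    return(list(score = score, n_bins = 1L))
  }
  keep <- if (includeDiagonal) upper.tri(bal, diag = TRUE) else upper.tri(bal)
  vals <- bal[keep]
  vals <- vals[!is.na(vals)]
  list(score = if (length(vals)) mean(vals) else NA_real_, n_bins = nb)
}

#' Score every transcript of a gene table
#'
#' Applies [geneBodyInteraction()] across a transcript/gene GRanges,
#' using the matching per-chromosome matrix.
#'
#' @param matrices named list of balanced [ContactMatrix] objects.
#' @param transcripts GRanges with `gene_id`.
#' @param includeDiagonal see [geneBodyInteraction()].
#' @return data.frame (gene_id, chrom, n_bins, score).
#' @export
geneBodyInteractionTable <- function(matrices, transcripts,
                                     includeDiagonal = FALSE) {
  chs <- as.character(GenomeInfoDb::seqnames(transcripts))
  res <- lapply(seq_along(transcripts), function(i) {
    m <- matrices[[chs[i]]]
    if (is.null(m)) return(data.frame(gene_id = transcripts$gene_id[i],
                                      chrom = chs[i], n_bins = NA_integer_,
                                      score = NA_real_))
    gb <- geneBodyInteraction(m, transcripts[i], includeDiagonal)
    data.frame(gene_id = transcripts$gene_id[i], chrom = chs[i],
               n_bins = gb$n_bins, score = gb$score)
  })
  do.call(rbind, res)
}

#' Interaction fold change between conditions
#'
#' `(score_cko + pseudocount) / (score_ctrl + pseudocount)`; `NA` when
#' either score is missing.
#'
#' @param scoreCko,scoreCtrl numeric scores (vectorised).
#' @param pseudocount stabilising constant, default 0 (the pipeline uses
#'   5% of the genome-wide median control score).
#' @return numeric fold changes.
#' @export
interactionFoldChange <- function(scoreCko, scoreCtrl, pseudocount = 0) {
  out <- (scoreCko + pseudocount) / (scoreCtrl + pseudocount)
  out[is.na(scoreCko) | is.na(scoreCtrl)] <- NA_real_
  out
}

#' Region-level fold-change map between two conditions
#'
#' Extracts the balanced submatrix of a region from both conditions,
#' scales each so its region sums are equal (removing depth), and returns
#' the entrywise `(b + pseudocount) / (a + pseudocount)` map. Masked
#' entries are `NA`.
#'
#' @param a,b balanced [ContactMatrix] objects for the two conditions
#'   (same grid and chromosome).
#' @param region GRanges of length 1.
#' @param pseudocount stabilising constant, default 0.
#' @return dense fold-change submatrix (rows/cols = region bins).
#' @export
submatrixFoldChangeMap <- function(a, b, region, pseudocount = 0) {
  stopifnot(identical(a@chrom, b@chrom),
            identical(a@grid@binSize, b@grid@binSize))
  ch <- as.character(GenomeInfoDb::seqnames(region))[1]
  if (!identical(ch, a@chrom)) stop("region chromosome does not match matrices")
  grid <- a@grid
  b1 <- binIndex(grid, ch, GenomicRanges::start(region)[1])
  b2 <- binIndex(grid, ch, min(GenomicRanges::end(region)[1], chromSizes(grid)[[ch]]))
  bins <- b1:b2
  subBal <- function(m) {
    w <- balancingWeights(m)[bins]
    s <- as.matrix(contactCounts(m)[bins, bins, drop = FALSE]) * outer(w, w)
    s
  }
  A <- subBal(a); B <- subBal(b)
  sA <- sum(A, na.rm = TRUE); sB <- sum(B, na.rm = TRUE)
  if (sA > 0 && sB > 0) B <- B * (sA / sB)
  (B + pseudocount) / (A + pseudocount)
}
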