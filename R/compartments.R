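#' First eigenvector of a Hi-C correlation matrix
#'
#' Power iteration for the eigenvector of the largest-magnitude eigenvalue
#' of the unmasked submatrix, re-expanded with `NA` at masked bins and
#' normalised to unit length. The overall sign is arbitrary at this stage
#' (see [orientEigenvector()]).
#'
#' @param cc symmetric correlation matrix (NA rows = masked bins).
#' @param tol convergence tolerance on the iterate, default 1e-12.
#' @param maxIter iteration cap, default 5000.
#' @return numeric per-bin scores (`NA` at masked bins), or all-NA when
#'   fewer than 3 usable bins remain.
#' @export
compartmentEigenvector <- function(cc, tol = 1e-12, maxIter = 5000L) {
  n <- nrow(cc)
  usable <- which(rowSums(!is.na(cc)) > 1L)
  out <- rep(NA_real_, n)
  if (length(usable) < 3L) return(out)
  S <- cc[usable, usable, drop = FALSE]
  S[is.na(S)] <- 0
  m <- nrow(S)
  # deterministic start, slightly graded to avoid orthogonal degeneracy
  v <- 1 + seq_len(m) * 1e-3
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(maxIter)) {
    u <- as.numeric(S %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    # dominant eigenvalue may be negative: compare up to sign
    if (sqrt(sum((u - v)^2)) < tol || sqrt(sum((u + v)^2)) < tol) { v <- u; break }
    v <- u
  }
  lam <- sum(v * as.numeric(S %*% v))
  # one Rayleigh-quotient refinement step keeps the sign convention stable
  v <- v / sqrt(sum(v^2))
  out[usable] <- v
  out
}

#' Orient compartment scores with histone-mark evidence
#'
#' Flips the eigenvector sign per chromosome so bins enriched for the
#' active mark (H3K27ac) and de-enriched for the repressive mark
#' (H3K9me3) carry positive scores (A compartment). Evidence is the
#' Pearson correlation of the scores with the rank difference
#' `rank(active) - rank(repressive)` over non-missing bins.
#'
#' @param scores named list chromosome -> raw eigenvector scores, or the
#'   output of [compartmentEigenvector()] for a single chromosome.
#' @param activeTrack,repressiveTrack named lists chromosome -> per-bin
#'   density (see [binnedPeakDensity()]).
#' @param grid the [BinGrid] of the scores.
#' @return a [CompartmentProfile].
#' @export
orientEigenvector <- function(scores, activeTrack, repressiveTrack, grid) {
  if (!is.list(scores)) scores <- setNames(list(scores), names(chromSizes(grid))[1])
  evid <- setNames(rep(NA_real_, length(scores)), names(scores))
  for (ch in names(scores)) {
    s <- scores[[ch]]
    ok <- !is.na(s)
    if (sum(ok) < 3L) next
    ev_track <- rank(activeTrack[[ch]]) - rank(repressiveTrack[[ch]])
    if (sd(ev_track[ok]) == 0 || sd(s[ok]) == 0) {
      warning("unresolved compartment orientation on ", ch,
              ": zero-variance evidence track")
      next
    }
    r <- cor(s[ok], ev_track[ok])
    if (is.na(r)) next
    if (r < 0) { s <- -s; r <- -r }
    scores[[ch]] <- s
    evid[[ch]] <- r
  }
  new("CompartmentProfile", grid = grid, scores = scores,
      orientationEvidence = evid, oriented = TRUE)
}

#' Compute an oriented compartment profile from contact matrices
#'
#' Convenience wrapper: balance (if needed), expected-by-distance, O/E,
#' correlation matrix, first eigenvector, orientation.
#'
#' @param matrices named list of [ContactMatrix] (one per chromosome).
#' @param activeTrack,repressiveTrack per-bin evidence tracks
#'   ([binnedPeakDensity()]).
#' @param minShared passed to [correlationMatrix()].
#' @return a [CompartmentProfile].
#' @export
compartmentProfile <- function(matrices, activeTrack, repressiveTrack,
                               minShared = 10L) {
  grid <- matrices[[1]]@grid
  scores <- lapply(matrices, function(m) {
    if (all(is.na(balancingWeights(m)))) m <- krBalance(m)
    oe <- observedOverExpected(m)
    compartmentEigenvector(correlationMatrix(oe, minShared = minShared))
  })
  names(scores) <- vapply(matrices, function(m) m@chrom, "")
  orientEigenvector(scores, activeTrack, repressiveTrack, grid)
}

#' Per-bin compartment score change between conditions
#'
#' `delta = score_b - score_a` per bin (cKO minus control), after each
#' profile's per-chromosome unit normalisation (done at eigenvector
#' computation); `NA` wherever either profile is missing.
#'
#' @param a control [CompartmentProfile].
#' @param b perturbed (cKO) [CompartmentProfile].
#' @return named list chromosome -> per-bin delta scores.
#' @export
deltaScores <- function(a, b) {
  stopifnot(identical(a@grid@binSize, b@grid@binSize),
            identical(a@grid@chromSizes, b@grid@chromSizes))
  if (!a@oriented || !b@oriented) stop("profiles must be oriented before differencing")
  out <- lapply(names(a@scores), function(ch) {
    sa <- unitNorm(a@scores[[ch]]); sb <- unitNorm(b@scores[[ch]])
    d <- sb - sa
    d[is.na(sa) | is.na(sb)] <- NA_real_
    d
  })
  setNames(out, names(a@scores))
}

unitNorm <- function(v) {
  nrm <- sqrt(sum(v^2, na.rm = TRUE))
  if (nrm == 0) return(v)
  v / nrm
}

#' Rank control A-compartment bins by score change and group them
#'
#' Restricts to bins with positive control score (A compartment), sorts by
#' signed delta ascending (strongest A-loss first; ties broken by
#' chromosome then bin index), and partitions into consecutive groups of
#' `groupSize` with a final shorter remainder.
#'
#' @param delta named list from [deltaScores()].
#' @param control the control [CompartmentProfile].
#' @param groupSize bins per group, default 500.
#' @return a [RankedBinGroups].
#' @export
rankAndGroup <- function(delta, control, groupSize = 500L) {
  grid <- control@grid
  rows <- lapply(names(delta), function(ch) {
    s <- control@scores[[ch]]; d <- delta[[ch]]
    keep <- which(!is.na(s) & s > 0 & !is.na(d))
    if (!length(keep)) return(NULL)
    st <- binStarts(grid, ch)[keep]
    data.frame(chrom = ch, bin = keep, start = st,
               end = pmin(st + binSize(grid) - 1, chromSizes(grid)[[ch]]),
               control = s[keep], delta = d[keep])
  })
  bins <- do.call(rbind, rows)
  if (is.null(bins) || nrow(bins) == 0L) {
    return(new("RankedBinGroups",
               bins = data.frame(chrom = character(), bin = integer(),
                                 start = numeric(), end = numeric(),
                                 control = numeric(), delta = numeric(),
                                 group = integer()),
               groupSize = as.integer(groupSize)))
  }
  bins <- bins[order(bins$delta, bins$chrom, bins$bin), ]
  bins$group <- as.integer((seq_len(nrow(bins)) - 1L) %/% groupSize + 1L)
  rownames(bins) <- NULL
  new("RankedBinGroups", bins = bins, groupSize = as.integer(groupSize))
}

rankedBinRanges <- function(groups) {
  GenomicRanges::GRanges(groups@bins$chrom,
                         IRanges::IRanges(groups@bins$start, groups@bins$end))
}

#' Per-group mean expression change of the nearest protein-coding gene
#'
#' For each ranked bin, finds the nearest protein-coding gene with control
#' log2 CPM > 0 (edge distance, lower-start tie-break) and averages those
#' genes' log2 fold changes within each group. Bins with no eligible gene
#' on their chromosome are excluded from the group mean.
#'
#' @param groups a [RankedBinGroups].
#' @param genes GRanges with `biotype`, `log2cpm` (control) and `log2fc`.
#' @return data.frame (group, n, mean_log2fc).
#' @export
groupFeatureExpression <- function(groups, genes) {
  eligible <- genes$biotype == "protein_coding" & !is.na(genes$log2cpm) &
    genes$log2cpm > 0
  q <- rankedBinRanges(groups)
  nf <- nearestFeature(q, genes, filter = eligible)
  fc <- ifelse(is.na(nf$feature), NA_real_, genes$log2fc[nf$feature])
  agg <- tapply(fc, groups@bins$group, function(v) mean(v, na.rm = TRUE))
  data.frame(group = as.integer(names(agg)),
             n = as.integer(table(groups@bins$group)[names(agg)]),
             mean_log2fc = as.numeric(agg))
}

#' Per-group fraction of bins overlapping expressed gene bodies
#'
#' A bin counts as genic when any expressed gene body (control
#' log2 CPM > 0) intersects it by at least 1 bp.
#'
#' @param groups a [RankedBinGroups].
#' @param genes GRanges with `log2cpm`.
#' @return data.frame (group, n, genic_fraction).
#' @export
groupFeatureGenicFraction <- function(groups, genes) {
  expressed <- genes[!is.na(genes$log2cpm) & genes$log2cpm > 0]
  q <- rankedBinRanges(groups)
  ov <- IRanges::countOverlaps(q, expressed, ignore.strand = TRUE) > 0
  agg <- tapply(ov, groups@bins$group, mean)
  data.frame(group = as.integer(names(agg)),
             n = as.integer(table(groups@bins$group)[names(agg)]),
             genic_fraction = as.numeric(agg))
}

#' Intergenic peaks: peaks clear of gene bodies and promoter windows
#'
#' Removes every peak overlapping a gene body or the strand-aware window
#' extending `promoterUpstreamBp` upstream of any TSS.
#'
#' @param peaks GRanges peak set.
#' @param genes gene GRanges (with `tss`).
#' @param promoterUpstreamBp upstream promoter window, default 500.
#' @return filtered GRanges.
#' @export
intergenicPeaks <- function(peaks, genes, promoterUpstreamBp = 500L) {
  excl <- c(GenomicRanges::granges(genes),
            GenomicRanges::granges(promoterUpstream(genes, promoterUpstreamBp)))
  hit <- IRanges::overlapsAny(peaks, excl, ignore.strand = TRUE)
  peaks[!hit]
}

#' Per-group mean distance to the nearest intergenic peak
#'
#' Peaks are pre-filtered with [intergenicPeaks()]; each bin's edge
#' distance to the nearest surviving peak is averaged per group. Bins on
#' chromosomes with no surviving peak are excluded.
#'
#' @param groups a [RankedBinGroups].
#' @param peaks GRanges peak set (one mark).
#' @param genes gene GRanges.
#' @param promoterUpstreamBp upstream promoter window, default 500.
#' @return data.frame (group, n, mean_distance).
#' @export
groupFeaturePeakDistance <- function(groups, peaks, genes,
                                     promoterUpstreamBp = 500L) {
  surviving <- intergenicPeaks(peaks, genes, promoterUpstreamBp)
  q <- rankedBinRanges(groups)
  nf <- nearestFeature(q, surviving)
  agg <- tapply(nf$distance, groups@bins$group, function(v) mean(v, na.rm = TRUE))
  data.frame(group = as.integer(names(agg)),
             n = as.integer(table(groups@bins$group)[names(agg)]),
             mean_distance = as.numeric(agg))
}

#' Length-weighted compartment score of arbitrary intervals
#'
#' Score of an interval is the mean of the scores of the bins it overlaps,
#' weighted by overlap length; missing bins are excluded from the
#' weighting.
#'
#' @param profile a [CompartmentProfile], or a named list chromosome ->
#'   per-bin scores with `grid` supplied.
#' @param intervals GRanges.
#' @param grid required when `profile` is a plain list.
#' @return numeric per-interval scores (`NA` when all overlapped bins are
#'   missing or the chromosome is absent).
#' @export
scoreAtIntervals <- function(profile, intervals, grid = NULL) {
  if (methods::is(profile, "CompartmentProfile")) {
    grid <- profile@grid; scores <- profile@scores
  } else scores <- profile
  out <- rep(NA_real_, length(intervals))
  br <- binRanges(grid)
  flat <- unlist(scores, use.names = FALSE)
  ov <- GenomicRanges::findOverlaps(intervals, br, ignore.strand = TRUE)
  if (length(ov) == 0L) return(out)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  wl <- GenomicRanges::width(GenomicRanges::pintersect(intervals[qi], br[si],
                                                       ignore.strand = TRUE))
  sc <- flat[si]
  ok <- !is.na(sc)
  if (!any(ok)) return(out)
  num <- tapply(wl[ok] * sc[ok], qi[ok], sum)
  den <- tapply(wl[ok], qi[ok], sum)
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  out
}
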