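#' Read a chrom.sizes file
#'
#' Two-column whitespace-delimited text: chromosome name, length in bp.
#' Order is preserved.
#'
#' @param path path to the chrom.sizes file.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty chrom.sizes file: ", path)
    return(setNames(numeric(0), character(0)))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) < 2L))
    stop("malformed chrom.sizes line: ", lines[which(lengths(parts) < 2L)[1]])
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in chrom.sizes: ", nm[duplicated(nm)][1])
  if (any(is.na(len) | len <= 0))
    stop("non-positive or non-numeric chromosome length in chrom.sizes")
  setNames(len, nm)
}

#' Read ChIP-seq peaks from a BED file
#'
#' BED3+ input (0-based half-open); the optional 5th column is read as the
#' per-peak signal. Records are returned sorted by (chrom, start) as a
#' GRanges in 1-based closed coordinates with metadata columns `signal`
#' and, if a 4th column exists, `name`. Overlapping records are retained
#' as-is (the reader does not merge).
#'
#' @param path path to the BED file.
#' @param chromSizes optional named vector; peaks on chromosomes absent
#'   from it are skipped with a warning that counts them.
#' @param mark optional mark label stored in `metadata(x)$mark`.
#' @return GRanges of peaks.
#' @export
readBed <- function(path, chromSizes = NULL, mark = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("BED file must have at least 3 columns: ", path)
  chrom <- dt[[1]]; start0 <- as.numeric(dt[[2]]); end0 <- as.numeric(dt[[3]])
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("invalid BED interval (start >= end) at record %d of %s", bad[1], path))
  signal <- if (ncol(dt) >= 5L) as.numeric(dt[[5]]) else rep(1, nrow(dt))
  if (any(signal < 0, na.rm = TRUE)) stop("negative peak signal in ", path)
  keep <- rep(TRUE, nrow(dt))
  if (!is.null(chromSizes)) {
    keep <- chrom %in% names(chromSizes)
    if (any(!keep))
      warning(sum(!keep), " BED record(s) on unknown chromosomes skipped")
  }
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start0[keep] + 1, end0[keep]),
                               signal = signal[keep])
  if (ncol(dt) >= 4L) gr$name <- as.character(dt[[4]])[keep]
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(mark)) S4Vectors::metadata(gr)$mark <- mark
  gr
}

#' Read a tab-delimited gene table
#'
#' Expected columns: gene_id, chrom, start, end, strand, biotype, plus any
#' extra columns (e.g. log2cpm, log2fc) carried through as metadata.
#' Coordinates are 1-based closed (GTF convention).
#'
#' @param path path to the TSV (with header).
#' @param chromSizes optional named vector; genes on unknown chromosomes
#'   are skipped with a counting warning.
#' @return GRanges with metadata columns `gene_id`, `biotype`, `tss`
#'   (strand-aware 5' end) and any extra input columns.
#' @export
readGeneTable <- function(path, chromSizes = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  req <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(req %in% names(dt)))
    stop("gene table missing columns: ", paste(setdiff(req, names(dt)), collapse = ", "))
  if (any(dt$start > dt$end)) stop("gene with start > end in ", path)
  keep <- rep(TRUE, nrow(dt))
  if (!is.null(chromSizes)) {
    keep <- dt$chrom %in% names(chromSizes)
    if (any(!keep)) warning(sum(!keep), " gene record(s) on unknown chromosomes skipped")
  }
  dt <- dt[keep]
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end),
                               strand = dt$strand)
  gr$gene_id <- dt$gene_id
  gr$biotype <- dt$biotype
  gr$tss <- ifelse(dt$strand == "-", dt$end, dt$start)
  for (col in setdiff(names(dt), req))
    S4Vectors::mcols(gr)[[col]] <- dt[[col]]
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Edge distance between two genomic intervals
#'
#' Unstranded nearest-edge gap: 0 when the intervals overlap or abut,
#' otherwise the number of bases strictly between them. Intervals on
#' different chromosomes have undefined distance (`NA` with a warning is
#' not returned; `NA` silently, matching GenomicRanges semantics).
#'
#' @param a,b GRanges (recycled to common length).
#' @return numeric vector of distances in bp (`NA` across chromosomes).
#' @export
intervalDistance <- function(a, b) {
  suppressWarnings(as.numeric(GenomicRanges::distance(a, b, ignore.strand = TRUE)))
}

#' Nearest feature to each query interval
#'
#' Exhaustive nearest search by edge distance with deterministic
#' tie-breaking (smaller start coordinate wins). Features failing
#' `filter` are removed before the search. Queries with no eligible
#' feature on their chromosome get `NA`.
#'
#' @param query GRanges of query intervals.
#' @param features GRanges of candidate features.
#' @param filter optional logical vector or predicate over `features`.
#' @return data.frame with columns `feature` (index into the filtered
#'   features as supplied), `distance` (bp).
#' @export
nearestFeature <- function(query, features, filter = NULL) {
  if (!is.null(filter)) {
    keepIdx <- if (is.function(filter)) which(filter(features)) else which(filter)
  } else keepIdx <- seq_along(features)
  feats <- features[keepIdx]
  out <- data.frame(feature = rep(NA_integer_, length(query)),
                    distance = rep(NA_real_, length(query)))
  if (length(feats) == 0L) return(out)
  hits <- GenomicRanges::distanceToNearest(query, feats, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits)
  dmin <- S4Vectors::mcols(hits)$distance
  # distanceToNearest picks an arbitrary representative among ties; collect
  # every feature at the minimal distance and break ties by smaller start
  expd <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(query)[qh],
    IRanges::IRanges(pmax(1, GenomicRanges::start(query)[qh] - dmin - 1L),
                     GenomicRanges::end(query)[qh] + dmin + 1L))
  ov <- GenomicRanges::findOverlaps(expd, feats, ignore.strand = TRUE)
  oq <- S4Vectors::queryHits(ov)      # index into qh/expd
  of <- S4Vectors::subjectHits(ov)
  pd <- intervalDistance(query[qh[oq]], feats[of])
  keep <- which(pd == dmin[oq])
  h <- data.frame(q = qh[oq[keep]], f = of[keep],
                  fstart = GenomicRanges::start(feats)[of[keep]])
  h <- h[order(h$q, h$fstart, h$f), ]
  h <- h[!duplicated(h$q), ]
  out$feature[h$q] <- keepIdx[h$f]
  out$distance[h$q] <- dmin[match(h$q, qh)]
  out
}

#' Merge two peak sets
#'
#' Union of the intervals with overlapping or abutting intervals coalesced
#' into single intervals. Marks must agree when both sets carry one.
#'
#' @param a,b GRanges peak sets (as from [readBed()]).
#' @return GRanges of merged intervals (signal is dropped; merged
#'   intervals no longer have a single per-peak signal).
#' @export
mergePeaks <- function(a, b) {
  ma <- S4Vectors::metadata(a)$mark; mb <- S4Vectors::metadata(b)$mark
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb))
    stop("cannot merge peak sets with different marks: ", ma, " vs ", mb)
  merged <- GenomicRanges::reduce(c(GenomicRanges::granges(a), GenomicRanges::granges(b)),
                                  ignore.strand = TRUE)
  if (!is.null(ma)) S4Vectors::metadata(merged)$mark <- ma
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}

#' Strand-aware TSS points and promoter windows
#'
#' `tssRanges` returns 1-bp TSS intervals; `promoterUpstream` returns the
#' strand-aware window extending `upstream` bp upstream of each TSS
#' (including the TSS base); `tssWindows` returns symmetric TSS +/- `half`
#' windows.
#'
#' @param genes GRanges from [readGeneTable()] (must carry `tss`).
#' @param upstream,half window sizes in bp.
#' @return GRanges.
#' @export
tssRanges <- function(genes) {
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                         IRanges::IRanges(genes$tss, width = 1L),
                         strand = GenomicRanges::strand(genes),
                         gene_id = genes$gene_id)
}

#' @rdname tssRanges
#' @export
promoterUpstream <- function(genes, upstream = 500L) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  st <- ifelse(minus, genes$tss, pmax(1, genes$tss - upstream))
  en <- ifelse(minus, genes$tss + upstream, genes$tss)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes), IRanges::IRanges(st, en),
                         gene_id = genes$gene_id)
}

#' @rdname tssRanges
#' @export
tssWindows <- function(genes, half = 1000L) {
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                         IRanges::IRanges(pmax(1, genes$tss - half), genes$tss + half),
                         gene_id = genes$gene_id)
}

#' Per-bin peak signal density track
#'
#' Sums peak signal into grid bins, weighting each peak's signal by the
#' fraction of the peak overlapping the bin. Used to build the
#' H3K27ac/H3K9me3 evidence tracks that orient compartment eigenvectors.
#'
#' @param peaks GRanges with a `signal` column (1 if absent).
#' @param grid a [BinGrid].
#' @return named list chromosome -> per-bin numeric density.
#' @export
binnedPeakDensity <- function(peaks, grid) {
  sig <- if (!is.null(peaks$signal)) peaks$signal else rep(1, length(peaks))
  out <- lapply(names(chromSizes(grid)), function(ch) {
    v <- numeric(nBins(grid, ch))
    sel <- as.character(GenomeInfoDb::seqnames(peaks)) == ch
    if (!any(sel)) return(v)
    p <- peaks[sel]; s <- sig[sel]
    br <- binRanges(grid, ch)
    ov <- GenomicRanges::findOverlaps(p, br, ignore.strand = TRUE)
    if (length(ov) == 0L) return(v)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    inter <- GenomicRanges::pintersect(p[qi], br[si], ignore.strand = TRUE)
    frac <- GenomicRanges::width(inter) / GenomicRanges::width(p)[qi]
    contrib <- tapply(s[qi] * frac, si, sum)
    v[as.integer(names(contrib))] <- as.numeric(contrib)
    v
  })
  setNames(out, names(chromSizes(grid)))
}
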