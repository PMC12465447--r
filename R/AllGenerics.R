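#' @rdname BinGrid
#' @param binSize bin width in bp.
#' @param chromSizes named numeric vector of chromosome lengths.
#' @return `BinGrid()` returns a BinGrid object.
#' @export
BinGrid <- function(binSize, chromSizes) {
  new("BinGrid", binSize = as.integer(binSize),
      chromSizes = chromSizes)
}

#' @describeIn BinGrid bin width in bp.
#' @param x,object a BinGrid (or object carrying one).
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @describeIn BinGrid named chromosome length vector.
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @describeIn BinGrid number of bins on a chromosome.
#' @param chrom chromosome name.
#' @export
setGeneric("nBins", function(x, chrom) standardGeneric("nBins"))

setMethod("binSize", "BinGrid", function(x) x@binSize)
setMethod("chromSizes", "BinGrid", function(x) x@chromSizes)
setMethod("nBins", "BinGrid", function(x, chrom) {
  if (!chrom %in% names(x@chromSizes))
    stop("unknown chromosome: ", chrom)
  as.integer(ceiling(x@chromSizes[[chrom]] / x@binSize))
})

setMethod("show", "BinGrid", function(object) {
  cat(sprintf("BinGrid: %d bp bins over %d chromosome(s), %d bins total\n",
              object@binSize, length(object@chromSizes),
              sum(ceiling(object@chromSizes / object@binSize))))
})

#' Map genomic positions to bin indices and back
#'
#' @param grid a [BinGrid].
#' @param chrom chromosome name.
#' @param pos 1-based genomic position(s).
#' @return `binIndex`: 1-based bin index per position. `binStarts`:
#'   1-based start coordinate of each bin on the chromosome.
#' @export
binIndex <- function(grid, chrom, pos) {
  n <- nBins(grid, chrom)
  if (any(pos < 1L | pos > chromSizes(grid)[[chrom]]))
    stop("position beyond chromosome length on ", chrom)
  idx <- as.integer((pos - 1L) %/% binSize(grid)) + 1L
  pmin.int(idx, n)
}

#' @rdname binIndex
#' @export
binStarts <- function(grid, chrom) {
  (seq_len(nBins(grid, chrom)) - 1L) * binSize(grid) + 1L
}

#' Bin intervals of a grid as a GRanges
#'
#' @param grid a [BinGrid].
#' @param chrom chromosome name (all chromosomes if NULL).
#' @return GRanges of bin intervals with a `bin` metadata column.
#' @export
binRanges <- function(grid, chrom = NULL) {
  chroms <- if (is.null(chrom)) names(chromSizes(grid)) else chrom
  grl <- lapply(chroms, function(ch) {
    n <- nBins(grid, ch)
    st <- binStarts(grid, ch)
    en <- pmin(st + binSize(grid) - 1L, chromSizes(grid)[[ch]])
    GenomicRanges::GRanges(ch, IRanges::IRanges(st, en), bin = seq_len(n))
  })
  do.call(c, grl)
}

#' @describeIn ContactMatrix raw count matrix accessor.
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @describeIn ContactMatrix balancing weight vector accessor
#'   (`NA` = masked or not balanced).
#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))

#' @describeIn ContactMatrix the balanced (normalised) matrix
#'   `diag(w) %*% counts %*% diag(w)`; masked rows/columns are NA.
#' @export
setGeneric("balancedMatrix", function(x) standardGeneric("balancedMatrix"))

setMethod("contactCounts", "ContactMatrix", function(x) x@counts)
setMethod("balancingWeights", "ContactMatrix", function(x) x@weights)
setMethod("binSize", "ContactMatrix", function(x) x@grid@binSize)

setMethod("balancedMatrix", "ContactMatrix", function(x) {
  w <- x@weights
  if (all(is.na(w))) stop("matrix has not been balanced; call krBalance() first")
  w0 <- ifelse(is.na(w), 0, w)
  b <- as.matrix(Diagonal(x = w0) %*% x@counts %*% Diagonal(x = w0))
  b[is.na(w), ] <- NA_real_
  b[, is.na(w)] <- NA_real_
  b
})

setMethod("show", "ContactMatrix", function(object) {
  n <- nrow(object@counts)
  cat(sprintf("ContactMatrix %s: %d bins @ %d bp, %.0f contacts, %s\n",
              object@chrom, n, object@grid@binSize,
              sum(object@counts@x) - sum(diag(object@counts)) / 2,
              if (all(is.na(object@weights))) "unbalanced"
              else sprintf("KR-balanced (%d masked bins)", sum(is.na(object@weights)))))
})

#' @describeIn CompartmentProfile per-chromosome score list accessor.
#' @export
setGeneric("compartmentScores", function(x) standardGeneric("compartmentScores"))
setMethod("compartmentScores", "CompartmentProfile", function(x) x@scores)

#' @describeIn CompartmentProfile orientation evidence accessor.
#' @export
setGeneric("orientationEvidence", function(x) standardGeneric("orientationEvidence"))
setMethod("orientationEvidence", "CompartmentProfile", function(x) x@orientationEvidence)

setMethod("show", "CompartmentProfile", function(object) {
  nb <- sum(lengths(object@scores))
  na <- sum(vapply(object@scores, function(s) sum(is.na(s)), 0))
  cat(sprintf("CompartmentProfile: %d bins @ %d bp on %d chromosome(s) (%d masked), %s\n",
              nb, object@grid@binSize, length(object@scores), na,
              if (object@oriented) "oriented" else "unoriented"))
})

setMethod("show", "RankedBinGroups", function(object) {
  cat(sprintf("RankedBinGroups: %d A-compartment bins in %d group(s) of %d\n",
              nrow(object@bins), length(unique(object@bins$group)),
              object@groupSize))
})

setMethod("show", "TruthManifest", function(object) {
  cat(sprintf(paste0("TruthManifest (seed %d): %d flipped bins, %d loop-depleted genes, ",
                     "%d DE genes, %d planted enhancers\n"),
              object@seed, nrow(object@flippedBins), nrow(object@loopDepletedGenes),
              nrow(object@deGenes), nrow(object@enhancerLayout)))
})
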