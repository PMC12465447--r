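#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod
#' @importFrom stats cor pbinom pchisq pt pnorm quantile rnbinom rpois runif
#'   rnorm rbeta median setNames sd complete.cases
#' @importFrom utils head tail modifyList
NULL

# allow data.table's [ semantics (.N, :=) inside package code
.datatable.aware <- TRUE

#' Regular genome binning grid
#'
#' A `BinGrid` partitions every chromosome of a genome into consecutive
#' fixed-width bins. Bin `i` (1-based) on a chromosome covers bases
#' `[(i-1)*binSize + 1, i*binSize]` (1-based closed); the last bin is
#' truncated at the chromosome end.
#'
#' @slot binSize integer(1), bin width in bp.
#' @slot chromSizes named numeric, chromosome lengths in bp.
#' @export
setClass("BinGrid", representation(binSize = "integer", chromSizes = "numeric"))

setValidity("BinGrid", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) || object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (length(object@chromSizes) == 0L)
    msg <- c(msg, "chromSizes must be non-empty")
  if (is.null(names(object@chromSizes)) || anyDuplicated(names(object@chromSizes)))
    msg <- c(msg, "chromSizes must have unique names")
  if (any(object@chromSizes <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-chromosome binned Hi-C contact matrix
#'
#' Symmetric sparse matrix of raw contact counts on a [BinGrid], together
#' with the per-bin Knight-Ruiz balancing weights once computed. Masked
#' bins (low coverage) carry `NA` weights.
#'
#' @slot chrom character(1), chromosome name.
#' @slot grid the [BinGrid] the matrix is binned on.
#' @slot counts symmetric sparse `Matrix` of raw counts.
#' @slot weights numeric per-bin balancing weights (`NA` = masked /
#'   not yet balanced).
#' @slot krConverged logical(1), whether balancing met its tolerance.
#' @slot krIterations integer(1), outer Newton iterations used.
#' @export
setClass("ContactMatrix", representation(
  chrom = "character", grid = "BinGrid", counts = "ANY",
  weights = "numeric", krConverged = "logical", krIterations = "integer"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (!object@chrom %in% names(object@grid@chromSizes))
    msg <- c(msg, "chrom not present in grid")
  n <- nBins(object@grid, object@chrom)
  if (!all(dim(object@counts) == c(n, n)))
    msg <- c(msg, sprintf("counts must be %d x %d for %s", n, n, object@chrom))
  if (length(object@weights) != n)
    msg <- c(msg, "weights length must equal bin count")
  if (any(object@counts@x < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Oriented A/B compartment score profile
#'
#' Per-bin first-eigenvector scores of the Hi-C correlation matrix, one
#' vector per chromosome, oriented so that positive scores mark the
#' active (H3K27ac-enriched, H3K9me3-depleted) A compartment.
#'
#' @slot grid the [BinGrid] (25 Kb or 500 Kb typically).
#' @slot scores named list, chromosome -> per-bin numeric scores
#'   (`NA` at masked bins); each vector unit-normalised over non-NA bins.
#' @slot orientationEvidence named numeric, per-chromosome correlation of
#'   the oriented scores with the active-minus-repressive rank track
#'   (non-negative after orientation; `NA` when unresolved).
#' @slot oriented logical(1).
#' @export
setClass("CompartmentProfile", representation(
  grid = "BinGrid", scores = "list",
  orientationEvidence = "numeric", oriented = "logical"))

#' Ranked differential-compartment bin groups
#'
#' Control-condition A-compartment bins ranked by signed compartment
#' score change (most negative, i.e. strongest A-loss, first) and
#' partitioned into consecutive groups.
#'
#' @slot bins data.frame with columns chrom, bin, start, end, control,
#'   delta, group (in ranked order).
#' @slot groupSize integer(1), nominal group size (last group may be a
#'   shorter remainder).
#' @export
setClass("RankedBinGroups", representation(bins = "data.frame", groupSize = "integer"))

#' Ground truth of a synthetic two-condition fixture
#'
#' @slot compartmentSign list condition -> list chromosome -> per-25Kb-bin
#'   sign (+1 A / -1 B).
#' @slot flippedBins data.frame (chrom, bin) of A->B flips planted in cKO.
#' @slot loopDepletedGenes data.frame (gene_id, depletion) of genes whose
#'   loop/TAD boost is reduced in cKO.
#' @slot deGenes data.frame (gene_id, log2fc) of true expression changes.
#' @slot enhancerLayout data.frame (gene_id, chrom, start, end, distance)
#'   of planted intergenic enhancers.
#' @slot binSize integer(1), bin size of the compartment signs.
#' @slot seed integer(1), RNG seed the fixture was generated with.
#' @export
setClass("TruthManifest", representation(
  compartmentSign = "list", flippedBins = "data.frame",
  loopDepletedGenes = "data.frame", deGenes = "data.frame",
  enhancerLayout = "data.frame", binSize = "integer", seed = "integer"))
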