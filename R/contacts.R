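#' Read Hi-C valid pairs (4DN pairs format)
#'
#' Header lines begin with `#`; data columns are
#' `readID chrom1 pos1 chrom2 pos2 strand1 strand2` (tab-delimited).
#' Pairs are canonicalised so that `(chrom1, pos1) <= (chrom2, pos2)`
#' lexicographically (chromosome order taken from `chromSizes`). Any
#' `#chromsize:` header declarations are validated against `chromSizes`.
#'
#' @param path path to the pairs file (optionally gzip-compressed).
#' @param chromSizes named chromosome length vector.
#' @return data.table with columns chrom1, pos1, chrom2, pos2, strand1,
#'   strand2, canonically ordered within each row.
#' @export
readPairs <- function(path, chromSizes) {
  con <- file(path, "r")
  hdr <- character(); n_hdr <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (!startsWith(ln, "#")) break
    hdr <- c(hdr, ln); n_hdr <- n_hdr + 1L
  }
  close(con)
  cs <- grep("^#chromsize:", hdr, value = TRUE)
  for (decl in cs) {
    f <- strsplit(trimws(sub("^#chromsize:\\s*", "", decl)), "\\s+")[[1]]
    if (!f[1] %in% names(chromSizes))
      stop("pairs header declares unknown chromosome: ", f[1])
    if (length(f) >= 2 && as.numeric(f[2]) != chromSizes[[f[1]]])
      stop("pairs header chromosome size mismatch for ", f[1])
  }
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t", skip = n_hdr,
                        fill = TRUE,
                        colClasses = list(character = c(1, 2, 4)))),
    error = function(e) data.table::data.table())  # header-only file
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom1 = character(), pos1 = numeric(),
                                  chrom2 = character(), pos2 = numeric(),
                                  strand1 = character(), strand2 = character()))
  if (ncol(dt) < 5L) {
    nf <- which(rowSums(!is.na(as.matrix(dt))) < 5L)
    stop(sprintf("malformed pairs line %d in %s: fewer than 5 columns",
                 n_hdr + if (length(nf)) nf[1] else 1L, path))
  }
  bad <- which(is.na(dt[[3]]) | is.na(dt[[5]]) | is.na(dt[[2]]) | dt[[2]] == "" |
                 is.na(dt[[4]]) | dt[[4]] == "")
  if (length(bad))
    stop(sprintf("malformed pairs line %d in %s", n_hdr + bad[1], path))
  out <- data.table::data.table(
    chrom1 = dt[[2]], pos1 = as.numeric(dt[[3]]),
    chrom2 = dt[[4]], pos2 = as.numeric(dt[[5]]),
    strand1 = if (ncol(dt) >= 6L) as.character(dt[[6]]) else ".",
    strand2 = if (ncol(dt) >= 7L) as.character(dt[[7]]) else ".")
  unknown <- !(out$chrom1 %in% names(chromSizes)) | !(out$chrom2 %in% names(chromSizes))
  if (any(unknown)) {
    warning(sum(unknown), " pair(s) on unknown chromosomes skipped")
    out <- out[!unknown]
  }
  canonicalizePairs(out, chromSizes)
}

#' @rdname readPairs
#' @param pairs a pairs data.table.
#' @export
canonicalizePairs <- function(pairs, chromSizes) {
  ord <- match(pairs$chrom1, names(chromSizes)) > match(pairs$chrom2, names(chromSizes)) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(ord)) {
    tmp <- pairs[ord]
    pairs[ord, `:=`(chrom1 = tmp$chrom2, pos1 = tmp$pos2,
                    chrom2 = tmp$chrom1, pos2 = tmp$pos1,
                    strand1 = tmp$strand2, strand2 = tmp$strand1)]
  }
  pairs[]
}

#' Filter valid pairs: minimum distance and PCR duplicates
#'
#' Intra-chromosomal pairs closer than `minDistance` bp are removed
#' (the boundary is inclusive: distance == minDistance is kept), then
#' exact duplicates (identical chrom1, pos1, chrom2, pos2, strand1,
#' strand2) are collapsed to a single pair.
#'
#' @param pairs canonicalised pairs data.table.
#' @param minDistance minimum intra-chromosomal genomic distance (bp),
#'   default 1000.
#' @return list with `pairs` (filtered data.table) and `report` (named
#'   counts: input, short_range, duplicate, kept).
#' @export
filterPairs <- function(pairs, minDistance = 1000) {
  nin <- nrow(pairs)
  short <- pairs$chrom1 == pairs$chrom2 & abs(pairs$pos2 - pairs$pos1) < minDistance
  kept <- pairs[!short]
  ndup <- 0L
  if (nrow(kept)) {
    uq <- unique(kept, by = c("chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2"))
    ndup <- nrow(kept) - nrow(uq)
    kept <- uq
  }
  list(pairs = kept,
       report = c(input = nin, short_range = sum(short),
                  duplicate = ndup, kept = nrow(kept)))
}

#' Bin intra-chromosomal pairs into per-chromosome contact matrices
#'
#' Each intra-chromosomal pair increments `counts[bin(pos1), bin(pos2)]`
#' and its mirror; both ends in the same bin increment the diagonal once.
#' Inter-chromosomal pairs are counted in the report but not stored.
#'
#' @param pairs filtered pairs data.table.
#' @param grid a [BinGrid].
#' @return list with `matrices` (named list of [ContactMatrix], one per
#'   grid chromosome) and `report` (intra / inter counts).
#' @export
binPairs <- function(pairs, grid) {
  cs <- chromSizes(grid)
  intra <- pairs$chrom1 == pairs$chrom2
  mats <- lapply(names(cs), function(ch) {
    n <- nBins(grid, ch)
    sel <- intra & pairs$chrom1 == ch
    if (any(sel)) {
      i <- binIndex(grid, ch, pairs$pos1[sel])
      j <- binIndex(grid, ch, pairs$pos2[sel])
      lo <- pmin.int(i, j); hi <- pmax.int(i, j)
      up <- sparseMatrix(i = lo, j = hi, x = 1, dims = c(n, n))
      m <- up + Matrix::t(up) - Diagonal(x = Matrix::diag(up))
    } else {
      m <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
    }
    new("ContactMatrix", chrom = ch, grid = grid, counts = methods::as(m, "CsparseMatrix"),
        weights = rep(NA_real_, n), krConverged = NA, krIterations = 0L)
  })
  list(matrices = setNames(mats, names(cs)),
       report = c(intra = sum(intra), inter = sum(!intra)))
}

#' Pool contact matrices from multiple datasets
#'
#' Element-wise sum of raw counts across matrices on identical grids and
#' chromosomes. Balancing weights are reset (recomputed, never summed).
#'
#' @param matrices list of [ContactMatrix] objects.
#' @return a [ContactMatrix] with summed counts and no weights.
#' @export
poolMatrices <- function(matrices) {
  if (length(matrices) == 0L) stop("no matrices to pool")
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(m@chrom, ref@chrom) ||
        !identical(m@grid@binSize, ref@grid@binSize) ||
        !identical(m@grid@chromSizes, ref@grid@chromSizes))
      stop("cannot pool matrices with mismatched grid or chromosome")
  }
  counts <- Reduce(`+`, lapply(matrices, contactCounts))
  new("ContactMatrix", chrom = ref@chrom, grid = ref@grid,
      counts = methods::as(counts, "CsparseMatrix"),
      weights = rep(NA_real_, nrow(counts)), krConverged = NA, krIterations = 0L)
}

#' Persist / restore a contact matrix as text
#'
#' Writes the upper triangle as a (bin1, bin2, count) TSV plus a sidecar
#' JSON with grid metadata and weights; `readContactMatrix` restores it.
#'
#' @param x a [ContactMatrix].
#' @param path output TSV path (sidecar written at `<path>.json`).
#' @export
writeContactMatrix <- function(x, path) {
  m <- contactCounts(x)
  tri <- Matrix::which(m != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] <= tri[, 2], , drop = FALSE]
  dt <- data.table::data.table(bin1 = tri[, 1], bin2 = tri[, 2],
                               count = m[tri])
  data.table::setorder(dt, bin1, bin2)
  data.table::fwrite(dt, path, sep = "\t")
  meta <- list(chrom = x@chrom, bin_size = binSize(x@grid),
               chrom_sizes = as.list(chromSizes(x@grid)),
               weights = x@weights, kr_converged = x@krConverged,
               kr_iterations = x@krIterations)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeContactMatrix
#' @export
readContactMatrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- BinGrid(meta$bin_size, unlist(meta$chrom_sizes))
  n <- nBins(grid, meta$chrom)
  dt <- data.table::fread(path, sep = "\t")
  up <- sparseMatrix(i = dt$bin1, j = dt$bin2, x = dt$count, dims = c(n, n))
  m <- up + Matrix::t(up) - Diagonal(x = Matrix::diag(up))
  w <- as.numeric(meta$weights); w[is.null(w)] <- NA_real_
  if (length(w) != n) w <- rep(NA_real_, n)
  new("ContactMatrix", chrom = meta$chrom, grid = grid,
      counts = methods::as(m, "CsparseMatrix"), weights = w,
      krConverged = if (is.null(meta$kr_converged)) NA else meta$kr_converged,
      krIterations = as.integer(meta$kr_iterations))
}

#' Export a per-bin track as bedGraph
#'
#' @param values named list chromosome -> per-bin numeric (NA bins skipped),
#'   or a [CompartmentProfile].
#' @param grid a [BinGrid] (taken from the profile if given one).
#' @param path output path.
#' @export
writeBedGraph <- function(values, grid = NULL, path) {
  if (methods::is(values, "CompartmentProfile")) {
    grid <- values@grid; values <- values@scores
  }
  rows <- lapply(names(values), function(ch) {
    v <- values[[ch]]
    st <- binStarts(grid, ch)
    en <- pmin(st + binSize(grid) - 1, chromSizes(grid)[[ch]])
    keep <- !is.na(v)
    data.table::data.table(chrom = ch, start = st[keep] - 1L, end = en[keep],
                           value = v[keep])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
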