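#' Knight-Ruiz matrix balancing
#'
#' Computes the positive weight vector `w` such that
#' `diag(w) %*% A %*% diag(w)` has unit row sums, using the Knight-Ruiz
#' inner-outer Newton iteration (conjugate-gradient inner solves with the
#' interior-point safeguards of the original algorithm). Bins whose
#' marginal raw count falls below the `maskQuantile` quantile of the
#' non-zero marginals are masked before balancing (KR diverges on
#' near-empty rows); masked bins get `NA` weights.
#'
#' @param x a [ContactMatrix] or a symmetric non-negative matrix.
#' @param tol convergence tolerance on `max|rowsum - 1|` of the balanced
#'   matrix, default 1e-8.
#' @param maxIter cap on outer Newton iterations, default 100.
#' @param maskQuantile low-coverage mask quantile over non-zero marginals
#'   (0 disables all but the empty-row mask), default 0.02.
#' @param maskFloorFrac cap on the mask threshold as a fraction of the
#'   median non-zero marginal, default 0.25. The mask protects the
#'   iteration from near-empty rows; a bin carrying more than a quarter
#'   of the median coverage is numerically safe, so the quantile rule is
#'   never allowed to mask it (this matters when coverage is tightly
#'   distributed and the low quantile would otherwise sit close to
#'   typical coverage).
#' @return For a ContactMatrix: the ContactMatrix with `weights`,
#'   `krConverged` and `krIterations` filled in. For a plain matrix: a
#'   list with `weights`, `converged`, `iterations`.
#' @export
krBalance <- function(x, tol = 1e-8, maxIter = 100L, maskQuantile = 0.02,
                      maskFloorFrac = 0.25) {
  if (methods::is(x, "ContactMatrix")) {
    res <- krBalance(contactCounts(x), tol = tol, maxIter = maxIter,
                     maskQuantile = maskQuantile, maskFloorFrac = maskFloorFrac)
    x@weights <- res$weights
    x@krConverged <- res$converged
    x@krIterations <- as.integer(res$iterations)
    return(x)
  }
  A <- x
  n <- nrow(A)
  marg <- as.numeric(rowSums(A))
  mask <- marg <= 0
  if (maskQuantile > 0 && any(marg > 0)) {
    nz <- marg[marg > 0]
    thr <- min(quantile(nz, maskQuantile, names = FALSE),
               maskFloorFrac * median(nz))
    mask <- mask | marg < thr
  }
  keep <- which(!mask)
  if (length(keep) == 0L) stop("fully masked matrix: nothing to balance")
  w <- rep(NA_real_, n)
  if (length(keep) == 1L) {
    d <- A[keep, keep]
    if (d <= 0) stop("single unmasked bin with zero diagonal cannot be balanced")
    w[keep] <- 1 / sqrt(d)
    return(list(weights = w, converged = TRUE, iterations = 0L))
  }
  sub <- A[keep, keep, drop = FALSE]
  res <- krNewton(sub, tol = tol, maxOuter = maxIter)
  w[keep] <- res$x
  list(weights = w, converged = res$converged, iterations = res$iterations)
}

# Knight-Ruiz inner-outer Newton iteration (CG inner solver, interior-point
# safeguards delta/Delta) for the doubly-stochastic scaling of a symmetric
# non-negative matrix with support.
krNewton <- function(A, tol = 1e-8, maxOuter = 100L,
                     delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  i <- 0L
  converged <- TRUE
  while (rout > rt) {
    i <- i + 1L
    if (i > maxOuter) { converged <- FALSE; i <- maxOuter; break }
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      if (k > 10L * n) break
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # Knight-Ruiz eta safeguard schedule
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, .Machine$double.eps))
  }
  list(x = x, converged = converged, iterations = i)
}

#' Expected contact by genomic distance
#'
#' For each diagonal offset `d`, the mean balanced contact over all
#' unmasked bin pairs at that offset (zeros included). Offsets with no
#' unmasked pair are `NA`.
#'
#' @param x a KR-balanced [ContactMatrix].
#' @return numeric vector of length `nbins` where element `d + 1` is the
#'   expected value at offset `d`.
#' @export
expectedByDistance <- function(x) {
  stopifnot(methods::is(x, "ContactMatrix"))
  w <- balancingWeights(x)
  if (all(is.na(w))) stop("balance the matrix before computing expected values")
  n <- length(w)
  valid <- !is.na(w)
  m <- contactCounts(x)
  trip <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  keepT <- trip$i <= trip$j & valid[trip$i] & valid[trip$j]
  trip <- trip[keepT, , drop = FALSE]
  bal <- trip$x * w[trip$i] * w[trip$j]
  off <- trip$j - trip$i
  sums <- numeric(n)
  if (nrow(trip)) {
    agg <- tapply(bal, off, sum)
    sums[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  # number of unmasked pairs per offset
  npairs <- vapply(0:(n - 1L), function(d) {
    if (d == 0L) sum(valid) else sum(valid[1:(n - d)] & valid[(1L + d):n])
  }, 0)
  out <- ifelse(npairs > 0, sums / npairs, NA_real_)
  out
}

#' Observed-over-expected matrix
#'
#' Balanced contact divided by the expected value at the pair's genomic
#' distance. Entries at masked bins or zero/missing expected are `NA`.
#'
#' @param x a KR-balanced [ContactMatrix].
#' @param expected optional precomputed [expectedByDistance()] vector.
#' @return dense symmetric matrix of O/E values.
#' @export
observedOverExpected <- function(x, expected = NULL) {
  if (is.null(expected)) expected <- expectedByDistance(x)
  b <- balancedMatrix(x)
  n <- nrow(b)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  ev <- expected[d + 1L]
  ev[!is.na(ev) & ev == 0] <- NA_real_
  oe <- b / ev
  dim(oe) <- c(n, n)
  oe
}

#' Correlation matrix of O/E rows
#'
#' Pearson correlation between every pair of rows of the O/E matrix,
#' computed over columns where both rows are non-missing. Pairs sharing
#' fewer than `minShared` complete columns, and zero-variance rows, are
#' `NA`. Diagonal is 1 for usable bins.
#'
#' @param oe dense O/E matrix.
#' @param minShared minimum shared non-missing columns per row pair,
#'   default 10.
#' @return dense symmetric correlation matrix.
#' @export
correlationMatrix <- function(oe, minShared = 10L) {
  n <- nrow(oe)
  cc <- suppressWarnings(cor(t(oe), use = "pairwise.complete.obs"))
  ok <- !is.na(oe)
  shared <- tcrossprod(ok)  # pairwise complete-column counts between rows
  cc[shared < minShared] <- NA_real_
  usable <- rowSums(ok) > 0
  diag(cc)[usable & !is.na(diag(cc))] <- 1
  cc
}
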