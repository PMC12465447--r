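#' Exact two-sided sign test for paired differences
#'
#' Zeros are dropped; with `k` positive signs out of `n` non-zero
#' differences, the two-sided p-value is the exact binomial
#' `min(1, 2 * min(P(X <= k), P(X >= k)))` under `p = 0.5`.
#'
#' @param differences numeric vector of paired differences.
#' @return an object of class `htest` with `statistic` (k positives),
#'   `p.value`, `n.effective` and a `notes` flag for degeneracies.
#' @export
signTest <- function(differences) {
  d <- differences[!is.na(differences)]
  nz <- d[d != 0]
  n <- length(nz)
  k <- sum(nz > 0)
  notes <- character()
  if (length(d) != length(differences)) notes <- c(notes, "NAs dropped")
  if (n < length(d)) notes <- c(notes, sprintf("%d zero difference(s) dropped", length(d) - n))
  if (n == 0L) {
    p <- NA_real_
    notes <- c(notes, "no non-zero differences")
  } else {
    p <- min(1, 2 * min(pbinom(k, n, 0.5), 1 - pbinom(k - 1, n, 0.5)))
  }
  structure(list(statistic = c(`positive signs` = k), p.value = p,
                 n.effective = n, method = "Exact sign test (two-sided)",
                 data.name = deparse(substitute(differences)),
                 notes = notes),
            class = "htest")
}

#' Mood's median test
#'
#' Dichotomises the pooled data at the grand median ("above" vs
#' "not above"; ties count as not-above) and tests the resulting
#' groups-by-dichotomy contingency table with a chi-square statistic on
#' `length(groups) - 1` degrees of freedom, without continuity
#' correction.
#'
#' @param groups list of numeric samples.
#' @return an `htest` with `statistic` (X-squared), `parameter` (df),
#'   `p.value`, `n.effective` and degeneracy `notes`.
#' @export
moodsMedianTest <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least two groups")
  pooled <- unlist(groups)
  m <- median(pooled)
  above <- vapply(groups, function(g) sum(g > m), 0)
  below <- vapply(groups, function(g) sum(g <= m), 0)
  notes <- character()
  if (any(above + below > 0 & above == 0 & vapply(groups, function(g) all(g == m), TRUE)))
    notes <- c(notes, "a group lies entirely at the grand median")
  tab <- rbind(above = above, not_above = below)
  rowTot <- rowSums(tab); colTot <- colSums(tab); N <- sum(tab)
  if (any(rowTot == 0)) {
    stat <- 0; p <- 1
    notes <- c(notes, "degenerate dichotomy (all values on one side)")
  } else {
    E <- outer(rowTot, colTot) / N
    stat <- sum((tab - E)^2 / E)
    if (any(E < 5)) notes <- c(notes, "expected cell count < 5")
    p <- pchisq(stat, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = length(groups) - 1L),
                 p.value = p, n.effective = N,
                 method = "Mood's median test", data.name = "groups",
                 notes = notes, table = tab),
            class = "htest")
}

#' @describeIn moodsMedianTest every group versus a control group,
#'   returning one raw p-value per comparison (input for [bhAdjust()]).
#' @param control numeric control sample.
#' @return `pairwiseMoodsVsControl`: data.frame (group, statistic,
#'   p.value, p.adjusted).
#' @export
pairwiseMoodsVsControl <- function(groups, control) {
  res <- lapply(groups, function(g) moodsMedianTest(list(control, g)))
  p <- vapply(res, function(r) r$p.value, 0)
  data.frame(group = if (!is.null(names(groups))) names(groups)
             else seq_along(groups),
             statistic = vapply(res, function(r) unname(r$statistic), 0),
             p.value = p, p.adjusted = bhAdjust(p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= i} (p_(j) * m / j)` over the ascending order, capped
#' at 1 and returned in the input order.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Student's two-sample t-test
#'
#' Pooled-variance (unpaired) Student's t, or the paired t on
#' differences; two-sided p from the t distribution.
#'
#' @param a,b numeric samples.
#' @param paired logical, default FALSE.
#' @return an `htest` with `statistic`, `parameter` (df), `p.value` and
#'   degeneracy `notes`.
#' @export
twoSampleT <- function(a, b, paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  notes <- character()
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    d <- a - b
    n <- length(d)
    df <- n - 1L
    sdd <- sd(d)
    if (sdd == 0) {
      if (mean(d) == 0) { t <- 0; p <- 1 } else { t <- Inf * sign(mean(d)); p <- 0 }
      notes <- c(notes, "zero variance of differences")
    } else {
      t <- mean(d) / (sdd / sqrt(n))
      p <- 2 * pt(-abs(t), df)
    }
  } else {
    n1 <- length(a); n2 <- length(b)
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
    if (sp2 == 0) {
      if (mean(a) == mean(b)) { t <- 0; p <- 1 } else { t <- Inf * sign(mean(a) - mean(b)); p <- 0 }
      notes <- c(notes, "zero pooled variance")
    } else {
      t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * pt(-abs(t), df)
    }
  }
  structure(list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                 method = if (paired) "Paired Student's t-test"
                 else "Two-sample pooled-variance Student's t-test",
                 data.name = "a vs b", notes = notes,
                 n.effective = if (paired) length(a) else length(a) + length(b)),
            class = "htest")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H with the standard tie correction, followed by Dunn's
#' pairwise z-statistics (tie-corrected) with Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param groups list of numeric samples.
#' @return list with `kruskal` (an `htest`: H statistic, df, p) and
#'   `dunn` (data.frame: group1, group2, z, p.value, p.adjusted).
#' @export
kruskalDunn <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  g <- length(groups)
  if (g < 2L) stop("need at least two groups")
  n <- lengths(groups)
  N <- sum(n)
  pooled <- unlist(groups)
  r <- rank(pooled)
  idx <- rep(seq_len(g), n)
  Rsum <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  ties <- table(pooled)
  tieSum <- sum(ties^3 - ties)
  C <- 1 - tieSum / (N^3 - N)
  if (C > 0) H <- H / C
  p <- if (all(pooled == pooled[1])) 1 else pchisq(H, df = g - 1L, lower.tail = FALSE)
  if (all(pooled == pooled[1])) H <- 0
  kres <- structure(list(statistic = c(H = H), parameter = c(df = g - 1L),
                         p.value = p, method = "Kruskal-Wallis rank sum test",
                         data.name = "groups", n.effective = N,
                         notes = if (tieSum > 0) "tie-corrected" else character()),
                    class = "htest")
  Rbar <- Rsum / n
  sig2 <- N * (N + 1) / 12 - tieSum / (12 * (N - 1))
  pairs <- utils::combn(g, 2)
  dunn <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = vapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      den <- sqrt(sig2 * (1 / n[i] + 1 / n[j]))
      if (den == 0) 0 else (Rbar[i] - Rbar[j]) / den
    }, 0))
  dunn$p.value <- 2 * stats::pnorm(-abs(dunn$z))
  dunn$p.adjusted <- bhAdjust(dunn$p.value)
  list(kruskal = kres, dunn = dunn)
}

#' t-test for a Pearson correlation
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric vectors (pairs with NAs dropped).
#' @return an `htest` with `estimate` (r), `statistic` (t), `parameter`
#'   (df), `p.value` and degeneracy `notes`.
#' @export
correlationTTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  notes <- character()
  if (n < 2L) stop("need at least two complete pairs")
  r <- suppressWarnings(cor(x, y))
  if (is.na(r)) {
    # zero-variance input carries no linear association
    r <- 0; t <- 0; p <- 1
    notes <- c(notes, "zero-variance input: correlation taken as 0")
  } else if (n == 2L) {
    t <- NA_real_; p <- NA_real_
    notes <- c(notes, "df = 0: p-value undefined")
    warning("correlation t-test with n = 2 has zero degrees of freedom")
  } else if (abs(r) >= 1 - 1e-12) {
    t <- Inf * sign(r); p <- 0
    notes <- c(notes, "exact linear fit")
  } else if (r == 0) {
    t <- 0; p <- 1
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  structure(list(statistic = c(t = t), parameter = c(df = n - 2L),
                 p.value = p, estimate = c(cor = r),
                 method = "t-test for Pearson correlation",
                 data.name = "x vs y", n.effective = n, notes = notes),
            class = "htest")
}
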