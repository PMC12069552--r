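## Nonparametric grouping statistics: Kruskal-Wallis, Dunn's post hoc test
## with Benjamini-Hochberg adjustment and compact letter display, and
## Pearson's chi-square with Yates correction.

#' Kruskal-Wallis rank-sum test
#'
#' Wraps \code{stats::kruskal.test} (tie-corrected H, chi-square p-value).
#' When every value is identical across all groups the statistic is
#' degenerate; by convention H = 0 and p = 1 are returned with a warning.
#'
#' @param value Numeric vector of observations.
#' @param group Group labels (>= 2 groups, each with >= 1 observation).
#' @return List with \code{statistic} (H), \code{p.value}, \code{df}.
#' @examples
#' kruskalWallis(c(1, 2, 3, 101, 102, 103, 201, 202, 203),
#'               rep(c("a", "b", "c"), each = 3))
#' @export
kruskalWallis <- function(value, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("at least two groups required")
  if (length(unique(value)) == 1L) {
    warning("all values identical; returning H = 0, p = 1 by convention")
    return(list(statistic = 0, p.value = 1, df = nlevels(group) - 1L))
  }
  kt <- stats::kruskal.test(value, group)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post hoc test with BH adjustment and compact letters
#'
#' All pairwise Dunn z-statistics on the joint ranks with tie-corrected
#' pooled variance, two-sided p-values adjusted by Benjamini-Hochberg over
#' the k(k-1)/2 comparisons, and a compact letter display: two groups share
#' a letter iff their adjusted p-value is >= alpha.
#'
#' @param value Numeric vector of observations.
#' @param group Group labels.
#' @param alpha Significance level for the letter display, default 0.05.
#' @return List with matrices \code{z} and \code{p.adjusted}, the
#'   \code{letters} per group, and \code{alpha}.
#' @export
dunnBH <- function(value, group, alpha = 0.05) {
  group <- as.factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("at least two groups required")
  N <- length(value)
  r <- rank(value)
  rbar <- tapply(r, group, mean)
  n <- tabulate(group)
  ties <- table(value)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  z <- p <- matrix(NA_real_, k, k, dimnames = list(levels(group), levels(group)))
  pairs <- utils::combn(k, 2)
  praw <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[i] + 1 / n[j]))
    zz <- (rbar[i] - rbar[j]) / se
    z[i, j] <- z[j, i] <- zz
    praw[q] <- 2 * stats::pnorm(-abs(zz))
  }
  padj <- stats::p.adjust(praw, method = "BH")
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    p[i, j] <- p[j, i] <- padj[q]
  }
  list(z = z, p.adjusted = p,
       letters = compactLetters(p, alpha = alpha), alpha = alpha)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: starting from a single letter covering all
#' groups, each significant pair splits every letter set containing both
#' members; sets contained in another are absorbed. Groups share a letter
#' iff they are not significantly different.
#'
#' @param pmat Symmetric matrix of (adjusted) pairwise p-values with group
#'   dimnames; the diagonal is ignored.
#' @param alpha Significance level.
#' @return Named character vector of letter strings per group.
#' @export
compactLetters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  sets <- list(seq_len(k))
  pairs <- utils::combn(k, 2)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    for (s in rev(seq_along(sets))) {
      if (all(c(i, j) %in% sets[[s]])) {
        s1 <- setdiff(sets[[s]], i)
        s2 <- setdiff(sets[[s]], j)
        sets[[s]] <- NULL
        for (cand in list(s1, s2)) {
          if (!length(cand)) next
          absorbed <- any(vapply(sets, function(x) all(cand %in% x), logical(1)))
          if (!absorbed) sets[[length(sets) + 1L]] <- cand
        }
      }
    }
  }
  ## drop sets absorbed by later insertions, order by smallest member
  keep <- vapply(seq_along(sets), function(s)
    !any(vapply(seq_along(sets), function(u)
      u != s && all(sets[[s]] %in% sets[[u]]) &&
        length(sets[[u]]) > length(sets[[s]]), logical(1))), logical(1))
  sets <- sets[keep]
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- setNames(rep("", k), groups)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}

#' Pearson's chi-square with Yates continuity correction
#'
#' @param tab 2x2 matrix of non-negative counts; a zero marginal is an
#'   error.
#' @return List with \code{statistic}, \code{p.value}, \code{df}.
#' @examples
#' chiSquaredYates(matrix(c(30, 10, 10, 30), 2))
#' @export
chiSquaredYates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the table")
  ct <- stats::chisq.test(tab, correct = TRUE)
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       df = unname(ct$parameter))
}
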