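## Shared statistical primitives. auROC and step-wise auPRC are implemented
## here; correlation and exact tests delegate to the standard stats routines.

checkLabeled <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with half credit for ties: the probability that
#' a random positive outscores a random negative. Equals the trapezoidal
#' area under the ROC curve.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels logical (or 0/1) class labels, TRUE = positive.
#' @return auROC in [0, 1].
#' @examples
#' auROC(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
#' @export
auROC <- function(scores, labels) {
  labels <- checkLabeled(scores, labels)
  r <- rank(scores)                 # midranks give ties half credit
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Descending-score sweep with tied scores grouped into a single step and
#' step-wise (right-continuous) interpolation: the area is the sum over
#' steps of (recall gained) x (precision at the step).
#'
#' @inheritParams auROC
#' @return auPRC in (0, 1].
#' @export
auPRC <- function(scores, labels) {
  labels <- checkLabeled(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y)
  allCum <- seq_along(y)
  lastOfGrp <- !duplicated(grp, fromLast = TRUE)
  tp <- tpCum[lastOfGrp]
  n <- allCum[lastOfGrp]
  prec <- tp / n
  nPos <- sum(y)
  recall <- tp / nPos
  dRecall <- diff(c(0, recall))
  sum(dRecall * prec)
}

#' Tie-corrected Kendall rank correlation
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in [-1, 1].
#' @export
kendallTauB <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("tau-b undefined: a variable is constant")
  unname(cor(x, y, method = "kendall"))
}

#' Pearson product-moment correlation
#'
#' @inheritParams kendallTauB
#' @return rho in [-1, 1].
#' @export
pearsonRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined: a variable has zero variance")
  unname(cor(x, y, method = "pearson"))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Rows are the positive and neutral subsets, columns concordant and
#' discordant calls. `side = "greater"` tests for enrichment of concordance
#' in the positive subset.
#'
#' @param a,b concordant and discordant counts in the positive subset.
#' @param c,d concordant and discordant counts in the neutral subset.
#' @param side "greater" or "two_sided".
#' @return the P-value.
#' @export
fisherExact <- function(a, b, c, d, side = c("greater", "two_sided")) {
  side <- match.arg(side)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) stop("empty contingency table")
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  alternative <- if (side == "greater") "greater" else "two.sided"
  fisher.test(tab, alternative = alternative)$p.value
}

#' Upper binomial tail
#'
#' P(X >= k) for X ~ Binomial(n, q), computed in log space by `pbinom` for
#' numerical stability.
#'
#' @param n number of trials.
#' @param k observed successes.
#' @param q success probability.
#' @return the tail probability.
#' @export
binomialTail <- function(n, k, q) {
  stopifnot(k >= 0, k <= n, q > 0, q < 1)
  if (k == 0) return(1)
  exp(pbinom(k - 1, n, q, lower.tail = FALSE, log.p = TRUE))
}
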