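## Core PWM machinery: log-odds conversion, double-stranded scanning with a
## neutral N policy, and the exact discretized score distribution that backs
## all P-value and threshold queries.

#' Convert a count matrix to a log-odds weight matrix
#'
#' Weights are \eqn{w(i,b) = \ln\{(c(i,b) + \kappa p_b) / ((W + \kappa) p_b)\}}
#' where \eqn{c(i,b)} are the counts, \eqn{W} the word count, \eqn{p_b} the
#' background frequency of base \eqn{b} and \eqn{\kappa} the pseudocount
#' weight. The default \eqn{\kappa = \max(1, \ln W)} scales smoothing with
#' the (log) depth of the alignment.
#'
#' @param pcm a [PositionCountMatrix-class].
#' @param bg a [BackgroundModel-class]; its mononucleotide part is used.
#' @param kappa non-negative pseudocount weight.
#' @param ... metadata passed to [PositionWeightMatrix()] (tf, subtype,
#'   provenance flags, quality).
#' @return A [PositionWeightMatrix-class] named after the PCM.
#' @examples
#' pcm <- PositionCountMatrix("toy", rbind(c(4, 0, 0, 0), c(0, 4, 0, 0)))
#' weights(pcmToPwm(pcm, uniformBackground(), kappa = 1))
#' @export
pcmToPwm <- function(pcm, bg = uniformBackground(),
                     kappa = max(1, log(wordCount(pcm))), ...) {
  stopifnot(methods::is(pcm, "PositionCountMatrix"),
            methods::is(bg, "BackgroundModel"), kappa >= 0)
  W <- wordCount(pcm)
  if (W <= 0) stop("zero word count")
  p <- bg@mono
  w <- log(t((t(counts(pcm)) + kappa * p) / ((W + kappa) * p)))
  PositionWeightMatrix(name(pcm), w, ...)
}

## weights + N column (background-expected contribution per position);
## when `step` is given the columns are rounded to its multiples so that
## window scores live on the same discretized scale as a ScoreDistribution
## (raw scores could otherwise exceed the discretized support and return a
## zero P-value)
weightsWithN <- function(pwm, bg, step = NULL) {
  w <- pwm@weights
  w5 <- cbind(w, as.vector(w %*% bg@mono))
  if (!is.null(step)) w5 <- round(w5 / step) * step
  w5
}

## Window scores on both strands. Returns a list with `plus` and `minus`
## numeric vectors indexed by 0-based window offset in the ORIGINAL sequence
## (element i corresponds to offset i - 1). Ns score the background-expected
## column; on the minus strand an N stays N.
windowScoresBoth <- function(w5, codes) {
  L <- nrow(w5)
  n <- length(codes)
  if (n < L) stop("sequence shorter than the motif")
  nwin <- n - L + 1L
  plus <- numeric(nwin)
  for (i in seq_len(L)) plus <- plus + w5[i, codes[i:(i + nwin - 1L)]]
  rc <- rev(c(4L, 3L, 2L, 1L, 5L)[codes])
  minusRc <- numeric(nwin)
  for (i in seq_len(L)) minusRc <- minusRc + w5[i, rc[i:(i + nwin - 1L)]]
  ## offset o (0-based) on the reverse complement maps to original offset
  ## n - L - o, so reversing restores original-offset indexing
  list(plus = plus, minus = rev(minusRc))
}

#' Best PWM hit on a sequence
#'
#' Scans every window of both strands and returns the maximal-scoring hit.
#' An N in the sequence contributes the background-expected weight of the
#' matrix column it meets, so Ns neither create nor destroy hits. Ties are
#' broken towards the smaller offset, then the plus strand.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param seq a single DNA string (ACGTN) or length-1 DNAStringSet; must be
#'   at least as long as the motif.
#' @param bg background used for the N column and, via `dist`, the P-value.
#' @param dist optional [ScoreDistribution-class]; when supplied the hit
#'   carries P(score >= observed).
#' @return A [MotifHit-class].
#' @examples
#' pwm <- PositionWeightMatrix("ac", rbind(c(2, -2, -2, -2), c(-2, 2, -2, -2)))
#' bestHit(pwm, "TTACTT")
#' @export
bestHit <- function(pwm, seq, bg = uniformBackground(), dist = NULL) {
  seq <- asSequenceCharacters(seq)
  stopifnot(length(seq) == 1L)
  codes <- encodeDNA(seq)
  w5 <- weightsWithN(pwm, bg, step = if (is.null(dist)) NULL else dist@step)
  sc <- windowScoresBoth(w5, codes)
  cand <- data.frame(
    score = c(sc$plus, sc$minus),
    offset = rep.int(seq_along(sc$plus) - 1L, 2L),
    strandIdx = rep(c(0L, 1L), each = length(sc$plus)))
  best <- cand[order(-cand$score, cand$offset, cand$strandIdx)[1L], ]
  pv <- if (is.null(dist)) NA_real_ else pvalueOfScore(dist, best$score)
  new("MotifHit", offset = as.integer(best$offset),
      strand = c("+", "-")[best$strandIdx + 1L],
      score = best$score, pvalue = pv)
}

## Fast path used by the benchmarks: best-hit scores for many sequences.
#' Best-hit scores for a set of sequences
#'
#' Vectorized form of [bestHit()] returning only the maximal window score of
#' each sequence (both strands).
#'
#' @inheritParams bestHit
#' @param seqs character vector or DNAStringSet.
#' @return numeric vector of best-hit scores, one per sequence.
#' @export
bestHitScores <- function(pwm, seqs, bg = uniformBackground()) {
  seqs <- asSequenceCharacters(seqs)
  w5 <- weightsWithN(pwm, bg)
  vapply(seqs, function(s) {
    sc <- windowScoresBoth(w5, encodeDNA(s))
    max(sc$plus, sc$minus)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Exact discretized score distribution of a PWM
#'
#' Distribution of the single-window, single-strand score of a random L-mer
#' drawn i.i.d. from the mononucleotide background, computed by positional
#' convolution over discretized score bins. Each weight is rounded to the
#' nearest multiple of `step`.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param bg a [BackgroundModel-class] (mononucleotide part used).
#' @param step discretization unit; defaults to 1/1000 of the total score
#'   range of the matrix.
#' @return A [ScoreDistribution-class].
#' @examples
#' pwm <- PositionWeightMatrix("toy", rbind(c(2, 1, 0, -1)))
#' scoreDistribution(pwm, step = 1)
#' @export
scoreDistribution <- function(pwm, bg = uniformBackground(), step = NULL) {
  w <- pwm@weights
  if (is.null(step)) {
    rng <- sum(apply(w, 1, max)) - sum(apply(w, 1, min))
    step <- if (rng > 0) rng / 1000 else 1e-3
  }
  stopifnot(step > 0)
  k <- round(w / step)
  p <- bg@mono
  mass <- 1
  base <- 0
  for (i in seq_len(nrow(k))) {
    ki <- k[i, ]
    kmin <- min(ki)
    len <- length(mass) + (max(ki) - kmin)
    nm <- numeric(len)
    for (b in 1:4) {
      sh <- ki[b] - kmin
      idx <- seq_along(mass) + sh
      nm[idx] <- nm[idx] + mass * p[b]
    }
    mass <- nm
    base <- base + kmin
  }
  keep <- mass > 0
  new("ScoreDistribution", step = step,
      bins = (base + which(keep) - 1), mass = unname(mass[keep]))
}

#' P-value of a PWM score
#'
#' Returns P(score >= s) under the discretized background distribution.
#' Monotone non-increasing in s; 1 at or below the support minimum, 0 above
#' the support maximum.
#'
#' @param dist a [ScoreDistribution-class].
#' @param s numeric vector of scores.
#' @return numeric vector of tail probabilities.
#' @export
pvalueOfScore <- function(dist, s) {
  bins <- dist@bins
  tail <- rev(cumsum(rev(dist@mass)))
  kq <- ceiling(s / dist@step - 1e-9)
  ## first bin index >= kq
  j <- findInterval(kq - 0.5, bins) + 1L
  out <- numeric(length(s))
  inside <- j <= length(bins)
  out[inside] <- tail[j[inside]]
  out
}

#' Score threshold for a target P-value
#'
#' The minimal score t with P(score >= t) <= p (a "strong" threshold). When
#' no achievable score qualifies the support maximum plus one step is
#' returned, so the round trip `pvalueOfScore(dist, thresholdForPvalue(dist,
#' p)) <= p` always holds.
#'
#' @param dist a [ScoreDistribution-class].
#' @param p target P-value in (0, 1].
#' @return numeric score threshold.
#' @export
thresholdForPvalue <- function(dist, p) {
  stopifnot(length(p) == 1L, p > 0, p <= 1)
  bins <- dist@bins
  tail <- rev(cumsum(rev(dist@mass)))
  ok <- which(tail <= p + 1e-15)
  if (length(ok) == 0L) return((bins[length(bins)] + 1) * dist@step)
  bins[ok[1L]] * dist@step
}

#' PWM hit P-values for the two alleles of a variant
#'
#' For each allele the variant base is substituted into the context, all
#' windows (both strands) overlapping the variant position are scored, and
#' the P-value of the best overlapping hit is returned.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param dist the matching [ScoreDistribution-class].
#' @param context DNA string carrying the variant.
#' @param pos 1-based position of the variant within `context`.
#' @param ref,alt reference and alternative bases; `context[pos]` must equal
#'   `ref`.
#' @param bg background for the N policy of scanning.
#' @return named numeric(2): `ref` and `alt` best-hit P-values.
#' @examples
#' pwm <- PositionWeightMatrix("toy", rbind(c(2, -2, -2, -2), c(-2, 2, -2, -2)))
#' d <- scoreDistribution(pwm)
#' allelePvalues(pwm, d, "TTACTT", 3, "A", "G")
#' @export
allelePvalues <- function(pwm, dist, context, pos, ref, alt,
                          bg = uniformBackground()) {
  context <- asSequenceCharacters(context)
  codes <- encodeDNA(context)
  L <- motifLength(pwm)
  n <- length(codes)
  stopifnot(pos >= 1L, pos <= n)
  if (codes[pos] != match(toupper(ref), DNA_BASES))
    stop("reference allele does not match the context at `pos`")
  if (n < L || pos < 1L)
    stop("context too short for any window to overlap the variant")
  w5 <- weightsWithN(pwm, bg, step = dist@step)
  ## 0-based offsets of windows overlapping pos
  lo <- max(0L, pos - L)          # pos0 - L + 1 with pos0 = pos - 1
  hi <- min(n - L, pos - 1L)
  if (lo > hi) stop("no window of the motif length overlaps the variant")
  scoreAllele <- function(base) {
    cds <- codes
    cds[pos] <- match(toupper(base), DNA_BASES)
    sc <- windowScoresBoth(w5, cds)
    idx <- (lo:hi) + 1L
    max(sc$plus[idx], sc$minus[idx])
  }
  c(ref = pvalueOfScore(dist, scoreAllele(ref)),
    alt = pvalueOfScore(dist, scoreAllele(alt)))
}
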