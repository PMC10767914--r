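## Independent oracles used across the suite. Each reimplements the checked
## quantity by brute force or direct enumeration, sharing no code with the
## package internals.

BASES <- c("A", "C", "G", "T")

randomPwm <- function(L, seed, sd = 1.5) {
  set.seed(seed)
  PositionWeightMatrix(sprintf("rnd_%d", seed),
                       matrix(rnorm(L * 4, sd = sd), ncol = 4))
}

randomSeq <- function(len, seed, alphabet = BASES) {
  set.seed(seed)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

revcompChar <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

## naive per-window scoring, N handled as mean weight under uniform bg
oracleWindowScore <- function(w, seq, offset0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  s <- 0
  for (i in seq_len(nrow(w))) {
    ch <- chars[offset0 + i]
    s <- s + if (ch == "N") mean(w[i, ]) else w[i, match(ch, BASES)]
  }
  s
}

## exhaustive max over all offsets and both strands
oracleBestScore <- function(w, seq) {
  L <- nrow(w)
  best <- -Inf
  for (s in c(seq, revcompChar(seq))) {
    for (o in 0:(nchar(s) - L)) {
      best <- max(best, oracleWindowScore(w, s, o))
    }
  }
  best
}

## all 4^L words of length L as a matrix of base indices
allWords <- function(L) {
  as.matrix(expand.grid(rep(list(1:4), L)))
}

## exact tail P(score >= s) by enumerating every word, with weights
## discretized exactly as the distribution does
oracleTail <- function(w, step, mono, s) {
  wr <- round(w / step) * step
  words <- allWords(nrow(w))
  scores <- rowSums(matrix(wr[cbind(rep(seq_len(nrow(w)),
                                        each = nrow(words)),
                                    as.vector(words))],
                           nrow = nrow(words)))
  probs <- apply(words, 1, function(b) prod(mono[b]))
  sum(probs[scores >= s - 1e-9])
}

## pair-counting auROC: wins + half ties over all (pos, neg) pairs
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

## exhaustive precision-recall sweep over distinct thresholds
oracleAuprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels)
  prevRecall <- 0
  area <- 0
  for (t in thr) {
    called <- scores >= t
    prec <- sum(labels & called) / sum(called)
    recall <- sum(labels & called) / nPos
    area <- area + (recall - prevRecall) * prec
    prevRecall <- recall
  }
  area
}

## O(n^2) concordant/discordant counting for tau-b
oracleTauB <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i])
    dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

## hypergeometric summation for the one-sided (greater) Fisher test
oracleFisherGreater <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  tot <- 0
  for (x in a:min(m, k)) {
    tot <- tot + choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  tot
}

## direct binomial upper-tail summation
oracleBinomTail <- function(n, k, q) {
  sum(vapply(k:n, function(x) choose(n, x) * q^x * (1 - q)^(n - x),
             numeric(1)))
}

## dinucleotide count vector (16 cells, keyed "XY")
dinucCounts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  di <- paste0(chars[-length(chars)], chars[-1L])
  table(factor(di, levels = as.vector(outer(BASES, BASES, paste0))))
}
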