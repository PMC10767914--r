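## The three in-vivo benchmarks: flank-negative auROC/auPRC, pseudo-ROC
## variants against first-order Markov negatives, and motif centrality
## E-values; plus the dataset/subtype applicability filters.

benchmarkResult <- function(motif, dataset, metric, value,
                            sortKey = NA_character_) {
  data.frame(motif = motif, dataset = dataset, metric = metric,
             sort_key = sortKey, value = value, stringsAsFactors = FALSE)
}

#' Flank-negative ChIP-Seq benchmark
#'
#' Scores every motif on summit-window positives versus flanking negatives
#' (best-hit score as classifier score) and reports auROC and auPRC.
#'
#' @param pwms list of [PositionWeightMatrix-class].
#' @param positives [SequenceSet-class] of summit windows.
#' @param negatives [SequenceSet-class] of flanking windows.
#' @param dataset dataset identifier stamped into the results.
#' @param sortKey which peak ranking produced the sets ("signal" or
#'   "significance"); carried into the results.
#' @param bg background for scanning.
#' @return data.frame of benchmark rows (motif, dataset, metric, sort_key,
#'   value) with metrics `auROC_flank` and `auPRC_flank`.
#' @export
benchFlank <- function(pwms, positives, negatives, dataset = positives@id,
                       sortKey = NA_character_, bg = uniformBackground()) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("empty positive or negative set")
  posSeq <- sequences(positives)
  negSeq <- sequences(negatives)
  labels <- c(rep(TRUE, length(posSeq)), rep(FALSE, length(negSeq)))
  allSeq <- c(as.character(posSeq), as.character(negSeq))
  do.call(rbind, lapply(pwms, function(pwm) {
    sc <- bestHitScores(pwm, allSeq, bg)
    rbind(
      benchmarkResult(name(pwm), dataset, "auROC_flank",
                      auROC(sc, labels), sortKey),
      benchmarkResult(name(pwm), dataset, "auPRC_flank",
                      auPRC(sc, labels), sortKey))
  }))
}

#' Pseudo-ROC benchmarks against Markov negatives
#'
#' Two variants sharing the positive set of 301-bp summit windows:
#' `pseudo_auROC` samples `negPerPos` negatives per positive from a
#' first-order Markov model fitted to the positives and computes auROC of
#' best-hit scores; `pseudo_au_logROC` is the asymptotic variant, the mean
#' over a log-uniform grid of P-value cutoffs p of the fraction of positives
#' whose best-hit P-value is <= p (no sampled negatives).
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param positives [SequenceSet-class] of equal-width summit windows.
#' @param negPerPos sampled negatives per positive (default 1).
#' @param seed integer seed for the negative sampling.
#' @param dataset,sortKey identifiers stamped into the results.
#' @param pGrid P-value grid for the asymptotic variant; default 50
#'   log-uniformly spaced points in [1e-5, 1e-2].
#' @return data.frame of benchmark rows with metrics `pseudo_auROC` and
#'   `pseudo_au_logROC`.
#' @export
benchPseudo <- function(pwm, positives, negPerPos = 1L, seed = 1L,
                        dataset = positives@id, sortKey = NA_character_,
                        pGrid = 10^seq(-5, -2, length.out = 50L)) {
  if (length(positives) == 0L) stop("empty positive set")
  posChar <- as.character(sequences(positives))
  widths <- nchar(posChar)
  stopifnot(length(unique(widths)) == 1L)
  bgModel <- fitMarkov1(posChar)
  negs <- sampleMarkov1(bgModel, widths[1L],
                        negPerPos * length(posChar), seed)
  scPos <- bestHitScores(pwm, posChar, bgModel)
  scNeg <- bestHitScores(pwm, negs, bgModel)
  pseudoAuroc <- auROC(c(scPos, scNeg),
                       c(rep(TRUE, length(scPos)), rep(FALSE, length(scNeg))))
  dist <- scoreDistribution(pwm, bgModel)
  pvPos <- pvalueOfScore(dist, scPos)
  sens <- vapply(pGrid, function(p) mean(pvPos <= p), numeric(1))
  rbind(
    benchmarkResult(name(pwm), dataset, "pseudo_auROC", pseudoAuroc, sortKey),
    benchmarkResult(name(pwm), dataset, "pseudo_au_logROC", mean(sens),
                    sortKey))
}

#' Motif centrality benchmark
#'
#' Measures how best hits concentrate near the window centers (peak
#' summits). For each half-width w on a 5-bp grid the count of hit centers
#' within +/- w of the window center is compared with the fraction of
#' possible hit centers in that band via an upper binomial tail; the
#' E-value is the minimal tail probability Bonferroni-corrected by the
#' number of tested half-widths. Returns -log10(E); negative values mean no
#' central enrichment.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param positives [SequenceSet-class] of equal-width summit windows, wider
#'   than the motif.
#' @param dataset,sortKey identifiers stamped into the results.
#' @param bg background for scanning.
#' @param gridStep spacing of tested half-widths in bp (default 5).
#' @return data.frame with one benchmark row, metric `centrality_neglogE`.
#' @export
benchCentrality <- function(pwm, positives, dataset = positives@id,
                            sortKey = NA_character_,
                            bg = uniformBackground(), gridStep = 5L) {
  posChar <- as.character(sequences(positives))
  W <- unique(nchar(posChar))
  stopifnot(length(W) == 1L)
  L <- motifLength(pwm)
  if (W <= L) stop("windows must be wider than the motif")
  w5 <- weightsWithN(pwm, bg)
  ## best-hit center offsets from the window center
  center <- (W - 1) / 2
  delta <- vapply(posChar, function(s) {
    sc <- windowScoresBoth(w5, encodeDNA(s))
    cand <- data.frame(score = c(sc$plus, sc$minus),
                       offset = rep.int(seq_along(sc$plus) - 1L, 2L),
                       strandIdx = rep(c(0L, 1L), each = length(sc$plus)))
    off <- cand$offset[order(-cand$score, cand$offset, cand$strandIdx)[1L]]
    off + (L - 1) / 2 - center
  }, numeric(1), USE.NAMES = FALSE)
  nWin <- W - L + 1L
  offsets <- (seq_len(nWin) - 1L) + (L - 1) / 2 - center
  halfWidths <- seq(gridStep, floor(W / 2), by = gridStep)
  n <- length(delta)
  pvals <- vapply(halfWidths, function(w) {
    q <- mean(abs(offsets) <= w)
    if (q <= 0 || q >= 1) return(1)
    binomialTail(n, sum(abs(delta) <= w), q)
  }, numeric(1))
  evalue <- min(pvals) * length(halfWidths)
  benchmarkResult(name(pwm), dataset, "centrality_neglogE",
                  -log10(evalue), sortKey)
}

#' Applicability filters for the ChIP-Seq benchmark
#'
#' Datasets are retained only when (I) the peak set comprises at least
#' `minPeaks` peaks and (II) at least one tested motif reached auROC >=
#' `aurocMin` on them. Motif subtypes for which no motif reaches auROC >=
#' `aurocMin` on any dataset are flagged as not applicable to ChIP-Seq data
#' (and are later excluded from the in-vivo subcollection).
#'
#' @param results data.frame of benchmark rows; auROC-type metrics
#'   (`auROC_flank`, `pseudo_auROC`) are used for rule (II).
#' @param peakCounts named integer vector: peaks per dataset.
#' @param subtypeOf named character vector mapping motif name to subtype
#'   label (optional; when NULL each motif is its own subtype).
#' @param minPeaks,aurocMin the filter thresholds (defaults 100 and 0.6).
#' @return list with `retainedDatasets`, `excludedDatasets`,
#'   `inapplicableSubtypes` and the filtered `results`.
#' @export
chipseqFilters <- function(results, peakCounts, subtypeOf = NULL,
                           minPeaks = 100L, aurocMin = 0.6) {
  aurocRows <- results[results$metric %in% c("auROC_flank", "pseudo_auROC"), ]
  datasets <- unique(results$dataset)
  bigEnough <- datasets[peakCounts[datasets] >= minPeaks]
  bigEnough <- bigEnough[!is.na(bigEnough)]
  anyGood <- vapply(datasets, function(d) {
    any(aurocRows$value[aurocRows$dataset == d] >= aurocMin)
  }, logical(1))
  retained <- intersect(bigEnough, datasets[anyGood])
  if (is.null(subtypeOf)) {
    subtypeOf <- setNames(unique(results$motif), unique(results$motif))
  }
  subtypes <- unique(subtypeOf[aurocRows$motif])
  bestBySub <- vapply(subtypes, function(st) {
    rows <- aurocRows[subtypeOf[aurocRows$motif] == st, ]
    if (nrow(rows) == 0L) -Inf else max(rows$value)
  }, numeric(1))
  list(retainedDatasets = retained,
       excludedDatasets = setdiff(datasets, retained),
       inapplicableSubtypes = subtypes[bestBySub < aurocMin],
       results = results[results$dataset %in% retained, , drop = FALSE])
}
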