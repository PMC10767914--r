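## The in-vitro benchmark on pooled HT-SELEX reads.

#' Subsample unique reads to a cap
#'
#' Uniform seeded sampling without replacement when the pool exceeds `cap`
#' (default 500000), identity otherwise. Order of the survivors follows the
#' input.
#'
#' @param seqset a ranked [SequenceSet-class] of unique reads.
#' @param cap maximum number of reads retained.
#' @param seed integer seed.
#' @return A [SequenceSet-class].
#' @export
subsampleUnique <- function(seqset, cap = 500000L, seed = 1L) {
  n <- length(seqset)
  if (n <= cap) return(seqset)
  keep <- withSeed(seed, sort(sample.int(n, cap)))
  new("SequenceSet", id = seqset@id, role = seqset@role,
      sequences = sequences(seqset)[keep])
}

#' HT-SELEX read-enrichment benchmark
#'
#' The top `fraction` of reads by experiment-level enrichment score are the
#' positives; the classifier score is the best-hit score of the tested PWM.
#' Reports auROC and auPRC per motif and fraction. Ranking the positives by
#' the experiment-level 5-mer enrichment (rather than by the tested PWM
#' itself) keeps the positive set fixed across motifs, so the comparison is
#' not self-fulfilling.
#'
#' @param pwms list of [PositionWeightMatrix-class].
#' @param seqset [SequenceSet-class] of unique reads with enrichment scores
#'   (see [kmerEnrichmentRank()]), already capped via [subsampleUnique()].
#' @param fraction one or more of 0.10, 0.25, 0.50.
#' @param dataset identifier stamped into the results.
#' @param bg background for scanning.
#' @return data.frame of benchmark rows with metrics `auROC_selex` and
#'   `auPRC_selex`; the `sort_key` column records the fraction.
#' @export
benchSelex <- function(pwms, seqset, fraction = c(0.10, 0.25, 0.50),
                       dataset = seqset@id, bg = uniformBackground()) {
  if (!all(fraction %in% c(0.10, 0.25, 0.50)))
    stop("fraction must be one of 0.10, 0.25, 0.50")
  enr <- enrichmentScores(seqset)
  if (is.null(enr)) stop("sequence set carries no enrichment scores")
  seqs <- as.character(sequences(seqset))
  n <- length(seqs)
  rkOrd <- order(-enr)
  do.call(rbind, lapply(pwms, function(pwm) {
    sc <- bestHitScores(pwm, seqs, bg)
    do.call(rbind, lapply(fraction, function(f) {
      nPos <- ceiling(f * n)
      labels <- logical(n)
      labels[rkOrd[seq_len(nPos)]] <- TRUE
      rbind(
        benchmarkResult(name(pwm), dataset, "auROC_selex",
                        auROC(sc, labels), sprintf("frac%.2f", f)),
        benchmarkResult(name(pwm), dataset, "auPRC_selex",
                        auPRC(sc, labels), sprintf("frac%.2f", f)))
    }))
  }))
}

#' Applicability filter for the HT-SELEX benchmark
#'
#' Benchmarks (dataset and fraction combinations) where no tested motif
#' reaches auROC >= `aurocMin` are dropped from the ranking; subtypes for
#' which no motif reaches the bar anywhere are flagged as not applicable to
#' HT-SELEX data (excluded from the in-vitro subcollection).
#'
#' @param results data.frame of `benchSelex` rows.
#' @param subtypeOf named character vector motif -> subtype (optional).
#' @param aurocMin the auROC bar (default 0.6).
#' @return list with `retainedGroups`, `inapplicableSubtypes` and filtered
#'   `results` (groups are dataset x sort_key combinations).
#' @export
selexFilters <- function(results, subtypeOf = NULL, aurocMin = 0.6) {
  aurocRows <- results[results$metric == "auROC_selex", ]
  grp <- paste(results$dataset, results$sort_key, sep = "|")
  grpA <- paste(aurocRows$dataset, aurocRows$sort_key, sep = "|")
  groups <- unique(grpA)
  goodGroup <- vapply(groups, function(g) {
    any(aurocRows$value[grpA == g] >= aurocMin)
  }, logical(1))
  retained <- groups[goodGroup]
  if (is.null(subtypeOf)) {
    subtypeOf <- setNames(unique(results$motif), unique(results$motif))
  }
  subtypes <- unique(subtypeOf[aurocRows$motif])
  bestBySub <- vapply(subtypes, function(st) {
    rows <- aurocRows[subtypeOf[aurocRows$motif] == st, ]
    if (nrow(rows) == 0L) -Inf else max(rows$value)
  }, numeric(1))
  list(retainedGroups = retained,
       inapplicableSubtypes = subtypes[bestBySub < aurocMin],
       results = results[grp %in% retained, , drop = FALSE])
}
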