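#' Position count matrix
#'
#' Per-position counts of A/C/G/T observed in an alignment of binding-site
#' words. Rows are motif positions, columns the four bases; every row sums to
#' the word count of the alignment.
#'
#' @slot name motif identifier.
#' @slot counts numeric matrix, L x 4, columns A, C, G, T; all entries
#'   non-negative, row sums equal within a relative tolerance of 1e-6.
#'
#' @seealso [PositionCountMatrix()], [pcmToPwm()]
#' @exportClass PositionCountMatrix
setClass("PositionCountMatrix",
         representation(name = "character", counts = "matrix"))

setValidity("PositionCountMatrix", function(object) {
  cts <- object@counts
  if (!is.numeric(cts) || ncol(cts) != 4L || nrow(cts) < 1L)
    return("counts must be a numeric matrix with four columns and >= 1 row")
  if (any(cts < 0)) return("counts must be non-negative")
  rs <- rowSums(cts)
  W <- rs[1L]
  if (W <= 0) return("word count must be positive")
  if (any(abs(rs - W) > 1e-6 * W))
    return("row sums must agree within 1e-6 relative tolerance")
  TRUE
})

#' Background base-composition model
#'
#' Mononucleotide frequencies, optionally with first-order (dinucleotide)
#' transition frequencies, describing the sequence background used for
#' log-odds conversion, P-value computation and negative-set sampling.
#'
#' @slot mono numeric(4), frequencies of A, C, G, T; strictly positive,
#'   summing to 1.
#' @slot transition 4 x 4 row-stochastic matrix of first-order transition
#'   frequencies, or a 0 x 0 matrix when only the mononucleotide part is set.
#'
#' @seealso [BackgroundModel()], [fitMarkov1()]
#' @exportClass BackgroundModel
setClass("BackgroundModel",
         representation(mono = "numeric", transition = "matrix"))

setValidity("BackgroundModel", function(object) {
  p <- object@mono
  if (length(p) != 4L || any(p <= 0) || any(p >= 1))
    return("mono must be four frequencies in (0,1)")
  if (abs(sum(p) - 1) > 1e-9) return("mono frequencies must sum to 1")
  tr <- object@transition
  if (length(tr)) {
    if (!all(dim(tr) == c(4L, 4L))) return("transition must be 4 x 4")
    if (any(tr <= 0) || any(tr >= 1))
      return("transition frequencies must be in (0,1)")
    if (any(abs(rowSums(tr) - 1) > 1e-9))
      return("transition rows must sum to 1")
  }
  TRUE
})

#' Position weight matrix
#'
#' Per-position log-odds weights over A/C/G/T. The score of an L-bp window is
#' the sum of the weights of its bases. Carries the motif subtype label and
#' ordinal, provenance flags (which experiment types support the motif) and
#' an optional A/B/C/D quality rating.
#'
#' @slot name motif identifier.
#' @slot weights numeric matrix, L x 4, finite log-odds weights.
#' @slot tf transcription factor the motif belongs to ("" if unset).
#' @slot subtype subtype label ("" if unset).
#' @slot subtypeOrdinal integer ordinal of the subtype within its TF
#'   (NA until assigned by benchmarking).
#' @slot provenance logical flags: fromChipseq, fromHtselex,
#'   fromMethylHtselex, speciesExclusive.
#' @slot quality "A", "B", "C", "D" or NA.
#'
#' @seealso [PositionWeightMatrix()], [pcmToPwm()], [bestHit()]
#' @exportClass PositionWeightMatrix
setClass("PositionWeightMatrix",
         representation(name = "character", weights = "matrix",
                        tf = "character", subtype = "character",
                        subtypeOrdinal = "integer", provenance = "logical",
                        quality = "character"))

setValidity("PositionWeightMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w) || ncol(w) != 4L || nrow(w) < 1L)
    return("weights must be a numeric matrix with four columns and >= 1 row")
  if (!all(is.finite(w))) return("weights must be finite")
  if (!is.na(object@quality) && !object@quality %in% c("A", "B", "C", "D"))
    return("quality must be A, B, C, D or NA")
  TRUE
})

#' Exact discretized PWM score distribution
#'
#' Distribution of the single-window, single-strand score of a random L-mer
#' drawn i.i.d. from a mononucleotide background, with weights rounded to the
#' nearest multiple of the discretization unit `step`. Supports P-value and
#' threshold queries.
#'
#' @slot step positive discretization unit (score per bin).
#' @slot bins integer-valued bin indices (score = bins * step), ascending.
#' @slot mass probabilities parallel to `bins`, summing to 1.
#'
#' @seealso [scoreDistribution()], [pvalueOfScore()], [thresholdForPvalue()]
#' @exportClass ScoreDistribution
setClass("ScoreDistribution",
         representation(step = "numeric", bins = "numeric", mass = "numeric"))

setValidity("ScoreDistribution", function(object) {
  if (length(object@step) != 1L || object@step <= 0)
    return("step must be a single positive number")
  if (length(object@bins) != length(object@mass))
    return("bins and mass must be parallel")
  if (is.unsorted(object@bins, strictly = TRUE))
    return("bins must be strictly ascending")
  if (any(object@mass < 0)) return("mass must be non-negative")
  if (abs(sum(object@mass) - 1) > 1e-9) return("total mass must be 1")
  TRUE
})

#' Best-hit record
#'
#' The best-scoring window of a PWM on a sequence: 0-based window start,
#' strand, score, and (when computed against a [ScoreDistribution]) its
#' P-value.
#'
#' @slot offset 0-based window start within the scanned sequence.
#' @slot strand "+" or "-".
#' @slot score window log-odds score.
#' @slot pvalue P(score >= observed) under the background, or NA.
#'
#' @seealso [bestHit()]
#' @exportClass MotifHit
setClass("MotifHit",
         representation(offset = "integer", strand = "character",
                        score = "numeric", pvalue = "numeric"))

setValidity("MotifHit", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  if (object@offset < 0L) return("offset must be >= 0")
  if (!is.na(object@pvalue) &&
      (object@pvalue <= 0 || object@pvalue > 1))
    return("pvalue must be in (0, 1]")
  TRUE
})

#' Sequence set with roles and enrichment scores
#'
#' A named collection of DNA sequences playing a role in a benchmark
#' (positive, negative or candidate), optionally carrying per-sequence
#' enrichment scores (as used by the HT-SELEX read ranking).
#'
#' @slot id dataset identifier.
#' @slot role one of "positive", "negative", "candidate".
#' @slot sequences a [Biostrings::DNAStringSet]; the `enrichment` and
#'   `multiplicity` columns of its `mcols`, when present, hold per-read
#'   scores and duplicate counts.
#'
#' @seealso [summitWindows()], [flankNegatives()], [kmerEnrichmentRank()]
#' @exportClass SequenceSet
setClass("SequenceSet",
         representation(id = "character", role = "character",
                        sequences = "DNAStringSet"))

setValidity("SequenceSet", function(object) {
  if (!object@role %in% c("positive", "negative", "candidate"))
    return("role must be positive, negative or candidate")
  TRUE
})

#' HT-SELEX read set
#'
#' Reads of one HT-SELEX experiment keyed by selection cycle, plus the
#' constant adapter bases flanking the random insert.
#'
#' @slot cycles named list; names are cycle numbers (>= 0, strictly
#'   increasing), elements are character vectors of uppercase ACGTN reads.
#' @slot adapterFlanks character(2): the constant bases adjacent to the
#'   5' and 3' ends of the random insert.
#'
#' @seealso [poolCycles()], [extendWithAdapters()]
#' @exportClass SelexReadSet
setClass("SelexReadSet",
         representation(cycles = "list", adapterFlanks = "character"))

setValidity("SelexReadSet", function(object) {
  cyc <- suppressWarnings(as.integer(names(object@cycles)))
  if (length(object@cycles) == 0L) return("at least one cycle required")
  if (anyNA(cyc) || any(cyc < 0L)) return("cycle names must be integers >= 0")
  if (is.unsorted(cyc, strictly = TRUE))
    return("cycle numbers must be strictly increasing")
  if (!all(grepl("^[ACGTN]*$", unlist(object@cycles, use.names = FALSE))))
    return("reads must be uppercase ACGTN")
  if (length(object@adapterFlanks) != 2L)
    return("adapterFlanks must have length 2")
  TRUE
})
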