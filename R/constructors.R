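#' Construct a position count matrix
#'
#' @param name motif identifier.
#' @param counts L x 4 numeric matrix of per-position base counts in
#'   A, C, G, T column order.
#' @return A [PositionCountMatrix-class] object.
#' @examples
#' pcm <- PositionCountMatrix("toy", rbind(c(8, 1, 1, 0), c(0, 9, 0, 1)))
#' wordCount(pcm)
#' @export
PositionCountMatrix <- function(name, counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(NULL, DNA_BASES)
  new("PositionCountMatrix", name = as.character(name), counts = counts)
}

#' Construct a background model
#'
#' @param mono numeric(4) frequencies of A, C, G, T (normalized internally).
#' @param transition optional 4 x 4 row-stochastic transition matrix.
#' @return A [BackgroundModel-class] object.
#' @examples
#' uniformBackground()
#' BackgroundModel(c(0.3, 0.2, 0.2, 0.3))
#' @export
BackgroundModel <- function(mono = rep(0.25, 4), transition = NULL) {
  mono <- mono / sum(mono)
  names(mono) <- DNA_BASES
  tr <- if (is.null(transition)) {
    matrix(numeric(0), 0L, 0L)
  } else {
    transition <- matrix(as.numeric(transition), nrow = nrow(transition),
                         dimnames = list(DNA_BASES, DNA_BASES))
    transition / rowSums(transition)
  }
  new("BackgroundModel", mono = mono, transition = tr)
}

#' @rdname BackgroundModel
#' @export
uniformBackground <- function() BackgroundModel()

#' Construct a position weight matrix
#'
#' @param name motif identifier.
#' @param weights L x 4 numeric matrix of log-odds weights in A, C, G, T
#'   column order.
#' @param tf,subtype transcription factor and motif-subtype labels.
#' @param subtypeOrdinal integer ordinal of the subtype within its TF.
#' @param fromChipseq,fromHtselex,fromMethylHtselex,speciesExclusive
#'   provenance flags.
#' @param quality "A", "B", "C", "D" or NA.
#' @return A [PositionWeightMatrix-class] object.
#' @examples
#' PositionWeightMatrix("toy", rbind(c(1, -1, -1, -1), c(-1, 1, -1, -1)))
#' @export
PositionWeightMatrix <- function(name, weights, tf = "", subtype = "",
                                 subtypeOrdinal = NA_integer_,
                                 fromChipseq = FALSE, fromHtselex = FALSE,
                                 fromMethylHtselex = FALSE,
                                 speciesExclusive = FALSE,
                                 quality = NA_character_) {
  weights <- as.matrix(weights)
  dimnames(weights) <- list(NULL, DNA_BASES)
  new("PositionWeightMatrix", name = as.character(name), weights = weights,
      tf = as.character(tf), subtype = as.character(subtype),
      subtypeOrdinal = as.integer(subtypeOrdinal),
      provenance = c(fromChipseq = fromChipseq, fromHtselex = fromHtselex,
                     fromMethylHtselex = fromMethylHtselex,
                     speciesExclusive = speciesExclusive),
      quality = as.character(quality))
}

#' Construct a sequence set
#'
#' @param id dataset identifier.
#' @param sequences character vector or [Biostrings::DNAStringSet].
#' @param role "positive", "negative" or "candidate".
#' @param enrichment optional numeric per-sequence enrichment scores.
#' @param multiplicity optional integer per-sequence duplicate counts.
#' @return A [SequenceSet-class] object.
#' @export
SequenceSet <- function(id, sequences, role = "candidate",
                        enrichment = NULL, multiplicity = NULL) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (!is.null(enrichment))
    S4Vectors::mcols(sequences)$enrichment <- enrichment
  if (!is.null(multiplicity))
    S4Vectors::mcols(sequences)$multiplicity <- multiplicity
  new("SequenceSet", id = as.character(id), role = role,
      sequences = sequences)
}

#' Construct an HT-SELEX read set
#'
#' @param cycles named list mapping cycle number to a character vector of
#'   reads (uppercase ACGTN).
#' @param adapterFlanks character(2): constant adapter bases flanking the
#'   random insert on the 5' and 3' sides.
#' @return A [SelexReadSet-class] object.
#' @examples
#' SelexReadSet(list(`1` = c("ACGT", "AAAA"), `3` = "ACGG"), c("G", "C"))
#' @export
SelexReadSet <- function(cycles, adapterFlanks = c("A", "A")) {
  ord <- order(as.integer(names(cycles)))
  new("SelexReadSet", cycles = cycles[ord],
      adapterFlanks = as.character(adapterFlanks))
}

## ---- accessors ----

#' @describeIn PositionCountMatrix-class motif name
#' @param object,x a pwmbench object
#' @export
setMethod("name", "PositionCountMatrix", function(object) object@name)

#' @describeIn PositionWeightMatrix-class motif name
#' @export
setMethod("name", "PositionWeightMatrix", function(object) object@name)

#' @describeIn PositionCountMatrix-class L x 4 count matrix
#' @export
setMethod("counts", "PositionCountMatrix",
          function(object, ...) object@counts)

#' @describeIn PositionWeightMatrix-class L x 4 log-odds weight matrix
#' @export
setMethod("weights", "PositionWeightMatrix",
          function(object, ...) object@weights)

#' Motif length (number of positions)
#' @param x a [PositionCountMatrix-class] or [PositionWeightMatrix-class]
#' @return integer motif length
#' @export
motifLength <- function(x) {
  nrow(if (methods::is(x, "PositionCountMatrix")) x@counts else x@weights)
}

#' Word count of a position count matrix
#' @param x a [PositionCountMatrix-class]
#' @return the (constant) row sum
#' @export
wordCount <- function(x) {
  stopifnot(methods::is(x, "PositionCountMatrix"))
  mean(rowSums(x@counts))
}

#' @describeIn MotifHit-class score accessor
#' @export
setMethod("score", "MotifHit", function(x, ...) x@score)

#' Hit fields
#' @param x a [MotifHit-class]
#' @return offset (0-based), strand or P-value of the hit
#' @export
hitOffset <- function(x) x@offset

#' @rdname hitOffset
#' @export
hitStrand <- function(x) x@strand

#' @rdname hitOffset
#' @export
hitPvalue <- function(x) x@pvalue

#' @describeIn SequenceSet-class the underlying DNAStringSet
#' @export
setMethod("sequences", "SequenceSet", function(object) object@sequences)

#' @describeIn SequenceSet-class number of sequences
#' @export
setMethod("length", "SequenceSet", function(x) length(x@sequences))

#' Per-sequence enrichment scores of a [SequenceSet-class]
#' @param x a SequenceSet
#' @return numeric vector or NULL
#' @export
enrichmentScores <- function(x) S4Vectors::mcols(x@sequences)$enrichment

## ---- show methods ----

setMethod("show", "PositionCountMatrix", function(object) {
  cat(sprintf("PositionCountMatrix '%s': %d positions, word count %.6g\n",
              object@name, nrow(object@counts), wordCount(object)))
})

setMethod("show", "PositionWeightMatrix", function(object) {
  cat(sprintf("PositionWeightMatrix '%s': %d positions%s%s\n",
              object@name, nrow(object@weights),
              if (nzchar(object@tf)) paste0(", TF ", object@tf) else "",
              if (!is.na(object@quality))
                paste0(", quality ", object@quality) else ""))
})

setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf(
    "ScoreDistribution: step %.3g, %d bins, score range [%.4g, %.4g]\n",
    object@step, length(object@bins),
    min(object@bins) * object@step, max(object@bins) * object@step))
})

setMethod("show", "MotifHit", function(object) {
  cat(sprintf("MotifHit: offset %d, strand %s, score %.4g%s\n",
              object@offset, object@strand, object@score,
              if (is.na(object@pvalue)) ""
              else sprintf(", P = %.3g", object@pvalue)))
})

setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet '%s' (%s): %d sequences\n",
              object@id, object@role, length(object@sequences)))
})

setMethod("show", "SelexReadSet", function(object) {
  cat(sprintf("SelexReadSet: cycles %s; %d reads total\n",
              paste(names(object@cycles), collapse = ","),
              sum(lengths(object@cycles))))
})
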