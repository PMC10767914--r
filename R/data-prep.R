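## Preparation of positive and negative sequence sets from ChIP-Seq peaks
## and HT-SELEX read pools.

#' Select the top peaks of a peak set
#'
#' Peaks are ordered descending by the chosen key (peak height or reported
#' statistical significance), ties resolved by ascending (chrom, start), and
#' the first `n` returned.
#'
#' @param peaks GRanges with `signal`, `significance` and `summit` metadata
#'   columns (see [readNarrowPeak()]).
#' @param n number of peaks to keep (default 1000).
#' @param key "signal" or "significance".
#' @return GRanges of at most `n` peaks in key order.
#' @export
selectTopPeaks <- function(peaks, n = 1000L, key = c("signal", "significance")) {
  key <- match.arg(key)
  stopifnot(n >= 1L)
  val <- S4Vectors::mcols(peaks)[[key]]
  ord <- order(-val, as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks))
  peaks[head(ord, n)]
}

#' Extract fixed-width windows around peak summits
#'
#' Windows of `width` bp (default 301) centered at each peak summit,
#' 0-based half-open. Windows truncated by a chromosome end are dropped;
#' peaks on chromosomes absent from the genome are skipped with a warning.
#'
#' @param peaks GRanges with a `summit` metadata column (0-based offset from
#'   the peak start).
#' @param genome named DNAStringSet (or named character vector) of
#'   chromosome sequences.
#' @param width odd window width in bp.
#' @return A [SequenceSet-class] with role "positive"; the window
#'   coordinates are kept in the `mcols` of its sequences (chrom, start,
#'   end; 0-based half-open).
#' @export
summitWindows <- function(peaks, genome, width = 301L) {
  stopifnot(width %% 2L == 1L)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  half <- (width - 1L) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  summitAbs <- GenomicRanges::start(peaks) - 1L +
    S4Vectors::mcols(peaks)$summit          # 0-based absolute summit
  starts <- summitAbs - half                 # 0-based window start
  known <- chrom %in% names(genome)
  if (!all(known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the genome ",
            "were skipped")
  }
  chrLen <- setNames(Biostrings::width(genome), names(genome))
  inBounds <- known & starts >= 0L &
    (starts + width) <= chrLen[chrom]
  inBounds[is.na(inBounds)] <- FALSE
  if (!any(inBounds)) stop("no summit window fits inside the genome")
  idx <- which(inBounds)
  seqs <- Biostrings::DNAStringSet(vapply(idx, function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    start = starts[i] + 1L,
                                    width = width))
  }, character(1)))
  names(seqs) <- sprintf("%s:%d-%d", chrom[idx], starts[idx],
                         starts[idx] + width)
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    chrom = chrom[idx], start = starts[idx], end = starts[idx] + width)
  new("SequenceSet", id = "summit_windows", role = "positive",
      sequences = seqs)
}

#' Flanking negative windows for summit windows
#'
#' For every positive window two same-width windows are taken, starting
#' `gap` bp beyond its upstream and downstream edges. Flanks that overlap
#' any positive window or run past a chromosome end are dropped.
#'
#' @param windows a [SequenceSet-class] from [summitWindows()].
#' @param genome named DNAStringSet of chromosome sequences.
#' @param gap distance in bp between a positive window edge and the start of
#'   its flank (default 300).
#' @return A [SequenceSet-class] with role "negative".
#' @export
flankNegatives <- function(windows, genome, gap = 300L) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  mc <- S4Vectors::mcols(sequences(windows))
  if (is.null(mc$chrom)) stop("windows must carry coordinates from summitWindows()")
  width <- unique(mc$end - mc$start)
  stopifnot(length(width) == 1L)
  chrLen <- setNames(Biostrings::width(genome), names(genome))
  pos <- GenomicRanges::GRanges(mc$chrom,
                                IRanges::IRanges(mc$start + 1L, mc$end))
  cand <- data.frame(
    chrom = rep(mc$chrom, 2L),
    start = c(mc$start - gap - width, mc$end + gap))  # 0-based
  ok <- cand$start >= 0L & (cand$start + width) <= chrLen[cand$chrom]
  ok[is.na(ok)] <- FALSE
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) > 0L) {
    gr <- GenomicRanges::GRanges(cand$chrom,
                                 IRanges::IRanges(cand$start + 1L,
                                                  cand$start + width))
    hits <- GenomicRanges::countOverlaps(gr, pos)
    cand <- cand[hits == 0L, , drop = FALSE]
  }
  if (nrow(cand) == 0L) stop("no flanking negative survives the overlap rule")
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(cand)), function(i) {
    as.character(Biostrings::subseq(genome[[cand$chrom[i]]],
                                    start = cand$start[i] + 1L,
                                    width = width))
  }, character(1)))
  names(seqs) <- sprintf("%s:%d-%d", cand$chrom, cand$start,
                         cand$start + width)
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    chrom = cand$chrom, start = cand$start, end = cand$start + width)
  new("SequenceSet", id = paste0(windows@id, "_flanks"), role = "negative",
      sequences = seqs)
}

#' Pool HT-SELEX cycles
#'
#' `full` concatenates the reads of all cycles; `late` keeps cycles >= 3
#' only (later cycles resemble the binding consensus better, but earlier
#' cycles may retain diversity the late pools have lost).
#'
#' @param rs a [SelexReadSet-class].
#' @param mode "full" or "late".
#' @return character vector of pooled reads.
#' @export
poolCycles <- function(rs, mode = c("full", "late")) {
  mode <- match.arg(mode)
  cyc <- as.integer(names(rs@cycles))
  keep <- if (mode == "full") rep(TRUE, length(cyc)) else cyc >= 3L
  if (!any(keep)) stop("no cycle >= 3 available for late-cycle pooling")
  unlist(rs@cycles[keep], use.names = FALSE)
}

#' Remove singleton reads from a pool
#'
#' Reads observed only once in the pooled dataset are removed; the survivors
#' are returned as unique reads with their multiplicities.
#'
#' @param reads character vector of pooled reads.
#' @return data.frame with columns `read` and `multiplicity` (>= 2), in
#'   order of first appearance.
#' @export
dropSingletons <- function(reads) {
  tb <- table(factor(reads, levels = unique(reads)))
  keep <- tb >= 2L
  if (!any(keep)) stop("all reads are singletons")
  data.frame(read = names(tb)[keep],
             multiplicity = as.integer(tb[keep]),
             row.names = NULL)
}

#' Rank reads by k-mer enrichment against a dinucleotide-shuffled background
#'
#' Observed k-mer counts are accumulated over all unique reads; background
#' counts over one dinucleotide-preserving shuffle of every N-free read.
#' The enrichment of k-mer m is ln((obs(m)+1)/(bg(m)+1)); a read's score is
#' the mean enrichment over its k-mers (k-mers containing N are skipped).
#' Reads are returned sorted descending by score, ties broken
#' lexicographically.
#'
#' @param reads character vector of unique reads, or the data.frame from
#'   [dropSingletons()].
#' @param k k-mer length (default 5).
#' @param seed integer seed driving the background shuffles.
#' @return A [SequenceSet-class] (role "candidate") with `enrichment` (and
#'   `multiplicity`, when supplied) in the `mcols` of its sequences.
#' @export
kmerEnrichmentRank <- function(reads, k = 5L, seed = 1L) {
  mult <- NULL
  if (is.data.frame(reads)) {
    mult <- reads$multiplicity
    reads <- reads$read
  }
  if (any(nchar(reads) < k)) stop("every read must have length >= k")
  kmersOf <- function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }
  obsK <- unlist(lapply(reads, kmersOf), use.names = FALSE)
  obsK <- obsK[!grepl("N", obsK, fixed = TRUE)]
  obsTab <- table(obsK)
  noN <- reads[!grepl("N", reads, fixed = TRUE)]
  shuffled <- withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max, length(noN))
    vapply(seq_along(noN), function(i) dinucShuffle(noN[i], seeds[i]), "")
  })
  bgK <- unlist(lapply(shuffled, kmersOf), use.names = FALSE)
  bgTab <- table(bgK)
  allK <- union(names(obsTab), names(bgTab))
  obs <- setNames(rep(0L, length(allK)), allK)
  obs[names(obsTab)] <- as.integer(obsTab)
  bg <- setNames(rep(0L, length(allK)), allK)
  bg[names(bgTab)] <- as.integer(bgTab)
  enr <- log((obs + 1) / (bg + 1))
  scores <- vapply(reads, function(s) {
    km <- kmersOf(s)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (length(km) == 0L) 0 else mean(enr[km])
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-scores, reads)
  SequenceSet("kmer_ranked", reads[ord], role = "candidate",
              enrichment = scores[ord],
              multiplicity = if (is.null(mult)) NULL else mult[ord])
}

#' Extend reads with adapter-derived flanks
#'
#' Each read becomes `NN X1 read X2 NN`, where X1 and X2 are the constant
#' adapter bases adjacent to the random insert. The Ns let motif occurrences
#' partially overhang the insert without biasing scores (Ns score neutrally
#' in [bestHit()]).
#'
#' @param reads character vector of reads.
#' @param flanks character(2) of single bases in ACGT.
#' @return character vector of extended reads.
#' @examples
#' extendWithAdapters("ACGT", c("G", "C"))
#' @export
extendWithAdapters <- function(reads, flanks) {
  stopifnot(length(flanks) == 2L)
  if (!all(flanks %in% DNA_BASES)) stop("adapter flanks must be A, C, G or T")
  paste0("NN", flanks[1L], reads, flanks[2L], "NN")
}

#' Take the top sequences of a ranked set
#'
#' Returns the first `min(n, size)` sequences of an already ranked
#' [SequenceSet-class] (all available reads when there are not enough).
#'
#' @param seqset a ranked [SequenceSet-class].
#' @param n target size; the canonical set sizes are 1000, 2500, 5000 and
#'   10000.
#' @return A [SequenceSet-class] prefix of the input.
#' @export
takeTop <- function(seqset, n) {
  stopifnot(n >= 1L)
  m <- min(n, length(seqset))
  seqs <- sequences(seqset)[seq_len(m)]
  new("SequenceSet", id = sprintf("%s_top%d", seqset@id, n),
      role = seqset@role, sequences = seqs)
}
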