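## Readers and writers for the plain-text motif dialect (">name" header, L
## rows of 4 tab-separated values in A C G T order; .pcm holds counts, .pwm
## holds weights), narrowPeak peak calls and FASTA sequence sets.

parseMotifFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) stop("empty motif file: ", path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L || headers[1L] != 1L)
    stop("motif file must start with a '>name' header: ", path)
  bounds <- c(headers, length(lines) + 1L)
  lapply(seq_along(headers), function(i) {
    nm <- sub("^>\\s*", "", lines[headers[i]])
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(seq_along(body), function(j) {
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(body[j]), "[\t ]+")[[1L]]))
      if (length(vals) != 4L || anyNA(vals))
        stop(sprintf("line %d of %s: expected 4 numeric values",
                     bounds[i] + j, path))
      vals
    })
    list(name = nm, matrix = do.call(rbind, rows))
  })
}

#' Read and write motif matrix files
#'
#' The dialect is a `>name` header followed by one line per motif position
#' with four tab-separated values in A C G T order; multiple motifs may be
#' concatenated in one file. `.pcm` files hold counts, `.pwm` files hold
#' log-odds weights.
#'
#' @param path file to read or write.
#' @return `readPcm` returns a list of [PositionCountMatrix-class]; `readPwm`
#'   a list of [PositionWeightMatrix-class]. Writers return `path`
#'   invisibly.
#' @export
readPcm <- function(path) {
  lapply(parseMotifFile(path), function(m) {
    PositionCountMatrix(m$name, m$matrix)
  })
}

#' @rdname readPcm
#' @export
readPwm <- function(path) {
  lapply(parseMotifFile(path), function(m) {
    PositionWeightMatrix(m$name, m$matrix)
  })
}

writeMotifFile <- function(mats, getter, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mats) {
    writeLines(paste0(">", name(m)), con)
    apply(getter(m), 1, function(row)
      writeLines(paste(format(row, scientific = FALSE, trim = TRUE,
                              nsmall = 0), collapse = "\t"), con))
  }
  invisible(path)
}

#' @rdname readPcm
#' @param pcms,pwms a list of matrices (or a single object) to write.
#' @export
writePcm <- function(pcms, path) {
  if (methods::is(pcms, "PositionCountMatrix")) pcms <- list(pcms)
  writeMotifFile(pcms, counts, path)
}

#' @rdname readPcm
#' @export
writePwm <- function(pwms, path) {
  if (methods::is(pwms, "PositionWeightMatrix")) pwms <- list(pwms)
  writeMotifFile(pwms, weights, path)
}

narrowPeakCols <- c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer")

#' Read and write ENCODE narrowPeak peak calls
#'
#' Peaks are returned as a [GenomicRanges::GRanges] with metadata columns
#' `signal` (column 7, signalValue), `significance` (column 9, qValue) and
#' `summit` (0-based offset of the summit from the peak start; peaks lacking
#' a summit, encoded as -1, get the interval midpoint). BED6 files are
#' accepted too, with midpoint summits and score as both signal and
#' significance.
#'
#' @param path narrowPeak (10-column) or BED6 file.
#' @return A GRanges of peaks.
#' @export
readNarrowPeak <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(first) >= 10L) {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = narrowPeakCols)
    summit <- S4Vectors::mcols(gr)$peak
    mid <- as.integer(floor((GenomicRanges::width(gr) - 1L) / 2L))
    summit[is.na(summit) | summit < 0L] <- mid[is.na(summit) | summit < 0L]
    sig <- S4Vectors::mcols(gr)$signalValue
    signif <- S4Vectors::mcols(gr)$qValue
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    summit <- as.integer(floor((GenomicRanges::width(gr) - 1L) / 2L))
    sig <- signif <- as.numeric(S4Vectors::mcols(gr)$score)
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    signal = as.numeric(sig), significance = as.numeric(signif),
    summit = as.integer(summit))
  gr
}

#' @rdname readNarrowPeak
#' @param peaks a GRanges as returned by [readNarrowPeak()].
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = if (is.null(names(peaks)))
      sprintf("peak_%d", seq_along(peaks)) else names(peaks),
    score = 0L, strand = ".",
    signalValue = S4Vectors::mcols(peaks)$signal,
    pValue = -1, qValue = S4Vectors::mcols(peaks)$significance,
    peak = S4Vectors::mcols(peaks)$summit)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()]; FASTQ qualities are
#' discarded.
#'
#' @param path input file.
#' @return A DNAStringSet.
#' @export
readSequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' @rdname readSequences
#' @param seqs a DNAStringSet or named character vector.
#' @export
writeSequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
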