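## First-order background models and the Euler-path dinucleotide shuffle.

#' Fit a first-order background model to a sequence set
#'
#' Mononucleotide frequencies and dinucleotide transition frequencies are
#' pooled over all sequences with add-one smoothing; Ns are skipped.
#'
#' @param seqs character vector, DNAStringSet or [SequenceSet-class].
#' @return A [BackgroundModel-class] with the transition table set.
#' @examples
#' bg <- fitMarkov1(c("ACACACAC", "ACACAAAC"))
#' bg@transition["A", "C"]
#' @export
fitMarkov1 <- function(seqs) {
  if (methods::is(seqs, "SequenceSet")) seqs <- sequences(seqs)
  seqs <- asSequenceCharacters(seqs)
  if (length(seqs) == 0L) stop("empty sequence set")
  monoCounts <- rep(1, 4)
  diCounts <- matrix(1, 4, 4)
  for (s in seqs) {
    codes <- encodeDNA(s)
    ok <- codes <= 4L
    tb <- tabulate(codes[ok], 4L)
    monoCounts <- monoCounts + tb
    if (length(codes) >= 2L) {
      from <- codes[-length(codes)]
      to <- codes[-1L]
      keep <- from <= 4L & to <= 4L
      if (any(keep)) {
        tt <- table(factor(from[keep], levels = 1:4),
                    factor(to[keep], levels = 1:4))
        diCounts <- diCounts + as.matrix(tt)
      }
    }
  }
  BackgroundModel(monoCounts / sum(monoCounts),
                  diCounts / rowSums(diCounts))
}

#' Sample sequences from a first-order background model
#'
#' The first base of each sequence is drawn from the mononucleotide
#' frequencies, subsequent bases from the transition table (or i.i.d. from
#' the mononucleotide frequencies when no transition table is set). Fully
#' determined by `seed`.
#'
#' @param bg a [BackgroundModel-class].
#' @param length sequence length.
#' @param count number of sequences.
#' @param seed integer seed.
#' @return character vector of `count` sequences.
#' @export
sampleMarkov1 <- function(bg, length, count, seed) {
  stopifnot(length >= 1L, count >= 1L)
  withSeed(seed, {
    useTrans <- base::length(bg@transition) > 0L
    out <- matrix(0L, nrow = count, ncol = length)
    out[, 1L] <- sample.int(4L, count, replace = TRUE, prob = bg@mono)
    if (length > 1L) {
      cum <- if (useTrans) t(apply(bg@transition, 1, cumsum))
             else matrix(cumsum(bg@mono), 4, 4, byrow = TRUE)
      for (j in 2:length) {
        u <- runif(count)
        out[, j] <- rowSums(cum[out[, j - 1L], , drop = FALSE] < u) + 1L
      }
    }
    apply(out, 1, function(row) paste(DNA_BASES[row], collapse = ""))
  })
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the output has exactly the same
#' dinucleotide multiset as the input and preserves the first and last base.
#' The random last-edge arborescence is drawn until it connects every vertex
#' to the terminal base; remaining out-edges are permuted uniformly.
#'
#' @param seq a DNA string without N of length >= 2.
#' @param seed integer seed.
#' @return the shuffled string.
#' @examples
#' dinucShuffle("ACGTACGTAC", seed = 1)
#' @export
dinucShuffle <- function(seq, seed) {
  codes <- encodeDNA(seq)
  if (any(codes > 4L)) stop("dinucShuffle requires an N-free sequence")
  n <- length(codes)
  if (n < 2L) stop("sequence must have length >= 2")
  if (length(unique(codes)) == 1L) return(seq)  # homopolymer: unique path
  withSeed(seed, {
    ## adjacency: for each source base, the multiset of target bases
    from <- codes[-n]
    to <- codes[-1L]
    last <- codes[n]
    adj <- split(to, from)
    vertices <- as.integer(names(adj))
    repeat {
      ## candidate last edge for every vertex except the terminal one
      lastEdge <- rep(NA_integer_, 4L)
      for (v in vertices) {
        if (v != last) lastEdge[v] <- adj[[as.character(v)]][
          sample.int(length(adj[[as.character(v)]]), 1L)]
      }
      ## connectivity: following last edges from every vertex reaches `last`
      ok <- TRUE
      for (v in vertices) {
        if (v == last) next
        cur <- v
        for (step in 1:8) {
          cur <- lastEdge[cur]
          if (is.na(cur) || cur == last) break
        }
        if (is.na(cur) || cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    ## order out-edges: random permutation of the rest, chosen last edge last
    edgeLists <- lapply(vertices, function(v) {
      edges <- adj[[as.character(v)]]
      if (v == last) return(edges[sample.int(length(edges))])
      le <- lastEdge[v]
      drop1 <- which(edges == le)[1L]
      rest <- edges[-drop1]
      c(rest[sample.int(length(rest))], le)
    })
    names(edgeLists) <- vertices
    ptr <- setNames(rep(1L, length(vertices)), vertices)
    out <- integer(n)
    out[1L] <- codes[1L]
    cur <- codes[1L]
    for (i in 2:n) {
      key <- as.character(cur)
      nxt <- edgeLists[[key]][ptr[key]]
      ptr[key] <- ptr[key] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    decodeDNA(out)
  })
}
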