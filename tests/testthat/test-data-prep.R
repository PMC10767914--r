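makePeaks <- function(n, chrom = "chr1", spacing = 2500L, signal = NULL,
                      significance = NULL) {
  summit <- as.integer((seq_len(n) - 0.5) * spacing)
  starts0 <- summit - 150L
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(starts0 + 1L, starts0 + 301L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    signal = if (is.null(signal)) rev(seq_len(n)) else signal,
    significance = if (is.null(significance)) seq_len(n) else significance,
    summit = rep(150L, n))
  names(gr) <- sprintf("p%d", seq_len(n))
  gr
}

test_that("selectTopPeaks orders by key with coordinate tie-breaks", {
  pk <- makePeaks(5)
  top <- selectTopPeaks(pk, 3, "signal")
  expect_equal(names(top), c("p1", "p2", "p3"))
  top2 <- selectTopPeaks(pk, 3, "significance")
  expect_equal(names(top2), c("p5", "p4", "p3"))

  ## fewer peaks than requested: all returned
  expect_length(selectTopPeaks(pk, 1000), 5)

  ## equal keys: deterministic (chrom, start) order
  pkTie <- makePeaks(4, signal = rep(7, 4))
  expect_equal(names(selectTopPeaks(pkTie, 4, "signal")),
               c("p1", "p2", "p3", "p4"))
  expect_error(selectTopPeaks(pk, 3, "height"))
})

test_that("summitWindows extracts centered windows and drops boundary peaks", {
  set.seed(1)
  genome <- Biostrings::DNAStringSet(c(chr1 = randomSeq(10000, 1)))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 701))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(signal = 1, significance = 1,
                                               summit = 100L)
  win <- summitWindows(gr, genome, 301L)
  ## summit at 0-based 500 -> [350, 651)
  mc <- S4Vectors::mcols(sequences(win))
  expect_equal(mc$start, 350L)
  expect_equal(mc$end, 651L)
  expect_equal(as.character(sequences(win)[[1]]),
               substr(as.character(genome[[1]]), 351, 651))

  ## summit 100 bp from the chromosome start: window would be truncated
  grEdge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 301))
  S4Vectors::mcols(grEdge) <- S4Vectors::DataFrame(
    signal = 1, significance = 1, summit = 100L)
  expect_error(summitWindows(grEdge, genome, 301L), "no summit window")

  ## unknown chromosome: warned and skipped
  grX <- GenomicRanges::GRanges("chrX", IRanges::IRanges(401, 701))
  S4Vectors::mcols(grX) <- S4Vectors::mcols(gr)
  grMix <- suppressWarnings(c(gr, grX))
  expect_warning(win2 <- summitWindows(grMix, genome, 301L), "skipped")
  expect_equal(length(win2), 1L)
})

test_that("flankNegatives yields two clean flanks per mid-chromosome window", {
  genome <- Biostrings::DNAStringSet(c(chr1 = randomSeq(250000, 2)))
  pk <- makePeaks(100, spacing = 2500L)
  win <- summitWindows(pk, genome)
  neg <- flankNegatives(win, genome)
  expect_equal(length(neg), 200L)
  expect_true(all(Biostrings::width(sequences(neg)) == 301L))

  ## adjacent peaks whose flanks collide with the neighbour's window
  pkDense <- makePeaks(2, spacing = 700L)
  winDense <- summitWindows(pkDense, genome)
  negDense <- flankNegatives(winDense, genome)
  expect_lt(length(negDense), 4L)
})

test_that("poolCycles pools full and late cycles with the cycle >= 3 rule", {
  rs <- SelexReadSet(list(`1` = rep("AAAA", 10), `2` = rep("CCCC", 10),
                          `3` = rep("GGGG", 10), `4` = rep("TTTT", 10)))
  expect_length(poolCycles(rs, "full"), 40)
  late <- poolCycles(rs, "late")
  expect_length(late, 20)
  expect_true(all(late %in% c("GGGG", "TTTT")))
  rs12 <- SelexReadSet(list(`1` = "AAAA", `2` = "CCCC"))
  expect_error(poolCycles(rs12, "late"), "cycle")
})

test_that("dropSingletons keeps multiplicity >= 2 and errors when none", {
  out <- dropSingletons(c("AA", "AA", "AC"))
  expect_equal(out$read, "AA")
  expect_equal(out$multiplicity, 2L)
  expect_error(dropSingletons(c("AA", "AC", "AG")), "singleton")

  ## exact multiset counting on a random pool
  set.seed(7)
  pool <- sample(c("ACGT", "AAAA", "CCCC", "GGGG"), 60, replace = TRUE,
                 prob = c(0.5, 0.3, 0.15, 0.05))
  out2 <- dropSingletons(pool)
  tab <- table(pool)
  expect_equal(sort(out2$multiplicity),
               sort(as.integer(tab[tab >= 2])))
})

test_that("dinucShuffle preserves dinucleotide counts and terminal bases", {
  expect_equal(dinucShuffle("AAAA", 1), "AAAA")
  for (i in 1:200) {
    s <- randomSeq(20, seed = 5000 + i)
    sh <- dinucShuffle(s, seed = i)
    expect_equal(dinucCounts(sh), dinucCounts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 20, 20), substr(s, 20, 20))
  }
  ## seeded determinism
  expect_equal(dinucShuffle("ACGTACGTACGTAAGG", 42),
               dinucShuffle("ACGTACGTACGTAAGG", 42))
})

test_that("kmerEnrichmentRank ranks planted-motif reads to the top", {
  ## homopolymers are invariant under the shuffle: all scores 0
  homo <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT")
  rk <- kmerEnrichmentRank(homo, seed = 1)
  expect_equal(unname(enrichmentScores(rk)), rep(0, 4))
  expect_equal(as.character(sequences(rk)), sort(homo))

  ## plant a 5-mer in half the reads
  set.seed(11)
  n <- 60
  reads <- vapply(1:n, function(i) randomSeq(20, 6000 + i), "")
  planted <- seq_len(n / 2)
  for (i in planted) {
    substr(reads[i], 7, 14) <- "ACGTGACC"
  }
  rk2 <- kmerEnrichmentRank(reads, seed = 2)
  topHalf <- as.character(sequences(rk2))[seq_len(n / 2)]
  expect_gte(mean(topHalf %in% reads[planted]), 0.9)

  ## determinism under the same seed
  rk3 <- kmerEnrichmentRank(reads, seed = 2)
  expect_equal(as.character(sequences(rk3)), as.character(sequences(rk2)))
  expect_error(kmerEnrichmentRank(c("ACG"), k = 5), "length >= k")
})

test_that("extendWithAdapters builds NN-flanked reads", {
  expect_equal(extendWithAdapters("ACGT", c("G", "C")), "NNGACGTCNN")
  reads <- c("AAAA", "CCCCC")
  ext <- extendWithAdapters(reads, c("A", "T"))
  expect_equal(nchar(ext) - nchar(reads), c(6L, 6L))
  expect_error(extendWithAdapters("ACGT", c("N", "C")), "flanks")
})

test_that("takeTop returns a prefix capped at the available reads", {
  ss <- SequenceSet("x", vapply(1:700, function(i) randomSeq(8, i), ""))
  expect_equal(length(takeTop(ss, 1000)), 700L)
  top <- takeTop(ss, 100)
  expect_equal(as.character(sequences(top)),
               as.character(sequences(ss))[1:100])
})

test_that("fitMarkov1/sampleMarkov1 reproduce source dinucleotide structure", {
  ## add-one smoothing: 9 of 9 A->C transitions give (9+1)/(9+4)
  bg <- fitMarkov1("ACACACACACACACACACAC")
  expect_gt(bg@transition["A", "C"], 0.75)
  expect_gt(bg@transition["C", "A"], 0.7)
  expect_lt(bg@transition["A", "G"], 0.1)

  ## sampled composition close to the fitted chain
  src <- vapply(1:50, function(i) randomSeq(200, 7000 + i), "")
  bg2 <- fitMarkov1(src)
  smp <- sampleMarkov1(bg2, 500L, 200L, seed = 3)
  expect_equal(sampleMarkov1(bg2, 500L, 200L, seed = 3), smp)
  obs <- colSums(do.call(rbind, lapply(smp, function(s)
    as.vector(dinucCounts(s)))))
  tot <- sum(obs)
  exp <- as.vector(t(bg2@transition * bg2@mono))  # stationary-ish expectation
  exp <- exp / sum(exp)
  ## within 3 sigma of the multinomial error for each of the 16 cells
  for (j in 1:16) {
    sigma <- sqrt(tot * exp[j] * (1 - exp[j]))
    expect_lt(abs(obs[j] - tot * exp[j]), 3.5 * sigma + 3)
  }
})

test_that("narrowPeak round trip preserves coordinates and summits", {
  pk <- makePeaks(7)
  f <- tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(pk, f)
  back <- readNarrowPeak(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pk))
  expect_equal(S4Vectors::mcols(back)$summit, S4Vectors::mcols(pk)$summit)
  expect_equal(S4Vectors::mcols(back)$signal, S4Vectors::mcols(pk)$signal)
})

test_that("subsampleUnique caps large pools deterministically", {
  ss <- SequenceSet("big", vapply(1:1200, function(i) randomSeq(10, i), ""))
  expect_identical(subsampleUnique(ss, cap = 2000, seed = 1), ss)
  sub <- subsampleUnique(ss, cap = 500, seed = 1)
  expect_equal(length(sub), 500L)
  expect_equal(as.character(sequences(subsampleUnique(ss, 500, 1))),
               as.character(sequences(sub)))
})
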