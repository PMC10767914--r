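test_that("pcmToPwm implements the log-odds formula", {
  ## uniform rows under uniform background with no pseudocount are log-odds 0
  pcm <- PositionCountMatrix("flat", rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)))
  pwm <- pcmToPwm(pcm, uniformBackground(), kappa = 0)
  expect_equal(unname(weights(pwm)), matrix(0, 2, 4))

  ## hand-computed smoothed case
  pcm2 <- PositionCountMatrix("a", rbind(c(4, 0, 0, 0)))
  pwm2 <- pcmToPwm(pcm2, uniformBackground(), kappa = 1)
  expect_equal(unname(weights(pwm2)[1, "A"]), log((4 + 0.25) / (5 * 0.25)))
  expect_equal(unname(weights(pwm2)[1, "C"]), log(0.25 / 1.25))

  ## normalization identity: sum_b p_b exp(w) = 1 per row when kappa = 0
  pcm3 <- PositionCountMatrix("pos", rbind(c(3, 2, 4, 1), c(5, 2, 2, 1)))
  pwm3 <- pcmToPwm(pcm3, uniformBackground(), kappa = 0)
  expect_equal(unname(rowSums(exp(weights(pwm3)) * 0.25)), c(1, 1))

  ## an all-zero count matrix (zero word count) is rejected at construction
  expect_error(PositionCountMatrix("z", rbind(c(0, 0, 0, 0))),
               "word count")
})

test_that("bestHit finds the planted consensus and breaks ties deterministically", {
  pwm <- PositionWeightMatrix("ac", rbind(c(2, -2, -2, -2),
                                          c(-2, 2, -2, -2)))
  h <- bestHit(pwm, "TTACTT")
  expect_equal(hitOffset(h), 2L)
  expect_equal(hitStrand(h), "+")
  expect_equal(score(h), 4)

  ## two equal-scoring windows: smaller offset wins
  h2 <- bestHit(pwm, "ACTTAC")
  expect_equal(hitOffset(h2), 0L)

  ## a + and - strand hit at the same offset: + preferred
  pal <- PositionWeightMatrix("pal", rbind(c(1, 0, 0, 1), c(1, 0, 0, 1)))
  h3 <- bestHit(pal, "TATA")
  expect_equal(hitStrand(h3), "+")

  expect_error(bestHit(pwm, "A"), "shorter")
})

test_that("bestHit equals the brute-force scan oracle on random cases", {
  for (i in 1:60) {
    pwm <- randomPwm(4L, seed = i)
    seq <- randomSeq(12L, seed = 1000 + i)
    expect_equal(score(bestHit(pwm, seq)),
                 oracleBestScore(weights(pwm), seq), tolerance = 1e-12)
  }
})

test_that("best-hit score is invariant under reverse complement", {
  for (i in 1:25) {
    pwm <- randomPwm(5L, seed = i)
    seq <- randomSeq(30L, seed = 2000 + i)
    expect_equal(score(bestHit(pwm, seq)),
                 score(bestHit(pwm, revcompChar(seq))), tolerance = 1e-12)
  }
})

test_that("N positions contribute the background-expected weight", {
  pwm <- randomPwm(3L, seed = 9)
  w <- weights(pwm)
  sAllN <- bestHitScores(pwm, "NNN")
  ## a fully-N window scores the sum of per-position mean weights (uniform bg)
  expect_equal(sAllN, sum(rowMeans(w)), tolerance = 1e-12)
})

test_that("scoreDistribution conserves mass and matches enumeration", {
  ## L = 1 uniform case: four equal masses
  pwm1 <- PositionWeightMatrix("L1", rbind(c(2, 1, 0, -1)))
  d1 <- scoreDistribution(pwm1, step = 1)
  expect_equal(sum(d1@mass), 1, tolerance = 1e-12)
  expect_equal(unname(d1@mass), rep(0.25, 4))

  ## L = 3 exhaustive check over every achievable threshold
  pwm3 <- randomPwm(3L, seed = 5)
  d3 <- scoreDistribution(pwm3)
  expect_equal(sum(d3@mass), 1, tolerance = 1e-10)
  mono <- rep(0.25, 4)
  for (t in d3@bins * d3@step) {
    expect_equal(pvalueOfScore(d3, t),
                 oracleTail(weights(pwm3), d3@step, mono, t),
                 tolerance = 1e-9)
  }
})

test_that("pvalueOfScore respects support bounds and monotonicity", {
  pwm <- randomPwm(4L, seed = 11)
  d <- scoreDistribution(pwm)
  lo <- min(d@bins) * d@step
  hi <- max(d@bins) * d@step
  expect_equal(pvalueOfScore(d, lo - 1), 1)
  expect_equal(pvalueOfScore(d, lo), 1)
  expect_equal(pvalueOfScore(d, hi + 1), 0)
  grid <- seq(lo - 0.5, hi + 0.5, length.out = 200)
  pv <- pvalueOfScore(d, grid)
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("thresholdForPvalue is the minimal qualifying score", {
  pwm <- randomPwm(3L, seed = 21)
  d <- scoreDistribution(pwm)
  expect_equal(thresholdForPvalue(d, 1), min(d@bins) * d@step)
  for (p in c(0.05, 0.001, 0.0005)) {
    t <- thresholdForPvalue(d, p)
    expect_lte(pvalueOfScore(d, t), p)
    ## minimality: one bin lower must violate the bound (when in support)
    below <- d@bins[d@bins * d@step < t]
    if (length(below)) {
      expect_gt(pvalueOfScore(d, max(below) * d@step), p)
    }
  }
  ## impossible p: above support maximum
  tiny <- min(d@mass) / 10
  tTiny <- thresholdForPvalue(d, tiny)
  expect_gt(tTiny, max(d@bins) * d@step)
  expect_equal(pvalueOfScore(d, tTiny), 0)

  ## threshold non-decreasing as p decreases
  ps <- 10^seq(0, -4, length.out = 20)
  ts <- vapply(ps, function(p) thresholdForPvalue(d, p), numeric(1))
  expect_true(all(diff(ts) >= -1e-12))
})

test_that("allelePvalues matches a brute-force two-allele rescan", {
  for (i in 1:20) {
    pwm <- randomPwm(4L, seed = 30 + i)
    d <- scoreDistribution(pwm)
    set.seed(4000 + i)
    ctx <- randomSeq(11L, seed = 4000 + i)
    pos <- sample(2:10, 1)
    ref <- substr(ctx, pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    pv <- allelePvalues(pwm, d, ctx, pos, ref, alt)

    ## oracle: substitute, scan only windows overlapping pos on both strands
    wr <- round(cbind(weights(pwm),
                      rowMeans(weights(pwm))) / d@step) * d@step
    bruteP <- function(base) {
      s <- ctx
      substr(s, pos, pos) <- base
      L <- 4L
      offs <- max(0, pos - L):min(nchar(s) - L, pos - 1)
      best <- -Inf
      for (o in offs) {
        best <- max(best, oracleWindowScore(wr[, 1:4], s, o))
        ## minus strand: same window on the reverse complement
        rc <- revcompChar(s)
        oRc <- nchar(s) - L - o
        best <- max(best, oracleWindowScore(wr[, 1:4], rc, oRc))
      }
      pvalueOfScore(d, best)
    }
    expect_equal(unname(pv["ref"]), bruteP(ref), tolerance = 1e-12)
    expect_equal(unname(pv["alt"]), bruteP(alt), tolerance = 1e-12)
  }
})

test_that("allelePvalues is symmetric when ref equals alt and checks input", {
  pwm <- randomPwm(4L, seed = 77)
  d <- scoreDistribution(pwm)
  pv <- allelePvalues(pwm, d, "ACGTACGTA", 5, "A", "A")
  expect_equal(unname(pv["ref"]), unname(pv["alt"]))
  expect_error(allelePvalues(pwm, d, "ACGTACGTA", 5, "C", "G"),
               "reference allele")
})

test_that("motif file round trips preserve matrices", {
  pcm <- genPwm(6L, seed = 3)
  pwm <- pcmToPwm(pcm)
  fPcm <- tempfile(fileext = ".pcm")
  fPwm <- tempfile(fileext = ".pwm")
  writePcm(pcm, fPcm)
  writePwm(pwm, fPwm)
  expect_equal(counts(readPcm(fPcm)[[1]]), counts(pcm), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(weights(readPwm(fPwm)[[1]]), weights(pwm), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(name(readPcm(fPcm)[[1]]), name(pcm))

  ## multiple motifs per file, order preserved
  f2 <- tempfile(fileext = ".pwm")
  writePwm(list(pwm, randomPwm(3, 1)), f2)
  got <- readPwm(f2)
  expect_length(got, 2)
  expect_equal(name(got[[2]]), "rnd_1")

  ## malformed row arity is reported with its line
  bad <- tempfile()
  writeLines(c(">x", "1\t2\t3"), bad)
  expect_error(readPcm(bad), "line 2")
})
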