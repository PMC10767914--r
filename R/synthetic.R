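## Seeded generators of ChIP-Seq-like, HT-SELEX-like and rSNP-like inputs
## with known ground truth, so every benchmark is testable end to end
## without external data.

#' Ground truth for synthetic benchmark inputs
#'
#' Bundles the planted motif and the generation parameters shared by the
#' synthetic generators: the fraction of positives carrying a binding site,
#' the positional spread of sites around peak summits, and the noise on
#' variant effect measurements.
#'
#' @slot truePwm the planted [PositionWeightMatrix-class].
#' @slot truePcm the count matrix the PWM came from (sites are sampled from
#'   its per-position base frequencies).
#' @slot plantRate fraction of positives carrying a site (default 0.8).
#' @slot positionalSd SD in bp of site placement around the summit
#'   (default 10).
#' @slot effectNoiseSd SD of the noise added to variant effect measurements
#'   (default 0.25, on the log10 P-value scale).
#'
#' @seealso [groundTruth()], [genChipseq()], [genSelex()], [genSnpSelex()]
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(truePwm = "PositionWeightMatrix",
                        truePcm = "PositionCountMatrix",
                        plantRate = "numeric", positionalSd = "numeric",
                        effectNoiseSd = "numeric"))

setValidity("GroundTruth", function(object) {
  if (object@plantRate < 0 || object@plantRate > 1)
    return("plantRate must be in [0, 1]")
  if (object@positionalSd < 0 || object@effectNoiseSd < 0)
    return("spreads must be non-negative")
  TRUE
})

#' Construct a ground truth object
#'
#' @param pcm planted motif as a [PositionCountMatrix-class]; by default a
#'   fresh draw from [genPwm()].
#' @param plantRate,positionalSd,effectNoiseSd see
#'   [GroundTruth-class].
#' @param bg background used to derive the log-odds form of the planted
#'   motif.
#' @param seed seed for the default motif draw.
#' @return A [GroundTruth-class].
#' @export
groundTruth <- function(pcm = genPwm(10L, sharpness = 6, seed = seed),
                        plantRate = 0.8, positionalSd = 10,
                        effectNoiseSd = 0.25,
                        bg = uniformBackground(), seed = 1L) {
  pwm <- pcmToPwm(pcm, bg)
  new("GroundTruth", truePwm = pwm, truePcm = pcm,
      plantRate = plantRate, positionalSd = positionalSd,
      effectNoiseSd = effectNoiseSd)
}

#' Draw a random motif count matrix
#'
#' Per-position base-frequency vectors are drawn from a symmetric Dirichlet
#' whose concentration decreases with `sharpness` (larger = more peaked
#' positions, higher information content), then scaled to a word count of
#' 1000.
#'
#' @param length motif length (>= 4).
#' @param sharpness positivity-constrained peakedness; the Dirichlet
#'   concentration is 1/sharpness.
#' @param seed integer seed.
#' @return A [PositionCountMatrix-class].
#' @examples
#' genPwm(8, sharpness = 6, seed = 42)
#' @export
genPwm <- function(length, sharpness = 6, seed = 1L) {
  stopifnot(length >= 4L, sharpness > 0)
  withSeed(seed, {
    rows <- t(vapply(seq_len(length), function(i) {
      g <- rgamma(4L, shape = 1 / sharpness, rate = 1)
      while (sum(g) == 0) g <- rgamma(4L, shape = 1 / sharpness, rate = 1)
      g / sum(g)
    }, numeric(4)))
    PositionCountMatrix(sprintf("synthetic_L%d_s%d", length, seed),
                        rows * 1000)
  })
}

## sample one site (character) from the per-position base frequencies
sampleSite <- function(pcm) {
  freq <- counts(pcm) / rowSums(counts(pcm))
  paste(vapply(seq_len(nrow(freq)), function(i)
    sample(DNA_BASES, 1L, prob = freq[i, ]), ""), collapse = "")
}

## genome background: first-order chain sampled in chunks for speed
genGenome <- function(len, bg, seed) {
  chunk <- 1000L
  nChunks <- ceiling(len / chunk)
  paste(sampleMarkov1(bg, chunk, nChunks, seed), collapse = "") |>
    substr(1L, len)
}

#' Generate a synthetic ChIP-Seq experiment
#'
#' A background genome is drawn from a first-order chain; `nPeaks`
#' non-overlapping peaks are placed on it, and a fraction `plantRate` of
#' them receive one binding site sampled from the planted motif, positioned
#' at the summit plus Normal(0, positionalSd) bp on a random strand. Peak
#' signal and significance are correlated with the planted site's
#' log-probability under the motif (plus independent noise), so top-peak
#' selection by either key enriches for planted sites.
#'
#' @param gt a [GroundTruth-class].
#' @param nPeaks number of peaks (default 500).
#' @param genomeLength genome size in bp; default spaces peaks 2500 bp
#'   apart, enough for summit windows and their flanking negatives.
#' @param seed integer seed.
#' @param bg background composition of the genome.
#' @param dir optional directory; when given, `genome.fa` and
#'   `peaks.narrowPeak` are written there.
#' @return list with `genome` (named DNAStringSet), `peaks` (GRanges with
#'   signal/significance/summit), and `truth` (data.frame: planted flag,
#'   site position, strand per peak).
#' @export
genChipseq <- function(gt, nPeaks = 500L, genomeLength = nPeaks * 2500L,
                       seed = 1L, bg = BackgroundModel(c(0.3, 0.2, 0.2, 0.3)),
                       dir = NULL) {
  spacing <- genomeLength %/% nPeaks
  L <- motifLength(gt@truePcm)
  if (spacing < 1600L + 2L * L)
    stop("genome too short to pack the peaks with their flanks")
  withSeed(seed, {
    genome <- genGenome(genomeLength, bg, sample.int(1e9, 1L))
    summit <- as.integer(round((seq_len(nPeaks) - 0.5) * spacing +
                                 runif(nPeaks, -50, 50)))  # 0-based
    planted <- runif(nPeaks) < gt@plantRate
    sitePos <- rep(NA_integer_, nPeaks)
    strand <- rep(NA_character_, nPeaks)
    siteLogp <- rep(NA_real_, nPeaks)
    freq <- counts(gt@truePcm) / rowSums(counts(gt@truePcm))
    chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
    for (i in which(planted)) {
      site <- sampleSite(gt@truePcm)
      codes <- encodeDNA(site)
      siteLogp[i] <- sum(log(freq[cbind(seq_len(L), codes)] + 1e-9))
      strand[i] <- sample(c("+", "-"), 1L)
      if (strand[i] == "-") site <- revcompDNA(site)
      pos0 <- summit[i] + as.integer(round(rnorm(1, 0, gt@positionalSd))) -
        L %/% 2L
      pos0 <- max(0L, min(genomeLength - L, pos0))
      sitePos[i] <- pos0
      chars[(pos0 + 1L):(pos0 + L)] <- strsplit(site, "", fixed = TRUE)[[1L]]
    }
    genome <- paste(chars, collapse = "")
    ## plant strength drives both ranking keys, with independent noise
    strength <- ifelse(planted, siteLogp - min(siteLogp, na.rm = TRUE) + 1, 0)
    signal <- strength + rexpNoise(nPeaks)
    significance <- 2 * strength + rexpNoise(nPeaks)
    peakHalf <- 150L
    starts0 <- pmax(0L, summit - peakHalf)
    ends0 <- pmin(genomeLength, summit + peakHalf + 1L)
    peaks <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(starts0 + 1L, ends0))
    S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
      signal = signal, significance = significance,
      summit = summit - starts0)
    names(peaks) <- sprintf("peak_%d", seq_len(nPeaks))
    genomeSet <- Biostrings::DNAStringSet(setNames(genome, "chr1"))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      writeSequences(genomeSet, file.path(dir, "genome.fa"))
      writeNarrowPeak(peaks, file.path(dir, "peaks.narrowPeak"))
    }
    list(genome = genomeSet, peaks = peaks,
         truth = data.frame(peak = names(peaks), planted = planted,
                            sitePos = sitePos, strand = strand))
  })
}

rexpNoise <- function(n) stats::rexp(n, rate = 2)

#' Generate a synthetic HT-SELEX experiment
#'
#' Cycle 1 reads are uniform random; each later cycle resamples the
#' previous pool with selection probability proportional to a logistic
#' function of the planted motif's best-hit score (midpoint at the P = 1e-3
#' threshold score), then mutates 1% of bases. Duplicate reads arise
#' naturally from the resampling.
#'
#' @param gt a [GroundTruth-class].
#' @param nReads reads per cycle (default 2000).
#' @param readLength insert length in bp (default 20).
#' @param cycles number of cycles (default 4).
#' @param seed integer seed.
#' @param adapterFlanks constant adapter bases for the read set.
#' @return A [SelexReadSet-class] with cycles 1..cycles.
#' @export
genSelex <- function(gt, nReads = 2000L, readLength = 20L, cycles = 4L,
                     seed = 1L, adapterFlanks = c("G", "C")) {
  stopifnot(cycles >= 1L)
  pwm <- gt@truePwm
  dist <- scoreDistribution(pwm)
  tMid <- thresholdForPvalue(dist, 1e-3)
  tMax <- max(dist@bins) * dist@step
  scale <- max((tMax - tMid) / 4, 1e-6)
  withSeed(seed, {
    pool <- vapply(seq_len(nReads), function(i)
      paste(sample(DNA_BASES, readLength, replace = TRUE), collapse = ""), "")
    out <- list(pool)
    if (cycles > 1L) for (cyc in 2:cycles) {
      sc <- bestHitScores(pwm, pool)
      w <- 1 / (1 + exp(-(sc - tMid) / scale))
      pool <- pool[sample.int(nReads, nReads, replace = TRUE, prob = w)]
      ## 1% per-base mutation
      mat <- do.call(rbind, strsplit(pool, "", fixed = TRUE))
      hit <- which(matrix(runif(length(mat)) < 0.01, nrow(mat)))
      if (length(hit))
        mat[hit] <- sample(DNA_BASES, length(hit), replace = TRUE)
      pool <- apply(mat, 1, paste, collapse = "")
      out[[cyc]] <- pool
    }
    names(out) <- seq_len(cycles)
    SelexReadSet(out, adapterFlanks)
  })
}

## shared helper: contexts with one planted site and a variant inside it
genVariantCore <- function(gt, nRecords, contextLength, plantSite = TRUE) {
  L <- motifLength(gt@truePcm)
  stopifnot(contextLength >= L + 2L)
  t(vapply(seq_len(nRecords), function(i) {
    ctx <- paste(sample(DNA_BASES, contextLength, replace = TRUE),
                 collapse = "")
    sitePos0 <- sample.int(contextLength - L + 1L, 1L) - 1L
    if (plantSite) {
      site <- sampleSite(gt@truePcm)
      substr(ctx, sitePos0 + 1L, sitePos0 + L) <- site
    }
    pos <- sitePos0 + sample.int(L, 1L)     # 1-based, inside the site
    ref <- substr(ctx, pos, pos)
    alt <- sample(setdiff(DNA_BASES, ref), 1L)
    c(ctx, as.character(pos), ref, alt)
  }, character(4)))
}

#' Generate synthetic SNP-SELEX records
#'
#' Contexts carry one planted site; variants fall inside it. The
#' experimental differential-binding measurement is the true predicted
#' effect of the planted motif (delta log10 P) plus Normal(0,
#' effectNoiseSd) noise; variants whose |true effect| exceeds the
#' (1 - prevalence) quantile are labeled positive.
#'
#' @param gt a [GroundTruth-class].
#' @param nRecords number of variants.
#' @param contextLength context length (default motif length + 20).
#' @param prevalence fraction labeled positive (default 0.5).
#' @param seed integer seed.
#' @param batch batch label stamped on the records.
#' @return data.frame in the [snpSelexBench()] dialect.
#' @export
genSnpSelex <- function(gt, nRecords = 250L,
                        contextLength = motifLength(gt@truePcm) + 20L,
                        prevalence = 0.5, seed = 1L, batch = "batch1") {
  pwm <- gt@truePwm
  dist <- scoreDistribution(pwm)
  withSeed(seed, {
    core <- genVariantCore(gt, nRecords, contextLength)
    rec <- data.frame(id = sprintf("snv_%d", seq_len(nRecords)),
                      context = core[, 1L], pos = as.integer(core[, 2L]),
                      ref = core[, 3L], alt = core[, 4L],
                      batch = batch, stringsAsFactors = FALSE)
    trueDelta <- deltaLogp(pwm, dist, rec)
    thr <- stats::quantile(abs(trueDelta), 1 - prevalence, names = FALSE)
    rec$label <- ifelse(abs(trueDelta) >= thr, "positive", "negative")
    rec$exp_logp <- trueDelta + rnorm(nRecords, 0, gt@effectNoiseSd)
    rec$bound <- TRUE
    rec
  })
}

#' Generate synthetic allele-specific binding records
#'
#' All records carry a planted site (so they pass the motif-occurrence
#' candidate filter). For "biased" records the FDR of the better-bound
#' allele is a monotone transform of |true effect| (more extreme effect =
#' more significant), the other allele's FDR is flat at 0.9; direction
#' matches the effect's sign. "Neutral" records get both FDRs uniform in
#' (0.5, 1].
#'
#' @param gt a [GroundTruth-class].
#' @param nRecords total records; roughly half biased, half neutral.
#' @param contextLength context length (default motif length + 20).
#' @param seed integer seed.
#' @return data.frame in the [asbCandidateFilter()] dialect with a
#'   `trueBiased` truth column.
#' @export
genAsb <- function(gt, nRecords = 120L,
                   contextLength = motifLength(gt@truePcm) + 20L,
                   seed = 1L) {
  pwm <- gt@truePwm
  dist <- scoreDistribution(pwm)
  withSeed(seed, {
    core <- genVariantCore(gt, nRecords, contextLength)
    rec <- data.frame(id = sprintf("asb_%d", seq_len(nRecords)),
                      context = core[, 1L], pos = as.integer(core[, 2L]),
                      ref = core[, 3L], alt = core[, 4L],
                      stringsAsFactors = FALSE)
    trueDelta <- deltaLogp(pwm, dist, rec)
    ## records with a decent effect become biased, the rest neutral; an
    ## effect-less record cannot carry a credible allelic imbalance
    biased <- rank(-abs(trueDelta), ties.method = "first") <=
      ceiling(nRecords / 2)
    m <- 1.5 + 2 * abs(trueDelta) + abs(rnorm(nRecords, 0, gt@effectNoiseSd))
    fdrPref <- pmin(10^(-m), 0.049)
    fdrRef <- runif(nRecords, 0.5 + 1e-6, 1)
    fdrAlt <- runif(nRecords, 0.5 + 1e-6, 1)
    prefRef <- trueDelta > 0 | (trueDelta == 0 & runif(nRecords) < 0.5)
    fdrRef[biased & prefRef] <- fdrPref[biased & prefRef]
    fdrRef[biased & !prefRef] <- 0.9
    fdrAlt[biased & !prefRef] <- fdrPref[biased & !prefRef]
    fdrAlt[biased & prefRef] <- 0.9
    rec$fdr_ref <- fdrRef
    rec$fdr_alt <- fdrAlt
    rec$trueBiased <- biased
    rec
  })
}

#' Decoy motifs for benchmark null comparisons
#'
#' Independent random draws from [genPwm()] with the same length as the
#' planted motif, named decoy_1..decoy_n.
#'
#' @param gt a [GroundTruth-class].
#' @param n number of decoys.
#' @param seed integer seed.
#' @param sharpness peakedness of the decoys (default as [genPwm()]).
#' @param bg background for the log-odds conversion.
#' @return list of [PositionWeightMatrix-class].
#' @export
genDecoys <- function(gt, n = 3L, seed = 1L, sharpness = 6,
                      bg = uniformBackground()) {
  L <- motifLength(gt@truePcm)
  lapply(seq_len(n), function(i) {
    pcm <- genPwm(L, sharpness, seed = seed * 1000L + i)
    pwm <- pcmToPwm(pcm, bg)
    pwm@name <- sprintf("decoy_%d", i)
    pwm
  })
}
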