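## End-to-end orchestration on synthetic fixtures: data preparation, the
## three benchmark families, applicability filtering, rank aggregation and
## subcollection assembly, with deterministic on-disk outputs.

#' Run the ChIP-Seq benchmark family on one experiment
#'
#' Top-peak selection (both ranking keys), summit windows, flanking
#' negatives, then the flank, pseudo and centrality benchmarks for every
#' motif.
#'
#' @param pwms list of [PositionWeightMatrix-class].
#' @param peaks GRanges of peaks with signal/significance/summit.
#' @param genome named DNAStringSet.
#' @param dataset dataset identifier.
#' @param topN peak cap (default 1000).
#' @param width summit window width (default 301).
#' @param gap flank gap (default 300).
#' @param seed seed for the pseudo-benchmark negative sampling.
#' @param sortKeys ranking keys to run (default both).
#' @return data.frame of benchmark rows across all three benchmarks.
#' @export
runChipseqBenchmarks <- function(pwms, peaks, genome, dataset = "chipseq",
                                 topN = 1000L, width = 301L, gap = 300L,
                                 seed = 1L,
                                 sortKeys = c("signal", "significance")) {
  do.call(rbind, lapply(sortKeys, function(key) {
    top <- selectTopPeaks(peaks, topN, key)
    pos <- summitWindows(top, genome, width)
    neg <- flankNegatives(pos, genome, gap)
    rbind(
      benchFlank(pwms, pos, neg, dataset = dataset, sortKey = key),
      do.call(rbind, lapply(pwms, function(pwm)
        benchPseudo(pwm, pos, seed = seed, dataset = dataset,
                    sortKey = key))),
      do.call(rbind, lapply(pwms, function(pwm)
        benchCentrality(pwm, pos, dataset = dataset, sortKey = key))))
  }))
}

#' Run the HT-SELEX benchmark family on one experiment
#'
#' Pools cycles (full and, when available, late), removes singletons, ranks
#' unique reads by 5-mer enrichment, extends them with adapter flanks, caps
#' the pool and benchmarks every motif at the three positive fractions.
#'
#' @param pwms list of [PositionWeightMatrix-class].
#' @param readSet a [SelexReadSet-class].
#' @param dataset dataset identifier prefix.
#' @param cap unique-read cap (default 500000).
#' @param seed seed for ranking shuffles and subsampling.
#' @param modes pooling modes to run.
#' @return data.frame of benchmark rows (datasets `<dataset>_full`,
#'   `<dataset>_late`).
#' @export
runSelexBenchmarks <- function(pwms, readSet, dataset = "selex",
                               cap = 500000L, seed = 1L,
                               modes = c("full", "late")) {
  do.call(rbind, lapply(modes, function(mode) {
    pooled <- tryCatch(poolCycles(readSet, mode), error = function(e) NULL)
    if (is.null(pooled)) return(NULL)
    uniq <- tryCatch(dropSingletons(pooled), error = function(e) NULL)
    if (is.null(uniq)) return(NULL)
    ranked <- kmerEnrichmentRank(uniq, seed = seed)
    extended <- SequenceSet(
      sprintf("%s_%s", dataset, mode),
      extendWithAdapters(as.character(sequences(ranked)),
                         readSet@adapterFlanks),
      role = "candidate",
      enrichment = enrichmentScores(ranked))
    capped <- subsampleUnique(extended, cap, seed)
    benchSelex(pwms, capped)
  }))
}

#' Run the rSNP benchmark family
#'
#' SNP-SELEX classification/correlation per batch plus ASB concordance per
#' motif, with the candidate filter and positive/neutral partition.
#'
#' @param pwms list of [PositionWeightMatrix-class].
#' @param snpRecords SNP-SELEX-style variant table (see
#'   [snpSelexBench()]).
#' @param asbRecords ASB variant table (see [asbCandidateFilter()]).
#' @param bg scanning background.
#' @param pThresh candidate-filter P-value bound.
#' @return list with `results` (rank-ready rows including ASB tau/rho and
#'   -log10 Fisher P), `snpSelexApplicable`, `asbApplicable` (named logical
#'   per motif) and the per-motif ASB detail list.
#' @export
runRsnpBenchmarks <- function(pwms, snpRecords, asbRecords,
                              bg = uniformBackground(), pThresh = 5e-4) {
  dists <- lapply(pwms, scoreDistribution, bg = bg)
  names(dists) <- vapply(pwms, name, "")
  snp <- snpSelexBench(pwms, snpRecords, dists, bg)
  asbRows <- list()
  asbApplicable <- setNames(rep(NA, length(pwms)), vapply(pwms, name, ""))
  asbDetail <- list()
  for (pwm in pwms) {
    d <- dists[[name(pwm)]]
    cand <- asbCandidateFilter(pwm, d, asbRecords, pThresh, bg)
    part <- asbPartition(cand)
    res <- asbBench(pwm, d, part$positives, part$neutral, bg)
    asbDetail[[name(pwm)]] <- res
    if (!res$skipped) {
      asbApplicable[name(pwm)] <- res$applicable
      asbRows[[name(pwm)]] <- rbind(
        benchmarkResult(name(pwm), "asb", "tau_asb", res$tau),
        benchmarkResult(name(pwm), "asb", "rho_asb", res$rho),
        benchmarkResult(name(pwm), "asb", "neglog_fisher_asb",
                        -log10(res$fisher_p)))
    }
  }
  results <- rbind(snp$results,
                   if (length(asbRows)) do.call(rbind, asbRows) else NULL)
  results <- results[!is.na(results$value), , drop = FALSE]
  list(results = results, snpSelexApplicable = snp$applicable,
       asbApplicable = asbApplicable, asbDetail = asbDetail,
       snpSkipped = snp$skipped)
}

subtypeStatusFromFilter <- function(subtypes, inapplicable, tested) {
  setNames(ifelse(!subtypes %in% tested, "untested",
                  ifelse(subtypes %in% inapplicable, "inapplicable",
                         "applicable")), subtypes)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic ChIP-Seq experiment, an HT-SELEX experiment, and
#' SNP-SELEX/ASB variant tables from one planted motif; benchmarks the
#' planted motif against decoys in all three categories; aggregates ranks;
#' and assembles the core and category subcollections. Everything is
#' determined by `seed`; when `outDir` is given the manifests, rank tables
#' and motif files are written there deterministically.
#'
#' @param seed integer master seed.
#' @param outDir optional output directory.
#' @param nPeaks synthetic peak count (default 500).
#' @param nDecoys number of decoy motifs (default 3).
#' @param gt optional [GroundTruth-class]; by default drawn from `seed`.
#' @param nSelexReads reads per HT-SELEX cycle.
#' @param nSnp,nAsb variant counts for the rSNP tables.
#' @return list with the benchmark tables, applicability reports, the
#'   selection, the subcollections and the ground truth.
#' @export
runPipeline <- function(seed = 1L, outDir = NULL, nPeaks = 500L,
                        nDecoys = 3L, gt = NULL, nSelexReads = 2000L,
                        nSnp = 250L, nAsb = 120L) {
  if (is.null(gt)) gt <- groundTruth(seed = seed)
  truePwm <- gt@truePwm
  truePwm@name <- "planted"
  decoys <- genDecoys(gt, nDecoys, seed)
  pwms <- c(list(truePwm), decoys)
  motifNames <- vapply(pwms, name, "")
  ## subtype layout: the planted motif and the first decoy compete within
  ## subtype "main"; remaining decoys form subtype "alt"
  subtypeOf <- setNames(ifelse(motifNames %in% c("planted", "decoy_1"),
                               "main", "alt"), motifNames)
  motifInfo <- data.frame(motif = motifNames, tf = "TF1",
                          subtype = subtypeOf[motifNames])

  ## ---- in vivo ----
  chip <- genChipseq(gt, nPeaks = nPeaks, seed = seed)
  chipRes <- runChipseqBenchmarks(pwms, chip$peaks, chip$genome,
                                  dataset = "chipseq_1", seed = seed)
  chipFilt <- chipseqFilters(chipRes,
                             peakCounts = c(chipseq_1 = length(chip$peaks)),
                             subtypeOf = subtypeOf)

  ## ---- in vitro ----
  selex <- genSelex(gt, nReads = nSelexReads, seed = seed)
  selexRes <- runSelexBenchmarks(pwms, selex, dataset = "selex_1",
                                 seed = seed)
  selexFilt <- selexFilters(selexRes, subtypeOf = subtypeOf)

  ## ---- rSNP ----
  snpRecords <- rbind(
    genSnpSelex(gt, nSnp, seed = seed, batch = "batch1"),
    genSnpSelex(gt, nSnp, seed = seed + 1L, batch = "batch2"))
  asbRecords <- genAsb(gt, nAsb, seed = seed)
  rsnp <- runRsnpBenchmarks(pwms, snpRecords, asbRecords)

  ## ---- aggregation ----
  invivoAgg <- aggregateRanks(rankWithinGroups(chipFilt$results))
  invitroAgg <- aggregateRanks(rankWithinGroups(selexFilt$results))
  rsnpAgg <- aggregateRanks(rankWithinGroups(rsnp$results))
  categoryAggregates <- Filter(length, list(invivo = invivoAgg,
                                            invitro = invitroAgg,
                                            rsnp = rsnpAgg))
  selection <- selectBest(categoryAggregates, motifInfo)

  ## ---- applicability and exclusions ----
  subtypes <- unique(subtypeOf)
  toSubtype <- function(applicablePerMotif) {
    vapply(subtypes, function(st) {
      v <- applicablePerMotif[names(applicablePerMotif) %in%
                                names(subtypeOf)[subtypeOf == st]]
      if (all(is.na(v))) NA else any(v, na.rm = TRUE)
    }, logical(1))
  }
  invivoStatus <- subtypeStatusFromFilter(
    subtypes, chipFilt$inapplicableSubtypes,
    tested = unique(subtypeOf[chipRes$motif]))
  invitroStatus <- subtypeStatusFromFilter(
    subtypes, selexFilt$inapplicableSubtypes,
    tested = unique(subtypeOf[selexRes$motif]))
  rsnpExcl <- rsnpApplicability(toSubtype(rsnp$snpSelexApplicable),
                                toSubtype(rsnp$asbApplicable),
                                invivoStatus, invitroStatus,
                                allSubtypes = subtypes)

  evidence <- data.frame(subtype = subtypes,
                         nChipseqSupport = 1L,
                         nHtselexSupport = ifelse(subtypes == "main", 1L, 0L))
  collections <- assembleSubcollections(
    selection, evidence,
    invivoInapplicable = chipFilt$inapplicableSubtypes,
    invitroInapplicable = selexFilt$inapplicableSubtypes,
    rsnpInapplicable = rsnpExcl$dropFromRsnp,
    coreExcluded = rsnpExcl$dropFromCore)

  out <- list(groundTruth = gt, pwms = pwms, motifInfo = motifInfo,
              chipseqResults = chipRes, chipseqFilter = chipFilt,
              selexResults = selexRes, selexFilter = selexFilt,
              rsnp = rsnp, categoryAggregates = categoryAggregates,
              selection = selection, collections = collections)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

## deterministic on-disk rendering of a pipeline run
writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTsv <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
    write.table(df, file.path(outDir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  writeTsv(out$chipseqResults, "results_chipseq.tsv")
  writeTsv(out$selexResults, "results_selex.tsv")
  writeTsv(out$rsnp$results, "results_rsnp.tsv")
  for (cat in names(out$categoryAggregates)) {
    agg <- out$categoryAggregates[[cat]]
    writeTsv(data.frame(motif = names(agg), aggregate = unname(agg)),
             sprintf("ranks_%s.tsv", cat))
  }
  for (nm in names(out$collections)) {
    writeTsv(out$collections[[nm]], sprintf("collection_%s.tsv", nm))
  }
  writePwm(out$pwms, file.path(outDir, "motifs.pwm"))
  invisible(outDir)
}
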