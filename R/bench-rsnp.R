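## Regulatory-SNV benchmarks: SNP-SELEX-style classification/correlation and
## allele-specific binding (ASB) concordance.
##
## Variant tables are plain data.frames with columns id, context, pos
## (1-based index of the variant within context), ref, alt, plus
## benchmark-specific columns: label + exp_logp (SNP-SELEX) or
## fdr_ref + fdr_alt (ASB).

checkVariantTable <- function(records, extra = character(0)) {
  need <- c("id", "context", "pos", "ref", "alt", extra)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  invisible(records)
}

#' Predicted differential binding of a variant
#'
#' log10(P_alt) - log10(P_ref) of the best PWM hit overlapping the variant;
#' positive values mean the reference allele is better bound. The absolute
#' value serves as a classification score, the sign as the predicted
#' direction of allelic preference.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param dist the matching [ScoreDistribution-class].
#' @param records variant table (see above); vectorized over rows.
#' @param bg background for scanning.
#' @return numeric vector of signed log10 P-value ratios.
#' @export
deltaLogp <- function(pwm, dist, records, bg = uniformBackground()) {
  checkVariantTable(records)
  vapply(seq_len(nrow(records)), function(i) {
    pv <- allelePvalues(pwm, dist, records$context[i], records$pos[i],
                        records$ref[i], records$alt[i], bg)
    log10(pv[["alt"]]) - log10(pv[["ref"]])
  }, numeric(1))
}

#' SNP-SELEX-style rSNP benchmark
#'
#' Classification of positive versus negative variants by |delta log10 P|
#' (auROC, auPRC), plus Kendall tau-b and Pearson rho between the signed
#' predicted effect and the experimentally measured differential-binding
#' log-P over the positives only. Test sets with fewer than `minPositives`
#' positives are skipped. A motif is applicable when auROC >= `aurocMin`
#' with both tau-b > 0 and rho > 0.
#'
#' @param pwms list of [PositionWeightMatrix-class].
#' @param records variant table with `label` ("positive"/"negative") and
#'   `exp_logp` columns; an optional `batch` column splits it into
#'   independently evaluated test sets.
#' @param dists optional named list of precomputed score distributions.
#' @param bg background for scanning.
#' @param minPositives minimal positive count per test set (default 10).
#' @param aurocMin applicability bar (default 0.6).
#' @return list with `results` (motif, dataset, metric, value rows),
#'   `applicable` (named logical per motif) and `skipped` (test sets below
#'   the positive-count bar).
#' @export
snpSelexBench <- function(pwms, records, dists = NULL,
                          bg = uniformBackground(),
                          minPositives = 10L, aurocMin = 0.6) {
  checkVariantTable(records, c("label", "exp_logp"))
  if (is.null(records$batch)) records$batch <- "batch1"
  batches <- split(records, records$batch)
  nPos <- vapply(batches, function(b) sum(b$label == "positive"), integer(1))
  skipped <- names(batches)[nPos < minPositives]
  batches <- batches[nPos >= minPositives]
  if (is.null(dists)) {
    dists <- lapply(pwms, scoreDistribution, bg = bg)
    names(dists) <- vapply(pwms, name, "")
  }
  rows <- list()
  applicable <- setNames(rep(FALSE, length(pwms)),
                         vapply(pwms, name, ""))
  for (bt in names(batches)) {
    b <- batches[[bt]]
    isPos <- b$label == "positive"
    for (pwm in pwms) {
      dl <- deltaLogp(pwm, dists[[name(pwm)]], b, bg)
      roc <- auROC(abs(dl), isPos)
      prc <- auPRC(abs(dl), isPos)
      tau <- tryCatch(kendallTauB(dl[isPos], b$exp_logp[isPos]),
                      error = function(e) NA_real_)
      rho <- tryCatch(pearsonRho(dl[isPos], b$exp_logp[isPos]),
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- rbind(
        benchmarkResult(name(pwm), bt, "auROC_snpselex", roc),
        benchmarkResult(name(pwm), bt, "auPRC_snpselex", prc),
        benchmarkResult(name(pwm), bt, "tau_snpselex", tau),
        benchmarkResult(name(pwm), bt, "rho_snpselex", rho))
      if (!is.na(tau) && !is.na(rho) &&
          roc >= aurocMin && tau > 0 && rho > 0)
        applicable[name(pwm)] <- TRUE
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), dataset = character(0),
               metric = character(0), sort_key = character(0),
               value = numeric(0))
  list(results = res, applicable = applicable, skipped = skipped)
}

#' Candidate filter for ASB variants
#'
#' Keeps variants directly overlapping a motif occurrence: the smaller of
#' the two allelic best-hit P-values must be strictly below `pThresh`
#' (default 0.0005).
#'
#' @param pwm,dist,bg as in [deltaLogp()].
#' @param records ASB variant table.
#' @param pThresh P-value bound (strict inequality).
#' @return the filtered table, with `p_ref`, `p_alt` columns attached.
#' @export
asbCandidateFilter <- function(pwm, dist, records, pThresh = 5e-4,
                               bg = uniformBackground()) {
  checkVariantTable(records)
  pv <- t(vapply(seq_len(nrow(records)), function(i) {
    allelePvalues(pwm, dist, records$context[i], records$pos[i],
                  records$ref[i], records$alt[i], bg)
  }, numeric(2)))
  records$p_ref <- pv[, 1L]
  records$p_alt <- pv[, 2L]
  records[pmin(records$p_ref, records$p_alt) < pThresh, , drop = FALSE]
}

#' Partition ASB variants into positive and neutral sets
#'
#' Positive: the smaller allelic FDR is below `fdrPos` (significant allelic
#' bias towards either allele). Neutral: both allelic FDRs exceed
#' `fdrNeutral` (no hint of bias). Variants in neither set are discarded;
#' the two sets are disjoint by construction.
#'
#' @param records ASB table with `fdr_ref`, `fdr_alt` columns.
#' @param fdrPos positive-set bound (default 0.05).
#' @param fdrNeutral neutral-set bound (default 0.5).
#' @return list of data.frames `positives` and `neutral`.
#' @export
asbPartition <- function(records, fdrPos = 0.05, fdrNeutral = 0.5) {
  checkVariantTable(records, c("fdr_ref", "fdr_alt"))
  lo <- pmin(records$fdr_ref, records$fdr_alt)
  list(positives = records[lo < fdrPos, , drop = FALSE],
       neutral = records[lo > fdrNeutral, , drop = FALSE])
}

#' ASB concordance benchmark
#'
#' Over the positives, Kendall tau-b and Pearson rho between the predicted
#' effect (delta log10 P) and the observed allelic-bias effect
#' (log10 FDR_alt - log10 FDR_ref, so that a more significant
#' reference-allele bias is positive, matching the prediction's sign
#' convention). Concordance of signs is tabulated separately for the
#' positive and neutral sets and tested with Fisher's exact test (greater
#' tail: concordance enriched among positives). The motif is applicable
#' when Fisher P < `fisherMax` with both tau-b > 0 and rho > 0. TFs with
#' fewer than `minPositives` positives are skipped.
#'
#' @param pwm,dist,bg as in [deltaLogp()].
#' @param positives,neutral data.frames from [asbPartition()].
#' @param minPositives minimal positive count (default 10).
#' @param fisherMax applicability bound on the Fisher P-value (default
#'   0.05).
#' @return list with `tau`, `rho`, `fisher_p`, `table` (the 2 x 2 counts),
#'   `applicable`, and `skipped` (TRUE when below the positive bar).
#' @export
asbBench <- function(pwm, dist, positives, neutral,
                     bg = uniformBackground(), minPositives = 10L,
                     fisherMax = 0.05) {
  if (nrow(positives) < minPositives) {
    return(list(tau = NA_real_, rho = NA_real_, fisher_p = NA_real_,
                table = NULL, applicable = FALSE, skipped = TRUE))
  }
  obsEffect <- function(df) log10(df$fdr_alt) - log10(df$fdr_ref)
  dlPos <- deltaLogp(pwm, dist, positives, bg)
  dlNeu <- if (nrow(neutral)) deltaLogp(pwm, dist, neutral, bg) else numeric(0)
  effPos <- obsEffect(positives)
  effNeu <- if (nrow(neutral)) obsEffect(neutral) else numeric(0)
  tau <- tryCatch(kendallTauB(dlPos, effPos), error = function(e) NA_real_)
  rho <- tryCatch(pearsonRho(dlPos, effPos), error = function(e) NA_real_)
  concord <- function(dl, eff) sign(dl) != 0 & sign(dl) == sign(eff)
  discord <- function(dl, eff) sign(dl) != 0 & sign(eff) != 0 &
    sign(dl) != sign(eff)
  tab <- c(a = sum(concord(dlPos, effPos)), b = sum(discord(dlPos, effPos)),
           c = sum(concord(dlNeu, effNeu)), d = sum(discord(dlNeu, effNeu)))
  fp <- if (sum(tab) == 0) NA_real_ else
    fisherExact(tab["a"], tab["b"], tab["c"], tab["d"], side = "greater")
  applicable <- !is.na(tau) && !is.na(rho) && !is.na(fp) &&
    fp < fisherMax && tau > 0 && rho > 0
  list(tau = tau, rho = rho, fisher_p = fp, table = tab,
       applicable = applicable, skipped = FALSE)
}

#' Combine rSNP applicability into exclusion sets
#'
#' A subtype inapplicable to both SNP-SELEX and ASB is dropped from the
#' rSNP subcollection. A subtype inapplicable to every data type for which
#' it was tested anywhere (in vivo, in vitro, rSNP) is excluded from the
#' core collection. Subtypes with no data of a given type are "untested",
#' not inapplicable.
#'
#' @param snpSelexApplicable,asbApplicable named logical vectors per
#'   subtype; NA or absent = untested on that data source.
#' @param invivoStatus,invitroStatus named character vectors per subtype
#'   with values "applicable", "inapplicable" or "untested" (absent =
#'   untested), as derivable from [chipseqFilters()] / [selexFilters()].
#' @param allSubtypes character vector of every subtype under evaluation.
#' @return list with `dropFromRsnp` and `dropFromCore` character vectors.
#' @export
rsnpApplicability <- function(snpSelexApplicable, asbApplicable,
                              invivoStatus = character(0),
                              invitroStatus = character(0),
                              allSubtypes = NULL) {
  if (is.null(allSubtypes))
    allSubtypes <- unique(c(names(snpSelexApplicable), names(asbApplicable),
                            names(invivoStatus), names(invitroStatus)))
  logiStatus <- function(appl, st) {
    if (!st %in% names(appl) || is.na(appl[[st]])) "untested"
    else if (appl[[st]]) "applicable" else "inapplicable"
  }
  charStatus <- function(stat, st) {
    if (!st %in% names(stat)) "untested" else stat[[st]]
  }
  dropFromRsnp <- Filter(function(st) {
    logiStatus(snpSelexApplicable, st) == "inapplicable" &&
      logiStatus(asbApplicable, st) == "inapplicable"
  }, allSubtypes)
  dropFromCore <- Filter(function(st) {
    rsnpStatus <- c(logiStatus(snpSelexApplicable, st),
                    logiStatus(asbApplicable, st))
    verdicts <- c(
      invivo = charStatus(invivoStatus, st),
      invitro = charStatus(invitroStatus, st),
      rsnp = if (any(rsnpStatus == "applicable")) "applicable"
             else if (all(rsnpStatus == "untested")) "untested"
             else "inapplicable")
    ## excluded from core when inapplicable to every data type that has
    ## data; a subtype with no data anywhere stays (it is untested)
    any(verdicts == "inapplicable") && !any(verdicts == "applicable")
  }, allSubtypes)
  list(dropFromRsnp = as.character(dropFromRsnp),
       dropFromCore = as.character(dropFromCore))
}
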