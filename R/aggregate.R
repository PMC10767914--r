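## Rank aggregation across metrics/benchmarks/datasets, quality ratings,
## and assembly of the four motif subcollections.

#' Fractional ranks within (dataset, metric, sort key) groups
#'
#' Every metric is oriented so that larger values are better; within each
#' group the motifs are ranked descending by value with average fractional
#' ranks for ties (1 = best).
#'
#' @param results data.frame of benchmark rows (motif, dataset, metric,
#'   sort_key, value).
#' @return the input with a `rank` column and a `group` id column added.
#' @export
rankWithinGroups <- function(results) {
  if (nrow(results) == 0L) return(cbind(results, group = character(0),
                                        rank = numeric(0)))
  results$group <- paste(results$dataset, results$metric, results$sort_key,
                         sep = "|")
  results$rank <- NA_real_
  for (g in unique(results$group)) {
    idx <- which(results$group == g)
    results$rank[idx] <- rank(-results$value[idx], ties.method = "average")
  }
  results
}

#' Log-rank aggregation of one motif's ranks
#'
#' The mean of ln(rank) over the groups where the motif was evaluated;
#' lower is better. Using the mean rather than the sum keeps motifs that
#' were evaluated on different numbers of groups comparable. `fun = "sum"`
#' switches to the plain sum of logs.
#'
#' @param ranks numeric vector of fractional ranks (>= 1).
#' @param fun "mean" (default) or "sum".
#' @return the aggregate (0 when every rank is 1 under "mean").
#' @export
logRankSum <- function(ranks, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  stopifnot(length(ranks) >= 1L, all(ranks >= 1))
  if (fun == "mean") mean(log(ranks)) else sum(log(ranks))
}

#' Aggregate ranked results per motif
#'
#' @param ranked output of [rankWithinGroups()].
#' @param fun aggregation flavor passed to [logRankSum()].
#' @return named numeric vector: log-rank aggregate per motif (lower =
#'   better), sorted ascending.
#' @export
aggregateRanks <- function(ranked, fun = "mean") {
  if (nrow(ranked) == 0L) return(setNames(numeric(0), character(0)))
  agg <- vapply(split(ranked$rank, ranked$motif), logRankSum, numeric(1),
                fun = fun)
  sort(agg)
}

#' Select category and core winners per (TF, subtype)
#'
#' Within each benchmarking category the motif minimizing that category's
#' log-rank aggregate wins the (TF, subtype) slot of the category
#' subcollection. The core winner minimizes a second round of log-rank
#' aggregation over the motif's ranks across categories. Subtype ordinals
#' (0, 1, ...) are assigned within each TF by ascending core aggregate of
#' the subtype winners.
#'
#' @param categoryAggregates named list of category -> named numeric vector
#'   of per-motif aggregates (as from [aggregateRanks()]); categories are
#'   e.g. "invivo", "invitro", "rsnp".
#' @param motifInfo data.frame with columns motif, tf, subtype covering
#'   every motif present in the aggregates.
#' @return list with `categoryWinners` (data.frame tf, subtype, category,
#'   motif), `coreWinners` (data.frame tf, subtype, motif, coreAggregate,
#'   ordinal) and `secondRound` (per-motif mean-log category rank).
#' @export
selectBest <- function(categoryAggregates, motifInfo) {
  stopifnot(all(c("motif", "tf", "subtype") %in% names(motifInfo)))
  motifInfo <- unique(motifInfo[, c("motif", "tf", "subtype")])
  rownames(motifInfo) <- motifInfo$motif
  slotOf <- function(m) paste(motifInfo[m, "tf"], motifInfo[m, "subtype"],
                              sep = "|")

  ## category winners: per (TF, subtype) the motif with the lowest aggregate
  categoryWinners <- do.call(rbind, lapply(names(categoryAggregates),
                                           function(cat) {
    agg <- categoryAggregates[[cat]]
    if (length(agg) == 0L) return(NULL)
    slots <- slotOf(names(agg))
    winners <- vapply(split(seq_along(agg), slots), function(idx) {
      names(agg)[idx][which.min(agg[idx])]
    }, "")
    data.frame(tf = motifInfo[winners, "tf"],
               subtype = motifInfo[winners, "subtype"],
               category = cat, motif = unname(winners),
               row.names = NULL)
  }))

  ## second round: rank motifs within (TF, subtype, category), aggregate
  secondRows <- do.call(rbind, lapply(names(categoryAggregates),
                                      function(cat) {
    agg <- categoryAggregates[[cat]]
    if (length(agg) == 0L) return(NULL)
    data.frame(motif = names(agg), dataset = slotOf(names(agg)),
               metric = cat, sort_key = NA_character_,
               value = -agg, row.names = NULL)  # larger = better for ranking
  }))
  if (is.null(secondRows) || nrow(secondRows) == 0L)
    stop("no category aggregates to select from")
  ranked2 <- rankWithinGroups(secondRows)
  secondRound <- aggregateRanks(ranked2)

  slots <- slotOf(names(secondRound))
  coreIdx <- vapply(split(seq_along(secondRound), slots), function(idx) {
    idx[which.min(secondRound[idx])]
  }, integer(1))
  coreWinners <- data.frame(
    tf = motifInfo[names(secondRound)[coreIdx], "tf"],
    subtype = motifInfo[names(secondRound)[coreIdx], "subtype"],
    motif = names(secondRound)[coreIdx],
    coreAggregate = unname(secondRound[coreIdx]),
    row.names = NULL)
  ## subtype ordinals within each TF by ascending core aggregate
  coreWinners$ordinal <- NA_integer_
  for (tf in unique(coreWinners$tf)) {
    idx <- which(coreWinners$tf == tf)
    coreWinners$ordinal[idx][order(coreWinners$coreAggregate[idx])] <-
      seq_along(idx) - 1L
  }
  list(categoryWinners = categoryWinners, coreWinners = coreWinners,
       secondRound = secondRound)
}

#' A/B/C/D quality from experimental support
#'
#' A: the subtype is supported both in vivo (ChIP-Seq) and in vitro
#' (HT-SELEX). B: reproducible between individual experiments of one data
#' type only. C: all other cases that passed curation. D: inherited from a
#' previous release without being rediscovered.
#'
#' @param nChipseqSupport,nHtselexSupport numbers of supporting experiments.
#' @param inheritedFromPrevious flag: motif carried over from the previous
#'   release and not rediscovered.
#' @return "A", "B", "C" or "D".
#' @examples
#' assignQuality(3, 1)  # "A"
#' assignQuality(2, 0)  # "B"
#' assignQuality(1, 0)  # "C"
#' @export
assignQuality <- function(nChipseqSupport, nHtselexSupport,
                          inheritedFromPrevious = FALSE) {
  stopifnot(nChipseqSupport >= 0, nHtselexSupport >= 0)
  if (inheritedFromPrevious && nChipseqSupport == 0 && nHtselexSupport == 0)
    return("D")
  if (nChipseqSupport >= 1 && nHtselexSupport >= 1) return("A")
  if (max(nChipseqSupport, nHtselexSupport) >= 2) return("B")
  "C"
}

#' Assemble the four motif subcollections
#'
#' `core` holds the overall winners minus subtypes inapplicable to every
#' data type. `invivo` / `invitro` / `rsnp` hold their category winners
#' minus the subtypes flagged inapplicable for that category; subtypes
#' without the relevant data are retained but marked quality D
#' ("untested").
#'
#' @param selection output of [selectBest()].
#' @param evidence data.frame with columns subtype, nChipseqSupport,
#'   nHtselexSupport and optionally inheritedFromPrevious.
#' @param invivoInapplicable,invitroInapplicable,rsnpInapplicable character
#'   vectors of subtype labels to exclude from the respective
#'   subcollections.
#' @param coreExcluded subtypes to exclude from the core collection.
#' @param untestedInvivo,untestedInvitro,untestedRsnp subtypes lacking the
#'   data for the respective benchmark (kept, rated D).
#' @return named list of four data.frames (core, invivo, invitro, rsnp)
#'   with columns tf, subtype, ordinal, motif, quality.
#' @export
assembleSubcollections <- function(selection, evidence,
                                   invivoInapplicable = character(0),
                                   invitroInapplicable = character(0),
                                   rsnpInapplicable = character(0),
                                   coreExcluded = character(0),
                                   untestedInvivo = character(0),
                                   untestedInvitro = character(0),
                                   untestedRsnp = character(0)) {
  stopifnot(all(c("subtype", "nChipseqSupport", "nHtselexSupport") %in%
                  names(evidence)))
  if (is.null(evidence$inheritedFromPrevious))
    evidence$inheritedFromPrevious <- FALSE
  evidence <- unique(evidence)
  rownames(evidence) <- evidence$subtype
  qualityOf <- function(st) {
    if (!st %in% rownames(evidence)) return("C")
    e <- evidence[st, ]
    assignQuality(e$nChipseqSupport, e$nHtselexSupport,
                  e$inheritedFromPrevious)
  }
  core <- selection$coreWinners
  ordinalOf <- setNames(core$ordinal, paste(core$tf, core$subtype, sep = "|"))

  coreOut <- core[!core$subtype %in% coreExcluded,
                  c("tf", "subtype", "ordinal", "motif")]
  coreOut$quality <- vapply(coreOut$subtype, qualityOf, "")

  catTable <- function(cat, inapplicable, untested) {
    cw <- selection$categoryWinners
    tab <- cw[cw$category == cat & !cw$subtype %in% inapplicable,
              c("tf", "subtype", "motif")]
    ## untested subtypes enter from the core winners, rated D
    extra <- core[core$subtype %in% untested &
                    !core$subtype %in% tab$subtype,
                  c("tf", "subtype", "motif")]
    tab$quality <- vapply(tab$subtype, qualityOf, "")
    if (nrow(extra)) extra$quality <- "D"
    tab <- rbind(tab, extra)
    tab$ordinal <- ordinalOf[paste(tab$tf, tab$subtype, sep = "|")]
    tab[order(tab$tf, tab$ordinal), c("tf", "subtype", "ordinal", "motif",
                                      "quality")]
  }
  list(core = coreOut[order(coreOut$tf, coreOut$ordinal), ],
       invivo = catTable("invivo", invivoInapplicable, untestedInvivo),
       invitro = catTable("invitro", invitroInapplicable, untestedInvitro),
       rsnp = catTable("rsnp", rsnpInapplicable, untestedRsnp))
}
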