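test_that("rankWithinGroups averages ties and ranks within groups", {
  rows <- data.frame(motif = c("a", "b", "c", "d"),
                     dataset = "d1", metric = "auROC_flank",
                     sort_key = "signal",
                     value = c(0.9, 0.8, 0.8, 0.1))
  rk <- rankWithinGroups(rows)
  expect_equal(rk$rank, c(1, 2.5, 2.5, 4))

  ## single motif in a group ranks 1
  one <- data.frame(motif = "a", dataset = "d2", metric = "m",
                    sort_key = NA, value = 0.2)
  expect_equal(rankWithinGroups(one)$rank, 1)

  ## permuting input order does not change assigned ranks
  perm <- rows[c(3, 1, 4, 2), ]
  rkPerm <- rankWithinGroups(perm)
  expect_equal(rkPerm$rank[match(rows$motif, rkPerm$motif)], rk$rank)
})

test_that("logRankSum is the mean of log ranks with a sum option", {
  expect_equal(logRankSum(c(1, 1, 1)), 0)
  expect_equal(logRankSum(c(2, 8)), mean(log(c(2, 8))))
  expect_equal(logRankSum(c(2, 8), fun = "sum"), sum(log(c(2, 8))))
  ## symmetric rank profiles aggregate equally
  expect_equal(logRankSum(c(1, 2)), logRankSum(c(2, 1)))
})

test_that("log-rank aggregation respects dominance", {
  set.seed(5)
  for (i in 1:200) {
    nGroups <- sample(2:6, 1)
    rA <- sample(1:10, nGroups, replace = TRUE)
    rB <- rA + sample(0:3, nGroups, replace = TRUE)
    if (all(rB == rA)) rB[1] <- rA[1] + 1
    expect_lt(logRankSum(rA), logRankSum(rB))
  }
})

test_that("aggregation is invariant to group enumeration order", {
  set.seed(8)
  rows <- expand.grid(motif = c("a", "b", "c"),
                      dataset = c("d1", "d2"),
                      metric = c("m1", "m2"),
                      stringsAsFactors = FALSE)
  rows$sort_key <- "k"
  rows$value <- runif(nrow(rows))
  agg1 <- aggregateRanks(rankWithinGroups(rows))
  rows2 <- rows[sample(nrow(rows)), ]
  rows2$metric <- chartr("m", "z", rows2$metric)  # rename metrics
  agg2 <- aggregateRanks(rankWithinGroups(rows2))
  expect_equal(agg1, agg2[names(agg1)])
})

test_that("selectBest picks category and core winners per (TF, subtype)", {
  info <- data.frame(motif = c("m1", "m2", "m3"),
                     tf = "TF1", subtype = c("s1", "s1", "s2"))
  ## m1 better in vivo, m2 better in vitro, m1 better on aggregate
  aggs <- list(invivo = c(m1 = 0.1, m2 = 0.9, m3 = 0.5),
               invitro = c(m1 = 0.8, m2 = 0.2, m3 = 0.4))
  sel <- selectBest(aggs, info)
  cw <- sel$categoryWinners
  expect_equal(cw$motif[cw$category == "invivo" & cw$subtype == "s1"], "m1")
  expect_equal(cw$motif[cw$category == "invitro" & cw$subtype == "s1"], "m2")
  ## m3 alone in s2 wins everywhere
  expect_true(all(cw$motif[cw$subtype == "s2"] == "m3"))
  ## core: m1 and m2 tie on category ranks (1+2 vs 2+1); deterministic pick
  core <- sel$coreWinners
  expect_equal(nrow(core), 2L)
  ## ordinals are 0..k-1 within the TF
  expect_setequal(core$ordinal, c(0L, 1L))

  ## dominance: motif best in every category wins the core slot
  aggs2 <- list(invivo = c(m1 = 0.1, m2 = 0.9),
                invitro = c(m1 = 0.2, m2 = 0.8))
  sel2 <- selectBest(aggs2, info[1:2, ])
  expect_equal(sel2$coreWinners$motif, "m1")
  expect_equal(sel2$coreWinners$ordinal, 0L)
})

test_that("assignQuality reproduces the rating truth table", {
  expect_equal(assignQuality(3, 1), "A")
  expect_equal(assignQuality(1, 1), "A")
  expect_equal(assignQuality(2, 0), "B")
  expect_equal(assignQuality(0, 5), "B")
  expect_equal(assignQuality(1, 0), "C")
  expect_equal(assignQuality(0, 1), "C")
  expect_equal(assignQuality(0, 0), "C")
  expect_equal(assignQuality(0, 0, inheritedFromPrevious = TRUE), "D")
  ## rediscovered inherited motifs are rated on their new evidence
  expect_equal(assignQuality(1, 1, inheritedFromPrevious = TRUE), "A")

  ## pure function: property check over a grid
  for (chip in 0:3) for (selex in 0:3) {
    q <- assignQuality(chip, selex)
    want <- if (chip >= 1 && selex >= 1) "A"
            else if (max(chip, selex) >= 2) "B" else "C"
    expect_equal(q, want)
  }
})

test_that("assembleSubcollections applies exclusions and D-for-untested", {
  info <- data.frame(motif = c("m1", "m2"), tf = "TF1",
                     subtype = c("s1", "s2"))
  aggs <- list(invivo = c(m1 = 0.1, m2 = 0.3),
               invitro = c(m1 = 0.2, m2 = 0.6))
  sel <- selectBest(aggs, info)
  ev <- data.frame(subtype = c("s1", "s2"),
                   nChipseqSupport = c(1L, 1L),
                   nHtselexSupport = c(1L, 0L))
  cols <- assembleSubcollections(
    sel, ev,
    invivoInapplicable = "s2",
    untestedRsnp = "s2")
  expect_setequal(cols$core$subtype, c("s1", "s2"))
  expect_equal(cols$core$quality[cols$core$subtype == "s1"], "A")
  expect_equal(cols$core$quality[cols$core$subtype == "s2"], "C")
  ## s2 inapplicable in vivo: absent from invivo
  expect_false("s2" %in% cols$invivo$subtype)
  ## s2 untested for rSNPs: present with quality D
  expect_equal(cols$rsnp$quality[cols$rsnp$subtype == "s2"], "D")
  ## core exclusion removes the subtype entirely
  cols2 <- assembleSubcollections(sel, ev, coreExcluded = "s2")
  expect_false("s2" %in% cols2$core$subtype)
})
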