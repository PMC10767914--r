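rsnpFixture <- local({
  gt <- groundTruth(seed = 303)
  pwm <- gt@truePwm
  pwm@name <- "planted"
  dist <- scoreDistribution(pwm)
  list(gt = gt, pwm = pwm, dist = dist)
})

test_that("deltaLogp is zero for null substitutions and antisymmetric", {
  pwm <- rsnpFixture$pwm
  d <- rsnpFixture$dist
  rec <- data.frame(id = "x", context = "ACGTACGTACGTACG", pos = 8,
                    ref = "T", alt = "T")
  expect_equal(deltaLogp(pwm, d, rec), 0)

  ## swapping ref/alt flips the sign exactly
  recAB <- data.frame(id = "x", context = "ACGTACGTACGTACG", pos = 8,
                      ref = "T", alt = "G")
  ctxSwap <- "ACGTACGGACGTACG"  # the alt allele substituted in
  recBA <- data.frame(id = "x", context = ctxSwap, pos = 8,
                      ref = "G", alt = "T")
  expect_equal(deltaLogp(pwm, d, recAB), -deltaLogp(pwm, d, recBA))

  ## a variant under uniform (uninformative) columns has no effect
  uni <- PositionWeightMatrix("uni", rbind(c(2, -2, -2, -2), c(0, 0, 0, 0)))
  dU <- scoreDistribution(uni)
  recU <- data.frame(id = "u", context = "TTTATTTT", pos = 5, ref = "T",
                     alt = "C")
  ## pos 5 can only sit under the uniform column when the A column is at 4
  expect_equal(deltaLogp(uni, dU, recU), 0)
})

test_that("snpSelexBench recovers the generator and applies the 10-positive rule", {
  gt <- rsnpFixture$gt
  pwm <- rsnpFixture$pwm
  rec <- genSnpSelex(gt, 120, seed = 9)
  out <- snpSelexBench(list(pwm), rec)
  vals <- setNames(out$results$value, out$results$metric)
  expect_gt(vals[["auROC_snpselex"]], 0.6)
  expect_gt(vals[["tau_snpselex"]], 0)
  expect_gt(vals[["rho_snpselex"]], 0)
  expect_true(out$applicable[["planted"]])

  ## noise-free effects give perfect correlation
  gt0 <- groundTruth(seed = 303, effectNoiseSd = 0)
  pwm0 <- gt0@truePwm
  pwm0@name <- "planted"
  rec0 <- genSnpSelex(gt0, 80, seed = 10)
  out0 <- snpSelexBench(list(pwm0), rec0)
  v0 <- setNames(out0$results$value, out0$results$metric)
  expect_equal(v0[["tau_snpselex"]], 1, ignore_attr = TRUE)
  expect_equal(v0[["rho_snpselex"]], 1, ignore_attr = TRUE)

  ## sign-flipped measurements give negative correlation
  recFlip <- rec0
  recFlip$exp_logp <- -recFlip$exp_logp
  outF <- snpSelexBench(list(pwm0), recFlip)
  expect_lt(outF$results$value[outF$results$metric == "rho_snpselex"], 0)

  ## 9 positives: the test set is skipped
  rec9 <- rec[rec$label == "positive", ][1:9, ]
  rec9 <- rbind(rec9, rec[rec$label == "negative", ][1:20, ])
  out9 <- snpSelexBench(list(pwm), rec9)
  expect_equal(out9$skipped, "batch1")
  expect_equal(nrow(out9$results), 0L)
})

test_that("asbCandidateFilter enforces the strict P < 0.0005 bound", {
  pwm <- rsnpFixture$pwm
  d <- rsnpFixture$dist
  gt <- rsnpFixture$gt
  rec <- genAsb(gt, 40, seed = 11)
  cand <- asbCandidateFilter(pwm, d, rec)
  expect_true(all(pmin(cand$p_ref, cand$p_alt) < 5e-4))

  ## a weak-context record is dropped even at P = 0.01
  set.seed(2)
  weak <- data.frame(id = "w", context = randomSeq(30, 12345), pos = 15,
                     ref = NA, alt = "A")
  weak$ref <- substr(weak$context, 15, 15)
  weak$alt <- setdiff(BASES, weak$ref)[1]
  pv <- allelePvalues(pwm, d, weak$context, 15, weak$ref, weak$alt)
  if (min(pv) >= 5e-4) {
    expect_equal(nrow(asbCandidateFilter(pwm, d, weak)), 0L)
  }

  ## boundary: exactly at the threshold is excluded (strict <)
  fake <- rec[1, ]
  got <- asbCandidateFilter(pwm, d, fake, pThresh = min(
    allelePvalues(pwm, d, fake$context, fake$pos, fake$ref, fake$alt)))
  expect_equal(nrow(got), 0L)
})

test_that("asbPartition splits by min-FDR rules into disjoint sets", {
  rec <- data.frame(id = c("a", "b", "c"),
                    context = "ACGTACGT", pos = 1, ref = "A", alt = "C",
                    fdr_ref = c(0.01, 0.7, 0.2),
                    fdr_alt = c(0.9, 0.8, 0.3))
  part <- asbPartition(rec)
  expect_equal(part$positives$id, "a")
  expect_equal(part$neutral$id, "b")
  expect_false("c" %in% c(part$positives$id, part$neutral$id))
  expect_length(intersect(part$positives$id, part$neutral$id), 0)
})

test_that("asbBench finds concordance for the generator and skips tiny sets", {
  gt <- rsnpFixture$gt
  pwm <- rsnpFixture$pwm
  d <- rsnpFixture$dist
  rec <- genAsb(gt, 120, seed = 12)
  cand <- asbCandidateFilter(pwm, d, rec)
  part <- asbPartition(cand)
  res <- asbBench(pwm, d, part$positives, part$neutral)
  expect_false(res$skipped)
  expect_gt(res$tau, 0)
  expect_gt(res$rho, 0)
  expect_lt(res$fisher_p, 0.05)
  expect_true(res$applicable)

  ## 9 positives: skipped
  res9 <- asbBench(pwm, d, part$positives[1:9, ], part$neutral)
  expect_true(res9$skipped)
  expect_false(res9$applicable)

  ## a decoy is not applicable (its candidates rarely reach 10 positives,
  ## and when they do the concordance is random)
  decoy <- genDecoys(gt, 1, seed = 13)[[1]]
  dD <- scoreDistribution(decoy)
  candD <- asbCandidateFilter(decoy, dD, rec)
  partD <- asbPartition(candD)
  resD <- asbBench(decoy, dD, partD$positives, partD$neutral)
  expect_false(isTRUE(resD$applicable))
})

test_that("rsnpApplicability applies the both-rule and the core rule", {
  snp <- c(stA = FALSE, stB = FALSE, stC = TRUE)
  asb <- c(stA = TRUE, stB = FALSE, stC = NA)
  ## stA fails SNP-SELEX but passes ASB: kept in rsnp
  out <- rsnpApplicability(snp, asb)
  expect_false("stA" %in% out$dropFromRsnp)
  ## stB fails both: dropped from rsnp
  expect_true("stB" %in% out$dropFromRsnp)

  ## core rule: inapplicable to every data type with data
  out2 <- rsnpApplicability(
    snp, asb,
    invivoStatus = c(stA = "inapplicable", stB = "inapplicable",
                     stC = "applicable"),
    invitroStatus = c(stA = "untested", stB = "inapplicable",
                      stC = "untested"))
  expect_true("stB" %in% out2$dropFromCore)
  expect_false("stC" %in% out2$dropFromCore)
  expect_false("stA" %in% out2$dropFromCore)  # ASB-applicable

  ## a subtype with no rSNP data at all is untested, not inapplicable
  out3 <- rsnpApplicability(c(stD = NA), c(stD = NA))
  expect_false("stD" %in% out3$dropFromRsnp)
})
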