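---
title: "Benchmarking and selecting TF binding motifs with pwmbench"
author: "pwmbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking and selecting TF binding motifs with pwmbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmbench)
```

## The problem

Large motif collections are assembled by generating many candidate position
weight matrices (PWMs) per transcription factor (TF) — from ChIP-Seq peak
sets, from HT-SELEX read pools, across parameterizations — and then picking,
for each TF and each distinct binding pattern ("motif subtype"), the matrix
that best predicts independent experimental evidence. pwmbench implements
that evaluation-and-selection machinery: sequence-set preparation, three
families of benchmarks (in vivo, in vitro, regulatory variants), rank
aggregation, quality ratings and subcollection assembly. Motif *discovery*
is out of scope; the package consumes candidate matrices.

Because the full evaluation corpus behind a production motif collection is
terabyte-scale, every component here is exercised on seeded synthetic data
with known ground truth. The generators are first-class, tested code: they
let any user verify that each benchmark detects what it claims to detect
before trusting it on real data.

## The PWM model and exact P-values

A PWM of length $L$ assigns each window $s_1 \dots s_L$ the score
$S = \sum_i w(i, s_i)$. Count matrices are converted to weights by

$$ w(i,b) = \ln \frac{c(i,b) + \kappa p_b}{(W + \kappa)\, p_b} $$

with counts $c$, word count $W$, background frequencies $p_b$ and
pseudocount weight $\kappa$. The default $\kappa = \max(1, \ln W)$ scales
smoothing with the (log) depth of the alignment; it is a configurable
convention, not a claim about any upstream collection's internals, which are
unpublished.

`scoreDistribution()` computes the exact distribution of the single-window
score of a random $L$-mer drawn i.i.d. from the mononucleotide background,
by convolving per-position score distributions over discretized bins.
Weights are rounded to the nearest multiple of a step $\varepsilon$
(default: $10^{-3}$ of the total score range). Rounding to nearest (not
flooring) keeps P-values stable under sign flips of the weights. All
P-value queries — `pvalueOfScore()`, `thresholdForPvalue()`,
`allelePvalues()` — operate on this discretized scale, and scanning done in
the service of a P-value query rounds the weights to the same grid, so an
observed score is always achievable under the distribution and P-values are
never zero. The discretization error of a P-value at
$\varepsilon = 10^{-3}$ of the score range is negligible relative to the
benchmark decisions made from it (the unit tests verify agreement with
exhaustive $4^L$ enumeration to $10^{-9}$).

Scanning (`bestHit()`) considers every window on both strands; ties prefer
the smaller offset, then the plus strand, so outputs are deterministic. An
`N` in the sequence contributes the background-expected weight of the
matrix column it meets — neutral by construction, so the `NN`-padded
adapter extensions used for HT-SELEX reads neither create nor destroy hits.

## Sequence-set preparation

**ChIP-Seq.** Peaks are ranked by peak height (`signal`) or reported
statistical significance and the top 1000 retained; each retained peak
contributes a 301-bp window centered on its summit (windows truncated by
chromosome ends are dropped). Negatives are same-width windows 300 bp
beyond each window edge, discarded when they collide with any positive
window or a chromosome end. Coordinates are 0-based half-open throughout;
peaks lacking an explicit summit get the interval midpoint.

**HT-SELEX.** Reads are pooled either across all cycles or from cycle 3
onward (late pools resemble the consensus better; early pools retain
diversity). Singleton reads are removed. Unique reads are ranked by 5-mer
enrichment against a dinucleotide-preserving shuffle of each N-free read
(Altschul–Erickson Euler-path shuffle, exact dinucleotide counts and
terminal bases preserved; one shuffle per read keeps per-read composition
exact). The enrichment of a 5-mer $m$ is
$\ln\{(\mathrm{obs}(m)+1)/(\mathrm{bg}(m)+1)\}$; a read's score is the
*mean* over its 5-mers — robust to read-length differences, with +1
smoothing avoiding $\ln 0$. How per-read aggregation and the number of
shuffles should be chosen is not pinned down by any published protocol;
mean-over-kmers and one-shuffle-per-read are this package's defaults.
Finally reads are extended with `NN` plus the constant adapter base on each
side, letting motif occurrences overhang the random insert by up to 3 bp.

## The benchmarks

**In vivo (ChIP-Seq), three protocols.** (1) `benchFlank()`: best-hit
scores on summit windows versus flanking negatives, summarized as auROC and
step-interpolated auPRC, run once per peak-ranking key. (2)
`benchPseudo()`: negatives are sampled from a first-order Markov model
fitted to the positives (matching their dinucleotide composition);
`pseudo_auROC` is the resulting auROC, and the asymptotic
`pseudo_au_logROC` needs no sampled negatives at all — it averages, over 50
log-uniformly spaced P-value cutoffs $p \in [10^{-5}, 10^{-2}]$, the
fraction of positives whose best-hit P-value is at most $p$. The two
pseudo-variant definitions reconstruct the quoted protocol names from their
description; the original grids and negative counts are not recoverable, so
both are configurable. (3) `benchCentrality()`: for half-widths $w = 5, 10,
\dots$ bp around the window center, the count of best-hit centers within
$\pm w$ is compared against the fraction of possible hit centers in that
band by an upper binomial tail; the E-value is the minimal tail probability
times the number of tested half-widths (a Bonferroni correction), reported
as $-\log_{10} E$. This follows the construction of motif-centrality
E-values, not any specific tool's window enumeration.

Datasets with fewer than 100 peaks, and datasets on which no tested motif
reaches auROC ≥ 0.6, are excluded from ranking; subtypes whose motifs never
reach auROC ≥ 0.6 are flagged inapplicable to ChIP-Seq data and excluded
from the in-vivo subcollection.

**In vitro (HT-SELEX).** Up to 500 000 unique reads are used; the top 10%,
25% or 50% by the *experiment-level* 5-mer enrichment score are the
positives, and each motif's best-hit score is the classifier. Ranking
positives by the tested PWM itself would make the benchmark self-fulfilling;
tying the positive set to the experiment-level enrichment keeps it fixed
across motifs (this reading of the protocol is switchable). The same
auROC ≥ 0.6 applicability rule governs the in-vitro subcollection.

**Regulatory SNVs.** The predicted allelic effect of a variant is
$\Delta = \log_{10} P_{\mathrm{alt}} - \log_{10} P_{\mathrm{ref}}$ of the
best PWM hits overlapping the variant (positive = reference allele better
bound). Against SNP-SELEX-style measurements, $|\Delta|$ classifies
positive versus negative variants (auROC/auPRC) and signed $\Delta$ is
correlated (Kendall $\tau_b$, Pearson $\rho$) with the measured
differential-binding log-P over positives; test sets need at least ten
positives, and a motif is applicable at auROC ≥ 0.6 with both
$\tau_b > 0$ and $\rho > 0$. Against allele-specific binding (ASB) data,
candidate variants must overlap a motif occurrence (allelic P-value
< 0.0005, strict); positives have minimal allelic FDR < 0.05, neutrals
have both FDRs > 0.5 (the min-over-alleles reading keeps the two sets
disjoint), and the remainder is discarded. The observed effect is encoded
as $\log_{10}\mathrm{FDR}_{\mathrm{alt}} -
\log_{10}\mathrm{FDR}_{\mathrm{ref}}$, which makes a more significant
reference-allele bias positive, matching $\Delta$'s sign convention.
Concordance of predicted and observed signs is tabulated for positives and
neutrals and tested with a one-sided (greater) Fisher exact test — the
question is specifically whether concordance among positives exceeds the
neutral baseline, hence the one-sided default (switchable). Applicability
requires Fisher P < 0.05 with $\tau_b > 0$ and $\rho > 0$. Subtypes
inapplicable to both rSNP sources leave the rSNP subcollection; subtypes
applicable to no data type at all leave the core collection.

## Aggregation, ratings, subcollections

Within every (dataset, metric, ranking-key) group, motifs receive
fractional ranks (descending by value, ties averaged). A motif's category
aggregate is the mean of $\ln(\mathrm{rank})$ over its groups — the mean
rather than the sum, because motifs evaluated on different numbers of
groups must stay comparable; on equal coverage the two orderings coincide,
and `logRankSum(fun = "sum")` restores the plain sum. Missing (motif,
group) pairs are simply absent from the mean; the applicability filters
have already removed uninformative groups. Category winners per (TF,
subtype) form the in-vivo, in-vitro and rSNP subcollections; a second
round of rank aggregation across categories picks the core winner, and
subtype ordinals (0, 1, ...) within a TF follow the core aggregate.

Quality ratings are a pure function of experimental support: **A** when a
subtype is supported both in vivo and in vitro, **B** when reproducible
across experiments of a single data type, **C** otherwise, **D** for
motifs inherited without rediscovery or untested on a subcollection's data
type.

## What the synthetic generators emulate — and what they do not

`groundTruth()` fixes a planted motif (Dirichlet-drawn count matrix,
word count 1000) and the study conditions: 80% of peaks carry a site
(`plantRate`), sites scatter around summits with SD 10 bp
(`positionalSd`), and variant-effect measurements carry Normal noise with
SD 0.25 on the $\log_{10}$ P scale (`effectNoiseSd`). `genChipseq()`
writes a first-order-chain genome with non-overlapping peaks whose signal
and significance correlate with the planted site's strength;
`genSelex()` grows cycle-wise enrichment by logistic selection on the
planted motif's best-hit score (midpoint at its P = $10^{-3}$ threshold —
partial enrichment rather than consensus collapse) followed by 1%
per-base mutation; `genSnpSelex()` and `genAsb()` place variants inside
planted sites and derive measurements from the true allelic effect. Test
sets default to 250 variants per batch, the scale at which a real
differential-binding assay stabilizes its estimates; ASB tables default
to 120 records so the ten-positive rule is met after candidate filtering.
Defining variant ground truth through the same `deltaLogp()` operation
being tested is deliberate and safe here because the downstream checks
compare rankings, signs and applicability decisions, not reproduction of
the generator's arithmetic.

What the generators do **not** emulate: real genome backgrounds (repeats,
CpG islands, ALU-family artifacts), antibody or peak-caller biases,
cycle-specific SELEX chemistry including methylated ligands, linkage
between nearby variants, or human curation. A benchmark passing on these
fixtures therefore demonstrates that the machinery measures what it claims
under controlled conditions — not that any particular real-data collection
is optimal.

## Numerical choices and degenerate inputs

* Discretization rounds to nearest; the default step adapts to the score
  range; a zero-range (constant) matrix falls back to a fixed step.
* `thresholdForPvalue()` returns the support maximum plus one step when no
  achievable score satisfies the bound, so the round trip
  `pvalueOfScore(thresholdForPvalue(p)) <= p` always holds.
* Empty sets fail loudly: all-singleton read pools, late-cycle pooling
  without a cycle ≥ 3, summit windows that all fall off chromosome ends,
  and flank sets emptied by overlap all raise errors rather than returning
  silently empty results.
* Correlation metrics signal degenerate (constant) input instead of
  returning NA silently; the benchmarks catch that signal and mark the
  motif "not applicable" with the reason retained.
* All randomness flows through explicit integer seeds; reruns are
  byte-identical, which the test suite verifies on full pipeline output.

## Problem sizes used in the packaged studies

The packaged synthetic studies run at 500 peaks (benchmarks use up to the
top 1000, so every peak participates), 2000 reads per SELEX cycle over 4
cycles, 250 SNP-SELEX variants per batch and 120 ASB records, with 3 decoy
motifs per study; planted-motif recovery is evaluated over 20 seeded
replicates. These sizes give the benchmarks enough resolution for stable
rankings while keeping a complete run of the pipeline in seconds on a
laptop.

## A worked run

```{r pipeline, eval = FALSE}
out <- runPipeline(seed = 1, outDir = "collection")
out$collections$core
#    tf subtype ordinal   motif quality
#  TF1    main       0 planted       A
```

The core manifest names the planted motif as the subtype-0 winner with an
A rating (it is supported by both the synthetic ChIP-Seq and the synthetic
HT-SELEX experiment); decoy-only subtypes fail the auROC ≥ 0.6
applicability bars and drop out of the collections they are inapplicable
to.

## Known limitations

* Dinucleotide PWMs are out of scope by design; the scanning and P-value
  machinery is strictly mononucleotide.
* The score distribution always uses the mononucleotide background, even
  when a first-order model is available for sequence generation — P-values
  stay closed-form, at the cost of ignoring dinucleotide structure in the
  null.
* The benchmarks share sequence data with whatever produced the candidate
  motifs upstream (no train/test split); cross-dataset evaluation is the
  intended safeguard, as in the protocols this package implements.
* Centrality E-values follow the binomial construction, not any specific
  tool's local-maxima window enumeration; absolute values are comparable
  within a run, not across tools.
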