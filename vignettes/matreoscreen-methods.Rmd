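---
title: "Methods: matrisome signatures, drug concordance and reporter dose selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrisome signatures, drug concordance and reporter dose selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matreoscreen)
```

## The problem

Expression of extracellular-matrix (ECM) genes drifts with age: collagens
decline while matrix proteases (MMPs, ADAMs) rise. The matrisome — the
catalogue of roughly a thousand ECM and ECM-associated genes in six
categories (collagens, glycoproteins, proteoglycans, ECM regulators,
secreted factors, ECM-affiliated) — therefore carries a compact ageing
signature, sometimes called a *matreotype*. `matreoscreen` implements a
drug-repurposing workflow built on that observation:

1. estimate per-gene age associations in age-stratified cohorts and
   assemble a multi-source consensus *aged* signature, invertible to its
   *youthful* mirror;
2. score compound perturbation profiles (drug-by-gene differential
   expression z-scores) for overall matrisome regulation and for
   concordance with the signature, compiling top-k hit lists and a
   lifespan-flag enrichment;
3. model a collagen promoter-driven GFP reporter in *C. elegans*, whose
   near-linear decline over adulthood days 1–5 serves as a surrogate
   longevity marker, to pick a working dose per compound.

Because the upstream resources (age-stratified human transcriptomes,
compound perturbation libraries, curated lifespan databases) cannot ship
with a package, a synthetic-data module generates every input with planted
ground truth. All validation claims in this package are claims about
recovery of planted structure, not about any external dataset.

## Age associations and the consensus signature

For each gene the old donor group (by default the two oldest brackets) is
compared against the young group (two youngest). Two change statistics are
kept: the **absolute** change `mean_old − mean_young` on the expression
scale, which favours highly expressed genes, and the **relative** change
`(mean_old − mean_young)/mean_young`, which favours low-expressed genes.
Both agree in sign whenever the young mean is positive; a zero young mean
makes the relative change undefined and the gene is excluded from relative
rankings. Significance comes from Welch's t test on `log(x + 1)` values —
the published screen inherits its significance calls from upstream studies
and fixes only the FDR threshold, so the test is a replaceable strategy
behind one interface. `bh_adjust()` implements Benjamini–Hochberg step-up
explicitly (`q_(i) = min_{j≥i} n·p_(j)/j`) and is checked against a
brute-force oracle; adjustment is applied per tissue, not pooled.

`build_compendium()` merges per-source directional calls: a gene enters
the signature when at least `min_sources` (default 3) sources support it;
its direction is the strict majority among directional sources. Sources
reporting association without direction count toward support but abstain
from the vote. Exact ties — the behaviour tissue-dependent genes such as
GDF15 show — are excluded and recorded as conflicts rather than
arbitrated, because no principled tie-break exists at this granularity.
The result is invariant to source ordering. `invert_signature()` flips
every direction and toggles the aged/youthful kind; it is an involution.

The inclusion channel (absolute, relative, or their union) is
configurable in `associations_to_source()`. We default to the absolute
channel: with positive young means the relative channel selects a subset
of the same significant genes, so the union equals the absolute channel
and the distinction only matters for ranking, which the consensus step
does not use.

## Drug scoring

**Matrisome regulation.** The per-compound score standardizes the mean
z-score over matrisome genes against size-matched random gene sets drawn
from the *same* profile, controlling for drug-wide expression shifts:
`score = (mean(z[M]) − mean_null)/sd_null`. When `choose(|U|, |M|)` is
small (≤ 1e5) the null is enumerated exactly. Otherwise the null mean is
estimated from `n_null` (default 1000) uniform draws under one seeded
stream, while the null standard deviation uses the closed form for the
mean of a simple random sample without replacement,
`sqrt(S²/m · (1 − m/N))`: estimating the sd from draws would add error
proportional to the score itself, and the exhaustive enumeration's
population sd equals the closed form anyway. An all-constant profile has a
degenerate null and scores 0 with a flag. Under a fully null library the
scores are approximately standard normal, so the fraction beyond ±1.5
approaches `2·Φ(−1.5) ≈ 0.134`; compounds beyond ±1.5 are classified
`increased`/`decreased` (strong regulators), the rest `minor`.

**Signature concordance.** The score is the signed mean of z over
signature genes (weight −1 for genes up with age, +1 for genes down with
age), so positive *reversed* scores mean the drug pushes the signature
toward youth; the *potentiated* score is the exact negation, and the
reversed score on the aged signature equals the potentiated score on the
youthful one identically — a consistency the acceptance suite asserts
exactly. We deliberately use this simplest monotone statistic rather than
a weighted Kolmogorov–Smirnov enrichment: the published method describes
correlating expression patterns and taking the top 50 without a formula,
and the scoring function is isolated behind one interface should a KS
mode be wanted. Signature genes missing from the measured universe are
dropped with a message (in the real screen only 594 of 1027 matrisome
genes were quantified; the package mirrors that behaviour, not the
number). Ranking is deterministic: descending score, alphabetical
tie-break, prefix-stable in k.

The four top-k lists (2 halves × reversed/potentiated) are compiled into a
hit compendium; the overlap count is the number of compounds selected by
both the reversed and the potentiated side. Lifespan-flag enrichment of
the unique hits against the library background uses the upper-tail
hypergeometric test, checked against brute-force enumeration. Heatmap
export orders rows and columns by average-linkage agglomerative
clustering on `1 − Pearson` distance; zero-variance rows or columns get
the maximal distance (2) and are flagged.

## Literature mining

`filter_lifespan()` keeps compounds whose best reported mean lifespan
extension is *strictly* above 5% ("above" read as a strict inequality;
the boundary case is tested). `keyword_hits()` matches the ten canonical
ECM keywords (collagen, ECM, extracellular, matrix, proteoglycan,
hyaluronic, hyaluronan, TGF, integrin, TGFbeta) case-insensitively by
token prefix — a keyword matches any word token beginning with it, so
"TGF" matches "TGFbeta" — and counts each keyword once. Whether published
keyword counts were distinct-keyword or total-occurrence counts is not
knowable from the figure legends; distinct counting is the default and an
occurrence mode is available (`distinct = FALSE`). Abstract retrieval is
out of scope; abstracts arrive as a table column.

## Reporter assay

Intensities are binned into four ordered categories by half-open
intervals at three cutoffs; the packaged default derives the cutoffs from
the day-1 control quartiles, a reproducible stand-in for visual-inspection
binning, which published no numeric thresholds. Decline is fit by
ordinary least squares of per-day mean intensity on day (slope in
intensity units per day; scale-equivariant). The treated-vs-control
effect at the scoring day (default day 4 of adulthood, the most common
published readout; configurable for late readouts such as day 5) is the
difference in means over the pooled SD, with a Wilcoxon–Mann–Whitney
p-value — robust to the skewed distributions the 4-bin scoring implies;
the published statistics behind the reporter panels are not described, so
the test is pluggable. `select_dose()` BH-adjusts across doses and picks
the maximal positive significant effect, ties to the lowest dose, `NA`
when nothing qualifies — encoding the observation that dose–response
curves are often U- or J-shaped, so a single pre-chosen dose produces
false negatives.

## The synthetic world

The generator defaults are the stated world of the desk-scale screen and
are not tuned to test outcomes:

* **Cohorts** (`cohort_config()`): six decade brackets (20s–70s,
  midpoints 25–75), 30 donors per bracket, five tissues (skin, thyroid,
  pituitary, aorta, coronary artery — the tissues with usable age
  signal), 200 genes of which 40 matrisome, residual log-scale SD 0.5,
  planted end-to-end shift 1.0 (= 2 × noise SD, the regime under which
  ≥ 90% planted-gene recovery is asserted), 25% of matrisome genes
  planted up and 25% down. The age effect is linear in the bracket
  midpoint — not a two-group shift — so both the absolute and the
  relative estimator are exercised on ordinal brackets; simulation is on
  the log scale and exponentiated, guaranteeing positive baselines.
* **Drug libraries** (`drug_library_config()`): 500 compounds × 200
  genes, background z i.i.d. standard normal, 20 planted reversed and 20
  planted potentiated drugs at per-gene offset `delta = 1`, lifespan
  flags Bernoulli with base rate 5% (the background rate in the
  published library) and planted rate 25%, chosen once so that a top-50
  list containing roughly 40% planted drugs shows a low-teens hit-list
  percentage against the 5% background — the published enrichment
  pattern. Flags are independent given planted status, the simplest
  model producing that pattern.
* **Reporter** (`reporter_config()`): intercept 6, decline 1 intensity
  unit/day over days 1–5 (near-linear decline, zero-truncated), noise SD
  0.2, 50 animals per arm, doses 1/5/10/50/100 with a Gaussian dose
  response centred at 10 (width 5) and maximal slowing 0.5 units at the
  final day — a single-optimum shape compatible with U/J-shaped
  dose–response curves.

What the generators do **not** emulate: realistic expression covariance,
batch effects, dropout, tissue-specific signatures, or pharmacology. A
green recovery test therefore establishes that the pipeline's inference
machinery recovers the structure it assumes, at the stated effect sizes —
not that it would recover signal in any particular real dataset.

## Numerical choices and degenerate inputs

* All generators run in a private RNG stream and restore the caller's
  state; the pipeline derives per-stage seeds from one root seed, and
  every output artifact carries an md5 hash of the effective config.
* Zero-variance genes in the t test: p = 1 when the group means agree,
  p = 0 otherwise (a noiseless certain difference).
* Degenerate regulation nulls score 0 with a flag; degenerate
  prolongation comparisons (no variance in either arm) return effect 0,
  p = 1, flagged.
* Ties: compound ranking breaks ties alphabetically; dose selection
  breaks effect ties toward the lowest dose; direction votes that tie are
  excluded as conflicts.
* Dose units are opaque strings, carried through but never converted.

## Known limitations

The signature stage ships no tissue-specific catalogues (a stated
shortcoming of the multi-tissue consensus approach); the concordance
score is unweighted; the literature module does no retrieval or
curation; and the dataset-dependent headline counts of the original
screen (167 strong regulators, the 99-gene compendium, 594 quantified
matrisome genes) are not reproducible without the external resources and
are replaced by in-package arithmetic anchors and planted-signal
recovery, computed by the test suite and `scripts/acceptance.R`.
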