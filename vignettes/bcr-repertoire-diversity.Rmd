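---
title: "Clonal networks, diversity recovery and MRD tracking in BCR repertoires"
author: "bcrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal networks, diversity recovery and MRD tracking in BCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrnet)
```

## The problem

Germinal centers (GCs) are where naive B cells proliferate and diversify
their receptors through somatic hypermutation (SHM). Malignant B cells
residing in or near GCs suppress this diversification, so the clonal
diversity of the peripheral B cell receptor (BCR) repertoire — and in
particular the *rate* at which diversity recovers after the lymphocytic
pool has been ablated and re-established by high-dose therapy with
autologous stem cell rescue (HDT-ASCR) — carries a prognostic signal for
residual disease. `bcrnet` implements the analysis chain for this setting:
clonal network construction from CDR3 nucleotide sequences, diversity
indices normalized to a healthy cohort, tumor-clone (MRD) tracking by edit
distance, and ROC discrimination of relapse by the diversity recovery
ΔSDI. Because the raw sequencing data behind such studies are rarely
available at desk scale, the package also ships first-class simulators
that generate inputs with the statistical structure the analysis assumes.

## Clonal networks

A repertoire is a set of clonotypes: unique (CDR3 nucleotide sequence,
V gene, J gene) records with read counts. In the network, *vertex identity
is the CDR3 nucleotide sequence alone* — V/J calls are metadata, and
counts are aggregated over them. Edges join vertices that differ by a
single nucleotide; a clone (cluster) is a connected component, i.e. a
lineage of sequences linked by chains of single point mutations.

Two neighbour rules are provided. The default, `hamming1`, reads "single
nucleotide difference" as a point mutation: equal length and Hamming
distance exactly 1. Since SHM produces substitutions overwhelmingly more
often than indels, this is the default; `levenshtein1` additionally
accepts a single insertion or deletion for data where junction-length
variants should merge. Equal-length pairs at edit distance 1 are exactly
the Hamming-1 pairs, so the second rule only adds pairs whose lengths
differ by one.

Neighbour search does not compare all pairs. Each sequence emits one
*masked key* per position (the sequence with that position wildcarded);
two unique sequences share a key if and only if they differ exactly at the
masked position. Keys are encoded as base-4 digit words in
double-precision floats (exact below 2^53) and grouped by radix sort, so
the search is expected near-linear in total sequence length. The naive
all-pairs computation is retained in the test suite as the oracle, and the
two paths are checked to produce identical edge sets on random
repertoires.

Cluster ids are deterministic — decreasing aggregate read count, ties
broken by the lexicographically smallest member sequence, numbered from
0 — so that reports are reproducible run to run. Layouts for network plots
use the classic Fruchterman–Reingold force-directed algorithm
(`layout_fr()`, seeded, via igraph).

## Diversity indices

For clone frequencies $p_i$ (at vertex or cluster level):

* Shannon diversity index (SDI): $H = -\sum_i p_i \ln p_i$;
* Gini–Simpson coefficient: $D = 1 - \sum_i p_i^2$;
* Gini index: $G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)$.

Plug-in estimators are used throughout; no bias correction is applied, and
no rarefaction by default (`rarefy_repertoire()` exists for depth-matched
comparisons but is off by default, because the analyses the package
supports report unrarefied indices). The SDI uses the natural logarithm;
a `base` argument exists for comparability with bits-based reports.

Patient indices are normalized as a **ratio to the healthy-cohort
arithmetic mean**, index by index and level by level. The alternative —
z-scoring — was rejected because the downstream dichotomous cut-offs live
naturally near 1 on the ratio scale (a patient at the healthy mean scores
exactly 1), and because with 12 healthy volunteers the cohort standard
deviation would be an unstable divisor.

ΔSDI is fixed as normalized SDI(TP3) − normalized SDI(TP2): the increase
from the transplant nadir (immediately before stem-cell transfusion) to
the 6–8-week follow-up. Subjects missing either timepoint receive a
missing marker and are excluded (with a warning) from the ΔSDI ROC.

## ROC analysis

`roc_analysis()` computes the empirical ROC over all distinct score
thresholds, with the positive class defaulting to `non_relapse`
(diversity-type scores run *higher* in patients who do not relapse, so
AUC > 0.5 when that direction holds). AUC is the trapezoid area, which
equals the Mann–Whitney rank statistic; the suite verifies this identity
against explicit pair enumeration and against pROC. The reported cut-off
maximizes Youden's J, with deterministic tie-breaks (highest sensitivity,
then lowest threshold) and is placed at the midpoint between the adjacent
distinct scores it separates. Group comparisons use Welch's
unequal-variance t test — group variances of small clinical cohorts
should not be assumed equal. No multiple-testing correction is applied
across measures and timepoints; with three indices, two levels and four
timepoints the ROC table is exploratory, and users should treat
per-measure p-values accordingly.

## Tumor tracking

A patient's tumor signature is a set of CDR3 sequences with read counts or
fractions. `extract_primary_clusters()` builds the clonal network of the
tumor repertoire and flags clusters holding at least 5% (configurable) of
total tumor reads as *primary*. Matching against a peripheral repertoire
reports, per tumor sequence, the closest peripheral sequence by
Levenshtein distance (ties broken lexicographically). MRD positivity
requires **exact identity** (LD = 0); LD = 1 clones are reported as
`related` — evidence of ongoing clonal evolution — but never flip the MRD
flag, and the tumor read fraction counts exact matches only. Edit
distances are computed with `utils::adist()` (exact C implementation);
the suite cross-checks it against a hand-written dynamic-programming
oracle and verifies the triangle inequality on random triples.

## The co-culture simulator

`simulate_coculture()` emulates an in-vitro GC culture on a feeder layer:

* **Growth schedule** (`growth`, per day): 1.2 on days 0–4 (IL-4 only),
  2.0 on days 4–14 (IL-21-driven expansion), 1.1 after day 14. The
  expansion factor 2.0 was calibrated once so that the cumulative
  fold-expansion $\prod_t g(t)$ reaches $1.2^4 \times 2^{10} \approx 2123
  \ge 2000$ by day 14, the observed scale of such cultures; replating
  (downsampling to $10^5$ cells at days 8, 12, 16, proportions preserved)
  affects cell counts but not the cumulative fold.
* **SHM** (`shm_rate`, default 0.02/cell/day from day 4): each newborn
  cell mutates with this probability, producing a daughter clone at
  Hamming distance 1 from its parent, so the clonal network grows outward
  from the naive vertices. The rate is a free default — no quantitative
  in-vitro SHM rate is established for this system.
* **Maturation clock**: mutation stops after 8 *effective* dark-zone days
  (accrued at rate $1-s$ per day, where $s$ is the current suppression),
  modeling the SHM-to-class-switch transition. Without tumor the clock
  completes at day 12, so diversity peaks there; suppression slows the
  clock, delaying the diversity peak past day 14. The clock is this
  package's mechanism for a transition whose timing, not cause, is the
  observable.
* **Tumor compartment** (`tumor_seed` cells per $10^5$ naive; growth 2.0
  per day; emits no BCR reads by default, as the modeled tumor line lacks
  a stably expressed BCR): suppression is $s = s_{max} f_T/(f_T + K)$
  with $s_{max} = 0.5$, $K = 10^{-5}$, applied multiplicatively to the
  daily growth *increment* ($g_{eff} = 1 + (g-1)(1-s)$) and to the SHM
  rate. $K = 10^{-5}$ makes even a 0.001% seed produce a large effect —
  the dominant drop is from zero to the smallest seed, with mild
  dose-dependence above it. Multiplying the increment rather than the
  factor keeps the suppressed culture growing exponentially at a reduced
  rate rather than stalling outright, matching the observed halving of
  the day-12 population rather than its collapse. The functional form is
  declared, not claimed biological (the mechanism — likely paracrine — is
  unresolved).
* **Modes**: `mean_field` propagates expected counts deterministically
  (mutation events are discretized by a per-clone accumulator);
  `stochastic` draws Poisson births, binomial mutation counts and
  multinomial replating. Both are bit-reproducible given the seed.

With these defaults the simulator reproduces, without further tuning, a
day-14 tumor fraction near 16% for a 0.1% seed (about a 160-fold rise)
and the characteristic ordering of diversity curves: the day-of-maximum
SDI is 12 with no tumor and at least 14 with tumor.

## The patient-cohort generator

`simulate_patient_cohort()` generates the full clinical structure: 8
relapse and 9 non-relapse patients, 12 healthy volunteers, timepoints
TP1–TP3 (TP4 for relapse patients only — non-relapse patients have no
relapse visit).

* **Healthy repertoires**: ~5000 clones with log-normal (heavy-tailed)
  clone sizes, 20000 reads. Richness and tail are invented but sized so
  the realized SDI sits near $\ln(\text{richness})$ minus a tail penalty,
  the regime real peripheral repertoires occupy.
* **Per-sample targets**: each patient sample receives a target
  *normalized* SDI — TP1 mean 0.55 (suppressed by prior treatment), TP2
  mean 0.35 at 200 reads (the near-ablated nadir, where mRNA yield is the
  limiting factor), TP3 mean 1.0 (non-relapse) vs 0.6 (relapse) with
  common sd 0.15, TP4 mean 0.95. The TP3 gap is the configured effect the
  ΔSDI discrimination rests on; it is realized through richness (reduced
  novel-clone influx), the single knob the data cannot distinguish from
  clone-size skew.
* **Target inversion**: a target SDI is converted to a clone count by
  binary-searching the richness of a Zipf ($p_i \propto i^{-0.3}$)
  clone-size law against the *realized* healthy-cohort mean, followed by
  multinomial read sampling. The small exponent keeps the plug-in entropy
  bias at the package's desk-scale depths (10⁴ patient reads, 2×10⁴
  healthy, 200 at TP2 — stand-ins for the 10⁶-read repertoires of real
  studies) far below the configured group effect.
* **Planted tumor clones**: every relapse patient carries a monoclonal
  tumor CDR3 at a read fraction drawn log-uniformly from
  $[3\times10^{-5}, 0.014]$ — the orders of magnitude seen for
  circulating tumor clones — at every timepoint, with the read count
  floored at 1 so the clone is recoverable even below one expected read.
  Each relapse patient also receives a tumor signature containing the
  planted clone plus a minor one-substitution variant (they form a single
  primary cluster). The planted structure is exactly recoverable:
  `match_tumor_clones()` finds every planted clone at LD 0, and no
  non-relapse repertoire contains any planted sequence.

## What passing tests do and do not show

The generators produce repertoires whose clone sizes follow clean
parametric laws, whose sequences are uniform random (so background
Hamming-1 adjacencies are rare), and whose group effect is planted
directly on the quantity being tested. Passing the recovery tests
therefore shows that the *analysis chain is correct and sensitive at the
configured effect size* (TP3 normalized-SDI 0.6 vs 1.0, sd 0.15 — mean
ΔSDI AUC ≈ 0.96 over 20 cohorts), not that real cohorts of 17 patients
will reach any particular AUC: real repertoires have sequencing error,
primer bias, shared public clones and non-parametric clone-size tails
that the generator deliberately omits.

## Numerical choices and degenerate inputs

* Diversity functions accept any positive weights (they are
  scale-invariant); empty or nonpositive abundance vectors are errors,
  and an empty-after-filter repertoire is an explicit error rather than a
  zero index, to avoid silently skewing cohort means.
* Mean-field trajectories compare equal across days once mutation stops;
  `sdi_peak_day()` therefore uses a 1e-9 tie tolerance and returns the
  earliest day attaining the maximum.
* Sequences are uppercased on input; any non-A/C/G/T character
  disqualifies the row (edges are defined on exact nucleotide identity),
  with dropped-row counts reported in warnings.
* Closest-match and cut-off ties break deterministically
  (lexicographic / highest-sensitivity-then-lowest-threshold), so all
  reports are reproducible.
* All simulation randomness flows through a single seed per config;
  `local_seed()` restores the caller's RNG state.

## Known limitations

Clone definition ignores V/J annotations entirely, which can merge
distinct rearrangements that converge on one CDR3. There are no
phylogenetic lineages within clusters, no isotype awareness, no
affinity/selection modeling (the in-vitro system this mirrors lacks
Fas-mediated selection), no Hill-number or coverage-adjusted diversity
family, and no confidence intervals on AUC (point estimates only, in
keeping with the small-cohort setting the package targets). The 5%
primary-cluster threshold, MRD-by-exact-identity rule and `related_max`
LD are configurable conventions, not biological constants.
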