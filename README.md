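# bcrnet

Clonal network and diversity analysis of B cell receptor (BCR) immune
repertoires, for tracking how residual malignant B cells distort the
recovery of repertoire diversity — e.g. in diffuse large B cell lymphoma
(DLBCL) patients undergoing high-dose therapy with autologous stem cell
rescue (HDT-ASCR), or in germinal-center B cell cultures seeded with tumor
cells. It is aimed at immunologists and computational biologists who work
with clonotype tables from upstream assemblers (AIRR Rearrangement TSV,
MiXCR exports) rather than raw reads.

## What it computes

**Clonal networks.** Each vertex is a unique CDR3 nucleotide sequence
(read counts aggregated across V/J calls); edges join vertices that differ
by a single nucleotide (substitutions only by default, optionally a single
indel); a *clone* (cluster) is a connected component — a set of sequences
identical or linked by chains of single point mutations. Neighbour search
uses position-masked key hashing (expected near-linear), verified in the
test suite against brute-force all-pairs distances.

**Diversity.** For clone frequencies `p_i` at vertex or cluster level:

- Shannon diversity index (SDI): `H = −Σ p_i ln p_i` (nats)
- Gini–Simpson coefficient: `D = 1 − Σ p_i²`
- Gini index: `G = Σ_i Σ_j |x_i − x_j| / (2 n² x̄)`

Patient indices are reported raw and normalized to the arithmetic mean of
a healthy cohort (`normalized_*` columns). The recovery of the normalized
SDI between the transplant nadir (TP2) and the 6–8-week follow-up (TP3),
`ΔSDI = SDI(TP3) − SDI(TP2)`, discriminates relapse from non-relapse
trajectories via an empirical ROC with a Youden-optimal cut-off.

**MRD tracking.** Primary tumor clusters (clusters carrying ≥ 5% of the
tumor BCR reads) are matched against peripheral repertoires by Levenshtein
distance: LD = 0 is minimal residual disease (MRD), LD = 1 flags related
clones (clonal evolution). Spike-in networks label tumor vertices
`tumor_mrd` / `tumor_absent` for visualization with a Fruchterman–Reingold
layout.

**Simulators.** `simulate_coculture()` reproduces a germinal-center
co-culture: two-phase exponential growth (≥ 2000-fold by day 14), somatic
hypermutation spawning single-mutation daughter clones until the
SHM-to-CSR transition, periodic replating, and an optional non-mutating
tumor compartment that suppresses normal growth and mutation through a
saturating function of the tumor fraction. `simulate_patient_cohort()`
generates a full HDT-ASCR study (default 8 relapse / 9 non-relapse
patients, 12 healthy volunteers) with planted tumor clones and a
configured TP3 diversity deficit in relapse patients.

## Worked example

```r
library(bcrnet)

rep <- read_clonotype_table(
  system.file("extdata", "example_clonotypes.tsv", package = "bcrnet"),
  dialect = "simple", chain_filter = "IGK")
net <- build_network(rep)
net
#> <ClonalNetwork> 7 vertices, 3 edges, 4 clusters (rule: hamming1 )

diversity_profile(rep, net, "vertex")[, c("richness", "shannon", "gini")]
#> # A tibble: 1 × 3
#>   richness shannon  gini
#>      <int>   <dbl> <dbl>
#> 1        7    1.40 0.561

sig <- extract_primary_clusters(read_tumor_signature(
  system.file("extdata", "tumor_signature_419.tsv", package = "bcrnet"),
  patient_id = "419"))
match_tumor_clones(sig, rep)[, c("tumor_seq", "ld", "mrd_positive", "related")]
#> # A tibble: 2 × 4
#>   tumor_seq                            ld mrd_positive related
#>   <chr>                             <int> <lgl>        <lgl>
#> 1 TGTCAGCAAAGTTACAGTATTCCTCGGACCTTC     0 TRUE         FALSE
#> 2 TGTCAGCAAAGTTACAGTATTCCTCGGACGTTC     0 TRUE         FALSE
tumor_fraction(sig, rep)
#> [1] 0.5182186
```

The seven kappa-chain clonotypes collapse into four clones: the two tumor
signature sequences are present verbatim in the sample (LD 0 on both →
MRD-positive), and exact tumor matches carry 52% of the sample's kappa
reads.

A full synthetic study:

```r
sim <- simulate_patient_cohort(patient_cohort_config(seed = 1))
report <- cohort_pipeline(sim$cohort, sim$repertoires, sim$healthy)
report
#> <CohortReport> 17 subjects, 118 profiles, 20 ROC rows
#>   delta-SDI (vertex) AUC: 0.931
```

Relapse patients recover diversity more slowly (mean ΔSDI 0.30 vs 0.58 in
non-relapse patients in this cohort), and ΔSDI separates the groups at
AUC 0.93.

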