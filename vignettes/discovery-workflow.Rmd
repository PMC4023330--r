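---
title: "Mapping a presence/absence volatile trait by in-silico bulked segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a presence/absence volatile trait by in-silico bulked segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactomap)
```

## The problem and the model

γ-decalactone (γ-D) is a lactone volatile that gives some strawberry
genotypes a peach-like aroma. The trait is qualitative: a genotype either
produces the compound in at least some harvests or never does, and
producer × non-producer crosses segregate roughly 1:1, the signature of a
single dominant locus carried in one dose (simplex) in the octoploid
genome. `lactomap` is built around the *hemizygous deletion model* for such
a locus: non-producers physically lack the causal gene, so absence of the
volatile, of the transcript, of a PCR amplicon in the gene, and of a linked
SSR allele all co-occur. Every module either exploits that structure
(candidate filtering, marker statistics) or measures it (phenotyping,
qPCR).

The discovery computation is bulked segregant analysis performed after data
collection: each genotype's transcriptome is quantified separately, the
genotypes are pooled *in silico* by phenotype, and a gene is a candidate
only if its expression separates the pools in **every** pairwise
comparison. In a highly heterozygous polyploid, homoeologous
(subgenome) segregation makes many genes present/absent across progeny
independently of any one trait; requiring separation in all
producer × non-producer pairs, rather than on pool averages, is what lets
that noise cancel.

Formally, with RPKM `R[g, s] = counts[g, s] · 10⁹ / (L_s · l_g)` (library
size `L_s` in mapped reads, gene length `l_g` in bp), a gene g survives the
filter at fold threshold F and pseudocount c iff

```
(R[g, p] + c) / (R[g, q] + c) > F   for every producer p, non-producer q,
```

and the presence/absence screen then keeps g only if it is detected
(`R > detect_threshold`) in all producers and in no non-producer. Because
the ratio is monotone, the binding pair is (lowest producer, highest
non-producer), which the implementation uses directly and the tests check
against a literal all-pairs loop.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fold_threshold` | 4 | ratio | the final, stricter end of the 2–4-fold screen; the report also lists counts at 2 and 3 |
| `pseudocount` | 0.1 | RPKM | keeps zero denominators finite without reordering genes; a true deletion (all non-producer RPKM = 0) survives at any pseudocount |
| `detect_threshold` | 1 | RPKM | presence/absence call; strict `>` so RPKM 0 is always "undetected" |
| `min_rpkm` | 10 | RPKM | parental comparison considers genes with RPKM > 10 in ≥ 1 parent |
| `parent_fold` | 5 | ratio | parental overexpression, inclusive ("at least 5 times") |
| `noise_floor` | 0.02 | normalized response | volatile detection floor; see below |
| `rel_tol` | 0.2 | fraction | relative margin for the trend classifier |
| `min_nonref_frac`, `min_depth`, `min_genotypes` | 0.95, 10, 2 | —, reads, genotypes | SNP criteria, all inclusive (≥) |

Comparison directions follow the rule each threshold expresses: strict `>`
for "more than 4-fold" and "RPKM > 10", inclusive `≥` for "at least
5 times" and for the SNP criteria ("10 or greater", "95% minimum").

**Noise floor.** GC/MS detection limits are matrix- and run-dependent, so
there is no universal constant. The default convention
(`estimate_noise_floor`) is mean + 3 SD of blank or known-negative
responses; everywhere a floor is consumed it is an explicit argument. A
non-producer call additionally requires at least three harvests with
nothing above the floor, because the trait is strongly environment- and
season-labile: two quiet harvests are compatible with a producer in a
non-inductive window, and such genotypes are reported
`INSUFFICIENT_DATA` and excluded from marker statistics.

**Trend classes.** Producers fall into four seasonal shapes over three
harvests — mid-season PEAK, the reciprocal VALLEY, an early DECREASE, and a
monotone INCREASE — with NONPRODUCER the fifth class. The classifier uses
relative comparisons (`a` exceeds `b` iff `a > b·(1 + rel_tol)`, default
20%) because the field data this emulates are classified by eye from
profiles spanning about three-fold. A flat producer profile fires no rule;
the tie-break priority is fixed (PEAK if the middle harvest is a weak
maximum, else DECREASE, else INCREASE) so the classifier is total and
single-valued — a property the test suite checks by enumeration over tied
grids and random profiles.

**Standard curves.** Concentration estimation inverts an OLS fit of
(response − matrix baseline) on spike concentration over 0.005–0.3 mM.
Estimates outside the calibrated range are returned but flagged
`extrapolated`; estimates below the lowest spike are flagged
`below_calibration` rather than reported as hard zeros.

## The population simulator

`sim_config()` defines the study conditions; `simulate_population()` builds
every input the pipeline reads. The defaults emulate a 16-genotype panel —
two parents plus 14 F1 progeny fixed at 11 producers / 5 non-producers,
mirroring a sequenced panel *selected* from a phenotyped population
(`simulate_cross()` is the place where segregation itself is random:
carrier draws are Bernoulli 0.5 for F1 and backcross-to-null, 0.75 for a
carrier-F1 × simplex-carrier backcross).

* **Counts**: negative binomial, per-gene means log-uniform on 5–500
  counts, shared dispersion 0.3 (`size = 1/0.3`) — standard bulk RNA-seq
  overdispersion. Library sizes are uniform on 0.3–0.85 million mapped
  reads per genotype, one tenth of the multi-million-read libraries such
  experiments produce, so a 2,000-gene panel builds in well under a second;
  RPKM is scale-free in this choice.
* **Causal gene**: zero counts in every non-carrier (the deletion is exact,
  not just low expression). In carriers its mean is 150 RPKM at the ripe
  stage in the inductive environment — the causal transcript is modeled as
  a highly abundant one — divided by `ripening_fold` (default 21) at
  blushing and by `env_effect_fold` (default 11) in the non-inductive
  environment.
* **Decoys** (default 50 of 2,000): abundant in a random half of genotypes
  irrespective of carrier status, the simulator's stand-in for subgenome
  presence/absence segregation. Each decoy matches the carrier pattern in
  all 16 genotypes with probability 2·0.5¹⁶ ≈ 3×10⁻⁵, so a spurious second
  candidate is expected in well under 1% of panels — the same arithmetic
  that makes the all-pairs filter effective on real polyploid data.
* **Volatiles**: two technical replicates per genotype × harvest; carriers
  emit `volatile_signal` (0.5) shaped by their trend class (PEAK = (1,3,1),
  VALLEY = (3,1,3), DECREASE = (3,1,1), INCREASE = (1,2,4) — the PEAK
  shape spans the ~3-fold seasonal range such profiles show) under 10%
  log-normal noise; non-carriers draw uniformly below
  `volatile_baseline` (0.01), so a non-carrier can never exceed a floor set
  above the baseline. Trend-class frequencies among carriers default to
  0.50/0.28/0.17/0.05, the relative pattern "most peak mid-season, a
  handful each of the others".
* **Markers**: the PCR amplicon sits inside the deletion (present iff
  carrier); SSR allele 205 is fully linked, 209 monomorphic, 215/219
  assigned at random.
* **qPCR**: triplicate CTs with Gaussian noise (default 0.05 cycles);
  non-carriers never amplify the target, and the analysis reports fold 0
  with a flag rather than imputing a maximum cycle.
* **Pileups**: a planted fraction of sites is constructed to satisfy the
  SNP criteria; background sites draw Poisson(8) depths with binomial(0.35)
  non-reference counts, which essentially never reach the 95% fraction.

All randomness flows from one master seed through named substreams, one per
operation, so identical configurations give byte-identical outputs and
adding draws to one stage never perturbs another.

**What the simulator does not emulate** — and therefore what passing tests
do not demonstrate about real data: reads, alignment and quantification
error; partial deletions or expression knock-down (the presence/absence
dichotomy is exact by construction); linkage disequilibrium beyond one
causal locus and one fully linked SSR; correlated library-quality effects;
genotype misclassification from field phenotyping (volatile noise never
crosses the floor by design). On real data the filter's behaviour at the
margins — a producer sampled in a non-inductive harvest, a low-quality
library — is exactly where the three-harvest rule and the pseudocount
matter, and those are exposed as configuration, not constants.

## Numerical and design choices

* **Pairwise over pool-mean semantics** for the candidate filter, because
  pooling averages can hide a single contradictory genotype;
  `poolmean_candidate_filter()` is provided for sensitivity analysis.
* **Zero handling**: the pseudocount (0.1 RPKM) is added to both sides of
  every ratio. Raising the fold threshold never adds candidates; lowering
  the pseudocount never removes a gene whose non-producer RPKMs are all
  zero (both properties are tested).
* **Dosage**: the carrier parent is modeled simplex because ~1:1
  segregation is what the trait shows; higher dosage is not modeled. The
  0.75 expectation for a carrier-F1 × simplex-carrier backcross is likewise
  a modeling consequence of simplex dosage, exposed through the cross type
  rather than hard-coded.
* **Degenerate 2×2 cosegregation tables**: with perfect cosegregation (or
  a zero margin) the chi-square approximation is meaningless, so the
  statistic is reported `NA` and the p-value is the exact probability
  2·0.5ⁿ that a phenotype-independent even-odds marker matches the
  phenotype in all n genotypes in either polarity.
* **Multiple testing**: none — these are single-locus confirmatory tests;
  per-allele SSR tables are reported unadjusted and labeled as such.
* **qPCR SD units**: replicate scatter is propagated on the CT scale
  (cycles) and also reported as the fold-scale interval
  `2^-(ΔΔCT ± SD)`, since "± x" is ambiguous between the two scales.
* **VCF**: written as minimal VCF 4.2 (INFO `NPASS`, per-sample `PA` pass
  flag), 1-based coordinates preserved from the pileups; the tests
  round-trip the files through `VariantAnnotation::readVcf`. Multi-allelic
  sites are out of scope (one alt allele per site record).

## Problem sizes

The defaults used throughout the tests and the analysis scripts are a
16-genotype × 2,000-gene panel, 3 harvests × 2 technical replicates of
volatile data, 200 pileup sites, and Monte-Carlo checks at 10,000 progeny
(segregation), 2,000 replicate genotypes (ripening-fold recovery) and
10,000 sites (pileup planting rate). These sizes put every Monte-Carlo
band at 3 standard errors or tighter while keeping a full test run around
a minute on one core.

## Known limitations

The package assumes gene-level counts as input — alignment and
quantification are upstream concerns. The deletion model is binary; a
trait caused by regulatory silencing rather than physical absence would
show transcript absence but marker presence, and the marker-concordance
report (not the candidate filter) is where that discrepancy would surface.
RPKM comparisons across genotypes inherit RPKM's known compositional
caveats; for presence/absence logic this is immaterial, but quantitative
fold rankings between surviving candidates should not be over-read — the
qPCR module exists precisely because quantitative effects need an
independent assay.
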