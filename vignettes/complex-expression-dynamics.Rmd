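---
title: "Methods: protein complex expression dynamics at transcript resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein complex expression dynamics at transcript resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcomplex)
```

## The model

A protein complex can only assemble when every subunit protein is available,
and a subunit protein is only available when at least one transcript that
encodes it is expressed. `txcomplex` operationalizes this chain on RNA-seq
expression estimates:

1. **Detection.** A feature (transcript or gene) is *detected* in a sample
   when its log-expression estimate is present and its posterior standard
   deviation is at most `sd_max` (default 1.5). The posterior SD of Bayesian
   isoform quantifiers grows without bound for features with no uniquely
   mapping reads, so the SD filter is a reliability filter, not an abundance
   filter; the estimate itself is deliberately not thresholded (an optional
   floor exists but defaults to off).
2. **Subunit expression.** A protein is *expressed* in a sample when **at
   least one** of its associated transcripts is detected (existential, not
   universal, detection). Universal detection would declare almost every
   multi-isoform protein absent, since tissues express isoform subsets.
3. **PFPC calling.** A complex is a *possible formable protein complex*
   (PFPC) in a sample when every subunit is expressed there. PFPC status is a
   transcript-presence proxy for assemblability; it says nothing about
   physical assembly, stoichiometry or localization.
4. **Major isoforms.** The *major (dominant) isoform* of a gene in a sample
   is its highest-expressed detected transcript. Complexes and subunits
   "involve" the major isoform when the subunit's transcript set contains the
   major isoform of one of the subunit's genes. A component *switches*
   between two samples when its gene's major isoform differs.
5. **Differential expression.** For case/control count matrices the signal
   per transcript is `M = log2(mean_case) - log2(mean_control)` and
   `D = |mean_case - mean_control|`; the noise distribution pools `(M*, D*)`
   pairs from all within-group sample pairs, across both groups and all
   transcripts. The DE probability is
   `q = mean(|M*| < |M| & D* < D)` — the fraction of noise pairs strictly
   dominated by the signal. `q` is a dominance fraction, not a p-value, and
   no multiplicity correction is applied to it.
6. **Impact propagation.** A DE transcript affects every complex with a
   subunit whose transcript set contains it. Because subunits are shared
   across complexes and each subunit pools several transcripts, two datasets
   with disjoint DE transcript sets can share many affected complexes; the
   package reports both overlap matrices and their ratio.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sd_max` | 1.5 | posterior-SD detection cutoff (log-expression units); boundary inclusive |
| `q_min` | 0.9 / 0.9 / 0.99 / 0.8 | DE probability cutoffs for breast / colon / lung / prostate-style datasets; stricter where biological replicates are missing |
| `pseudo_count` | 0.5 | replaces zero abundances before log ratios |
| `n_sim` | 5 | simulated technical replicates per sample in no-replicate mode |
| `min_tx` | 2 | same-gene transcript count making a component switch-eligible |

The detection boundary is **inclusive**: an SD of exactly 1.5 is kept, only
strictly larger values are excluded. The DE threshold is **strict**
(`q > q_min`), and so is noise domination (`|M*| < |M|`, `D* < D`): boundary
ties never count toward `q`, so a transcript identical in both groups has
`q = 0` rather than an arbitrary tie-dependent value.

## Numerical and design choices

* **Redundancy of complexes** is defined as an identical subunit accession
  set, ignoring id and name; the first record in file order is kept. This is
  the minimal defensible reading of "redundant", and it is deterministic.
* **Uncertain subunits** are tokens matching `[(|]` (curated catalogues
  encode ambiguous subunits as parenthesised alternatives); the pattern is an
  argument of `read_complex_table()`.
* **Ties** in major-isoform assignment are broken by the lexicographically
  smallest transcript id — reproducible across runs and platforms. The
  assignment depends only on within-sample ranking, so it is invariant under
  monotone per-sample rescalings.
* **Components with several qualifying genes** (rare multi-gene proteins)
  are evaluated on the gene contributing the most of their transcripts, ties
  to the smallest gene id.
* **Pair-specific denominators** in the switch matrix: each sample pair
  counts only components whose gene has a defined major isoform in both
  samples, and an empty denominator yields `NA`, never 0.
* **Gene-level analysis** uses an OR roll-up of transcript detection by
  default, which makes "transcript-level PFPCs ⊆ gene-level PFPCs" an exact
  theorem rather than an empirical tendency; a native gene-level matrix can
  be supplied instead, in which case the containment is only approximate.
* **Two-group PFPC comparison** intersects each group's per-sample PFPC sets
  (a complex must be formable in every sample of the group) before
  decomposing into shared and group-specific complexes.
* **Missing cells** (a feature absent from one sample's file) are "not
  detected" but are tracked separately from SD-filtered cells, so reports can
  distinguish "not measured" from "measured and unreliable".
* **No-replicate DE mode**: when a group has a single sample, each observed
  sample is resampled five times from a multinomial at its observed depth and
  noise pairs are taken among resamples of the same sample. Technical noise
  understates biological noise, which is why the conventional cutoff in this
  mode is 0.99 rather than 0.9.
* **Canonical sample order**: the DE statistic internally sorts columns by
  sample name, making `q` exactly invariant to the caller's column order
  (tie comparisons are knife-edge otherwise).
* **Degenerate inputs**: single-sample normalization is the identity; an
  empty DE set propagates to an empty impact; an empty complex table produces
  an empty but well-formed universe; a sample with no nonzero counts is an
  error rather than a silent `-Inf`.

## What the synthetic generator emulates

`synth_config()` defaults emulate the statistical structure of curated human
complex catalogues profiled across a 16-tissue RNA-seq panel:

* complex sizes concentrated on 2–4 subunits;
* about 2.26 transcripts and 1.01 genes per subunit (geometric-like counts,
  occasional two-gene proteins and same-gene subunit pairs);
* 49% of subunit proteins shared across ≥ 2 complexes. Sharing is built by
  an **exact construction**: `round(0.49 × n_proteins)` proteins receive
  extra complex memberships (mean multiplicity 1.3), so the realized sharing
  fraction equals the target up to rounding rather than merely in
  expectation;
* per-sample silent subunits at rate 0.06 (so a three-subunit complex is
  formable about 84% of the time), with all transcripts of a silent subunit
  pushed above the SD cutoff;
* strongly co-detected complex members (each member transcript of an
  expressed subunit detected with probability 0.94, the first always);
* a planted dominant isoform per gene and sample with a fixed margin
  (default 1 log unit) above the gene's other detected isoforms, involving
  the subunit's own transcripts at rate 0.78 when the gene also has
  non-subunit isoforms;
* an exact count `round(0.11 × n_eligible)` of major-isoform switches
  between the reference sample (S01) and every other sample;
* negative-binomial case/control counts (dispersion 0.05) at log-normal
  abundances (`meanlog = log(100)`, `sdlog = 0.6` — the quantifiable range),
  with 5% of transcripts planted as DE at fold change 4 applied
  **symmetrically** about the baseline (case × √4, control ÷ √4), so up- and
  down-regulation are equally strong signals; per-sample depth factors make
  the normalization step do real work.

Every planted structure is written to a ground-truth ledger that is
consistent with the emitted files by construction, and the package's tests
assert exact recovery in the zero-noise limit (no absences, full detection):
planted silent subunits reproduce the non-PFPC sets exactly, planted switch
rates are read back exactly, and planted involvement fractions match the
ledger.

### What it does not emulate

* **Cross-sample correlation of absences.** Subunit silencing is independent
  across samples, so the *common*-PFPC fraction across many samples is far
  smaller than in real tissue panels, where most complexes are constitutively
  expressed and absence is tissue-specific. Per-sample PFPC fractions are
  realistic; the 16-way intersection is not.
* **Abundance-dependent DE power.** Real transcript abundances span several
  more orders of magnitude than the generator's `sdlog = 0.6`; under a wide
  dynamic range the (M, D) dominance statistic loses power for low-abundance
  transcripts regardless of fold change, because their `D` can never dominate
  the noise of high-abundance features. Passing recovery tests therefore
  demonstrate correctness of the statistic, not its power profile on real
  data.
* Read-level phenomena (mapping ambiguity, positional bias), sequence
  content, and any protein-level biology (the PFPC is a transcript proxy).

## Problem sizes

The test suite runs randomized-fixture loops at 20–30 complexes and 3–4
samples (100 seeds for the oracle-equivalence and containment properties),
exact-recovery checks at 80–120 complexes, and one full-scale stochastic DE
recovery at 2000 transcripts with 5 vs 5 replicates. The acceptance script
regenerates the full default study: 500 complexes, ~1000 subunit proteins,
16 tissues, and four case/control datasets. These sizes were chosen so the
whole suite exercises every code path in well under a minute per property
while keeping the statistical checks (sharing ± 0.05, DE sensitivity ≥ 0.8)
meaningful.

## Known limitations

* PFPC calling treats detection as binary; partial, dosage-dependent
  assembly effects are invisible.
* The DE statistic's `q` is not calibrated as a false-discovery rate; the
  per-dataset cutoffs are conventions, not error-rate guarantees.
* Proteins absent from the identifier mapping drop their whole complex at
  resolution time; there is no partial-complex mode.
* The switch analysis conditions on the detection filter: a gene whose major
  isoform is filtered out in one sample leaves that pair's denominator
  rather than counting as a switch.
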