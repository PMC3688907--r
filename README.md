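# txcomplex

Protein complexes do their work as units: if any subunit is missing, the
complex cannot assemble. Because every subunit protein is translated from one
or more transcripts — and most complex subunits have several isoforms, not
all of which encode the protein — the question *"could this complex form in
this tissue?"* is best asked at **transcript** resolution, not gene
resolution. `txcomplex` implements that analysis for RNA-seq expression
estimates:

* map curated complexes (CORUM-style tables) onto genes and transcripts
  through a Uniprot→Ensembl-style identifier table, removing redundant and
  ambiguous complexes and keeping only fully mappable ones;
* call detected features per sample with the posterior-SD filter used for
  Bayesian isoform quantification output (a feature with posterior SD > 1.5
  is treated as unreliable; exactly 1.5 is kept);
* call **PFPCs** — *possible formable protein complexes*: a complex is
  formable in a sample iff every subunit has ≥ 1 detected associated
  transcript. Gene-level calls (by roll-up) are provided for comparison and
  always over-estimate the transcript-level calls;
* assign each gene's **major isoform** (highest-expressed detected
  transcript, ties broken by smallest id), quantify how often formable
  complexes and expressed subunits involve major isoforms, and compute the
  pairwise **isoform-switch matrix** over components with ≥ 2 same-gene
  transcripts;
* score case/control **differential expression** with a self-contained
  nonparametric (M, D) statistic: per transcript, M = log₂ ratio and
  D = absolute difference of group means are compared against a noise pool of
  within-group sample pairs, and `q` is the fraction of noise pairs strictly
  dominated (`|M*| < |M|` and `D* < D`). Datasets without biological
  replicates are handled by multinomial technical-replicate simulation with a
  stricter default cutoff;
* propagate DE transcripts to the **complexes they affect** and compare
  affected-complex and DE-transcript overlaps across datasets — the
  shared-subunit structure of complexes amplifies small transcript overlaps
  into much larger complex overlaps.

A synthetic-data generator (`synth_config()`, `simulate_universe()`,
`simulate_expression()`, `simulate_de_counts()`) produces complete studies
with ground-truth bookkeeping, so every claim above is testable without any
external download.

## Worked example

```r
library(txcomplex)

cfg      <- synth_config(seed = 42, n_complexes = 200, n_samples = 6)
universe <- simulate_universe(cfg)
resolved <- resolve_complexes(universe$complexes, universe$mapping)
complex_stats(resolved, universe$mapping)
#> complex_stats: 200 complexes, 412 proteins, 413 genes, 917 transcripts
#>   transcripts/subunit 2.23 (54.6% with >=2), genes/subunit 1.01
#>   49.0% of proteins shared across >=2 complexes (max 5, P00192)

expr    <- simulate_expression(cfg, universe)$expr
tx_call <- call_detection(expr, sd_max = 1.5)
pfpc    <- call_pfpc(resolved, tx_call, universe$mapping)
pfpc$summary[, c("sample", "n_pfpc", "pfpc_fraction", "n_missing_one")]
#>   sample n_pfpc pfpc_fraction n_missing_one
#> 1    S01    161         0.805            36
#> 2    S02    157         0.785            38
#> 3    S03    171         0.855            25
#> 4    S04    172         0.860            24
#> 5    S05    163         0.815            35
#> 6    S06    172         0.860            26
```

Roughly 80–86% of complexes are formable in each sample, and most
non-formable complexes miss exactly one subunit (`n_missing_one`). The
complexes formable in *every* sample:

```r
cross <- pfpc_cross_sample(pfpc)
length(cross$common)
#> [1] 73
```

Major-isoform switching between samples (fraction of eligible components
whose gene's dominant isoform differs, pair-specific denominators):

```r
assignment <- assign_major_isoforms(expr, tx_call, universe$mapping)
proteins   <- sort(unique(unlist(resolved$kept$subunits)))
round(switch_matrix(assignment, proteins, universe$mapping)$fraction, 3)
#>       S01   S02   S03   S04   S05   S06
#> S01 0.000 0.177 0.168 0.186 0.182 0.177
#> S02 0.177 0.000 0.314 0.327 0.341 0.299
#> ...
```

Sample S01 is the generator's reference, so its row shows the planted
per-pair switch rate plus detection noise; pairs of non-reference samples
compound two independent switch sets, hence the larger values.

The whole analysis — including four case/control datasets with
differential expression and complex-impact overlaps — runs as one call:

```r
run_pipeline(list(simulate = list(seed = 1)), outdir = "results/run")
```

which writes per-stage TSVs plus a `summary.json`.

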