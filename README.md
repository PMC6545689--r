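# methsig

Genome-wide DNA methylation signatures that separate long-term from
short-term survivors of IDH wild-type glioblastoma, implemented as a
reusable, fully tested R pipeline.

## The problem

Glioblastoma is almost uniformly lethal, yet a small minority of patients
survive beyond three years. In IDH wild-type tumours this difference is not
explained by the classical hypermethylator phenotype, and genome-wide
methylation offers a candidate axis: long-term survivors (LTS) show
*hyper*methylation inside CpG islands and *hypo*methylation in the open sea
(regions > 4 kb from any island) relative to short-term survivors (STS).
`methsig` implements the full analytical chain behind that observation for
450K-style array data — and, because the motivating cohorts are external
datasets, it ships a seeded synthetic-cohort generator that reproduces the
statistical structure of the study so that every stage is testable offline.

## The methods at its core

* **Beta values** with the standard offset, `beta = M / (M + U + 100)`,
  with detection p-values judged against negative-control probes,
  `p = 1 - Phi((M+U - mu_c) / sd_c)`, and six probe-exclusion rules
  (detection p > 0.01 or bead count < 3 in > 5% of samples; non-CpG, SNP,
  multi-mapped, sex-chromosome probes; all inequalities strict).
* **BMIQ-style normalization**: a three-state beta-mixture is fitted by EM
  per sample and per assay type, and type-II betas are quantile-mapped onto
  the type-I mixture, `beta' = F1^{-1}(F2(beta))` — monotone by
  construction, identity when the distributions already agree.
* **Differential methylation by inverse-method GLS**: the across-sample
  covariance of negative-control probes estimates unwanted variation
  (components kept by a Marchenko–Pastur edge criterion; spherical
  remainder), and each probe's beta is fitted by generalized least squares
  on the group indicator, t-tests with n − 2 df, Benjamini–Hochberg FDR,
  significance at q < 0.01.
* **Signatures**: significant Island sites with delta = mean(LTS) −
  mean(STS) > 0.2 (hyper set) and significant OpenSea sites with
  delta < −0.2 (hypo set), strict cutoffs.
* **Integration**: per-mark enrichment-proportion differences against
  histone ChIP intervals; per-gene maximum Pearson correlation between
  site beta and log2(FPKM + 1); mutation–methylation association via
  z-scores at sites with a somatic mutation within ±5 kb, compared between
  site sets by a two-sample Kolmogorov–Smirnov test.
* **Probe-bias-corrected gene-set enrichment**: random gene sets drawn
  without replacement with probability proportional to per-gene probe
  counts; empirical exceedance p over 1000 resamples, BH-adjusted at
  q < 0.05.
* **Two-score classifier**: a sample is called LTS iff its mean beta over
  the hyper signature *and* over the hypo signature both exceed 0.2.

## Worked example

Run the whole chain — simulate a cohort (17 LTS vs 12 STS, 2000 probes with
100 + 100 planted differential sites), preprocess, test, integrate, and
classify a held-out cohort:

```r
library(methsig)
cfg <- pipeline_config(seed = 1,
                       sim = sim_config(seed = 1, n_probes = 2000,
                                        n_hyper_island = 100,
                                        n_hypo_opensea = 100))
run_pipeline("all", cfg, "demo_out")

d <- read_tsv("demo_out/diff_results.tsv")
sum(d$significant)                    # sites at FDR < 0.01
```

The run prints per-stage progress and leaves plain-text artifacts under
`demo_out/`. With the seed above it reports:

```
significant sites: 202 of 1927
hyper signature: 100 | hypo signature: 84

          set    mark  prop_sig prop_insig difference
 hyper_island H3K27ac 0.7500000  0.2881159  0.4618841
 hyper_island H3K9me3 0.3800000  0.3600000  0.0200000
 hypo_opensea H3K27ac 0.1428571  0.2881159 -0.1452588
 hypo_opensea H3K9me3 0.8333333  0.3600000  0.4733333

 statistic p_value n_site n_background
  0.382324       0    826         5359

 tp fn tn fp sensitivity specificity
 17  0 12  0           1           1
```

Reading this: of 1927 probes surviving the filters, 202 are differentially
methylated at q < 0.01 (the generator planted 200); the hyper signature
recovers all 100 planted island sites. The enrichment table shows the
planted histone geography — H3K27ac covers 75% of hyper-island sites versus
29% of insignificant sites, while H3K9me3 is the mark enriched at
hypo-open-sea sites. The KS row shows that samples carrying a mutation near
a hypo-signature site have systematically higher methylation there (826
mutation-proximal site/sample pairs against 5359 background pairs), and the
held-out 29-sample cohort is classified perfectly by the two-score rule.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/methsig-pipeline.R all --seed 1 --outdir demo_out
```

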