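---
title: "Methods: methylation signatures of glioblastoma survival groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation signatures of glioblastoma survival groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsig)
```

## The analysis in one paragraph

`methsig` implements a genome-wide 450K-style DNA methylation contrast
between long-term (LTS, > 3 years) and short-term (STS, < 1 year) survivors
of IDH wild-type glioblastoma. Methylation at a CpG probe is summarised by
the beta value $\beta = M/(M+U+100)$, probes are filtered by six quality
rules, type-II betas are rescaled onto the type-I distribution (BMIQ-style
mixture quantile normalization), differential sites are called by a
generalized-least-squares test that uses negative-control probes to model
unwanted variation, and two signatures are extracted: CpG-island sites
hypermethylated in LTS and open-sea sites hypomethylated in LTS (mean
difference beyond 0.2 beta at FDR < 0.01). The signatures are then related
to histone-mark intervals, gene expression and somatic mutations, gene sets
are tested with a probe-count-weighted resampling scheme, and a two-score
classifier calls a sample LTS when its mean beta over *both* signatures
exceeds 0.2. Everything runs on a seeded synthetic cohort generator, so the
full pipeline is testable without any external downloads.

## Probe annotation

CpG-island (CGI) context uses distance from the probe to the nearest island
boundary base, with islands as 0-based half-open intervals: `Island` inside,
`Shore` for $0 < d \le 2000$, `Shelf` for $2000 < d \le 4000$, `OpenSea`
beyond. Both upper bounds are closed; the boundary cases
$d \in \{2000, 2001, 4000, 4001\}$ are covered by tests. Shores and shelves
carry an `N_`/`S_` prefix. Whether the vendor's N/S labels are genomic or
island-relative is ambiguous in common usage, so the convention is explicit
and configurable: under the default `"genomic"` convention `N_` means the
nearest island lies at higher coordinates; `ns_convention = "flipped"` swaps
the labels without touching the distance bands. A probe exactly equidistant
between two islands is labelled from the higher-coordinate island.

TSS context is strand-aware: `TSS200` covers 0–200 bases upstream
(inclusive), `TSS1500` the interval (200, 1500], `FirstExon` any position
inside a first exon, `Far` otherwise; across transcripts the single reported
category follows the priority FirstExon > TSS200 > TSS1500 > Far. Gene
assignment is deliberately simple — a probe belongs to the gene whose
body-plus-1500-bp-promoter window contains it, nearest body edge then
lexicographic id as tie-breaks — because downstream stages only need a
probe-to-gene map, not a transcript-model annotator.

## Preprocessing

**Detection p-values** use a Gaussian model of the negative-control total
intensities within each sample: $p = 1 - \Phi((M+U-\mu_c)/\sigma_c)$. The
model choice (rather than an empirical rank) is conventional for array
background; the rank version is available via `method = "empirical"`.
Degenerate controls (zero spread) are an error, and at least 10 controls
are required.

**Filters.** A probe is removed iff any of the six rules fires: detection
$p > 0.01$ in more than 5% of samples; bead count $< 3$ in more than 5% of
samples; non-CpG probe; SNP-overlapping probe; multi-mapped probe; sex
chromosome (`chrX`/`chrY`, configurable). All three numeric inequalities
are strict. Removal counts are attributed to the first rule that fires,
which affects only reporting, never membership.

**BMIQ.** A three-state (unmethylated / hemimethylated / methylated) beta
mixture is fitted by EM separately to the type-I and type-II betas of each
sample, and each type-II beta is mapped through the fitted distribution
functions, $\beta' = F_1^{-1}(F_2(\beta))$. Because both mixture CDFs are
strictly increasing this map is monotone by construction, preserves the
type-II rank order, fixes type-I betas, and is close to the identity when
the two distributions already agree. Numerical choices: EM updates use
weighted moment matching for the beta shapes; initialization is
deterministic (cutpoints at 0.25/0.75, softened); convergence is declared
when the three state means move by less than $10^{-4}$ (state means
stabilise long before the log-likelihood plateaus on overlapping
components); the iteration cap is 3000 and exceeding it is an error, as is
a state whose total responsibility vanishes; inputs larger than 2000 values
are quantile-thinned for the fit (the mixture is a distribution estimate,
so thinning does not bias it). Re-running BMIQ on its own output changes
betas by well under 0.01.

## Differential methylation

The test follows the inverse-method idea: negative-control probes are
assumed unassociated with survival group, so their across-sample covariance
estimates the unwanted-variation structure. Writing $Y_c$ for the
intercept-removed control rows, $\hat\Sigma = Y_c^\top Y_c / p_c$ is an
$n \times n$ working covariance of the samples. Each target probe is then
fitted by generalized least squares of beta on the group indicator
(LTS = 1, so a positive coefficient means hypermethylation in LTS), with
two-sided t-tests on $n - 2$ degrees of freedom.

Two numerical decisions matter here:

* **Component selection.** $\hat\Sigma$ estimated from a few hundred
  control probes has substantial Marchenko–Pastur sampling dispersion at
  $n = 29$; whitening with the raw estimate perturbs p-value ranks even
  when the controls carry no structure at all. The default therefore keeps
  only the eigencomponents exceeding the Marchenko–Pastur upper edge and
  replaces the remainder with spherical noise. The edge carries a 25%
  finite-sample margin: measured null top-eigenvalues stay within a few
  percent of the edge (heterogeneous control variances fatten it slightly)
  while genuine batch factors sit severalfold above, so the margin costs no
  sensitivity. With structureless controls this reduces *exactly* to ordinary
  least squares; every factor the controls actually evidence is retained
  and whitened out. An explicit `k` override is available.
* **Degenerate probes.** Zero-variance probes carry no information and are
  reported with statistic 0 and $p = 1$ rather than NaN.

Tests run on beta values directly (not M-values), matching the scale on
which the group difference (`delta`, always LTS − STS) is reported.
Multiple testing uses Benjamini–Hochberg ("FDR" is taken to mean BH, the
default reading when no procedure is named); sites are significant at
$q < 0.01$. Signatures apply strict cutoffs: hyper-island sites need
$\Delta\beta > 0.2$ on significant `Island` probes, hypo-open-sea sites
$\Delta\beta < -0.2$ on significant `OpenSea` probes; a site at exactly 0.2
is excluded.

## Integration analyses

**Histone marks.** The enrichment proportion of a site set for a mark is
the fraction of sites covered by at least one interval of that mark. Since
the source data provide intervals per mark per cell and no aggregation rule
is canonical, both modes are computed: the default unions a mark's
intervals across cells, and per-cell proportions are reported as a min–max
range. The headline quantity is the difference
$\mathrm{prop}(\text{sig}) - \mathrm{prop}(\text{insig}) \in [-1, 1]$, plus
the signature proportion binned into quarters.

**Expression.** Pearson correlation between a site's beta and
$\log_2(\mathrm{FPKM}+1)$ of its assigned gene across shared samples, after
dropping sites with beta SD $\le 0.1$ and genes with mean FPKM $\le 0$.
When several sites map to one gene the *maximum signed* correlation is
assigned — exactly the printed rule, even though it dilutes a planted
negative coupling whenever an uncoupled site also maps to the gene (the
acceptance script therefore also reports the direct promoter-site
correlation).

**Mutations.** A mutation is associated with a probe if it lies within
±5000 bp (inclusive at exactly 5000). Each (site, sample) pair counts once
no matter how many nearby mutations the sample carries. The sample's beta
is standardized against the across-sample mean and SD at that site
(zero-SD sites are dropped with a reported count), and the z-score
distributions of the hypo signature vs an insignificant open-sea background
are compared by a two-sample Kolmogorov–Smirnov test.

## Gene-set enrichment

Genes are not equally covered by array probes, so a plain hypergeometric
test is biased toward probe-dense genes. The resampling test draws
`n_resamples` (default 1000) random gene sets of the test-set size, without
replacement, with selection probability proportional to each gene's probe
count, and reports the empirical exceedance
$p = \#\{\text{count} \ge \text{observed}\}/B$ per term, BH-adjusted with
significance at $q < 0.05$. No pseudocount is added by default — the
reference reporting style includes exact zeros, which only arise without
the +1 correction — but `pseudocount = TRUE` gives the conservative
variant. With uniform weights the empirical p converges to the
hypergeometric tail, which the tests exploit as an oracle. Terms are flat
gene sets; no ontology-graph propagation is attempted.

## Classifier

A sample's two scores are arithmetic means of its betas over the
hyper-island and hypo-open-sea signature sites; it is called LTS iff both
scores strictly exceed 0.2 (a score of exactly 0.2 calls STS, and this
boundary is tested). Sites absent from an external cohort are skipped, with
the covered fraction of each signature reported; coverage-1 scoring is
unchanged by this policy. Validation cohorts are scored on the same
normalization state as the discovery betas — BMIQ is applied before scoring
— because the type-II compression otherwise biases island scores toward 0.5
and inflates the hyper score of true STS samples. Evaluation treats LTS as
the positive class: sensitivity $= TP/(TP+FN)$, specificity
$= TN/(TN+FP)$. The heatmap helper orders sites and samples by
complete-linkage clustering on Euclidean distances.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis relies on,
at the discovery design of 17 LTS vs 12 STS samples:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 5000 | target probes across 4 autosomes (+ ~1% on chrX/Y) |
| `n_hyper_island`, `n_hypo_opensea` | 250 + 250 | planted differential sites |
| `delta_beta` | 0.25 | planted LTS−STS mean difference (beta scale) |
| `beta_precision` | 50 | Beta-noise precision (within-group SD ≈ 0.07) |
| `batch_strength` | 0.5 | SD of the latent batch factor |
| `type2_shift` | 0.1 | compression of type-II betas toward 0.5 |
| `n_neg_controls` | 500 | negative-control probes |
| `mutation_rate` | 80 | somatic mutations per sample |
| `mutation_beta_coupling` | 2 | softmax weight pushing mutations into high-beta samples at hypo sites |
| `expression_coupling` | 1 | slope of the negative promoter-methylation/expression link |

Baseline methylation follows CGI context (islands low, around 0.15; open
sea high, around 0.65; shores/shelves intermediate), so the planted effects
reproduce the directional geography: hyper sites start at 0.15 in STS and
reach 0.40 in LTS, hypo sites fall from 0.65 to 0.40. Noise is
Beta-distributed around the group mean (respecting [0, 1] by construction);
a single latent batch factor loads additively on the logit scale on the
negative controls and a random 30% of target probes, giving the
differential test identifiable unwanted variation. Type-II chemistry is a
linear compression toward 0.5, so BMIQ has real work to do. Intensities are
derived from the betas with log-normal totals; a small fraction of entries
receive background-level totals (failed detection) and low bead counts to
exercise the filters. H3K27ac intervals preferentially cover planted hyper
sites and H3K9me3 the planted hypo sites; ten further marks are background.
Expression for genes whose promoter hosts a planted hyper site follows
$\log_2(\mathrm{FPKM}+1) = 5 - 4\,c\,\beta + \varepsilon$ (exactly affine,
$r = -1$, at zero noise). Half the mutations land within ±4 kb of planted
hypo sites in samples chosen with probability $\propto e^{2z}$ of the
site's beta z-score; the rest are uniform over probes and samples.

What the generator does **not** emulate: probe-level chemistry (IDAT-level
signals, dye bias), real genome sequence and CpG spacing, spatial
correlation between neighbouring probes, copy-number events, age/sex
covariates, and the ontology graph structure of real gene sets. Passing
tests therefore demonstrate that the implementation recovers the structure
it models, not that the biological conclusions transfer to any real cohort.

One interaction deserves note: when the mutation coupling is switched off
but planted methylation differences remain, the z-score distribution at
planted hypo sites is structurally bimodal (two group means) while the
open-sea background is unimodal, so the KS test still rejects — for shape
reasons unrelated to mutation placement. The clean null for the coupling
check is therefore a cohort with both the coupling and the planted
difference at zero, which is what the test suite uses for the off-arm.

## Problem sizes and runtimes

The packaged checks run the full design (5000 probes, 29 samples, 500
planted sites) for recovery, signature-geography, mutation and classifier
properties, across five seeds where a criterion asks for replication;
calibration checks use 2000-probe null cohorts; unit fixtures use 600–1000
probes. The resampling oracle comparison uses 100,000 draws on toy
universes and the null-uniformity check pools 30 terms over 200
repetitions at 500 draws each. End-to-end, `run_pipeline("all", ...)` at
the default size completes in well under a minute per stage on a single
CPU, with BMIQ the dominant cost.

## Known limitations

* The gene assignment is a nearest/overlap rule, not a transcript-aware
  annotator; probes in dense gene neighbourhoods may be attributed to a
  plausible but different gene than a full annotation pipeline would pick.
* The GLS working covariance is shared across probes; probe-specific batch
  loadings are handled only through the whitening geometry, which is the
  standard trade-off of control-based unwanted-variation methods.
* The empirical resampling p has resolution $1/B$ and is super-uniform
  under the null (conservative), which is visible as a small systematic
  KS distance from uniformity.
* Real headline quantities from the motivating study design (e.g. absolute
  significant-site counts on 450K arrays) depend on external cohorts and
  are out of scope; the pipeline reports the analogous quantities computed
  on its synthetic cohorts.
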