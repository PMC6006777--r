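---
title: "Methods: the confounder-corrected eCpG scan and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the confounder-corrected eCpG scan and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecpgscan)
```

## The problem

DNA methylation at a CpG can track the expression of a transcript for two
very different reasons: a genuine regulatory relationship (promoter or
enhancer methylation modulating transcription, possibly at long range or
across chromosomes), or a shared nuisance factor — above all cellular
heterogeneity in blood, which shifts both the methylation profile and the
transcriptome of a bulk sample. An all-pairs scan of hundreds of thousands
of CpGs against tens of thousands of transcripts multiplies any such
nuisance into millions of spurious associations. `ecpgscan` implements the
mixed-model correction that addresses this, the positional classification
of the resulting eCpGs, the corroboration and enrichment analyses around
them, and a synthetic-data module that makes every stage testable with
known truth.

## The mixed model and the intersample correlation matrix

For transcript $k$ and CpG $j$,
$$y_k = \mu_k + M_j a_{jk} + x\beta_{jk} + u_k + \epsilon_{jk},
\qquad u_k \sim N(0, \sigma^2_g H),\quad \epsilon_{jk} \sim N(0, \sigma^2_e I).$$

$H$ is estimated from the expression matrix itself: standardize each
transcript row to mean 0, sd 1 (sd with the $n-1$ denominator), and set
$\hat H = Z^\top Z / m$. Samples that share unmeasured drivers of global
expression — cell-type composition, technical batches — are correlated in
$\hat H$, and the random effect $u_k$ absorbs exactly that structure. The
construction mirrors the kinship-style estimators of mixed-model
association engines, with transcripts in the role of markers.

Fitting uses the spectral trick those engines rely on: one
eigendecomposition $H = U S U^\top$, computed once per scan, rotates every
vector into a frame where the covariance is diagonal,
$\sigma^2_g(S + \delta I)$ with $\delta = \sigma^2_e/\sigma^2_g$. The
likelihood is profiled over $\delta$ on 100 log-spaced points in
$[10^{-5}, 10^5]$ with golden-section refinement between the bracketing
grid points; estimation is maximum likelihood. (Restricted ML is the main
alternative; ML was chosen because $\delta$ is a per-fit nuisance whose
small-sample bias cancels in the Wald ratio, and because the identity-H
collapse below pins the statistic anyway.) The Wald statistic $T =
\hat a/\mathrm{se}(\hat a)$, with the residual variance estimated on
$n - q$ degrees of freedom ($q$ = estimable design columns including the
CpG), is referred to a $t_{n-q}$ distribution — deliberately conservative
relative to a normal reference at moderate $n$. With $H = I$ the whole
machinery reduces algebraically to ordinary least squares, which the test
suite asserts to $10^{-8}$ on random instances; OLS is also exposed
directly (`method = "ols"`) as the uncorrected comparator.

### Rank deficiency and the leave-one-out correction

Two numerical facts shape the implementation. First, row standardization
annihilates the all-ones vector, so $\hat H$ always has at least one zero
eigenvalue, and when fewer transcripts than samples are available
($m < n$) it is rank deficient outright. Eigenvalues are clamped at
$10^{-6}\lambda_{\max}$ inside the `intersample_correlation` object, but
fits are restricted to the positive eigenspace (with design columns that
vanish there, such as the intercept, dropped and the degrees of freedom
reduced accordingly): directions in which the estimated $H$ carries no
information contribute artifacts, not signal.

Second, the focal transcript is itself one of the $m$ rows that built
$\hat H$. Its standardized profile therefore lies exactly in the row space
of $Z$, it has zero residual in the null space of $\hat H$, and directions
aligned with it carry inflated eigenvalues — which attenuates that
transcript's own statistics (empirically, a type-I rate of ~0.043 at
nominal 0.05 in a pure-null scan). `ecpg_scan()` therefore tests each
transcript against the leave-one-out matrix
$H_{(k)} = (m\hat H - z_k z_k^\top)/(m-1)$. This needs no extra
eigendecompositions: in the rotated frame $H_{(k)}$ is a rank-one downdate
handled by the Sherman–Morrison identity, and when $z_k$ is linearly
independent of the other transcripts the single null direction of
$H_{(k)}$ (the transcript's own residual direction, $v \propto D^{-1}\hat
z_k$) is projected out exactly. With this correction the pure-null scan
sits inside the 99% binomial band at $\alpha = 0.05$ and planted effects
are recovered with relative bias under 1%; both checks are in
`test-acceptance.R`.

For speed, the scan estimates $\delta$ once per transcript under the
covariates-only model and reuses it for all CpGs of that transcript (the
two-step scheme of genome-scale mixed-model scans); the single-pair
`fit_lmm()` re-profiles $\delta$ with the CpG in the design. The two agree
closely because a single CpG barely moves the variance components.

### Inflation control

Per transcript, `GIF = median(T^2) / qchisq(0.5, 1)`; transcripts with
GIF > 2 are removed after the scan and before classification. Tiers use
strict thresholds: suggestive $p < 10^{-5}$, significant $p < 10^{-11}$,
the latter being `bonferroni_alpha(5e9, 0.05)`.

## Positional classification

Coordinates are 0-based half-open throughout (BED-native on I/O); a CpG is
the point coordinate of its C. Broad categories: **trans** (different
chromosome), **distal** (same chromosome, $\ge$ 50 kb from the gene span —
"within 50 kb" is strict, and distance is measured to the span between TSS
and TES, not to the TSS alone, so intragenic CpGs are cis at distance 0),
**cis** otherwise. Within cis, detailed categories are assigned with the
precedence

`near_promoter` > `in_gene_body` > `closest_downstream_gene` >
`closest_upstream_gene` > {`closer_5prime`, `closer_3prime`,
`gene_between`, `in_different_gene`} > `multiple_closer_between`,

all strand-aware. The promoter window is ±2500 bp around the TSS
(inclusive); the gene body is the span more than 2500 bp downstream of the
TSS, so the promoter wins the overlap zone just downstream of the TSS.
The "closest gene" comparisons use the next closest *other* gene, with
distance ties broken toward the associated gene in the closest-downstream
role. `multiple_closer_between` applies when more than one of the four
non-canonical predicates holds. The first four categories are the
canonical methylation–expression roles; canonical implies cis.

One subtlety is worth recording: the I/O layer reports TSS/TES as BED
boundary coordinates (TSS = `end` for minus-strand genes), but distances
are computed between *base* positions (`end - 1` for the minus-strand
TSS). Boundary coordinates are not invariant under mirroring the genome
(coordinate reflection plus strand flip) — they shift by one base — while
base positions are. The test suite asserts exact classification invariance
under `mirror_genome()`.

Multi-location expression probes are resolved per eCpG: candidates
annotatable to a gene are preferred; among them the same-chromosome
closest location wins, with ties broken by the primary > secondary > other
match rank and then by coordinate.

## Corroboration

**Between studies:** a pair replicates only on exact agreement of CpG id,
probe id, resolved probe location and correlation sign. The null
distribution comes from shuffling probe ids within each (study, broad
category) stratum — a permutation, not a bootstrap, so probe frequencies
are preserved — and recomputing the overlap; the observed overlap on
half-shared synthetic studies exceeds the null's 99th percentile.
Exact-location matching (rather than overlap) is the stricter of the two
readings of "same probe location" and is what is implemented.

**Within studies:** for windows of 100–2000 bp, among eCpGs with at least
one neighboring eCpG (query excluded, boundary inclusive), three nested
fractions: sharing at least one associated gene with some neighbor;
sharing gene and direction with some neighbor; and having *all* neighbors
congruent. Sharing is by resolved gene id, not probe id. The nesting
inequality holds by construction and is asserted on random data, as is the
monotone decline of full congruence with window growth (restricted to the
eCpGs that already had a neighbor at the smallest window — the unrestricted
fraction can jump when new queries enter the denominator).

## Enrichment

Shores are the 1.5 kb bands flanking merged CpG islands (islands
subtracted); shelves the next 1.5 kb (islands and shores subtracted);
interval arithmetic is delegated to IRanges and cross-checked against a
per-basepair oracle. Membership is point-in-half-open-interval. Fisher
2-by-2 tests run in two designs: across all tested CpGs (eCpG status vs.
feature), and within significant pairs (classification vs. feature, each
unique CpG–transcript pair counted once). The two-sided p-value is
computed by hypergeometric enumeration with the same tie rule as
`stats::fisher.test` (asserted equal on a random subset; the in-package
version is vectorized so the full enumeration over every table with total
$\le 40$ runs in seconds). The odds ratio is the cross-product $ad/bc$
with Haldane–Anscombe +0.5 on zero cells applied to the OR and its Wald CI
only — never to the p-value. Intermediate methylation means a mean beta in
$[0.2, 0.8]$, boundaries inclusive. ChromHMM groupings follow the printed
conventions of each analysis: promoters 1–3, strong enhancers 4–5, weak
6–7, insulator 8 for the feature panels; the gene-body sign analysis uses
promoters 1–3 vs. enhancers 4–8. Both are plain arguments to
`chromhmm_state_track()`, so either convention is a one-liner. Term
enrichment is the one-sided hypergeometric upper tail with BH FDR;
intergenic CpGs map to the gene with the closest downstream TSS
(strand-aware), intragenic CpGs to their host gene.

## Power arithmetic

`power_of_r2(n, alpha, r2)` is the noncentral-F power of the single
predictor test: critical value from central $F(1, n-2)$ at `alpha`,
noncentrality $n\,r^2/(1-r^2)$. Covariates are deliberately not counted in
the degrees of freedom: the detectability claims this reproduces predate
covariate bookkeeping, and at the relevant $n$ a ±1 df change is
invisible at two significant figures. `min_r2_detectable()` inverts it by
bisection to $10^{-6}$. At $\alpha = 10^{-11}$ and 80% power this gives
15.9% variance explained at $n = 333$ and 4.73% at $n = 1202$ — 16% and
4.7% at the two-figure precision the claims are stated at. The test suite
also checks the model empirically: planted effects at $r^2 \in \{0.05,
0.16, 0.5\}$, $n = 500$, scanned with the mixed model, yield empirical
power within two Monte-Carlo standard errors of the analytic value.

## The synthetic cohort generator

The generator emulates the statistical features the scan relies on, not
array chemistry:

* **Beta values.** A fraction `bimodal_fraction` (default 0.8) of CpGs is
  assigned a fully methylated or unmethylated mode with probability 1/2 —
  per-sample draws from Beta(10, 0.5) or Beta(0.5, 10) — and the rest are
  intermediate, Beta(5, 5). Assigning the mode per CpG (rather than mixing
  within a CpG) is what makes the distribution of *average* beta values
  bimodal, the array-wide signature the defaults are meant to reproduce,
  while leaving an intermediately methylated subpopulation where most
  detectable signal lives.
* **Confounders.** Each sample draws standard-normal loadings on K latent
  factors. Factors perturb every transcript (weights $N(0,1)$, scale 0.5
  log-units, i.e. roughly 40% of a null transcript's variance at K = 3)
  *and* every CpG on the logit scale (scale 0.5). Cellular heterogeneity
  acts on both assays; confounding that touched expression only would be
  statistically invisible to a per-pair test (an independent predictor is
  exactly null-calibrated regardless of the response's covariance), so
  both loadings are needed for the generator to reproduce the inflation
  the correction exists to remove. `confounder_scale_meth = 0` recovers
  the expression-only variant.
* **Covariates.** Age ~ Uniform(18, 78), sex ~ Bernoulli(0.5), with small
  effects (sd 0.005 per year, 0.25 per sex class) on a random 10% of
  transcripts.
* **Planted effects.** The effect size is calibrated against the realized
  baseline, $a = \pm\sqrt{v/(1-v)}\,\mathrm{sd(base)}/\mathrm{sd}(\beta)$,
  so the requested variance explained is realized within Monte-Carlo
  tolerance (±0.05 at $n \ge 500$, asserted over 20 seeds).
* **Determinism.** All randomness flows through the single required seed;
  identical arguments give bit-identical matrices.

The toy genome's first three genes per chromosome follow a fixed template
engineered so that *every* detailed classification category is realized by
at least one (CpG, gene) pair — including the single-predicate
configurations (a gene-between without a closer opposite TSS, a
closer-3-prime against a long minus-strand gene) and a nested gene pair
for the overlapping promoter/body scenario. Background CpGs are scattered
at the requested density on top.

What passing tests on this testbed do **not** show: robustness to probe
artifacts, batch structure, spatially correlated methylation, non-Gaussian
expression noise, or the real arrays' probe-quality blacklists — all
explicitly outside the generator's remit.

## Problem sizes and numerical choices

The suite's calibration scan uses 200 transcripts by 500 CpGs at n = 300
(100,000 tests — large enough that the 99% binomial band at
$\alpha = 0.05$ is ±0.0018 wide); confounder-correction replicates use 50
transcripts by 200 CpGs at n = 200, twenty seeds; parameter recovery uses
600 transcripts at n = 500 with 150 planted effects per effect-size level.
Simulated cohorts for power comparisons keep $m \ge n$, the regime the
estimator is built for (real arrays have $m \gg n$); with $m < n$ the
support truncation costs noncentrality in proportion to the discarded
dimensions and empirical power falls below the analytic curve.
Degenerate inputs: constant transcripts are excluded with a warning before
standardization, constant (or collinear) CpG vectors yield NA records in
the scan and an explicit error in `fit_lmm()`, zero residual variance
floors the p-value at the smallest positive double with a flag, and
distance bins without array CpGs report NA rather than zero. Sample
alignment is by id everywhere; order never matters, and mismatches name
the offending ids.

## Known limitations

* The grid bound $\delta \le 10^5$ effectively caps how close to pure OLS
  a fit can get; in practice the profile is flat there and the impact is
  below test tolerance.
* The leave-one-out correction assumes the focal transcript entered H with
  weight $1/m$; if a user supplies a precomputed H not derived from the
  scanned expression matrix, `loo` should be disabled.
* Between-study matching requires exact probe locations; replicates whose
  locations merely overlap are counted as non-matching.
* The power model ignores covariates and the mixed-model correction; it is
  exact for the identity-H single-predictor test and an approximation
  otherwise (empirically indistinguishable at the tested sizes).
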