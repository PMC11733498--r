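---
title: "Haploblock discovery and parallel-adaptation scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploblock discovery and parallel-adaptation scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscan)
```

# Overview

`haploscan` implements a population-genomic pipeline for species sampled
across latitudinal gradients in multiple ranges (for example a native range
and one or more invaded ranges): discovery and genotyping of large
structural-variant haploblocks from local population structure, tests of
latitudinal frequency clines against a random-SNP empirical null,
whitened differentiation and group-contrast genome scans aggregated into
10-kbp windows, enrichment statistics for haploblock involvement among
outlier windows, and degeneracy-based genetic-load estimation. A
synthetic-data generator reproduces the statistical structure each stage
relies on, so the whole pipeline is testable without external data.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
emulate.

# Haploblock discovery by local PCA

Chromosomal inversions and other large structural variants suppress
recombination between their two arrangements. Within the affected interval,
samples separate by arrangement genotype rather than by geography, so the
population structure computed locally differs sharply from the genome-wide
background. The discovery stage exploits this:

1. **Window covariances.** Dosages in 100-kbp windows are mean-imputed
   (missing entries only), centered per site, and averaged into a
   samples-by-samples covariance. Windows with fewer than `min_sites`
   polymorphic SNPs (default 25) are skipped. We chose 25 because at a
   typical filtered density of ~0.5 SNP/kbp a 100-kbp window holds ~50
   SNPs, and a higher floor would randomly drop about half of all windows
   and fragment the contiguous runs the merging step depends on; 25 keeps
   essentially all windows while still rejecting near-empty ones.
2. **Window distances.** Each covariance is trace-normalized and truncated
   to rank `k` (default 2); the distance between two windows is the
   Frobenius norm of the difference of their truncated matrices. The
   truncation compares the leading structure (the part an inversion
   distorts) while discarding sampling noise in trailing axes. The
   pairwise matrix is evaluated through the Gram identity
   `||A-B||^2 = ||A||^2 + ||B||^2 - 2<A,B>`, which is exact up to
   floating-point cancellation of order 1e-8 near zero distances.
3. **MDS embedding.** Classical (Torgerson) multidimensional scaling of the
   distance matrix onto 5 axes. Axis signs are fixed by making the
   largest-magnitude loading positive, so runs are reproducible.
4. **Corner outliers.** "Corners" of each of the 10 axis pairs are
   formalized as the four diagonal directions `(±1, ±1)/sqrt(2)`; a window
   is an outlier for a corner when its projection onto that direction
   exceeds the 95% quantile of all projections (tail configurable,
   default 0.05).
5. **Merging.** Same-chromosome outliers from the same corner merge into a
   candidate region when separated by at most `max_gap = 1` intervening
   windows; regions need at least `min_windows = 3` supporting outlier
   windows. Overlapping regions from different corners are unioned. This
   replaces the manual curation of MDS plots that an analyst would
   otherwise perform; the two knobs are exposed in the API.

# Genotyping and validating haploblocks

Within a candidate region a PCA of the region's SNPs separates samples into
three clusters along PC1 — the two homokaryotypes and the heterokaryotype.
Genotyping is 1-D k-means with k = 3, centers initialized at the minimum,
median and maximum score. The middle cluster is labeled AB; orientation is
fixed so that A is the globally more frequent arrangement (overridable), so
cline signs are comparable across runs.

K-means always returns three occupied clusters on continuous data, so
"three clusters present" is not by itself evidence of trimodality. A call
is therefore accepted only when the mean 1-D silhouette of the partition is
at least `min_silhouette = 0.75`. Genuine haploblocks produce extremely
tight clusters (silhouettes above 0.95 in simulation), while k-means on
unimodal PC1 scores rarely exceeds ~0.65, so 0.75 separates the two regimes
with margin; the threshold is exposed for unusual data. Samples farther
from every center than half the smallest center gap are left unassigned and
excluded from frequencies and tests rather than force-assigned.

Two diagnostics validate a call:

* **Heterozygosity test.** Heterokaryotypes should be heterozygous across
  the block. Per-sample observed heterozygosity (fraction of heterozygous
  genotypes among the region's SNPs) is summarised per class by mean ± SEM;
  the test passes when the AB band is disjoint from both homozygote bands
  and has the highest mean. Classes with fewer than 2 samples make the test
  "inconclusive", not failed. Note this uses called genotypes, not a
  genotype-likelihood estimator of heterozygosity; at moderate depth the
  two agree in expectation but hard calls are noisier at low depth.
* **LD contrast.** Composite-genotype r² (squared Pearson correlation of
  dosages) over pairs of up to 5,000 region SNPs with MAF > 0.05, computed
  on all samples and again within the major-homozygote subset. Arrangement
  segregation couples all arrangement-associated sites, so LD is high
  overall and collapses within homokaryotypes where recombination is free.
  The pass rule — median r² drop of at least `delta = 0.2` — is a
  package-defined operationalization of that qualitative expectation and is
  reported, not used, for confirmation.

A region is **confirmed** when it is trimodal and passes the heterozygosity
test; LD is reported as a diagnostic. Requiring both het and LD is stricter
than some analyses need, and the choice is configurable.

# Latitudinal clines and the random-SNP null

Arrangement (or allele) frequency is modeled against absolute latitude with
a binomial logistic regression per individual (dosage out of 2 trials),
fitted by iteratively reweighted least squares. On perfect separation the
fit is repeated with a ridge penalty of 1e-6 and flagged. Per-individual
fitting uses all samples and tolerates unequal population sizes; a
population-level weighted alternative would give similar slopes under
balanced designs.

Significance is not parametric: a haploblock's slope is compared against
the empirical distribution of slopes from 10,000 SNPs sampled outside genes
and haploblocks. The default call is two-sided (2.5% in each tail, 5%
total) because parallelism inference needs signed directions; a one-sided
mode is available, and the mode is recorded in the output. Non-converged or
separated null fits are excluded and counted. A unit is "parallel" when its
slope is significant with the same sign in at least two ranges.

# Whitened genome scans

Per-population allele frequencies (populations with n > 2) are standardized
per SNP at the across-population mean:
`ptilde_j = (p_j - pbar) / sqrt(pbar (1 - pbar))`. The covariance Ω of these
vectors across 10,000 background SNPs summarises shared demography (drift
covariance plus finite-sample noise); it is shrunk toward its diagonal with
weight 0.05 because centering at the per-SNP mean makes the raw covariance
rank-deficient (the standardized vector sums to ~0).

* **XtX surrogate.** `XtX* = J/(J-1) * ptilde' Ω⁻¹ ptilde`. The `J/(J-1)`
  factor restores the degree of freedom absorbed by centering at the
  across-population mean, so the statistic calibrates at `E[XtX*] ≈ J`
  under neutrality (the same calibration point as the Bayesian
  differentiation statistic it replaces). This is a closed-form moment
  surrogate, deterministic and testable against its null — not an MCMC
  posterior; outputs are labeled accordingly.
* **Contrast surrogate.** For two predefined groups (e.g. native vs
  invaded), `C* = (c' ptilde)² / (c' Ω c)` with contrast weights `1/J1` and
  `-1/J2`. Under neutrality `C*` is approximately χ²(1). The approximation
  is exact at the level of population frequencies; with finite samples
  (e.g. 20 diploids per population) frequencies are discrete, and tied
  group sums put a small atom of probability (~2-3%) at `C* = 0`. This
  matters only for strict distributional tests, not for outlier ranking,
  which uses genome-wide empirical ranks.
* **Environment association.** Tie-corrected Kendall τ-b between population
  frequencies and an environmental variable, with empirical p from the
  genome-wide rank of |τ|.
* **Fay & Wu's H.** `H = θπ - θH` over the unfolded SFS of polarized sites;
  windows with no polarized segregating sites are undefined and sites with
  unknown ancestral state are excluded and counted.
* **Association scan.** Per-SNP linear regression of a phenotype on dosage
  with the first two genotype PCs (computed from background SNPs) absorbed
  by projection — a simplified covariate-adjusted scan, not a
  mixed-model GWAS.

Per-SNP statistics become empirical p-values by genome-wide rank
(`rank/(N+1)`, so p never reaches 0 or 1; ties share average ranks) and are
aggregated into 10-kbp nonoverlapping windows with the weighted-Z analysis:
`z_i = Φ⁻¹(1 - p_i)`, weights `w_i = pbar_i (1 - pbar_i)`,
`Z_W = Σ w z / sqrt(Σ w²)`. The weight is the heterozygosity implied by the
mean across-population frequency; published weighted-Z variants differ in
this choice and the variant used is recorded here. Windows with fewer than
2 SNPs are flagged and excluded from ranking. Outlier tails follow the
scan presets: 5% for differentiation/environment scans, 1% for contrasts,
0.1% for trait associations.

# Enrichment statistics

Window-level units throughout: a window belongs to a haploblock when its
midpoint falls inside the interval (an overlap-fraction rule is available).
Haploblock enrichment among outlier windows is an upper-tail hypergeometric
test, Bonferroni-corrected across haploblocks; cross-range parallelism of
outlier sets is the upper-tail hypergeometric p of their intersection; and
the overall shift of haploblock windows is a two-sided Mann–Whitney U test
with conventional star coding. Upper-tail tests are the default because the
scientific claims are enrichments.

# Degeneracy and genetic load

A coding position is zero-fold degenerate when every substitution changes
the amino acid and four-fold degenerate when none does; substitutions
creating or destroying a stop codon count as changes, since they are
nonsynonymous in effect. Classification enumerates the three alternative
bases under the standard genetic code. The genomic map resolves CDS
features through strand and phase (minus-strand codons read from the
reverse complement; the phase field skips leading bases), skips transcripts
whose CDS is not a codon multiple after phase adjustment, and marks sites
with conflicting classes across overlapping transcripts as ambiguous.

Genetic load is proxied by the mean derived allele frequency at zero-fold
sites. Groups are first downsampled to a common number of individuals so
they are compared at equal sample size; sites with unknown ancestral state
are excluded (polarization is an input, not something this package infers).
Confidence intervals use a site-subsampling bootstrap — each of 100
replicates redraws 20% of sites without replacement and the CI is the
2.5%/97.5% band of replicate means. This subsample-of-sites scheme is
deliberately the default; a classical full-size resample with replacement
is available behind a flag. Subsampling at 20% yields wider intervals than
the classical bootstrap by roughly `sqrt(0.8/0.2) ≈ 2`, so comparisons
between groups are conservative.

# The synthetic-data generator

The generator emulates exactly the structure the estimators consume:

* **Neutral background.** Unlinked SNPs; ancestral frequency
  `π ~ Uniform(0.05, 0.95)`; population frequencies from the Beta drift
  model `p_j ~ Beta(π(1-F)/F, (1-π)(1-F)/F)` with drift intensity
  `F = 0.1` by default; Hardy–Weinberg dosages within populations. This
  yields the exchangeable drift covariance that Ω estimation and whitening
  assume.
* **Haploblocks.** A latent arrangement genotype per sample,
  `Binomial(2, q_j)`, with `logit(q_j)` linear in absolute latitude
  (default: frequency 0.1 at the lowest latitude, slope 0.1/degree, hence
  ~0.9 at the highest). Marker SNPs are fixed differences between
  arrangements perturbed by within-arrangement diversity `ε = 0.02`: with
  probability ε a marker dosage is resampled as Binomial(2, 0.5), so
  heterokaryotypes are heterozygous at `1 - ε/2` of markers and
  homokaryotypes at `ε/2`. The default density of 3,000 markers per 2-Mbp
  block makes arrangement-linked sites the majority of region SNPs,
  matching real inversion haploblocks in which most segregating sites in
  the region associate with the arrangement.
* **Traits.** `y = a·g_hb + Σ b_k g_k + e` with Normal polygenic effects
  and residual.
* **Coding contig.** Random intact CDS on a separate small contig, with
  minus-strand and phased multi-exon genes always present; coding SNPs at
  known zero-fold/four-fold positions, with derived frequencies
  `Beta(0.5, 2)` at four-fold sites and the same draw multiplied by 0.35 at
  zero-fold sites to emulate purifying selection.

Default scale — 10 populations × 20 diploids spanning latitudes 10–54°,
2 × 20 Mbp chromosomes, 20,000 background SNPs — runs end-to-end in tens of
seconds per replicate on one core. The latitude span is wide because the
default cline covers frequencies 0.1→0.9 at 0.1 logit units per degree;
narrower gradients with steeper slopes are equivalent for every test here.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage and recombination outside
haploblocks (background SNPs are unlinked, so there is no background LD
structure and no LD decay); genotype uncertainty from low-coverage
sequencing (the pipeline operates on called genotypes; the corner-outlier
sensitivity of hard calls at low depth relative to genotype-likelihood
methods is untested); admixture, isolation-by-distance and other
non-exchangeable demography (drift is exchangeable across populations);
gene flow between arrangement classes (no gene conversion or double
crossovers); and selection acting through time (purifying selection is a
static downweighting of derived frequencies).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF positions convert at
  the boundary.
* Missing dosages are mean-imputed only inside PCA/covariance computations;
  frequency statistics always use the raw calls, keeping them unbiased.
* Multi-allelic sites are dropped, not split.
* Ancestral-state resolution order: sidecar table, then the configured INFO
  tag, then unknown; unpolarized sites are excluded from H and load.
* All-zero distance matrices return a flagged degenerate MDS map; windows
  and regions below their site minima are skipped or rejected with recorded
  reasons; empty groups yield missing frequencies rather than errors.
* Empirical p-values use `rank/(N+1)` to avoid zeros; ties share average
  ranks.
* Ω is shrunk toward its diagonal (weight 0.05) and its condition number
  checked; a singular Ω after shrinkage is an error, not a silent
  pseudo-inverse.
* IRLS runs at most 50 iterations to a step tolerance of 1e-8; separation
  triggers a ridge (1e-6) refit and a flag.

# Known limitations

* The discovery stage automates what is often manual curation; its merging
  heuristics approximate, and cannot reproduce, expert judgement.
* The XtX and contrast statistics are moment surrogates: they share the
  whitening idea with their Bayesian namesakes but not the hierarchical
  shrinkage of allele frequencies, and will differ most at extreme
  frequencies and small population counts.
* Heterozygosity and derived-frequency estimates use called genotypes;
  low-depth datasets are better served upstream by genotype-likelihood
  machinery before entering this pipeline.
* Breakpoint refinement, inversion-vs-deletion classification, phasing and
  variant calling are out of scope.
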