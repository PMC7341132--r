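---
title: "Multi-allelic haplotype GBLUP and training-population optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-allelic haplotype GBLUP and training-population optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogs)
```

## The problem

Genomic selection in self-fertilized crops predicts the breeding value of
unphenotyped lines from genome-wide SNP genotypes. Two design choices
drive its accuracy in structured breeding panels:

* **the marker model** — single SNPs treated as biallelic additive loci,
  versus fixed-length *haplotype blocks* treated as multi-allelic loci,
  which capture local linkage disequilibrium (LD) and short-range allelic
  interactions that no single SNP tags; and
* **the calibration set** — random *k*-fold partitions of the panel,
  versus *stratified sampling* that draws a fixed fraction from every
  population cluster so all subpopulations are represented.

`haplogs` implements both axes end to end for inbred panels: HapMap
genotype input and QC, spatial adjustment of field-trial phenotypes,
REML heritability, haplotype-block construction, population-structure
diagnostics, single-SNP and multi-allelic haplotype GBLUP, and the
validation schemes and comparison statistics used to contrast them.

## Models

### Single-SNP GBLUP

The mixed model is
$$y = 1\mu + W_\alpha \alpha + e,$$
with $W_\alpha$ the $n \times m$ centered additive design: a line's entry
for a marker is $x_1 - 2p_1$ where $x_1$ counts copies of the A allele
and $p_1$ is its frequency in the reference line set, giving the
classical codings $2p_2$, $p_2 - p_1$, $-2p_1$ for the three genotypes.
Effects are i.i.d., $\mathrm{Var}(\alpha) = I\sigma^2_\alpha$, residuals
$\mathrm{Var}(e) = I\sigma^2_e$, so
$\mathrm{Var}(y) = W_\alpha W_\alpha' \sigma^2_\alpha + I\sigma^2_e$.

### Multi-allelic haplotype GBLUP

Each run of $L$ adjacent mapped markers within a chromosome is one
*block*; every distinct $L$-marker genotype vector observed across the
(fully inbred, hence phased) panel is one *haplotype allele* of that
block, numbered by first appearance. The haplotype design has one column
per (block, allele) with entries $x_k - 2p_k$, $x_k \in \{0, 2\}$ the
allele copy number. The classical printed multi-allelic codings
($2p_k$, $-(1-2p_k)$, $-2(1-p_k)$) equal these centered counts up to a
global sign; since GBLUP predictions are invariant to a global sign (and
to any scalar rescaling) of the design, the two conventions are
interchangeable, which the test suite asserts. With $L = 1$ the two
columns per marker are exact negatives of each other and the haplotype
model reproduces single-SNP predictions to numerical precision — a
strong internal consistency check.

### REML

Both models have two variance components. The restricted likelihood is
profiled on the ratio $\varphi = \sigma^2_\alpha / \sigma^2_e$ over the
eigen-spectrum of the intercept-projected training kernel
$S W W' S$ ($S = I - 11'/n$): the projected data are expressed on all
$n$ eigenvectors, the intercept direction contributing exactly zero, so
the reduction is valid whatever the kernel rank (when the kernel rank is
below $n-1$ the null space mixes the intercept with genuine residual
directions, and dropping a single eigenvector would corrupt the
transform — a subtlety the unit tests cover with $m < n$ instances).
The ratio is located by a coarse scan over $\log\varphi \in
[\log 10^{-9}, \log 10^{9}]$, refined by Brent search and polished by
closed-form Newton steps to relative precision $10^{-13}$; the residual
variance then has a closed form. A fit whose optimum sits at the scan
boundary is flagged `converged = FALSE`. The variance floor is
$10^{-12}$. We chose this profiled eigen-form over iterative EM updates
because it is exact, fast at panel scale, and free of step-size tuning;
a brute-force optimization of the explicit-matrix restricted likelihood
serves as the independent oracle in the tests.

Prediction is train-then-project:
$\hat\mu$ by GLS on the training lines,
$\hat\alpha = \hat\sigma^2_\alpha W_t' V^{-1}(y_t - 1\hat\mu)$ with
$V = W_t W_t'\hat\sigma^2_\alpha + I\hat\sigma^2_e$, and additive values
$a = W\hat\alpha$ for every line. This equals the joint
mixed-model-equations solution with unobserved phenotypes (asserted
against the effect-level ridge solution in the tests). Design
frequencies default to the full genotyped panel — candidate genotypes
are always available in genomic selection — with a training-only option
for sensitivity analyses.

## Phenotype pipeline

Plot values from each trial are adjusted with a **moving-grid**
covariate: the mean of observed values in the 3×3 ring of 8 surrounding
plots (shrinking at field edges), used as a covariate in a single-slope
regression, so the adjustment removes what a smooth local trend can
explain while preserving the trial grand mean. A zero-variance covariate
(e.g. a constant field) skips adjustment with a warning. Trials are then
centered on their own means and a line's values averaged across trials.

Variance components for broad-sense heritability come from the
plot-level mixed model `value ~ trial (fixed) + line (random)`, fitted
by REML via `lme4`; the entry-mean heritability is
$$H = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e / n},$$
with $n$ the number of trials. Residual variance requires at least two
trials (or replicated lines) to be identifiable.

## Population structure and LD

* **GRM**: $A = ZZ' / \big(2\sum_i p_i(1-p_i)\big)$, $Z = M - P$ with
  $M$ the $-1/0/1$ coded genotypes and $P_i = 2(p_i - 0.5)$.
* **Distance**: $1 - \mathrm{IBS}$, the mean shared-allele proportion.
* **Clustering**: because K-means needs coordinates, the distance matrix
  is embedded by classical multidimensional scaling (10 principal
  coordinates by default) and Hartigan–Wong K-means is run with 100
  seeded restarts, keeping the lowest inertia. K defaults to 3,
  matching a pedigree-informed choice for a three-family panel.
* **PCA** of the centered (unscaled) dosage matrix — standard for
  dosage data; scaling is not applied since rare alleles would otherwise
  be up-weighted.
* **Adjacent LD**: for inbred lines gametic phase is observed, so
  two-locus haplotype frequencies are read directly from the homozygous
  genotypes and $r^2 = D^2 / (p_A p_a p_B p_b)$; this equals the squared
  Pearson correlation of the dosage vectors (asserted to $10^{-12}$).
  The genome-wide mean is the mean of per-chromosome means, weighting
  chromosomes equally.

## Validation schemes and comparison statistics

* `make_kfold()` — per repetition, shuffle and split into *k* folds of
  near-equal size (defaults k = 4, 4 repetitions); every line is
  validated exactly once per repetition.
* `make_stratified()` — per replicate, draw round-half-up
  (fraction × cluster size) lines from every cluster (defaults 0.75, 16
  replicates). Half-up rounding is used because banker's rounding makes
  sample sizes depend on parity; for a 383-line panel in clusters of
  176/89/118 this yields 288 training and 95 validation lines. No
  global total reconciliation is applied: the per-cluster shares *are*
  the definition of the scheme.
* `leave_cluster_out()` — train on all clusters but one, predict the
  held-out cluster; the structure penalty shows as lower predictive
  ability than k-fold.

Predictive ability is the Pearson correlation between adjusted
phenotypes and predicted additive values in the validation set. Per
replicate values are Fisher-Z transformed ($z = \operatorname{arctanh} r$)
before the paired *t*-test contrasting the haplotype and single-SNP
models on identical calibration sets; the percent change is reported on
the mean-$r$ scale. The significance statistic for a single $r$ is
$T = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n$ the validation-set size (the
standard reading of the formula; $t_{n-2}$ reference).

## The synthetic-population generator

Because the real panel cannot be redistributed, `sim_config()` /
`simulate_population()` generate a stand-in with the statistical
structure the analysis assumes:

* **Structure** — cluster allele frequencies drawn around an ancestral
  frequency by a Balding–Nichols beta draw with drift parameter
  `divergence` (default 0.3; at 0 every cluster shares one founder pool
  and no structure exists).
* **LD** — per cluster, a pool of `founder_count_per_cluster` (default
  10, a plausible count of effective founders for a breeding-program
  family) founder haplotypes is generated by a Markov copy process:
  adjacent alleles are copied with probability
  $\exp(-\texttt{ld\_decay} \cdot d_\mathrm{cM})$. Each line is a
  recombinant mosaic of founders with long shared segments
  (switch rate 0.01/cM). With the default `ld_decay` = 0.15/cM and
  ~1.5 cM marker spacing, mean adjacent $r^2$ lands in the 0.5–0.7 band
  typical of selfing wheat panels.
* **Traits** — `qtl_mode = "snp"` draws additive effects at causal
  markers; `qtl_mode = "haplotype"` assigns an independent effect to
  every distinct haplotype observed in causal windows of `qtl_span`
  adjacent markers laid on the non-overlapping span grid (the
  generator's definition of a haplotype-local architecture; aligning
  windows to the grid makes the matched-length block model the
  correctly specified one). True additive values are standardized to
  unit variance, so the residual scale for a target entry-mean
  heritability $H$ over $n$ trials is simply $n(1-H)/H$.
* **Fields** — plots are placed randomly on a row×column grid per trial
  and a quadratic surface (gradients + curvature + interaction),
  rescaled to range `spatial_trend_amplitude`, is added — a trend shape
  a moving-mean covariate can absorb.

What the generator does *not* emulate: genotyping error, residual
heterozygosity beyond what QC handles, pedigree-explicit crossing,
dominance/epistasis beyond within-window allelic effects, check-based
augmented field designs, and trait correlations. Tests passing on this
generator therefore validate the machinery and its statistical
contracts, not field performance on any real panel.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale instances chosen
to keep the full battery comfortably reproducible on a single CPU: the
synthetic panel defaults to 383 lines × 21 chromosomes × 100 markers
(a stand-in for a ~14k-marker array panel), property checks use 90–150
line panels, REML recovery uses n = 500, and scheme invariants are
checked over hundreds of randomized small cases. Other fixed numerical
choices: marker QC removes MAF < 0.05 and missingness > 0.10 evaluated
jointly on the raw matrix; LD-kNN imputation defaults to k = 5
neighbours over l = 30 correlated markers (the method's published
defaults) and resolves heterozygous winners to the better-supported
homozygote (ties to the marker's major allele); trailing markers that do
not fill a block are dropped rather than pooled into a short block,
matching fixed-length block counts of the form
$\sum_c \lfloor m_c / L \rfloor$; haplotype-allele numbering follows
first appearance in line order, making codes deterministic and
relabeling-invariant.

## Known limitations

* Validation lines whose haplotype alleles are absent from the
  frequency reference receive $p_k = 0$ columns; rare-allele effects
  are then estimated from single carriers and shrink heavily.
* The moving grid supports ring windows of 8 or 24 plots only.
* REML assumes homoscedastic residuals across trials after adjustment.
* `estimate_variance_components` identifies $\sigma^2_e$ from
  replication across trials; single-trial unreplicated designs error.
```
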