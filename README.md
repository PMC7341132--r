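# haplogs

Genomic selection for structured inbred breeding panels, with
**multi-allelic haplotype GBLUP** and **training-population
optimization** alongside the standard single-SNP machinery.

In self-fertilized crops such as wheat, high LD between adjacent
markers means a short run of SNPs segregates as a small set of
haplotypes. Treating each fixed run of *L* adjacent mapped markers as
one multi-allelic locus — every distinct *L*-marker genotype vector an
"allele" — lets the prediction model capture local LD and short-range
allelic interactions that single SNPs miss. Independently, when a panel
splits into pedigree-driven clusters, building the calibration set by
**stratified sampling** (a fixed fraction from every cluster) keeps all
subpopulations represented, where random *k*-fold partitions need not.
`haplogs` implements both ideas end to end and the statistics to compare
them.

## What the package does

* **Genotype I/O and QC** — TASSEL-style HapMap (`hmp.txt`) reader and
  writer (single-letter IUPAC and two-letter diplotype calls, gzip),
  joint MAF/missingness marker filter, LD-kNN imputation, map ordering.
* **Phenotype pipeline** — moving-grid spatial adjustment on the field
  row×column grid (8-plot ring covariate), trial combination, REML
  variance components via the plot-level mixed model, and entry-mean
  broad-sense heritability `H = sg2 / (sg2 + se2 / n)`.
* **Population structure** — VanRaden genomic relationship matrix,
  1−IBS distances, K-means (Hartigan–Wong) on principal coordinates,
  PCA, within/between-cluster relationship summaries, adjacent-marker
  r² from directly observed gametic phase.
* **Prediction** — centered single-SNP and multi-allelic haplotype
  design matrices; two-component REML profiled on the eigen-spectrum of
  the marker kernel; GBLUP additive values and out-of-sample
  predictions.
* **Validation** — k-fold, stratified-sampling and leave-cluster-out
  schemes; predictive ability; Fisher-Z transform, T statistic and
  paired model comparisons.
* **Synthetic panels** — a seeded generator of fully inbred structured
  populations (Balding–Nichols cluster divergence, founder-mosaic LD,
  SNP- or haplotype-local trait architectures, spatial field trends) so
  every stage is testable without restricted data.

## Worked example

Heritability from published variance components (two trials):

```r
library(haplogs)
heritability(33737, 168275, 2)   # yield       -> 0.29 (rounded)
heritability(1.20, 1.19, 2)      # test weight -> 0.67
heritability(0.28, 0.27, 2)      # protein     -> 0.67
```

A full synthetic analysis — 150 inbred lines in three clusters, 240
mapped markers, a haplotype-local protein trait at target H = 0.7,
two trials with spatial trends:

```r
cfg <- sim_config(seed = 7, cluster_sizes = c(60L, 45L, 45L),
                  n_chromosomes = 4L, markers_per_chromosome = 60L,
                  divergence = 0.5, n_qtl = 30L,
                  qtl_mode = "haplotype", qtl_span = 5L,
                  field_rows = 13L, field_cols = 12L)
pop   <- simulate_population(cfg)
pheno <- apply_field_layout(simulate_phenotypes(pop, cfg), cfg)

adj <- moving_grid_adjust(pheno, "protein")
estimate_variance_components(adj, "protein")
#> sigma_g2 = 1.328, sigma_e2 = 0.7224, n_trials = 2, H = 0.79

g <- pop$genotypes
adjacent_ld(g, pop$map)$genome_mean        # mean adjacent r2: 0.56
cl <- kmeans_cluster(ibs_distance(g), K = 3, seed = 7)
adjusted_rand_index(cl$labels, pop$true_cluster_labels)  # 0.958

hbs <- build_blocks(g, pop$map, 5)
block_summary(hbs)$overall
#>   block_size n_blocks max_alleles mean_alleles mean_span_cM
#> 1          5       48          16     9.166667     10.27184

y  <- combine_trials(adj, "protein")
kf <- make_kfold(names(y), k = 4, repetitions = 2, seed = 7)
cmp <- paired_comparison(evaluate_scheme(y, build_snp_design(g), kf)$r,
                         evaluate_scheme(y, build_hap_design(hbs), kf)$r)
#> mean r: single-SNP 0.334, Haploblock-5 0.476 (+42.5%, paired p = 1.3e-05)
```

Reading the output: the REML fit recovers a heritability near the
simulated target; mean adjacent r² of 0.56 sits in the high-LD band
typical of a selfing crop; K-means on the 1−IBS principal coordinates
recovers the three simulated families almost exactly (adjusted Rand
index 0.96); the 240 markers form 48 five-marker blocks carrying ~9
haplotype alleles each; and because this trait's causal effects live on
local haplotypes, the multi-allelic model raises cross-validated
predictive ability from 0.33 to 0.48, a significant paired improvement.
`run_pipeline(run_config(sim = cfg))` chains all of the above (plus
stratified and leave-cluster-out validation) and writes per-stage CSV
artifacts; `report_run()` renders a text summary.

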