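# Synthetic structured inbred breeding populations: genotypes with
# pedigree-like clusters and high adjacent-marker LD, polygenic or
# haplotype-local trait architectures, and field layouts with smooth
# spatial trends.

#' Configuration for the synthetic population generator
#'
#' Defaults emulate a diversity panel of 383 fully inbred lines in three
#' pedigree-driven clusters genotyped at 2,100 mapped SNPs (21 chromosomes
#' x 100 markers) with strong adjacent-marker LD, two polygenic traits at
#' entry-mean heritabilities 0.3 and 0.7, and two field trials on a
#' 20 x 20 row-column grid.
#'
#' @param seed integer seed governing every random draw downstream.
#' @param n_clusters number of subpopulations.
#' @param cluster_sizes integer vector of lines per cluster
#'   (length `n_clusters`).
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome integer vector (recycled to
#'   `n_chromosomes`) of marker counts.
#' @param map_length_cM numeric vector (recycled) of chromosome map
#'   lengths in centimorgans.
#' @param founder_count_per_cluster size of each cluster's founder
#'   haplotype pool.
#' @param divergence drift parameter in \[0, 1\]: Balding-Nichols spread of
#'   cluster allele frequencies around the ancestral frequency (0 = no
#'   structure).
#' @param ld_decay per-cM intensity of the founder-haplotype copy process;
#'   smaller values give higher adjacent-marker r^2. The default of
#'   0.15/cM at ~1.5 cM marker spacing yields mean adjacent r^2 of about
#'   0.5-0.7, matching a selfing wheat panel.
#' @param n_qtl number of causal loci per trait.
#' @param heritability_targets named numeric vector of entry-mean
#'   broad-sense heritability targets in (0, 1\], one per trait.
#' @param n_trials number of field trials.
#' @param field_rows,field_cols field grid dimensions per trial.
#' @param spatial_trend_amplitude range (max - min), in trait units, of the
#'   smooth spatial surface added by [apply_field_layout()].
#' @param qtl_mode `"snp"` assigns additive effects to individual causal
#'   markers; `"haplotype"` assigns effects to the distinct local haplotypes
#'   in windows of `qtl_span` adjacent markers (a local high-order allelic
#'   architecture a single-SNP model cannot fully capture).
#' @param qtl_span window width (markers) for `qtl_mode = "haplotype"`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 3L,
                       cluster_sizes = c(176L, 89L, 118L),
                       n_chromosomes = 21L,
                       markers_per_chromosome = 100L,
                       map_length_cM = 150,
                       founder_count_per_cluster = 10L,
                       divergence = 0.3,
                       ld_decay = 0.15,
                       n_qtl = 100L,
                       heritability_targets = c(yield = 0.3, protein = 0.7),
                       n_trials = 2L,
                       field_rows = 20L,
                       field_cols = 20L,
                       spatial_trend_amplitude = 1,
                       qtl_mode = c("snp", "haplotype"),
                       qtl_span = 5L) {
  qtl_mode <- match.arg(qtl_mode)
  markers_per_chromosome <- rep_len(as.integer(markers_per_chromosome),
                                    n_chromosomes)
  map_length_cM <- rep_len(as.numeric(map_length_cM), n_chromosomes)
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              cluster_sizes = as.integer(cluster_sizes),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = markers_per_chromosome,
              map_length_cM = map_length_cM,
              founder_count_per_cluster = as.integer(founder_count_per_cluster),
              divergence = divergence, ld_decay = ld_decay,
              n_qtl = as.integer(n_qtl),
              heritability_targets = heritability_targets,
              n_trials = as.integer(n_trials),
              field_rows = as.integer(field_rows),
              field_cols = as.integer(field_cols),
              spatial_trend_amplitude = spatial_trend_amplitude,
              qtl_mode = qtl_mode, qtl_span = as.integer(qtl_span))
  if (length(cfg$cluster_sizes) != cfg$n_clusters)
    stop("cluster_sizes must have length n_clusters")
  counts <- c(cfg$cluster_sizes, cfg$n_chromosomes, cfg$markers_per_chromosome,
              cfg$founder_count_per_cluster, cfg$n_trials, cfg$field_rows,
              cfg$field_cols)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (is.null(names(cfg$heritability_targets)) ||
      any(names(cfg$heritability_targets) == ""))
    stop("heritability_targets must be a named vector")
  if (any(cfg$heritability_targets <= 0 | cfg$heritability_targets > 1))
    stop("heritability targets must lie in (0, 1]")
  if (cfg$divergence < 0 || cfg$divergence > 1)
    stop("divergence must lie in [0, 1]")
  if (sum(cfg$markers_per_chromosome) < cfg$n_qtl)
    stop("fewer markers than QTL requested")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured, fully inbred population
#'
#' Cluster allele frequencies are drawn around a common ancestral
#' frequency with Balding-Nichols variance controlled by `divergence`.
#' Within each cluster a pool of founder haplotypes is generated as a
#' Markov copy process along the map (adjacent alleles are copied with
#' probability exp(-ld_decay * d_cM), producing adjacent-marker LD), and
#' each line is a recombinant mosaic of those founders with long shared
#' segments. Lines are fully homozygous (dosages 0/2). Per-trait causal
#' architectures (marker effects, or haplotype-window effects under
#' `qtl_mode = "haplotype"`) are drawn and summed into true additive
#' values, standardized to unit variance per trait.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_population`: `genotypes`
#'   ([genotype_matrix]), `map` (marker_id, chrom, pos),
#'   `true_cluster_labels` (named integer), `qtl` (per-trait causal
#'   architecture), `true_additive_values` (lines x traits matrix,
#'   unit variance per trait).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  n <- sum(config$cluster_sizes)
  m_total <- sum(config$markers_per_chromosome)
  lines_id <- sprintf("L%03d", seq_len(n))
  labels <- rep(seq_len(config$n_clusters), config$cluster_sizes)
  names(labels) <- lines_id

  # map: sorted uniform positions per chromosome
  chrom_id <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  map_list <- lapply(seq_len(config$n_chromosomes), function(cc) {
    m <- config$markers_per_chromosome[cc]
    data.frame(marker_id = sprintf("%s_M%04d", chrom_id[cc], seq_len(m)),
               chrom = chrom_id[cc],
               pos = round(sort(stats::runif(m, 0, config$map_length_cM[cc])), 4),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, map_list)

  # ancestral and cluster allele frequencies (Balding-Nichols)
  p0 <- stats::runif(m_total, 0.1, 0.9)
  Fst <- config$divergence
  cluster_freq <- sapply(seq_len(config$n_clusters), function(cc) {
    if (Fst == 0) p0
    else stats::rbeta(m_total, p0 * (1 - Fst) / Fst, (1 - p0) * (1 - Fst) / Fst)
  })

  nf <- config$founder_count_per_cluster
  dos <- matrix(NA_real_, n, m_total,
                dimnames = list(lines_id, map$marker_id))
  offset <- 0L
  for (cc in seq_len(config$n_chromosomes)) {
    m <- config$markers_per_chromosome[cc]
    idx <- offset + seq_len(m)
    dcm <- diff(map_list[[cc]]$pos)
    copy_p <- exp(-config$ld_decay * dcm)          # founder-chain LD
    switch_p <- 1 - exp(-0.01 * dcm)               # mosaic recombination
    draw_founders <- function(pc) {
      founders <- matrix(0L, nf, m)
      founders[, 1] <- stats::rbinom(nf, 1, pc[1])
      if (m >= 2) for (j in 2:m) {
        fresh <- stats::rbinom(nf, 1, pc[j])
        keep <- stats::runif(nf) < copy_p[j - 1]
        founders[, j] <- ifelse(keep, founders[, j - 1], fresh)
      }
      founders
    }
    # divergence 0 means a single unstructured founder population:
    # every cluster mosaics from the same pool
    if (Fst == 0) shared <- draw_founders(p0[idx])
    for (k in seq_len(config$n_clusters)) {
      founders <- if (Fst == 0) shared else draw_founders(cluster_freq[idx, k])
      rows <- which(labels == k)
      for (i in rows) {
        path <- integer(m)
        path[1] <- sample.int(nf, 1)
        if (m >= 2) {
          sw <- stats::runif(m - 1) < switch_p
          for (j in 2:m)
            path[j] <- if (sw[j - 1]) sample.int(nf, 1) else path[j - 1]
        }
        dos[i, idx] <- 2 * founders[cbind(path, seq_len(m))]
      }
    }
    offset <- offset + m
  }

  # nucleotide labels: A allele = dosage-2 allele, drawn per marker
  pair <- t(vapply(seq_len(m_total),
                   function(j) sample(c("A", "C", "G", "T"), 2), character(2)))

  # causal architecture and true additive values, per trait
  traits <- names(config$heritability_targets)
  qtl <- vector("list", length(traits)); names(qtl) <- traits
  tav <- matrix(0, n, length(traits), dimnames = list(lines_id, traits))
  for (tr in traits) {
    if (config$qtl_mode == "snp") {
      qidx <- sort(sample.int(m_total, config$n_qtl))
      qeff <- stats::rnorm(config$n_qtl)
      g <- as.vector(dos[, qidx, drop = FALSE] %*% qeff)
      qtl[[tr]] <- list(mode = "snp", positions = qidx, effects = qeff)
    } else {
      # causal loci are non-overlapping windows of qtl_span adjacent
      # markers (the generator's haplotype grid); every distinct
      # haplotype observed in a window gets its own effect
      starts <- integer(config$n_qtl); spans <- config$qtl_span
      g <- numeric(n); wins <- vector("list", config$n_qtl)
      chrom_off <- c(0L, cumsum(config$markers_per_chromosome))
      for (q in seq_len(config$n_qtl)) {
        cc <- sample.int(config$n_chromosomes, 1)
        m <- config$markers_per_chromosome[cc]
        n_win <- max(1L, m %/% spans)
        s <- (sample.int(n_win, 1) - 1L) * spans + 1L
        widx <- chrom_off[cc] + s:(min(m, s + spans - 1L))
        hap <- apply(dos[, widx, drop = FALSE], 1, paste, collapse = "")
        code <- match(hap, unique(hap))
        eff <- stats::rnorm(max(code))
        g <- g + eff[code]
        wins[[q]] <- list(markers = widx, effects = eff)
        starts[q] <- widx[1]
      }
      qtl[[tr]] <- list(mode = "haplotype", windows = wins, positions = starts)
    }
    sg <- stats::sd(g)
    if (sg > 0) g <- (g - mean(g)) / sg   # unit genetic variance per trait
    tav[, tr] <- g
  }

  structure(list(genotypes = genotype_matrix(dos, pair), map = map,
                 true_cluster_labels = labels, qtl = qtl,
                 true_additive_values = tav, config = config),
            class = "sim_population")
}

#' Simulate plot-level phenotypes at target heritabilities
#'
#' Per trial, phenotype = true additive value + trial offset + Gaussian
#' residual. Genetic values have unit variance, so the residual standard
#' deviation is set from the entry-mean heritability identity
#' H = sg2 / (sg2 + se2 / n_trials), i.e. se2 = n_trials (1 - H) / H.
#'
#' @param pop a [simulate_population()] result.
#' @param config the same [sim_config()].
#' @return data.frame of class `pheno_table`: line_id, trial, then one
#'   column per trait.
#' @export
simulate_phenotypes <- function(pop, config) {
  stopifnot(inherits(pop, "sim_population"))
  if (any(config$heritability_targets <= 0))
    stop("heritability target of 0 is not admissible")
  set.seed(derive_seed(config$seed, 2))
  n <- nrow(pop$true_additive_values)
  traits <- colnames(pop$true_additive_values)
  out <- do.call(rbind, lapply(seq_len(config$n_trials), function(t) {
    data.frame(line_id = rownames(pop$true_additive_values), trial = t,
               stringsAsFactors = FALSE)
  }))
  for (tr in traits) {
    H <- config$heritability_targets[[tr]]
    se2 <- config$n_trials * (1 - H) / H
    vals <- numeric(0)
    for (t in seq_len(config$n_trials)) {
      trial_eff <- stats::rnorm(1, 0, 1)
      vals <- c(vals, pop$true_additive_values[, tr] + trial_eff +
                  stats::rnorm(n, 0, sqrt(se2)))
    }
    out[[tr]] <- vals
  }
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Assign field coordinates and add a smooth spatial trend
#'
#' Plots are placed row-major on a `field_rows` x `field_cols` grid in a
#' random order per trial; a quadratic surface (row/column gradients plus
#' curvature and interaction), rescaled so its range equals
#' `spatial_trend_amplitude`, is added to every trait.
#'
#' @param pheno a `pheno_table` from [simulate_phenotypes()].
#' @param config the same [sim_config()].
#' @return the `pheno_table` with `row`/`col` columns and trended values.
#' @export
apply_field_layout <- function(pheno, config) {
  n_per_trial <- length(unique(pheno$line_id))
  if (config$field_rows * config$field_cols < n_per_trial)
    stop("field grid too small for the population")
  set.seed(derive_seed(config$seed, 3))
  traits <- setdiff(names(pheno), c("line_id", "trial", "row", "col"))
  pheno$row <- NA_integer_; pheno$col <- NA_integer_
  for (t in unique(pheno$trial)) {
    sel <- which(pheno$trial == t)
    cells <- sample(seq_len(config$field_rows * config$field_cols),
                    length(sel))
    r <- (cells - 1L) %/% config$field_cols + 1L
    cl <- (cells - 1L) %% config$field_cols + 1L
    pheno$row[sel] <- r; pheno$col[sel] <- cl
    b <- stats::rnorm(5)
    rs <- (r - mean(r)) / max(1, stats::sd(r))
    cs <- (cl - mean(cl)) / max(1, stats::sd(cl))
    surf <- b[1] * rs + b[2] * cs + b[3] * rs^2 + b[4] * cs^2 + b[5] * rs * cs
    rng <- diff(range(surf))
    surf <- if (rng > 0) surf / rng * config$spatial_trend_amplitude
            else surf * 0
    for (tr in traits) pheno[[tr]][sel] <- pheno[[tr]][sel] + surf
  }
  pheno
}

#' Write a simulated dataset to disk
#'
#' Emits the genotypes as a HapMap file (`genotypes.hmp.txt`) and the
#' phenotype/layout table as CSV (`phenotypes.csv`); both round-trip
#' through [read_hapmap()] / [read_pheno()] exactly (map positions to 4
#' decimals).
#'
#' @param pop a `sim_population`.
#' @param pheno a `pheno_table`.
#' @param out_dir output directory (created if absent).
#' @return named character vector of the two file paths.
#' @export
write_dataset <- function(pop, pheno, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  gpath <- file.path(out_dir, "genotypes.hmp.txt")
  ppath <- file.path(out_dir, "phenotypes.csv")
  write_hapmap(pop$genotypes, pop$map, gpath)
  write_pheno(pheno, ppath)
  c(genotypes = gpath, phenotypes = ppath)
}
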