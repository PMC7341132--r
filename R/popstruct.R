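# Population structure: genomic relationship matrix, identity-by-state
# distances, K-means clustering on principal coordinates, PCA,
# within/between-cluster relationship summaries, adjacent-marker LD.

#' VanRaden genomic relationship matrix
#'
#' A = ZZ' / (2 * sum p_i (1 - p_i)) with Z = M - P, where M codes
#' genotypes -1/0/1 (dosage - 1), P_i = 2 (p_i - 0.5) and p_i is the
#' A-allele frequency of marker i computed from the supplied lines.
#'
#' @param g a fully imputed [genotype_matrix].
#' @return list of class `grm`: `A` (n x n symmetric, line-id dimnames),
#'   `p` (allele frequencies used).
#' @export
grm_vanraden <- function(g) {
  d <- g$dosages
  if (anyNA(d)) stop("missing dosages: impute before computing the GRM")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers monomorphic: GRM denominator is zero")
  Z <- sweep(d - 1, 2, 2 * (p - 0.5))
  A <- tcrossprod(Z) / denom
  dimnames(A) <- list(rownames(d), rownames(d))
  structure(list(A = A, p = p), class = "grm")
}

#' 1 - IBS genetic distance matrix
#'
#' IBS(i, j) is the mean over markers of the shared-allele proportion
#' 1 - |dosage_i - dosage_j| / 2; the distance is 1 - IBS (0 on the
#' diagonal, 1 for opposite homozygotes at every marker).
#'
#' @param g a fully imputed [genotype_matrix].
#' @return n x n symmetric numeric matrix with line-id dimnames.
#' @export
ibs_distance <- function(g) {
  d <- g$dosages
  if (anyNA(d)) stop("missing dosages: impute before computing IBS")
  D <- as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
  dimnames(D) <- list(rownames(d), rownames(d))
  D
}

#' K-means clustering of a genetic distance matrix
#'
#' The distance matrix is embedded by classical multidimensional scaling
#' (principal coordinates) and K-means (Hartigan-Wong) is run on the
#' leading axes with multiple seeded restarts, keeping the lowest
#' within-cluster sum of squares. Deterministic for a fixed seed.
#'
#' @param dist_mat square symmetric distance matrix (e.g. from
#'   [ibs_distance()]).
#' @param K number of clusters (default 3).
#' @param n_components number of principal-coordinate axes (default 10,
#'   capped at n - 1 and at the number of positive eigenvalues).
#' @param restarts number of K-means initializations (default 100).
#' @param seed RNG seed.
#' @return list of class `cluster_assignment`: `labels` (named integer,
#'   1..K), `K`, `inertia`.
#' @export
kmeans_cluster <- function(dist_mat, K = 3L, n_components = 10L,
                           restarts = 100L, seed = 1L) {
  dist_mat <- as.matrix(dist_mat)
  if (nrow(dist_mat) != ncol(dist_mat)) stop("distance matrix must be square")
  n <- nrow(dist_mat)
  if (K > n) stop("K exceeds the number of lines")
  k_axes <- min(n_components, n - 1)
  coords <- stats::cmdscale(dist_mat, k = k_axes)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  set.seed(derive_seed(seed, 11))
  if (K == n) {
    labels <- seq_len(n); inertia <- 0
  } else {
    km <- stats::kmeans(coords, centers = K, nstart = restarts,
                        iter.max = 100L, algorithm = "Hartigan-Wong")
    labels <- km$cluster; inertia <- km$tot.withinss
  }
  names(labels) <- rownames(dist_mat)
  structure(list(labels = labels, K = as.integer(K), inertia = inertia),
            class = "cluster_assignment")
}

#' Principal component analysis of a dosage matrix
#'
#' PCA of the column-centered (unscaled) dosage matrix. Sign convention:
#' each component's largest-magnitude loading is positive.
#'
#' @param g a fully imputed [genotype_matrix].
#' @param n_components number of components to return (default 10).
#' @return list: `coordinates` (lines x PCs), `variance_fractions`
#'   (non-increasing, summing to <= 1).
#' @export
pca_genotypes <- function(g, n_components = 10L) {
  d <- g$dosages
  if (anyNA(d)) stop("missing dosages: impute before PCA")
  if (nrow(d) < 2) stop("PCA needs at least 2 lines")
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) -1 else 1
  }, 0)
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  total_var <- sum(pc$sdev^2)
  list(coordinates = coords,
       variance_fractions = pc$sdev[seq_len(k)]^2 / total_var)
}

#' Within- and between-cluster genomic relationships
#'
#' For each cluster c: A_within is the mean off-diagonal relationship over
#' pairs with both lines in c, A_between the mean over pairs with exactly
#' one line in c; standard errors are of those means. A singleton cluster
#' has no within pairs and reports NA.
#'
#' @param grm a [grm_vanraden()] result (or a bare relationship matrix).
#' @param clusters a `cluster_assignment` (or a named label vector).
#' @return data.frame: cluster, n, A_between, SE_between, A_within,
#'   SE_within.
#' @export
cluster_relationships <- function(grm, clusters) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  labels <- labels[rownames(A)]
  if (anyNA(labels)) stop("cluster labels must cover every GRM line")
  up <- upper.tri(A)
  li <- row(A)[up]; lj <- col(A)[up]; a <- A[up]
  gi <- labels[li]; gj <- labels[lj]
  out <- lapply(sort(unique(labels)), function(cc) {
    within <- a[gi == cc & gj == cc]
    between <- a[xor(gi == cc, gj == cc)]
    data.frame(cluster = cc, n = sum(labels == cc),
               A_between = if (length(between) > 0) mean(between) else NA_real_,
               SE_between = if (length(between) > 1)
                 stats::sd(between) / sqrt(length(between)) else NA_real_,
               A_within = if (length(within) > 0) mean(within) else NA_real_,
               SE_within = if (length(within) > 1)
                 stats::sd(within) / sqrt(length(within)) else NA_real_)
  })
  do.call(rbind, out)
}

#' Adjacent-marker linkage disequilibrium (r^2)
#'
#' For every within-chromosome pair of adjacent mapped markers,
#' r^2 = D^2 / (pA pa pB pb) with two-locus haplotype frequencies read
#' directly from the homozygous genotypes (gametic phase is observed in
#' fully inbred lines). Monomorphic pairs are skipped; chromosomes with
#' fewer than 2 markers are skipped with a message. The genome-wide mean
#' is the mean of the per-chromosome means.
#'
#' @param g a fully imputed, homozygous [genotype_matrix].
#' @param map data.frame (marker_id, chrom, pos).
#' @return list of class `ld_table`: `pairs` (data.frame: chrom, marker_a,
#'   marker_b, r2), `chromosome_means` (named numeric), `genome_mean`.
#' @export
adjacent_ld <- function(g, map) {
  om <- order_by_map(g, map)
  d <- om$genotypes$dosages; map <- om$map
  if (anyNA(d)) stop("missing dosages: impute before estimating LD")
  if (any(d == 1)) stop("heterozygous dosages present: LD from gametic ",
                        "phase requires fully inbred (0/2) genotypes")
  rows <- list()
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    if (length(jj) < 2) {
      message("chromosome ", chr, " has < 2 markers; skipped for LD")
      next
    }
    for (t in seq_len(length(jj) - 1)) {
      ja <- jj[t]; jb <- jj[t + 1]
      xa <- d[, ja] / 2; xb <- d[, jb] / 2   # gamete alleles (0/1)
      pa <- mean(xa); pb <- mean(xb)
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) next  # monomorphic pair
      pab <- mean(xa * xb)
      r2 <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, marker_a = map$marker_id[ja],
        marker_b = map$marker_id[jb], r2 = r2, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) stop("no polymorphic adjacent marker pairs found")
  chr_means <- tapply(pairs$r2, pairs$chrom, mean)
  structure(list(pairs = pairs,
                 chromosome_means = chr_means,
                 genome_mean = mean(chr_means)),
            class = "ld_table")
}

#' Per-cluster trait means with a one-way ANOVA test
#'
#' @param values named numeric vector of one phenotype per line.
#' @param clusters a `cluster_assignment` or named label vector covering
#'   those lines.
#' @return list: `means` (data.frame: cluster, n, mean), `p_value`
#'   (one-way ANOVA F-test across clusters).
#' @export
cluster_trait_summary <- function(values, clusters) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  labels <- labels[names(values)]
  if (anyNA(labels)) stop("cluster labels must cover every phenotyped line")
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 clusters with >= 2 lines each")
  if (stats::var(values) == 0)
    stop("trait is constant: ANOVA F statistic undefined")
  fit <- stats::aov(values ~ factor(labels))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  means <- data.frame(cluster = names(sizes), n = as.vector(sizes),
                      mean = as.vector(tapply(values, labels, mean)))
  list(means = means, p_value = p)
}
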