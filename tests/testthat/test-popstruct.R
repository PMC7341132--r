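test_that("the VanRaden GRM matches the hand-computed 3-line example", {
  g <- toy_genotypes(rbind(c(2, 2), c(2, 0), c(0, 0)),
                     lines = c("L1", "L2", "L3"))
  A <- grm_vanraden(g)$A
  expect_equal(unname(A),
               rbind(c(2.5, -0.5, -2), c(-0.5, 1, -0.5), c(-2, -0.5, 2.5)))
  expect_equal(A, t(A))
  expect_equal(sum(A), 0, tolerance = 1e-12)  # centering identity
  # a duplicated line gives identical rows and columns
  g2 <- toy_genotypes(rbind(c(2, 0, 2), c(2, 0, 2), c(0, 2, 0), c(2, 2, 0)))
  A2 <- grm_vanraden(g2)$A
  expect_equal(unname(A2[1, ]), unname(A2[2, ]))
  expect_error(grm_vanraden(toy_genotypes(matrix(2, 3, 2))), "monomorphic")
})

test_that("1-IBS distances hit the stated boundary cases", {
  g <- toy_genotypes(rbind(a = c(2, 2, 0, 0), b = c(2, 2, 0, 0),
                           c = c(0, 0, 2, 2), d = c(0, 0, 0, 0)))
  D <- ibs_distance(g)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(unname(D[1, 2]), 0)      # identical lines
  expect_equal(unname(D[1, 3]), 1)      # opposite at every marker
  expect_equal(unname(D[1, 4]), 0.5)    # opposite at half the markers
})

test_that("GRM decreases as IBS distance increases on two-line swaps", {
  set.seed(42)
  base <- matrix(sample(c(0, 2), 2 * 60, replace = TRUE), nrow = 2)
  prev_a <- Inf
  for (n_swap in c(0, 10, 25)) {
    d <- base
    if (n_swap > 0) d[2, 1:n_swap] <- 2 - d[2, 1:n_swap]
    filler <- matrix(sample(c(0, 2), 4 * 60, replace = TRUE), nrow = 4)
    g <- toy_genotypes(rbind(d, filler))
    a12 <- grm_vanraden(g)$A[1, 2]
    expect_lt(a12, prev_a)
    prev_a <- a12
  }
})

test_that("K-means on principal coordinates handles degenerate K and recovers structure", {
  g <- toy_genotypes(matrix(sample(c(0, 2), 6 * 30, replace = TRUE), nrow = 6))
  D <- ibs_distance(g)
  one <- kmeans_cluster(D, K = 1, seed = 1)
  expect_equal(unname(one$labels), rep(1, 6))
  all_own <- kmeans_cluster(D, K = 6, seed = 1)
  expect_equal(sort(unique(all_own$labels)), 1:6)
  expect_equal(all_own$inertia, 0)
  expect_error(kmeans_cluster(D, K = 7), "exceeds")
  expect_error(kmeans_cluster(D[, 1:3], K = 2), "square")
  # same seed reproduces; restarts can only lower inertia
  cfg <- small_config(seed = 5, divergence = 0.5, cluster_sizes = c(40L, 40L, 40L),
                      n_chromosomes = 3L, markers_per_chromosome = 50L,
                      field_rows = 11L, field_cols = 11L)
  pop <- simulate_population(cfg)
  Dp <- ibs_distance(pop$genotypes)
  c1 <- kmeans_cluster(Dp, K = 3, seed = 7)
  c2 <- kmeans_cluster(Dp, K = 3, seed = 7)
  expect_identical(c1$labels, c2$labels)
  i1 <- kmeans_cluster(Dp, K = 3, restarts = 1, seed = 7)$inertia
  i20 <- kmeans_cluster(Dp, K = 3, restarts = 20, seed = 7)$inertia
  expect_lte(i20, i1)
  expect_gt(adjusted_rand_index(c1$labels, pop$true_cluster_labels), 0.9)
})

test_that("adjusted Rand index agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("genotype PCA separates duplicated clusters with the stated conventions", {
  block_a <- matrix(rep(c(2, 2, 0, 0, 2), 8), nrow = 8, ncol = 5, byrow = TRUE)
  block_b <- matrix(rep(c(0, 0, 2, 2, 0), 8), nrow = 8, ncol = 5, byrow = TRUE)
  d <- rbind(block_a[1:4, ], block_b[1:4, ])
  # add a little independent noise dimension so PCs beyond 1 exist
  set.seed(2)
  d <- cbind(d, sample(c(0, 2), 8, replace = TRUE))
  p <- pca_genotypes(toy_genotypes(d))
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  expect_lte(sum(p$variance_fractions), 1 + 1e-12)
  # PC1 splits the two duplicated groups
  pc1 <- p$coordinates[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) || min(pc1[1:4]) > max(pc1[5:8]))
  # coordinates invariant under marker permutation
  perm <- sample(ncol(d))
  p2 <- pca_genotypes(toy_genotypes(d[, perm],
                                    markers = colnames(d)[perm]))
  expect_equal(unname(p$coordinates), unname(p2$coordinates))
})

test_that("within-cluster relationships exceed between-cluster ones under structure", {
  cfg <- small_config(seed = 3, divergence = 0.5,
                      cluster_sizes = c(30L, 30L, 30L),
                      n_chromosomes = 3L, markers_per_chromosome = 40L,
                      field_rows = 10L, field_cols = 9L)
  pop <- simulate_population(cfg)
  grm <- grm_vanraden(pop$genotypes)
  rel <- cluster_relationships(grm, pop$true_cluster_labels)
  expect_true(all(rel$A_within > rel$A_between))
  # duplicated-pair cluster: A_within equals the pairwise value
  g <- toy_genotypes(rbind(c(2, 0, 2), c(2, 0, 2), c(0, 2, 0), c(0, 2, 2)))
  A <- grm_vanraden(g)
  lab <- c(L01 = 1, L02 = 1, L03 = 2, L04 = 2)
  rel2 <- cluster_relationships(A, lab)
  expect_equal(rel2$A_within[1], A$A[1, 2])
  # one all-encompassing cluster has no between pairs
  rel3 <- cluster_relationships(A, c(L01 = 1, L02 = 1, L03 = 1, L04 = 1))
  expect_true(is.na(rel3$A_between))
})

test_that("adjacent-marker r2 equals squared dosage correlation and hits its limits", {
  g <- toy_genotypes(cbind(m1 = c(2, 2, 0, 0, 2, 0),
                           m2 = c(2, 2, 0, 0, 2, 0),
                           m3 = c(0, 2, 2, 0, 2, 0)))
  ld <- adjacent_ld(g, toy_map(g))
  expect_equal(ld$pairs$r2[1], 1)  # perfectly co-inherited pair
  expect_equal(ld$pairs$r2[2], cor(g$dosages[, 2], g$dosages[, 3])^2,
               tolerance = 1e-12)
  # independent markers at large n: mean r2 near 0
  set.seed(31)
  big <- matrix(2 * rbinom(8000 * 12, 1, 0.5), nrow = 8000)
  ld0 <- adjacent_ld(toy_genotypes(big), toy_map(toy_genotypes(big)))
  expect_lt(ld0$genome_mean, 0.01)
  # heterozygotes are rejected; short chromosomes are skipped
  expect_error(adjacent_ld(toy_genotypes(cbind(c(1, 0), c(0, 2))),
                           toy_map(toy_genotypes(cbind(c(1, 0), c(0, 2))))),
               "inbred")
})

test_that("cluster trait summaries flag separated clusters and reject degenerate input", {
  set.seed(12)
  vals <- c(rnorm(30), rnorm(30) + 10)
  names(vals) <- sprintf("L%02d", 1:60)
  lab <- setNames(rep(1:2, each = 30), names(vals))
  res <- cluster_trait_summary(vals, lab)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$means$n, c(30, 30))
  vals_const <- setNames(rep(1, 10), sprintf("L%02d", 1:10))
  lab10 <- setNames(rep(1:2, 5), names(vals_const))
  expect_error(cluster_trait_summary(vals_const, lab10), "constant")
  expect_error(cluster_trait_summary(vals[1:3], setNames(c(1, 1, 2),
                                                         names(vals)[1:3])),
               ">= 2 lines")
})
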