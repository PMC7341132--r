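test_that("SNP design codings reproduce the additive substitution elements", {
  # p1 = p2 = 0.5: codings (1, 0, -1)
  d <- cbind(m1 = c(2, 1, 0, 2, 0, 1))
  rownames(d) <- sprintf("L%02d", 1:6)
  W <- build_snp_design(genotype_matrix(d))
  expect_equal(unname(W[1:3, 1]), c(1, 0, -1))
  # p1 = 0.25: codings (1.5, 0.5, -0.5)
  d2 <- cbind(m1 = c(2, 1, 0, 1, 0, 0, 0, 0))
  rownames(d2) <- sprintf("L%02d", 1:8)
  W2 <- build_snp_design(genotype_matrix(d2))
  expect_equal(unname(W2[1:3, 1]), c(1.5, 0.5, -0.5))
  expect_equal(sum(W2[, 1]), 0, tolerance = 1e-12)
  # monomorphic-in-reference columns are dropped
  d3 <- cbind(poly = c(0, 2, 2, 0), mono = c(2, 2, 2, 2))
  rownames(d3) <- sprintf("L%02d", 1:4)
  expect_message(W3 <- build_snp_design(genotype_matrix(d3)), "monomorphic")
  expect_equal(colnames(W3), "poly")
  expect_error(build_snp_design(genotype_matrix(d3), freq_ref = character(0)),
               "nonempty")
})

test_that("haplotype design codings follow centered copy numbers with zero row sums per block", {
  # 3-allele block with frequencies (0.5, 0.25, 0.25)
  d <- rbind(c(2, 2), c(2, 2), c(0, 2), c(2, 0))
  rownames(d) <- sprintf("L%02d", 1:4); colnames(d) <- c("M1", "M2")
  g <- genotype_matrix(d)
  map <- data.frame(marker_id = c("M1", "M2"), chrom = "1A", pos = 1:2)
  hbs <- build_blocks(g, map, 2)
  W <- build_hap_design(hbs)
  # line 3 carries allele 2: entries (-1, 1.5, -0.5)
  expect_equal(unname(W[3, ]), c(-1, 1.5, -0.5))
  # carrier of a p = 0.5 allele codes +1, non-carrier -1 on that column
  expect_equal(unname(W[1, 1]), 1)
  expect_equal(unname(W[3, 1]), -1)
  expect_equal(unname(rowSums(W)), rep(0, 4))
  expect_equal(unname(colSums(W)), rep(0, 3), tolerance = 1e-12)
})

test_that("profiled eigen-REML equals direct REML on the explicit covariance", {
  for (s in 1:3) {
    inst <- random_instance(50, 80, seed = s)
    fit <- reml_fit(inst$y, inst$W)
    ref <- direct_reml(inst$y, inst$W)
    expect_equal(fit$sigma_marker2, ref[1], tolerance = 1e-4)
    expect_equal(fit$sigma_e2, ref[2], tolerance = 1e-4)
  }
})

test_that("REML flags a constant phenotype as degenerate", {
  inst <- random_instance(30, 40, seed = 4)
  y0 <- setNames(rep(3, 30), names(inst$y))
  expect_warning(vc <- reml_fit(y0, inst$W), "degenerate")
  expect_equal(vc$sigma_marker2, 0)
  expect_false(vc$converged)
  expect_error(reml_fit(inst$y[1:2], inst$W), "more than 2")
})

test_that("zero residual variance interpolates the centred training phenotypes", {
  inst <- random_instance(30, 60, sigma2 = 0.1, sigma_e2 = 0.5, seed = 5)
  vc <- structure(list(sigma_marker2 = 0.1, sigma_e2 = 0),
                  class = "variance_components")
  train <- names(inst$y)[1:25]
  fit <- gblup_predict(inst$y, inst$W, training = train, vc = vc)
  expect_equal(unname(fit$additive_values[train]),
               unname(inst$y[train] - fit$mu), tolerance = 1e-8)
})

test_that("predictions are invariant to column order, global sign and scale of W", {
  inst <- random_instance(40, 50, seed = 6)
  train <- names(inst$y)[1:30]
  base <- gblup_predict(inst$y, inst$W, training = train)
  perm <- sample(ncol(inst$W))
  f_perm <- gblup_predict(inst$y, inst$W[, perm], training = train)
  expect_equal(f_perm$additive_values, base$additive_values, tolerance = 1e-8)
  f_neg <- gblup_predict(inst$y, -inst$W, training = train)
  expect_equal(f_neg$additive_values, base$additive_values, tolerance = 1e-6)
  f_scale <- gblup_predict(inst$y, 3 * inst$W, training = train)
  expect_equal(f_scale$additive_values, base$additive_values,
               tolerance = 1e-6)
  expect_equal(f_scale$vc$sigma_marker2, base$vc$sigma_marker2 / 9,
               tolerance = 1e-4)
  expect_error(gblup_predict(inst$y, inst$W, training = train,
                             validation = train[1]), "disjoint")
})

test_that("kernel-form GBLUP equals the effect-level mixed-model solution", {
  # m < n keeps the residual variance identifiable, so the REML optimum is
  # interior and both linear systems are well conditioned
  for (s in 1:5) {
    inst <- random_instance(30, 20, seed = s + 10)
    train <- names(inst$y)[1:22]
    fit <- gblup_predict(inst$y, inst$W, training = train)
    lambda <- fit$vc$sigma_e2 / fit$vc$sigma_marker2
    Wt <- inst$W[train, ]
    alpha_mme <- solve(crossprod(Wt) + diag(ncol(Wt)) * lambda,
                       crossprod(Wt, inst$y[train] - fit$mu))
    expect_equal(unname(fit$effects), unname(as.vector(alpha_mme)),
                 tolerance = 1e-8)
  }
})

test_that("additive values equal W times the effect vector exactly", {
  inst <- random_instance(25, 30, seed = 21)
  fit <- gblup_predict(inst$y, inst$W, training = names(inst$y)[1:20])
  expect_equal(fit$additive_values,
               setNames(as.vector(inst$W %*% fit$effects), rownames(inst$W)))
})

test_that("single-marker haplotype blocks reproduce SNP-model predictions", {
  cfg <- small_config(seed = 13, cluster_sizes = c(50L, 50L), n_clusters = 2L,
                      n_chromosomes = 2L, markers_per_chromosome = 40L,
                      field_rows = 10L, field_cols = 10L,
                      heritability_targets = c(tr = 0.5))
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes(pop, cfg)
  y <- combine_trials(ph, "tr")
  W_snp <- suppressMessages(build_snp_design(pop$genotypes))
  W_h1 <- build_hap_design(build_blocks(pop$genotypes, pop$map, 1))
  train <- names(y)[1:70]
  f_snp <- gblup_predict(y, W_snp, training = train)
  f_h1 <- gblup_predict(y, W_h1, training = train)
  expect_equal(f_h1$additive_values, f_snp$additive_values, tolerance = 1e-8)
})

test_that("cross-validated predictive ability rises with trait heritability", {
  better <- 0
  for (s in 1:6) {
    cfg <- small_config(seed = s, cluster_sizes = c(45L, 45L), n_clusters = 2L,
                        n_chromosomes = 2L, markers_per_chromosome = 40L,
                        field_rows = 10L, field_cols = 9L,
                        heritability_targets = c(lo = 0.3, hi = 0.7))
    pop <- simulate_population(cfg)
    ph <- simulate_phenotypes(pop, cfg)
    W <- suppressMessages(build_snp_design(pop$genotypes))
    sch <- make_kfold(line_ids(pop$genotypes), k = 4, repetitions = 1,
                      seed = s)
    r_lo <- mean(evaluate_scheme(combine_trials(ph, "lo"), W, sch)$r)
    r_hi <- mean(evaluate_scheme(combine_trials(ph, "hi"), W, sch)$r)
    if (r_hi > r_lo) better <- better + 1
  }
  expect_gte(better, 5)
})
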