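test_that("HapMap calls decode to A-allele dosages in both dialects", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_toy_hapmap(path)
  hm <- read_hapmap(path)
  expect_equal(unname(hm$genotypes$dosages[, "M01"]), c(2, 2, 0))
  # IUPAC het, N missing, two-letter homozygote
  expect_equal(unname(hm$genotypes$dosages[, "M02"]), c(1, NA, 0))
  expect_equal(hm$map$pos, c(10.5, 3.25))
  expect_equal(hm$map$chrom, c("1A", "1B"))
})

test_that("undecodable calls and malformed headers are rejected with context", {
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  write_toy_hapmap(path, calls2 = c("G", "A", "T"))  # G at an A/T marker
  expect_error(read_hapmap(path), "M02.*L01")
  writeLines(c("rs\talleles\tfoo", "x\ty\tz"), path)
  expect_error(read_hapmap(path), "malformed")
  expect_error(read_hapmap(tempfile()), "not found")
})

test_that("write/read round trip preserves dosages, ids, alleles and map", {
  cfg <- small_config(seed = 7, cluster_sizes = c(10L, 8L),
                      n_clusters = 2L, n_chromosomes = 2L,
                      markers_per_chromosome = 15L,
                      field_rows = 6L, field_cols = 3L, n_qtl = 5L)
  pop <- simulate_population(cfg)
  # inject a het and a missing call to cover all writer paths
  pop$genotypes$dosages[1, 2] <- 1
  pop$genotypes$dosages[2, 3] <- NA
  dir <- withr::local_tempdir()
  ph <- simulate_phenotypes(pop, cfg)
  paths <- write_dataset(pop, ph, dir)
  back <- read_hapmap(paths["genotypes"])
  expect_equal(back$genotypes$dosages, pop$genotypes$dosages)
  expect_equal(back$genotypes$alleles, pop$genotypes$alleles)
  expect_equal(back$map$marker_id, pop$map$marker_id)
  expect_equal(back$map$pos, round(pop$map$pos, 4))
  ph_back <- read_pheno(paths["phenotypes"])
  expect_equal(ph_back$line_id, ph$line_id)
  expect_equal(ph_back$yield, ph$yield, tolerance = 1e-12)
})

test_that("writing an empty panel is rejected", {
  g <- toy_genotypes(matrix(c(0, 2), 1, 2))
  g$dosages <- g$dosages[0, , drop = FALSE]
  expect_error(write_hapmap(g, toy_map(g), tempfile()), "no lines")
})

test_that("marker QC removes low-MAF and high-missingness markers at the stated boundaries", {
  # 100 lines so MAF/missingness hit exact fractions
  n <- 100
  d <- cbind(maf04 = c(rep(2, 96), rep(0, 4)),      # MAF 0.04 -> removed
             maf05 = c(rep(2, 95), rep(0, 5)),      # MAF 0.05 -> retained
             mono = rep(2, n),                      # MAF 0    -> removed
             miss11 = c(rep(NA, 11), rep(c(0, 2), length.out = 89)),
             clean = rep(c(0, 2), 50))
  g <- toy_genotypes(d, markers = colnames(d))
  f <- filter_markers(g, maf_min = 0.05, miss_max = 0.10)
  expect_setequal(marker_ids(f), c("maf05", "clean"))
  expect_equal(line_ids(f), line_ids(g))
  # idempotent under repeated application
  expect_equal(filter_markers(f, 0.05, 0.10)$dosages, f$dosages)
  low <- toy_genotypes(cbind(c(2, 2, 2, 0)))
  expect_error(filter_markers(low, maf_min = 0.3, miss_max = 1),
               "all markers removed")
})

test_that("kNN imputation is the identity on complete data and fills unanimous neighbourhoods", {
  d <- matrix(rep(c(0, 2), 12), nrow = 6)
  g <- toy_genotypes(d)
  expect_identical(impute_knn(g)$dosages, g$dosages)
  # a missing call whose neighbours all carry dosage 2
  d2 <- matrix(2, nrow = 6, ncol = 4)
  d2[, 1] <- c(0, 0, 0, 2, 2, 2)  # keep some polymorphism for correlations
  d2[1, 3] <- NA
  gi <- impute_knn(toy_genotypes(d2), k = 3, l = 2)
  expect_equal(gi$dosages[1, 3], 2)
  expect_false(anyNA(gi$dosages))
  all_miss <- toy_genotypes(cbind(c(0, 2, 2), c(NA, NA, NA)))
  expect_error(impute_knn(all_miss, k = 1, l = 1), "missing in all lines")
})

test_that("kNN imputation restores masked calls under high LD and never alters observed calls", {
  restored <- numeric(0)
  for (s in 1:3) {
    cfg <- small_config(seed = s, cluster_sizes = c(30L, 30L),
                        n_clusters = 2L, n_chromosomes = 2L,
                        markers_per_chromosome = 40L, ld_decay = 0.05,
                        field_rows = 10L, field_cols = 6L, n_qtl = 10L)
    pop <- simulate_population(cfg)
    d <- pop$genotypes$dosages
    set.seed(s)
    mask <- which(matrix(runif(length(d)) < 0.05, nrow(d)))
    truth <- d[mask]
    d[mask] <- NA
    gi <- impute_knn(genotype_matrix(d, pop$genotypes$alleles))
    restored <- c(restored, mean(gi$dosages[mask] == truth))
    obs <- setdiff(seq_along(d), mask)
    expect_equal(gi$dosages[obs], d[obs])
  }
  expect_gte(mean(restored), 0.90)
})

test_that("map ordering sorts by chromosome then position with marker-id tie-break", {
  d <- matrix(rep(c(0, 2), 8), nrow = 4)
  g <- toy_genotypes(d, markers = c("Mb", "Ma", "Mc", "Md"))
  map <- data.frame(marker_id = c("Mb", "Ma", "Mc", "Md"),
                    chrom = c("1B", "1A", "1A", "1A"),
                    pos = c(5, 7, 3, 3))
  om <- order_by_map(g, map)
  # ties at (1A, 3) broken lexicographically: Mc before Md
  expect_equal(marker_ids(om$genotypes), c("Mc", "Md", "Ma", "Mb"))
  expect_equal(om$map$marker_id, marker_ids(om$genotypes))
  # already ordered input is unchanged; unmapped markers are dropped
  om2 <- order_by_map(om$genotypes, om$map)
  expect_identical(om2$genotypes$dosages, om$genotypes$dosages)
  expect_message(om3 <- order_by_map(g, map[-1, ]), "1 unmapped")
  expect_equal(ncol(om3$genotypes$dosages), 3)
})
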