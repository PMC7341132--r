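# End-to-end orchestration: genotype QC -> field adjustment -> population
# structure -> haplotype blocks -> GBLUP -> validation schemes, with
# per-stage artifacts written to an output directory.

#' Run configuration for the full analysis
#'
#' Exactly one genotype source is used: file paths (`genotypes` +
#' `phenotypes`) or a [sim_config()] for a synthetic panel.
#'
#' @param genotypes path to a HapMap genotype file, or NULL.
#' @param phenotypes path to a phenotype CSV, or NULL.
#' @param sim a [sim_config()], or NULL.
#' @param maf_min,miss_max marker QC thresholds (defaults 0.05 / 0.10).
#' @param block_sizes haplotype block lengths (default c(5, 10, 15, 20)).
#' @param K number of population clusters (default 3).
#' @param schemes validation schemes to run, subset of
#'   c("kfold", "stratified", "lco").
#' @param k_folds,kfold_reps k-fold parameters (defaults 4 / 4).
#' @param train_fraction,stratified_reps stratified-sampling parameters
#'   (defaults 0.75 / 16).
#' @param seed master RNG seed.
#' @param out_dir output directory for artifacts (NULL: nothing written).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, phenotypes = NULL, sim = NULL,
                       maf_min = 0.05, miss_max = 0.10,
                       block_sizes = c(5L, 10L, 15L, 20L), K = 3L,
                       schemes = c("kfold", "stratified", "lco"),
                       k_folds = 4L, kfold_reps = 4L,
                       train_fraction = 0.75, stratified_reps = 16L,
                       seed = 1L, out_dir = NULL) {
  has_files <- !is.null(genotypes) || !is.null(phenotypes)
  if (has_files == !is.null(sim))
    stop("supply exactly one of (genotypes + phenotypes) or sim")
  if (has_files && (is.null(genotypes) || is.null(phenotypes)))
    stop("both genotype and phenotype paths are required")
  if (any(block_sizes < 1)) stop("block sizes must be >= 1")
  schemes <- match.arg(schemes, several.ok = TRUE)
  structure(list(genotypes = genotypes, phenotypes = phenotypes, sim = sim,
                 maf_min = maf_min, miss_max = miss_max,
                 block_sizes = as.integer(block_sizes), K = as.integer(K),
                 schemes = schemes, k_folds = as.integer(k_folds),
                 kfold_reps = as.integer(kfold_reps),
                 train_fraction = train_fraction,
                 stratified_reps = as.integer(stratified_reps),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Execute the full genomic-selection analysis
#'
#' Stages: genotype input (file or simulation) and QC; moving-grid
#' adjustment and trial combination per trait; REML variance components
#' and heritability; GRM / IBS / K-means / PCA / adjacent LD; haplotype
#' blocks per requested length; single-SNP and haplotype GBLUP under the
#' requested validation schemes; paired model comparisons. Artifacts are
#' written under `out_dir` when set.
#'
#' @param config a [run_config()].
#' @return list of class `run_result` with elements `heritability`,
#'   `structure` (clusters, relationships, LD, PCA), `block_summaries`,
#'   `predictive_ability` (tidy data.frame: trait, model, scheme,
#'   replicate, r), `comparisons`, plus the processed inputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # --- stage: input ---------------------------------------------------
  if (!is.null(config$sim)) {
    pop <- simulate_population(config$sim)
    pheno <- apply_field_layout(simulate_phenotypes(pop, config$sim),
                                config$sim)
    g <- pop$genotypes; map <- pop$map
  } else {
    if (!file.exists(config$genotypes))
      stop("genotype file not found: ", config$genotypes)
    if (!file.exists(config$phenotypes))
      stop("phenotype file not found: ", config$phenotypes)
    hm <- read_hapmap(config$genotypes)
    g <- hm$genotypes; map <- hm$map
    pheno <- read_pheno(config$phenotypes)
  }
  # --- stage: genotype QC --------------------------------------------
  g <- filter_markers(g, config$maf_min, config$miss_max)
  if (anyNA(g$dosages)) g <- impute_knn(g)
  om <- order_by_map(g, map)
  g <- om$genotypes; map <- om$map
  traits <- setdiff(names(pheno), c("line_id", "trial", "row", "col"))

  # --- stage: field adjustment and heritability ----------------------
  adjusted <- pheno
  herit <- list(); combined <- list()
  for (tr in traits) {
    if (all(c("row", "col") %in% names(adjusted)))
      adjusted <- moving_grid_adjust(adjusted, tr)
    herit[[tr]] <- estimate_variance_components(adjusted, tr)
    cmb <- combine_trials(adjusted, tr)
    combined[[tr]] <- cmb[intersect(names(cmb), line_ids(g))]
  }
  herit_tab <- do.call(rbind, lapply(traits, function(tr)
    data.frame(trait = tr, sigma_g2 = herit[[tr]]$sigma_g2,
               sigma_e2 = herit[[tr]]$sigma_e2,
               n_trials = herit[[tr]]$n_trials, H = herit[[tr]]$H)))

  # --- stage: population structure -----------------------------------
  grm <- grm_vanraden(g)
  D <- ibs_distance(g)
  clusters <- kmeans_cluster(D, K = config$K, seed = config$seed)
  rel <- cluster_relationships(grm, clusters)
  pcs <- pca_genotypes(g)
  ld <- adjacent_ld(g, map)

  # --- stage: haplotype blocks ---------------------------------------
  hbs_list <- lapply(config$block_sizes, function(L) build_blocks(g, map, L))
  names(hbs_list) <- paste0("L", config$block_sizes)
  block_tab <- do.call(rbind, lapply(hbs_list,
                                     function(h) block_summary(h)$overall))

  # --- stage: designs, GBLUP, validation schemes ---------------------
  W_snp <- build_snp_design(g)
  W_hap <- lapply(hbs_list, build_hap_design)
  models <- c(list(single_SNP = W_snp),
              stats::setNames(W_hap, paste0("Haploblock-", config$block_sizes)))
  pa_rows <- list(); comparisons <- list()
  for (tr in traits) {
    y <- combined[[tr]]
    sch <- list()
    if ("kfold" %in% config$schemes)
      sch$kfold <- make_kfold(names(y), k = config$k_folds,
                              repetitions = config$kfold_reps,
                              seed = config$seed)
    if ("stratified" %in% config$schemes)
      sch$stratified <- make_stratified(names(y), clusters,
                                        train_fraction = config$train_fraction,
                                        repetitions = config$stratified_reps,
                                        seed = config$seed)
    if ("lco" %in% config$schemes)
      sch$leave_cluster_out <- leave_cluster_out(names(y), clusters)
    for (sname in names(sch)) {
      per_model <- list()
      for (mname in names(models)) {
        res <- evaluate_scheme(y, models[[mname]], sch[[sname]])
        per_model[[mname]] <- res$r
        pa_rows[[length(pa_rows) + 1]] <- data.frame(
          trait = tr, model = mname, scheme = sname,
          replicate = res$replicate, n_val = res$n_val, r = res$r,
          stringsAsFactors = FALSE)
      }
      for (mname in setdiff(names(models), "single_SNP")) {
        cmp <- paired_comparison(per_model$single_SNP, per_model[[mname]])
        comparisons[[length(comparisons) + 1]] <- data.frame(
          trait = tr, scheme = sname, model = mname,
          pct_change = cmp$pct_change, t = cmp$t, p_value = cmp$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  result <- structure(list(
    heritability = herit_tab,
    structure = list(clusters = clusters, relationships = rel,
                     ld = ld, pca = pcs),
    block_summaries = block_tab,
    predictive_ability = do.call(rbind, pa_rows),
    comparisons = do.call(rbind, comparisons),
    genotypes = g, map = map, combined = combined,
    config = config), class = "run_result")
  if (!is.null(config$out_dir)) write_artifacts(result, config$out_dir)
  result
}

write_artifacts <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(result$heritability,
                   file.path(out_dir, "heritability.csv"), row.names = FALSE)
  utils::write.csv(result$block_summaries,
                   file.path(out_dir, "block_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(result$predictive_ability,
                   file.path(out_dir, "predictive_ability.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparisons,
                   file.path(out_dir, "model_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(line_id = names(result$structure$clusters$labels),
                              cluster = result$structure$clusters$labels),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(result$structure$relationships,
                   file.path(out_dir, "cluster_relationships.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = result$config$seed,
         genome_mean_r2 = result$structure$ld$genome_mean,
         chromosome_mean_r2 = as.list(result$structure$ld$chromosome_means)),
    file.path(out_dir, "ld_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a plain-text summary report of a pipeline run
#'
#' @param result a `run_result`.
#' @param path optional file to write the report to.
#' @return the report lines, invisibly (printed when `path` is NULL).
#' @export
report_run <- function(result, path = NULL) {
  stopifnot(inherits(result, "run_result"))
  fmt_tab <- function(df) utils::capture.output(print(df, row.names = FALSE))
  pa <- result$predictive_ability
  pa_sum <- do.call(rbind, lapply(split(pa, list(pa$trait, pa$model,
                                                 pa$scheme), drop = TRUE),
    function(d) data.frame(trait = d$trait[1], model = d$model[1],
                           scheme = d$scheme[1], mean_r = mean(d$r),
                           mean_z_back = tanh(mean(fisher_z(d$r))))))
  pa_sum <- pa_sum[order(pa_sum$trait, pa_sum$scheme, pa_sum$model), ]
  lines_out <- c(
    "Genomic selection run summary",
    "=============================",
    "",
    "Variance components and broad-sense heritability:",
    fmt_tab(result$heritability), "",
    "Haplotype block summaries:",
    fmt_tab(result$block_summaries), "",
    sprintf("Genome-wide mean adjacent-marker r2: %.3f",
            result$structure$ld$genome_mean), "",
    "Cluster relationships (GRM):",
    fmt_tab(result$structure$relationships), "",
    "Mean predictive ability by trait / scheme / model:",
    fmt_tab(pa_sum), "",
    "Haplotype vs single-SNP paired comparisons:",
    fmt_tab(result$comparisons))
  if (!is.null(path)) writeLines(lines_out, path) else cat(lines_out, sep = "\n")
  invisible(lines_out)
}
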