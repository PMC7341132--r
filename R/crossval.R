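# Validation schemes (k-fold, stratified sampling, leave-cluster-out),
# predictive ability and the comparison statistics.

new_cv_scheme <- function(type, replicates, params) {
  structure(list(scheme_type = type, replicates = replicates,
                 parameters = params),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("cv_scheme '%s': %d replicate(s)\n", x$scheme_type,
              length(x$replicates)))
  invisible(x)
}

#' k-fold cross-validation scheme
#'
#' Per repetition the lines are randomly shuffled and split into `k`
#' folds whose sizes differ by at most one; each fold serves once as the
#' validation set with the remaining folds as training, so every line is
#' validated exactly once per repetition.
#'
#' @param lines character vector of line ids.
#' @param k number of folds (default 4).
#' @param repetitions number of independent repetitions (default 4).
#' @param seed RNG seed.
#' @return a `cv_scheme`; each replicate holds `training`, `validation`,
#'   `repetition`, `fold`.
#' @export
make_kfold <- function(lines, k = 4L, repetitions = 4L, seed = 1L) {
  n <- length(lines)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of lines")
  set.seed(derive_seed(seed, 21))
  reps <- list()
  for (r in seq_len(repetitions)) {
    shuffled <- sample(lines)
    # assign folds on the shuffled order: sizes differ by <= 1
    fold_of <- integer(n)
    fold_of[match(shuffled, lines)] <- rep(seq_len(k), length.out = n)
    for (f in seq_len(k)) {
      val <- lines[fold_of == f]
      reps[[length(reps) + 1]] <- list(training = setdiff(lines, val),
                                       validation = val,
                                       repetition = r, fold = f)
    }
  }
  new_cv_scheme("kfold", reps,
                list(k = k, repetitions = repetitions, seed = seed))
}

#' Stratified-sampling training-set optimization scheme
#'
#' Per replicate, round-half-up(`train_fraction` x cluster size) lines
#' are sampled without replacement from every cluster as the calibration
#' set (so each subpopulation is represented in proportion to its size);
#' all remaining lines form the validation set.
#'
#' @param lines character vector of line ids.
#' @param clusters named label vector or `cluster_assignment` covering
#'   `lines`.
#' @param train_fraction calibration fraction in (0, 1) (default 0.75).
#' @param repetitions number of replicates (default 16).
#' @param seed RNG seed.
#' @return a `cv_scheme`; each replicate holds `training`, `validation`,
#'   `repetition`.
#' @export
make_stratified <- function(lines, clusters, train_fraction = 0.75,
                            repetitions = 16L, seed = 1L) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  labels <- labels[lines]
  if (anyNA(labels)) stop("every line must carry a cluster label")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every cluster must contain at least 2 lines")
  set.seed(derive_seed(seed, 22))
  reps <- list()
  for (r in seq_len(repetitions)) {
    train <- character(0)
    for (cc in names(sizes)) {
      members <- lines[labels == cc]
      n_c <- round_half_up(train_fraction * length(members))
      n_c <- min(max(n_c, 1L), length(members) - 1L)  # keep both sets nonempty
      train <- c(train, sample(members, n_c))
    }
    reps[[length(reps) + 1]] <- list(training = train,
                                     validation = setdiff(lines, train),
                                     repetition = r)
  }
  new_cv_scheme("stratified", reps,
                list(train_fraction = train_fraction,
                     repetitions = repetitions, seed = seed))
}

#' Leave-one-cluster-out validation scheme
#'
#' One replicate per cluster: training on all other clusters, validation
#' on the held-out cluster. Exposes the population-structure penalty on
#' predictive ability.
#'
#' @param lines character vector of line ids.
#' @param clusters named label vector or `cluster_assignment`.
#' @return a `cv_scheme`; each replicate holds `training`, `validation`,
#'   `held_out_cluster`.
#' @export
leave_cluster_out <- function(lines, clusters) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  labels <- labels[lines]
  if (anyNA(labels)) stop("every line must carry a cluster label")
  ids <- sort(unique(labels))
  if (length(ids) < 2) stop("need at least 2 clusters")
  reps <- lapply(ids, function(cc)
    list(training = lines[labels != cc], validation = lines[labels == cc],
         held_out_cluster = cc))
  new_cv_scheme("leave_cluster_out", reps, list(clusters = ids))
}

#' Predictive ability
#'
#' Pearson correlation between observed (adjusted) phenotypes and
#' predicted additive values in a validation set.
#'
#' @param y_val observed values.
#' @param a_val predicted additive values (same order).
#' @return correlation r in \[-1, 1\].
#' @export
predictive_ability <- function(y_val, a_val) {
  if (length(y_val) != length(a_val)) stop("vector length mismatch")
  if (length(y_val) < 3) stop("need at least 3 validation pairs")
  if (stats::sd(y_val) == 0 || stats::sd(a_val) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(y_val, a_val)
}

#' Fisher Z transform of a correlation
#'
#' @param r correlation with |r| < 1.
#' @return z = arctanh(r).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("Fisher Z requires |r| < 1")
  atanh(r)
}

#' T statistic for a predictive-ability estimate
#'
#' T = r sqrt(n - 2) / sqrt(1 - r^2), referred to a t distribution with
#' n - 2 degrees of freedom.
#'
#' @param r predictive ability, |r| < 1.
#' @param n validation-set size (> 2).
#' @return the T statistic.
#' @export
t_statistic <- function(r, n) {
  if (any(n <= 2)) stop("n must exceed 2")
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Paired comparison of two prediction models across replicates
#'
#' Given per-replicate predictive abilities of a baseline (single-SNP)
#' and a comparison (haplotype) model evaluated on identical calibration
#' sets, applies the Fisher Z transform and a paired t-test to the
#' per-replicate differences, and reports the percent change in mean r:
#' 100 (mean r_hap - mean r_single) / mean r_single.
#'
#' @param r_single baseline per-replicate correlations.
#' @param r_hap comparison per-replicate correlations (same replicates,
#'   same order).
#' @return list: `pct_change`, `t`, `p_value`, `mean_single`, `mean_hap`.
#' @export
paired_comparison <- function(r_single, r_hap) {
  if (length(r_single) != length(r_hap)) stop("replicate length mismatch")
  dz <- fisher_z(r_hap) - fisher_z(r_single)
  if (all(dz == 0)) {
    t_val <- 0; p <- 1
  } else if (stats::sd(dz) == 0) {
    # an exactly constant nonzero difference: the paired t diverges
    t_val <- sign(dz[1]) * Inf; p <- 0
  } else {
    tt <- stats::t.test(dz)
    t_val <- unname(tt$statistic); p <- tt$p.value
  }
  list(pct_change = 100 * (mean(r_hap) - mean(r_single)) / mean(r_single),
       t = t_val, p_value = p,
       mean_single = mean(r_single), mean_hap = mean(r_hap))
}

#' Run a fitted prediction model over a validation scheme
#'
#' Convenience driver: for every replicate of a scheme, fits REML + GBLUP
#' on the training lines and computes the predictive ability on the
#' validation lines.
#'
#' @param y named phenotype vector (combined adjusted values).
#' @param W design matrix ([build_snp_design()] or [build_hap_design()]).
#' @param scheme a `cv_scheme`.
#' @return data.frame: replicate, n_train, n_val, r.
#' @export
evaluate_scheme <- function(y, W, scheme) {
  rows <- lapply(seq_along(scheme$replicates), function(i) {
    rep_i <- scheme$replicates[[i]]
    train <- intersect(rep_i$training, names(y)[is.finite(y)])
    val <- intersect(rep_i$validation, names(y)[is.finite(y)])
    fit <- gblup_predict(y, W, training = train, validation = val)
    data.frame(replicate = i, n_train = length(train), n_val = length(val),
               r = predictive_ability(y[val], fit$predictions[val]))
  })
  do.call(rbind, rows)
}
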