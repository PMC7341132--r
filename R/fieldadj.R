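# Moving-grid spatial adjustment, trial combination, and REML variance
# components / broad-sense heritability on plot-level field data.

# mean of observed values in the square ring of `radius` around (r, cl);
# the ring shrinks at field edges and the focal plot is excluded
ring_mean <- function(grid, r, cl, radius) {
  rr <- max(1, r - radius):min(nrow(grid), r + radius)
  cc <- max(1, cl - radius):min(ncol(grid), cl + radius)
  nb <- grid[rr, cc, drop = FALSE]
  nb[match(r, rr), match(cl, cc)] <- NA
  mean(nb, na.rm = TRUE)
}

#' Moving-grid spatial adjustment of plot values
#'
#' Within each trial, every plot's local environment is summarised by the
#' mean of the observed values in the surrounding ring of grid cells (the
#' 3x3 ring of 8 neighbours by default; the ring shrinks at field edges).
#' A single-slope linear regression of plot value on this moving-mean
#' covariate is fitted per trial and the adjusted value is
#' `value - b * (covariate - mean(covariate))`, which removes the smooth
#' spatial trend while preserving the trial grand mean.
#'
#' @param pheno data.frame with `line_id`, `trial`, `row`, `col` and trait
#'   columns.
#' @param trait name of the trait column to adjust.
#' @param window number of surrounding plots in the ring: 8 (3x3 ring) or
#'   24 (5x5 ring).
#' @return `pheno` with the trait column replaced by adjusted values.
#' @export
moving_grid_adjust <- function(pheno, trait, window = 8L) {
  if (!all(c("row", "col") %in% names(pheno)))
    stop("row/col coordinates required for moving-grid adjustment")
  if (!trait %in% names(pheno)) stop("unknown trait: ", trait)
  radius <- switch(as.character(window), "8" = 1L, "24" = 2L,
                   stop("window must be 8 (3x3 ring) or 24 (5x5 ring)"))
  for (t in unique(pheno$trial)) {
    sel <- which(pheno$trial == t)
    r <- pheno$row[sel]; cl <- pheno$col[sel]; y <- pheno[[trait]][sel]
    grid <- matrix(NA_real_, max(r), max(cl))
    grid[cbind(r, cl)] <- y
    cov <- vapply(seq_along(sel),
                  function(i) ring_mean(grid, r[i], cl[i], radius), 0)
    usable <- is.finite(cov) & is.finite(y)
    if (stats::var(cov[usable]) == 0 || !any(usable)) {
      warning("zero-variance moving-mean covariate in trial ", t,
              "; adjustment skipped")
      next
    }
    b <- stats::coef(stats::lm(y[usable] ~ cov[usable]))[2]
    adj <- y
    adj[usable] <- y[usable] - b * (cov[usable] - mean(cov[usable]))
    pheno[[trait]][sel] <- adj
  }
  pheno
}

#' Combine trials into one adjusted value per line
#'
#' Each trial is centered on its own mean (removing trial-mean
#' differences) and a line's centered values are averaged over the trials
#' in which it appears. Lines with no finite record are excluded with a
#' message.
#'
#' @param pheno data.frame with `line_id`, `trial` and the trait column.
#' @param trait trait column name.
#' @return named numeric vector, one combined value per line.
#' @export
combine_trials <- function(pheno, trait) {
  if (!trait %in% names(pheno)) stop("unknown trait: ", trait)
  y <- pheno[[trait]]
  keep <- is.finite(y)
  dropped <- setdiff(unique(pheno$line_id), unique(pheno$line_id[keep]))
  if (length(dropped) > 0)
    message(length(dropped), " line(s) without any finite record excluded")
  ph <- pheno[keep, ]
  centered <- stats::ave(ph[[trait]], ph$trial, FUN = function(v) v - mean(v))
  agg <- tapply(centered, ph$line_id, mean)
  setNames(as.vector(agg), names(agg))[unique(ph$line_id)]
}

#' REML variance components and broad-sense heritability
#'
#' Fits the plot-level mixed model `value = trial (fixed) + line (random)
#' + residual` by REML and reports the genetic and residual variance
#' components together with entry-mean broad-sense heritability
#' H = sg2 / (sg2 + se2 / n_trials).
#'
#' @param pheno data.frame with `line_id`, `trial` and the trait column
#'   (typically after [moving_grid_adjust()]).
#' @param trait trait column name.
#' @return object of class `variance_components_h`: `sigma_g2`,
#'   `sigma_e2`, `n_trials`, `H`.
#' @export
estimate_variance_components <- function(pheno, trait) {
  if (!trait %in% names(pheno)) stop("unknown trait: ", trait)
  ph <- pheno[is.finite(pheno[[trait]]), ]
  n_trials <- length(unique(ph$trial))
  replicated <- any(table(ph$line_id, ph$trial) > 1)
  if (n_trials < 2 && !replicated)
    stop("residual variance is inestimable: need >= 2 trials or replicated lines")
  ph$.y <- ph[[trait]]
  fit <- lme4::lmer(.y ~ factor(trial) + (1 | line_id), data = ph,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_g2 <- vc$vcov[vc$grp == "line_id"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  structure(list(sigma_g2 = max(0, sigma_g2), sigma_e2 = max(0, sigma_e2),
                 n_trials = n_trials,
                 H = heritability(max(0, sigma_g2), max(0, sigma_e2), n_trials)),
            class = "variance_components_h")
}

#' Entry-mean broad-sense heritability
#'
#' H = sg2 / (sg2 + se2 / n_trials): the fraction of entry-mean
#' phenotypic variance attributable to genotypic variance when lines are
#' averaged over `n_trials` trials.
#'
#' @param sigma_g2 genotypic variance (or a `variance_components_h`
#'   object, in which case the other arguments are ignored).
#' @param sigma_e2 residual variance.
#' @param n_trials number of trials contributing to the entry mean.
#' @return H, in \[0, 1\].
#' @export
heritability <- function(sigma_g2, sigma_e2 = NULL, n_trials = NULL) {
  if (inherits(sigma_g2, "variance_components_h")) {
    vc <- sigma_g2
    sigma_g2 <- vc$sigma_g2; sigma_e2 <- vc$sigma_e2; n_trials <- vc$n_trials
  }
  if (sigma_g2 < 0 || sigma_e2 < 0) stop("variance components must be >= 0")
  if (sigma_g2 == 0 && sigma_e2 == 0)
    stop("heritability undefined when both variance components are 0")
  sigma_g2 / (sigma_g2 + sigma_e2 / n_trials)
}

#' @export
print.variance_components_h <- function(x, ...) {
  cat(sprintf("sigma_g2 = %.4g, sigma_e2 = %.4g, n_trials = %d, H = %.2f\n",
              x$sigma_g2, x$sigma_e2, x$n_trials, x$H))
  invisible(x)
}
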