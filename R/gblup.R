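# Single-SNP and multi-allelic haplotype GBLUP: centered design matrices,
# restricted maximum likelihood on the marker kernel, and out-of-sample
# prediction of additive values.
#
# Model: y = 1 mu + W alpha + e, Var(alpha) = I sigma2_marker,
# Var(e) = I sigma2_e, hence Var(y) = W W' sigma2_marker + I sigma2_e.
# REML is profiled on the variance ratio phi = sigma2_marker / sigma2_e
# over the eigen-spectrum of the (intercept-projected) kernel W W', and
# the ratio is optimized by Brent search on a log grid.

#' Centered single-SNP additive design matrix
#'
#' One column per SNP; a line's entry is x1 - 2 p1 where x1 is its copy
#' number of the A allele and p1 the A-allele frequency in the reference
#' line set. For genotypes (AA, AB, BB) this gives the classical additive
#' codings 2 p2, p2 - p1, -2 p1. Columns monomorphic in the reference set
#' are dropped with a message.
#'
#' @param g a fully imputed [genotype_matrix].
#' @param freq_ref line ids over which allele frequencies are computed
#'   (default: all lines of `g`).
#' @return n x m numeric matrix with line-id rownames and marker-id
#'   colnames; columns sum to zero over `freq_ref`.
#' @export
build_snp_design <- function(g, freq_ref = NULL) {
  d <- g$dosages
  if (anyNA(d)) stop("missing dosages: impute before building the design")
  if (is.null(freq_ref)) freq_ref <- rownames(d)
  if (length(freq_ref) == 0) stop("freq_ref must be nonempty")
  if (!all(freq_ref %in% rownames(d))) stop("unknown line in freq_ref")
  p1 <- colMeans(d[freq_ref, , drop = FALSE]) / 2
  keep <- p1 > 0 & p1 < 1
  if (!all(keep))
    message(sum(!keep), " marker(s) monomorphic in the reference set dropped")
  if (!any(keep)) stop("no polymorphic markers in the reference set")
  W <- sweep(d[, keep, drop = FALSE], 2, 2 * p1[keep])
  W
}

#' Centered multi-allelic haplotype design matrix
#'
#' One column per (block, haplotype allele) pair; a line's entry is
#' x_k - 2 p_k, where x_k is its copy number of haplotype allele k (0 or
#' 2 for inbreds) and p_k the allele's frequency in the reference line
#' set. This equals the classical multi-allelic codings up to a global
#' sign, which leaves additive values and predictions unchanged. Alleles
#' absent from the reference set keep their columns with p_k = 0; no
#' column is silently dropped.
#'
#' @param hbs a [build_blocks()] result.
#' @param freq_ref line ids for the frequency reference (default: all
#'   lines of the block set).
#' @return n x n_alpha numeric matrix, rownames = line ids, colnames =
#'   "block:allele".
#' @export
build_hap_design <- function(hbs, freq_ref = NULL) {
  codes <- hbs$allele_codes
  if (nrow(hbs$blocks) == 0) stop("empty block set")
  if (is.null(freq_ref)) freq_ref <- rownames(codes)
  if (length(freq_ref) == 0) stop("freq_ref must be nonempty")
  if (!all(freq_ref %in% rownames(codes))) stop("unknown line in freq_ref")
  cols <- list(); cn <- character(0)
  for (b in seq_len(nrow(hbs$blocks))) {
    cb <- codes[, b]
    alleles <- sort(unique(cb))
    ref_tab <- table(factor(codes[freq_ref, b], levels = alleles))
    p_k <- as.vector(ref_tab) / length(freq_ref)
    for (a in seq_along(alleles)) {
      x_k <- 2 * (cb == alleles[a])
      cols[[length(cols) + 1]] <- x_k - 2 * p_k[a]
      cn <- c(cn, paste0(hbs$blocks$block_id[b], ":", alleles[a]))
    }
  }
  W <- do.call(cbind, cols)
  dimnames(W) <- list(rownames(codes), cn)
  W
}

# profiled restricted log-likelihood machinery -------------------------

# eigen-reduce the kernel after projecting out the intercept. The
# projected data are expressed on all n eigenvectors of S G S: the
# intercept direction lies in the null space and contributes exactly zero
# to the quadratic form (eta = 0, xi = 0), leaving the q = n - 1 REML
# degrees of freedom.
reml_spectrum <- function(y, W_train) {
  n <- length(y)
  G <- tcrossprod(W_train)
  ones <- rep(1, n)
  S <- diag(n) - tcrossprod(ones) / n
  es <- eigen(S %*% G %*% S, symmetric = TRUE)
  xi <- pmax(es$values, 0)
  eta <- as.vector(crossprod(es$vectors, y - mean(y)))
  list(xi = xi, eta = eta, n = n, q = n - 1, G = G)
}

# restricted log-likelihood profiled in phi = sigma2_marker / sigma2_e
rll_profile <- function(log_phi, sp) {
  phi <- exp(log_phi)
  q <- sp$q
  v <- sp$xi * phi + 1
  ss <- sum(sp$eta^2 / v)
  0.5 * (q * log(q / (2 * pi)) - q - q * log(ss) - sum(log(v)))
}

# Newton refinement of the profiled ratio from a Brent starting point;
# closed-form first/second derivatives of the profiled restricted
# log-likelihood in phi
polish_phi <- function(phi, sp, max_iter = 50L, tol = 1e-13) {
  q <- sp$q
  for (i in seq_len(max_iter)) {
    v <- sp$xi * phi + 1
    A <- sum(sp$xi * sp$eta^2 / v^2)
    B <- sum(sp$eta^2 / v)
    d1 <- 0.5 * (q * A / B - sum(sp$xi / v))
    Ap <- -2 * sum(sp$xi^2 * sp$eta^2 / v^3)
    d2 <- 0.5 * (q * (Ap * B + A^2) / B^2 + sum(sp$xi^2 / v^2))
    if (!is.finite(d1) || !is.finite(d2) || d2 >= 0) break
    step <- d1 / d2
    phi_new <- phi - step
    if (phi_new <= 0) phi_new <- phi / 2
    if (abs(phi_new - phi) <= tol * max(phi, 1e-300)) {
      phi <- phi_new
      break
    }
    phi <- phi_new
  }
  phi
}

#' REML variance components for a marker design
#'
#' Estimates (sigma2_marker, sigma2_e) for y = 1 mu + W alpha + e with
#' Var(alpha) = I sigma2_marker by restricted maximum likelihood,
#' profiling the likelihood on the variance ratio over the eigenvalues of
#' the training kernel W W'. The ratio is located by a coarse log-spaced
#' scan refined with Brent optimization.
#'
#' @param y named numeric vector of phenotypes (one per line).
#' @param W design matrix from [build_snp_design()] or
#'   [build_hap_design()].
#' @param training line ids used for estimation (default: all lines with
#'   finite `y` present in `W`).
#' @return list of class `variance_components`: `sigma_marker2`,
#'   `sigma_e2`, `loglik` (restricted), `n_iter`, `converged`.
#' @export
reml_fit <- function(y, W, training = NULL) {
  if (is.null(training))
    training <- intersect(names(y)[is.finite(y)], rownames(W))
  if (length(training) <= 2) stop("need more than 2 training lines")
  yt <- y[training]
  Wt <- W[training, , drop = FALSE]
  if (stats::var(yt) < 1e-12) {
    warning("constant training phenotype: variance components degenerate at 0")
    return(structure(list(sigma_marker2 = 0, sigma_e2 = 0, loglik = NA_real_,
                          n_iter = 0L, converged = FALSE),
                     class = "variance_components"))
  }
  sp <- reml_spectrum(yt, Wt)
  if (max(sp$xi) <= 0) stop("marker kernel has rank 0 on the training set")
  grid <- seq(log(1e-9), log(1e9), length.out = 61)
  vals <- vapply(grid, rll_profile, 0, sp = sp)
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(rll_profile, c(lo, hi), sp = sp, maximum = TRUE,
                         tol = 1e-8)
  phi <- polish_phi(exp(opt$maximum), sp)
  q <- sp$q
  v <- sp$xi * phi + 1
  sigma_e2 <- max(sum(sp$eta^2 / v) / q, 1e-12)
  sigma_marker2 <- max(phi * sigma_e2, 0)
  edge <- log(phi) <= grid[1] + 1e-6 || log(phi) >= grid[61] - 1e-6
  structure(list(sigma_marker2 = sigma_marker2, sigma_e2 = sigma_e2,
                 loglik = rll_profile(log(phi), sp), n_iter = length(grid),
                 converged = !edge),
            class = "variance_components")
}

#' GBLUP additive values and out-of-sample predictions
#'
#' Given REML components, the GLS intercept is estimated on the training
#' lines, marker/haplotype effects are obtained as
#' alpha_hat = sigma2 W_train' V^-1 (y_train - 1 mu_hat) with
#' V = W_train W_train' sigma2 + I sigma2_e, and additive values
#' a = W alpha_hat are returned for every line of `W` (validation lines
#' use the same frequency-referenced design).
#'
#' @param y named numeric phenotype vector (training lines must be
#'   observed).
#' @param W design matrix covering training and validation lines.
#' @param training training line ids.
#' @param validation validation line ids (disjoint from training;
#'   default: all other lines of `W`).
#' @param vc optional precomputed `variance_components`; fitted by
#'   [reml_fit()] when absent.
#' @return list of class `gblup_fit`: `mu`, `effects`, `additive_values`
#'   (all lines), `predictions` (validation subset), `vc`.
#' @export
gblup_predict <- function(y, W, training, validation = NULL, vc = NULL) {
  if (is.null(validation)) validation <- setdiff(rownames(W), training)
  if (length(intersect(training, validation)) > 0)
    stop("training and validation sets must be disjoint")
  if (!all(training %in% rownames(W)))
    stop("training line missing from the design matrix")
  if (is.null(vc)) vc <- reml_fit(y, W, training)
  Wt <- W[training, , drop = FALSE]
  yt <- y[training]
  n <- length(training)
  V <- tcrossprod(Wt) * vc$sigma_marker2 + diag(n) * vc$sigma_e2
  if (vc$sigma_e2 < 1e-10) V <- V + diag(n) * 1e-10  # numeric guard
  Vinv <- solve(V)
  ones <- rep(1, n)
  mu <- as.numeric((crossprod(ones, Vinv) %*% yt) /
                     (crossprod(ones, Vinv) %*% ones))
  resid <- yt - mu
  effects <- vc$sigma_marker2 * as.vector(crossprod(Wt, Vinv %*% resid))
  names(effects) <- colnames(W)
  a <- as.vector(W %*% effects)
  names(a) <- rownames(W)
  structure(list(mu = mu, effects = effects, additive_values = a,
                 predictions = a[validation], vc = vc),
            class = "gblup_fit")
}
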