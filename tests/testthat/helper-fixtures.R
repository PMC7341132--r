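# shared fixtures: tiny hand-built genotype objects and desk-scale
# simulation configs used across test files

toy_genotypes <- function(dosages, lines = NULL, markers = NULL,
                          alleles = NULL) {
  d <- as.matrix(dosages)
  rownames(d) <- lines %||% sprintf("L%02d", seq_len(nrow(d)))
  colnames(d) <- markers %||% sprintf("M%02d", seq_len(ncol(d)))
  genotype_matrix(d, alleles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-chromosome map for a toy genotype matrix
toy_map <- function(g, chrom = "1A", pos = NULL) {
  data.frame(marker_id = marker_ids(g), chrom = chrom,
             pos = pos %||% seq_len(ncol(g$dosages)),
             stringsAsFactors = FALSE)
}

# small structured panel: 3 clusters, 4 chromosomes, quick to simulate
small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, cluster_sizes = c(50L, 40L, 40L),
                   n_chromosomes = 4L, markers_per_chromosome = 50L,
                   field_rows = 12L, field_cols = 11L, n_qtl = 40L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# write a 3-line x 2-marker HapMap file exercising both call dialects
write_toy_hapmap <- function(path, calls1 = c("A", "A", "T"),
                             calls2 = c("W", "N", "TT")) {
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    "L01", "L02", "L03"), collapse = "\t")
  row1 <- paste(c("M01", "A/T", "1A", "10.5", "+", rep("NA", 6), calls1),
                collapse = "\t")
  row2 <- paste(c("M02", "A/T", "1B", "3.25", "+", rep("NA", 6), calls2),
                collapse = "\t")
  writeLines(c(header, row1, row2), path)
  path
}

# random centered design + phenotype generator for REML/GBLUP oracles
random_instance <- function(n, m, sigma2 = 0.05, sigma_e2 = 1, seed = 1) {
  set.seed(seed)
  d <- matrix(2 * rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
              n, m, dimnames = list(sprintf("L%03d", 1:n),
                                    sprintf("M%03d", 1:m)))
  g <- genotype_matrix(d)
  W <- suppressMessages(build_snp_design(g))
  alpha <- rnorm(ncol(W), 0, sqrt(sigma2))
  y <- setNames(as.vector(W %*% alpha) + rnorm(n, 0, sqrt(sigma_e2)),
                rownames(W))
  list(g = g, W = W, y = y)
}

# reference REML: 1-D optimization of the explicit-matrix restricted
# likelihood in the variance ratio, residual variance profiled out
# analytically (no eigendecomposition; independent of the implementation)
direct_reml <- function(y, W) {
  n <- length(y); X <- matrix(1, n, 1); G <- tcrossprod(W); q <- n - 1
  prll <- function(lphi) {
    V0 <- G * exp(lphi) + diag(n)
    Vi <- solve(V0)
    XVX <- crossprod(X, Vi %*% X)
    P0 <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
    ss <- as.numeric(crossprod(y, P0 %*% y))
    -0.5 * (as.numeric(determinant(V0)$modulus) + log(XVX[1, 1]) +
              q * log(ss / q) + q)
  }
  o <- stats::optimize(prll, c(log(1e-9), log(1e9)), maximum = TRUE,
                       tol = 1e-6)
  o <- stats::optimize(prll, o$maximum + c(-0.01, 0.01), maximum = TRUE,
                       tol = 1e-12)
  phi <- exp(o$maximum)
  V0 <- G * phi + diag(n)
  Vi <- solve(V0)
  XVX <- crossprod(X, Vi %*% X)
  P0 <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  se2 <- as.numeric(crossprod(y, P0 %*% y)) / q
  c(phi * se2, se2)
}
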