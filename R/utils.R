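#' Round half away from zero
#'
#' Deterministic rounding used wherever sample sizes are derived from
#' fractions (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer vector, halves rounded up.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' observations; 1 for identical partitions (up to label permutation),
#' ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# derive a child seed (< 2^31) from a base seed and a stream tag
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + stream) %% 2147483647
}
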