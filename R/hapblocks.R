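# Fixed-length haplotype blocks: construction from map-ordered imputed
# genotypes, enumeration of multi-allelic haplotype alleles, summaries.

#' Build fixed-length haplotype blocks
#'
#' Treats every run of `L` adjacent mapped markers within a chromosome as
#' one multi-allelic locus. Each chromosome with m markers contributes
#' floor(m / L) consecutive non-overlapping blocks in map order; the
#' trailing m mod L markers are dropped (counted in a message). Blocks
#' never span chromosome boundaries.
#'
#' @param g a fully imputed, homozygous [genotype_matrix].
#' @param map data.frame (marker_id, chrom, pos) covering every marker of
#'   `g`; markers are ordered by (chrom, pos, marker_id) internally.
#' @param L block length in markers (>= 1).
#' @return object of class `haplotype_block_set`: `block_size`, `blocks`
#'   (data.frame: block_id, chrom, start_cM, end_cM, n_alleles),
#'   `allele_codes` (lines x blocks integer matrix), `allele_freqs`
#'   (list of per-block frequency vectors), `marker_index` (list of
#'   per-block marker-id vectors).
#' @export
build_blocks <- function(g, map, L) {
  if (L < 1) stop("block length L must be >= 1")
  if (anyNA(g$dosages)) stop("genotypes must be fully imputed before blocking")
  om <- order_by_map(g, map)
  g <- om$genotypes; map <- om$map
  n_blocks_per_chr <- tapply(map$marker_id, map$chrom, length)
  if (all(n_blocks_per_chr %/% L == 0))
    stop("L exceeds every chromosome's marker count: 0 blocks")
  dropped <- 0L
  block_rows <- list(); codes <- list(); freqs <- list(); midx <- list()
  bid <- 0L
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    nb <- length(jj) %/% L
    dropped <- dropped + length(jj) %% L
    if (nb == 0L) next
    for (b in seq_len(nb)) {
      bid <- bid + 1L
      cols <- jj[((b - 1L) * L + 1L):(b * L)]
      en <- enumerate_alleles(g$dosages[, cols, drop = FALSE])
      block_rows[[bid]] <- data.frame(
        block_id = sprintf("%s_B%04d", chr, b), chrom = chr,
        start_cM = map$pos[cols[1]], end_cM = map$pos[cols[L]],
        n_alleles = length(en$allele_freqs), stringsAsFactors = FALSE)
      codes[[bid]] <- en$allele_codes
      freqs[[bid]] <- en$allele_freqs
      midx[[bid]] <- map$marker_id[cols]
    }
  }
  if (dropped > 0)
    message(dropped, " trailing marker(s) dropped (incomplete blocks)")
  blocks <- do.call(rbind, block_rows)
  code_mat <- do.call(cbind, codes)
  dimnames(code_mat) <- list(line_ids(g), blocks$block_id)
  names(freqs) <- blocks$block_id
  names(midx) <- blocks$block_id
  structure(list(block_size = as.integer(L), blocks = blocks,
                 allele_codes = code_mat, allele_freqs = freqs,
                 marker_index = midx),
            class = "haplotype_block_set")
}

#' Enumerate haplotype alleles within one block
#'
#' Each distinct L-length homozygous dosage vector observed across lines
#' is one haplotype allele, numbered by order of first appearance in line
#' order. A fully inbred line carries two copies of a single allele, so
#' allele frequencies are carrier counts over the number of lines.
#'
#' @param block_dosages lines x L dosage matrix with entries in \{0, 2\}.
#' @return list: `allele_codes` (integer vector per line, 1..n_alleles),
#'   `allele_freqs` (numeric vector summing to 1).
#' @export
enumerate_alleles <- function(block_dosages) {
  block_dosages <- as.matrix(block_dosages)
  if (any(block_dosages == 1, na.rm = TRUE) || anyNA(block_dosages))
    stop("heterozygous or missing dosages in block: impute and resolve ",
         "residual heterozygotes (see impute_knn) before haplotyping")
  key <- apply(block_dosages, 1, paste, collapse = ",")
  codes <- match(key, unique(key))
  freqs <- as.vector(table(factor(codes, levels = seq_len(max(codes))))) /
    length(codes)
  names(freqs) <- seq_along(freqs)
  list(allele_codes = codes, allele_freqs = freqs)
}

#' Summarize a haplotype block set
#'
#' @param hbs a [build_blocks()] result.
#' @return list: `overall` (data.frame: block_size, n_blocks,
#'   max_alleles, mean_alleles, mean_span_cM — the span averaged within
#'   chromosomes then across chromosomes), `per_chromosome` (data.frame:
#'   chrom, n_blocks, max_alleles, mean_alleles, mean_span_cM).
#' @export
block_summary <- function(hbs) {
  b <- hbs$blocks
  span <- b$end_cM - b$start_cM
  per_chr <- do.call(rbind, lapply(split(seq_len(nrow(b)), b$chrom), function(i)
    data.frame(chrom = b$chrom[i[1]], n_blocks = length(i),
               max_alleles = max(b$n_alleles[i]),
               mean_alleles = mean(b$n_alleles[i]),
               mean_span_cM = mean(span[i]), stringsAsFactors = FALSE)))
  rownames(per_chr) <- NULL
  overall <- data.frame(block_size = hbs$block_size, n_blocks = nrow(b),
                        max_alleles = max(b$n_alleles),
                        mean_alleles = mean(b$n_alleles),
                        mean_span_cM = mean(per_chr$mean_span_cM))
  list(overall = overall, per_chromosome = per_chr)
}

#' @export
print.haplotype_block_set <- function(x, ...) {
  cat(sprintf("haplotype_block_set: %d blocks of %d markers, %d lines\n",
              nrow(x$blocks), x$block_size, nrow(x$allele_codes)))
  invisible(x)
}
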