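# Genotype and phenotype I/O, marker QC, LD-kNN imputation, map ordering.

#' Construct a genotype matrix object
#'
#' A light container for an inbred-panel dosage matrix: lines in rows,
#' markers in columns, entries counting copies of the A allele
#' (0, 1, 2 or NA for missing). The A allele is by convention the first
#' allele listed for the marker.
#'
#' @param dosages numeric matrix (lines x markers) with rownames (line ids)
#'   and colnames (marker ids); entries in \{0, 1, 2, NA\}.
#' @param alleles character matrix (markers x 2) of nucleotide codes, columns
#'   `A` and `B`; defaults to "A"/"B" placeholders.
#' @return an object of class `genotype_matrix` with fields `dosages` and
#'   `alleles`.
#' @export
genotype_matrix <- function(dosages, alleles = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(dosages))) stop("duplicate line ids")
  if (anyDuplicated(colnames(dosages))) stop("duplicate marker ids")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(alleles)) {
    alleles <- matrix(rep(c("A", "B"), each = ncol(dosages)), ncol = 2,
                      dimnames = list(colnames(dosages), c("A", "B")))
  } else {
    alleles <- as.matrix(alleles)
    if (nrow(alleles) != ncol(dosages)) stop("one allele pair per marker required")
    rownames(alleles) <- colnames(dosages)
    colnames(alleles) <- c("A", "B")
  }
  structure(list(dosages = dosages, alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Line identifiers of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector.
#' @export
line_ids <- function(g) rownames(g$dosages)

#' Marker identifiers of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector.
#' @export
marker_ids <- function(g) colnames(g$dosages)

iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a TASSEL-style HapMap genotype file
#'
#' Parses a tab-separated `hmp.txt` file (11 metadata columns — rs#,
#' alleles, chrom, pos, strand, assembly#, center, protLSID, assayLSID,
#' panelLSID, QCcode — then one genotype column per line). Genotype calls
#' may be single-letter (A/C/G/T homozygote, IUPAC ambiguity code for a
#' heterozygote, N missing) or two-letter diplotypes (AA, AT, NN).
#' Positions are taken as map positions (cM for consensus-map files).
#' Gzip-compressed files are read transparently.
#'
#' @param path path to the hmp.txt (optionally .gz) file.
#' @return list with elements `genotypes` (a [genotype_matrix]) and `map`
#'   (data.frame: marker_id, chrom, pos). Markers without a usable
#'   chromosome/position are absent from `map` and counted in the
#'   `n_unmapped` attribute of the map.
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = character(), colClasses = "character")
  required <- c("rs#", "alleles", "chrom", "pos")
  if (ncol(tab) < 12 || !all(required %in% names(tab)[1:4]))
    stop("malformed HapMap header: expected columns rs#, alleles, chrom, pos, ",
         "then 7 further metadata columns")
  meta <- tab[, 1:11]
  calls <- as.matrix(tab[, -(1:11), drop = FALSE])
  markers <- as.character(meta[["rs#"]])
  lines <- colnames(calls)
  allele_pairs <- strsplit(as.character(meta$alleles), "/", fixed = TRUE)
  bad <- lengths(allele_pairs) != 2
  if (any(bad)) stop("malformed alleles field for marker ", markers[which(bad)[1]])
  alleles <- do.call(rbind, allele_pairs)

  dos <- matrix(NA_real_, nrow = length(lines), ncol = length(markers),
                dimnames = list(lines, markers))
  for (j in seq_along(markers)) {
    a <- alleles[j, 1]; b <- alleles[j, 2]
    call_j <- toupper(calls[j, ])
    d <- rep(NA_real_, length(call_j))
    one <- nchar(call_j) == 1L
    d[one & call_j == a] <- 2
    d[one & call_j == b] <- 0
    het_code <- names(iupac_het)[match(paste0(sort(c(a, b)), collapse = ""),
                                       iupac_het)]
    if (length(het_code) == 1 && !is.na(het_code))
      d[one & call_j == het_code] <- 1
    d[one & call_j == "N"] <- NA
    two <- nchar(call_j) == 2L
    d[two & call_j == paste0(a, a)] <- 2
    d[two & call_j %in% c(paste0(a, b), paste0(b, a))] <- 1
    d[two & call_j == paste0(b, b)] <- 0
    d[two & call_j == "NN"] <- NA
    decoded <- !is.na(d) | call_j %in% c("N", "NN")
    if (!all(decoded)) {
      i <- which(!decoded)[1]
      stop(sprintf("undecodable genotype call '%s' at marker %s, line %s",
                   call_j[i], markers[j], lines[i]))
    }
    dos[, j] <- d
  }

  pos <- suppressWarnings(as.numeric(meta$pos))
  chrom <- as.character(meta$chrom)
  mapped <- is.finite(pos) & !is.na(chrom) & chrom != "" & chrom != "NA"
  map <- data.frame(marker_id = markers[mapped], chrom = chrom[mapped],
                    pos = pos[mapped], stringsAsFactors = FALSE)
  attr(map, "n_unmapped") <- sum(!mapped)
  list(genotypes = genotype_matrix(dos, alleles), map = map)
}

#' Write a genotype matrix as a HapMap file
#'
#' Inverse of [read_hapmap()]: homozygotes are written as single letters,
#' heterozygotes as the IUPAC ambiguity code, missing as N. Map positions
#' are written with 4 decimal places.
#'
#' @param g a [genotype_matrix].
#' @param map data.frame (marker_id, chrom, pos); markers absent from the
#'   map get chrom/pos `NA`.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(g, map, path) {
  if (nrow(g$dosages) == 0L) stop("no lines to write")
  markers <- marker_ids(g)
  idx <- match(markers, map$marker_id)
  chrom <- ifelse(is.na(idx), "NA", as.character(map$chrom[idx]))
  pos <- ifelse(is.na(idx), NA_real_, map$pos[idx])
  calls <- matrix("N", nrow = length(markers), ncol = nrow(g$dosages))
  for (j in seq_along(markers)) {
    a <- g$alleles[j, 1]; b <- g$alleles[j, 2]
    het <- names(iupac_het)[match(paste0(sort(c(a, b)), collapse = ""), iupac_het)]
    if (is.na(het)) het <- paste0(a, b)  # two-letter fallback for odd pairs
    d <- g$dosages[, j]
    calls[j, ] <- ifelse(is.na(d), "N",
                  ifelse(d == 2, a, ifelse(d == 0, b, het)))
  }
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              line_ids(g))
  body <- cbind(markers, paste(g$alleles[, 1], g$alleles[, 2], sep = "/"),
                chrom, ifelse(is.na(pos), "NA", sprintf("%.4f", pos)),
                "+", "NA", "NA", "NA", "NA", "NA", "NA", calls)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype/layout table
#'
#' @param path CSV with header `line_id,trial,row,col,<trait...>`.
#' @return data.frame with those columns.
#' @export
read_pheno <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "trial")
  if (!all(need %in% names(ph)))
    stop("phenotype table must contain columns line_id and trial")
  ph
}

#' Write a phenotype/layout table
#' @param pheno data.frame as returned by [read_pheno()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pheno <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter markers on minor allele frequency and missingness
#'
#' Removes markers whose minor-allele frequency (computed on non-missing
#' calls) is strictly below `maf_min` or whose missing fraction is strictly
#' above `miss_max`. Both statistics are evaluated on the raw input in a
#' single pass. Line order is preserved.
#'
#' @param g a [genotype_matrix].
#' @param maf_min minimum retained MAF, in \[0, 0.5\]; default 0.05.
#' @param miss_max maximum retained missing fraction, in \[0, 1\]; default 0.10.
#' @return filtered [genotype_matrix].
#' @export
filter_markers <- function(g, maf_min = 0.05, miss_max = 0.10) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (miss_max < 0 || miss_max > 1) stop("miss_max must lie in [0, 1]")
  d <- g$dosages
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0  # all-missing marker: MAF 0, removed whenever maf_min > 0
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & miss <= miss_max
  if (!any(keep)) stop("all markers removed by QC filters")
  genotype_matrix(d[, keep, drop = FALSE], g$alleles[keep, , drop = FALSE])
}

#' LD-based k-nearest-neighbour genotype imputation
#'
#' Fills each missing call using the LD-kNNi strategy: for the target
#' marker, the `l` markers most correlated with it (on pairwise-complete
#' dosages) define a local similarity space; lines with an observed call
#' at the marker are ranked by squared-difference distance to the target
#' line over those markers, and the `k` nearest vote with weight 1/(d+eps)
#' for their dosage class. The winning class is returned, with a
#' heterozygous winner resolved to whichever homozygote class carries more
#' vote weight (tie: the marker's major allele). Observed calls are never
#' altered.
#'
#' @param g a [genotype_matrix].
#' @param k number of neighbour lines (default 5).
#' @param l number of correlated markers defining the metric (default 30).
#' @return fully imputed [genotype_matrix] with homozygous (0/2) fills.
#' @export
impute_knn <- function(g, k = 5L, l = 30L) {
  if (k < 1 || l < 1) stop("k and l must be >= 1")
  d <- g$dosages
  if (nrow(d) < k + 1) stop("need at least k+1 lines")
  if (!anyNA(d)) return(g)
  all_missing <- colSums(!is.na(d)) == 0L
  if (any(all_missing))
    stop("marker missing in all lines: ", colnames(d)[which(all_missing)[1]])
  miss_cols <- which(colSums(is.na(d)) > 0L)
  for (j in miss_cols) {
    r <- suppressWarnings(stats::cor(d[, j], d[, -j, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    ord <- order(abs(r), decreasing = TRUE)
    panel <- setdiff(seq_len(ncol(d)), j)[ord[seq_len(min(l, length(ord)))]]
    obs_at_j <- which(!is.na(d[, j]))
    pj <- mean(d[obs_at_j, j]) / 2
    major <- if (pj >= 0.5) 2 else 0
    for (i in which(is.na(d[, j]))) {
      diff2 <- (d[obs_at_j, panel, drop = FALSE] -
                  rep(d[i, panel], each = length(obs_at_j)))^2
      dist_i <- rowMeans(diff2, na.rm = TRUE)
      dist_i[is.nan(dist_i)] <- max(dist_i, 1, na.rm = TRUE)  # no shared info
      nb <- obs_at_j[order(dist_i)[seq_len(min(k, length(obs_at_j)))]]
      w <- 1 / (sort(dist_i)[seq_along(nb)] + 1e-8)
      votes <- vapply(c(0, 1, 2), function(cl) sum(w[d[nb, j] == cl]), 0)
      win <- c(0, 1, 2)[which.max(votes)]
      if (win == 1) {
        win <- if (votes[1] > votes[3]) 0 else if (votes[3] > votes[1]) 2 else major
      }
      d[i, j] <- win
    }
  }
  genotype_matrix(d, g$alleles)
}

#' Order markers along the genetic map
#'
#' Sorts markers by (chromosome, cM position, marker id); markers absent
#' from the map are dropped with a message.
#'
#' @param g a [genotype_matrix].
#' @param map data.frame (marker_id, chrom, pos).
#' @return list with the reordered `genotypes` and the matching ordered
#'   `map` (rows align with marker columns).
#' @export
order_by_map <- function(g, map) {
  mk <- marker_ids(g)
  mapped <- mk[mk %in% map$marker_id]
  n_drop <- length(mk) - length(mapped)
  if (n_drop > 0)
    message(n_drop, " unmapped marker(s) dropped during map ordering")
  sub <- map[match(mapped, map$marker_id), ]
  ord <- order(sub$chrom, sub$pos, sub$marker_id)
  keep <- mapped[ord]
  list(genotypes = genotype_matrix(g$dosages[, keep, drop = FALSE],
                                   g$alleles[match(keep, mk), , drop = FALSE]),
       map = sub[ord, ])
}
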