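# cis instrument selection: window + MAF filter, greedy LD clumping,
# instrument strength.

#' Define a gene region
#' @param gene_id gene identifier.
#' @param chrom chromosome (character).
#' @param start,end 1-based inclusive coding-region bounds.
#' @return list of class `gene_region`.
#' @export
gene_region <- function(gene_id, chrom, start, end) {
  if (start > end) stop("gene_region: start > end")
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 start = start, end = end),
            class = "gene_region")
}

#' Select cis SNPs around a gene
#'
#' Retains SNPs on the gene's chromosome within `window_bp` of the gene body
#' (inclusive on both ends, anchored on gene start and end) with
#' MAF > `maf_min`. An empty result is returned (with a message attribute),
#' not an error.
#'
#' @param ss a [sumstats] object.
#' @param region a [gene_region()].
#' @param window_bp flanking window, default 1 Mb each side.
#' @param maf_min minor-allele-frequency floor, default 0.01.
#' @return filtered [sumstats].
#' @export
select_cis <- function(ss, region, window_bp = 1e6, maf_min = 0.01) {
  maf <- pmin(ss$EAF, 1 - ss$EAF)
  keep <- ss$CHR == region$chrom &
    ss$POS >= region$start - window_bp &
    ss$POS <= region$end + window_bp &
    maf > maf_min
  out <- .keep_sumstats(ss, keep)
  attr(out, "cis_empty") <- nrow(out) == 0
  out
}

#' Greedy LD clumping of associated SNPs
#'
#' Restricts to SNPs with `P < p_threshold`, then repeatedly takes the
#' smallest-p remaining SNP as an index and discards remaining SNPs within
#' `window_kb` of it whose squared LD with the index is `>= r2_threshold`.
#' Ties on p are broken by `(CHR, POS, SNP)` order. Index SNPs are returned
#' in selection order.
#'
#' @param ss a [sumstats] object.
#' @param ld an [ld_matrix()] covering all candidates.
#' @param p_threshold association threshold, default genome-wide 5e-8.
#' @param r2_threshold squared-correlation threshold, default 0.001.
#' @param window_kb clumping window in kb, default 10,000.
#' @return [sumstats] of index SNPs, in selection order.
#' @export
greedy_clump <- function(ss, ld, p_threshold = 5e-8, r2_threshold = 0.001,
                         window_kb = 10000) {
  cand <- which(ss$P < p_threshold)
  if (length(cand) == 0) return(.keep_sumstats(ss, integer(0)))
  sub <- as.data.frame(ss)[cand, , drop = FALSE]
  missing <- setdiff(sub$SNP, ld$snp_ids)
  if (length(missing) > 0) {
    stop("lookup error: SNP(s) missing from LD matrix: ",
         paste(missing, collapse = ", "))
  }
  r <- ld_subset(ld, sub$SNP)          # r2 is orientation-free
  ord <- order(sub$P, sub$CHR, sub$POS, sub$SNP)
  alive <- rep(TRUE, nrow(sub))
  picked <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    picked <- c(picked, i)
    near <- sub$CHR == sub$CHR[i] & abs(sub$POS - sub$POS[i]) <= window_kb * 1000
    kill <- alive & near & (r[i, ]^2 >= r2_threshold)
    alive[kill] <- FALSE
  }
  out <- .keep_sumstats(ss, cand[picked])
  # preserve selection order rather than positional sort
  attr(out, "selection_order") <- sub$SNP[picked]
  out
}

#' Instrument strength (approximate F-statistics)
#'
#' Per-instrument `F_j = (beta_exp_j / se_exp_j)^2` and their arithmetic
#' mean; sets with mean F below 10 are conventionally excluded as weak.
#'
#' @param pairs harmonized pairs (needs `beta_exp`, `se_exp`).
#' @return list with `f_per_snp`, `f_mean`, `f_min`.
#' @export
instrument_strength <- function(pairs) {
  if (nrow(pairs) == 0) stop("instrument_strength: empty instrument set")
  f <- (pairs$beta_exp / pairs$se_exp)^2
  list(f_per_snp = f, f_mean = mean(f), f_min = min(f))
}
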