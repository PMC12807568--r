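# GWAS summary-statistics containers, readers/writers, allele harmonization.

SUMSTATS_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

.valid_alleles <- function(a) {
  # single-base SNV alleles or explicit indel strings (ACGT runs of length > 1)
  grepl("^[ACGT]+$", a)
}

#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data frame with one row per variant and columns
#' `SNP`, `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N` and
#' optionally `N_CASES`, plus trait metadata carried as attributes.
#' Rows violating basic invariants (non-positive SE, allele frequency
#' outside (0,1), duplicated ids, indels, `EA == OA`) are dropped and
#' counted in `attr(x, "drop_log")`.
#'
#' @param df data frame with the canonical columns.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param sd_y trait standard deviation (quantitative traits), or `NULL`.
#' @param drop_indels drop alleles longer than one base (default `TRUE`).
#' @return A `sumstats` data frame sorted by `(CHR, POS)`.
#' @export
sumstats <- function(df, trait_name, trait_type = c("quantitative", "binary"),
                     sd_y = NULL, drop_indels = TRUE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("sumstats format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (!"N_CASES" %in% names(df)) df$N_CASES <- NA_real_
  df <- df[c(SUMSTATS_COLS, "N_CASES")]
  df$SNP <- as.character(df$SNP)
  df$CHR <- as.character(df$CHR)
  for (col in c("POS", "EAF", "BETA", "SE", "P", "N", "N_CASES")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$EA <- toupper(as.character(df$EA))
  df$OA <- toupper(as.character(df$OA))

  n0 <- nrow(df)
  drop_log <- c(bad_value = 0L, bad_allele = 0L, indel = 0L, duplicate = 0L)

  ok_val <- is.finite(df$POS) & df$POS >= 1 &
    is.finite(df$EAF) & df$EAF > 0 & df$EAF < 1 &
    is.finite(df$BETA) & is.finite(df$SE) & df$SE > 0 &
    is.finite(df$P) & df$P > 0 & df$P <= 1 &
    is.finite(df$N) & df$N > 0 &
    (is.na(df$N_CASES) | (df$N_CASES > 0 & df$N_CASES < df$N))
  ok_val[is.na(ok_val)] <- FALSE
  drop_log["bad_value"] <- sum(!ok_val)
  df <- df[ok_val, , drop = FALSE]

  ok_allele <- .valid_alleles(df$EA) & .valid_alleles(df$OA) & df$EA != df$OA
  drop_log["bad_allele"] <- sum(!ok_allele)
  df <- df[ok_allele, , drop = FALSE]

  if (drop_indels) {
    is_snv <- nchar(df$EA) == 1L & nchar(df$OA) == 1L
    drop_log["indel"] <- sum(!is_snv)
    df <- df[is_snv, , drop = FALSE]
  }

  dup <- duplicated(df$SNP) | duplicated(df$SNP, fromLast = TRUE)
  if (any(dup)) {
    drop_log["duplicate"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
  }

  df <- df[order(df$CHR, df$POS, df$SNP), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    class = c("sumstats", "data.frame"),
    trait_name = trait_name, trait_type = trait_type, sd_y = sd_y,
    drop_log = drop_log, n_input = n0
  )
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expects a header with columns `SNP CHR POS EA OA EAF BETA SE P N`
#' (`N_CASES` optional). Rows failing the `sumstats` invariants are dropped
#' and counted in the returned object's `drop_log` attribute.
#'
#' @inheritParams sumstats
#' @param path path to a TSV file.
#' @return A `sumstats` object.
#' @examples
#' demo <- system.file("extdata", "synthetic_protein_sumstats.tsv",
#'                     package = "netmr")
#' ss <- read_sumstats(demo, trait_name = "protein",
#'                     trait_type = "quantitative")
#' head(ss)
#' @export
read_sumstats <- function(path, trait_name, trait_type = c("quantitative", "binary"),
                          sd_y = NULL) {
  trait_type <- match.arg(trait_type)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  ss <- sumstats(df, trait_name = trait_name, trait_type = trait_type, sd_y = sd_y)
  if (nrow(ss) == 0) stop("empty-input error: no rows survive filtering in ", path)
  ss
}

#' Write summary statistics to TSV
#'
#' Numeric columns are written with enough precision for a 6-significant-digit
#' round trip.
#'
#' @param x a `sumstats` object.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)
  if (all(is.na(out$N_CASES))) out$N_CASES <- NULL
  out$POS <- format(out$POS, scientific = FALSE, trim = TRUE)
  for (col in intersect(c("EAF", "BETA", "SE", "P"), names(out))) {
    out[[col]] <- formatC(out[[col]], digits = 10, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: %s (%s), %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  dl <- attr(x, "drop_log")
  if (!is.null(dl) && sum(dl) > 0) {
    cat("  dropped:", paste(sprintf("%s=%d", names(dl), dl), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

.keep_sumstats <- function(x, idx) {
  at <- attributes(x)
  y <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(y) <- NULL
  structure(y,
    class = c("sumstats", "data.frame"),
    trait_name = at$trait_name, trait_type = at$trait_type, sd_y = at$sd_y,
    drop_log = at$drop_log, n_input = at$n_input
  )
}

# ---------------------------------------------------------------------------
# LD matrix

#' Construct a reference LD matrix
#'
#' Signed allelic correlations over a SNP panel; each SNP's orientation is
#' defined by its (effect, other) allele pair.
#'
#' @param r symmetric numeric matrix of correlations in \[-1, 1\].
#' @param snp_ids character vector of SNP ids (panel order).
#' @param ea,oa effect/other allele per SNP, defining the orientation of `r`.
#' @return An `ld_matrix` object (list with `r`, `snp_ids`, `ea`, `oa`).
#' @export
ld_matrix <- function(r, snp_ids, ea, oa) {
  r <- as.matrix(r)
  m <- length(snp_ids)
  stopifnot(nrow(r) == m, ncol(r) == m, length(ea) == m, length(oa) == m)
  if (anyDuplicated(snp_ids)) stop("ld_matrix: duplicated snp ids")
  if (max(abs(r - t(r))) > 1e-12) stop("ld_matrix: r not symmetric")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (any(abs(r) > 1 + 1e-8)) stop("ld_matrix: |r| > 1")
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(r = r, snp_ids = as.character(snp_ids),
                 ea = toupper(ea), oa = toupper(oa)),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Layout: first row and first column carry SNP ids; a sidecar
#' `<path>.alleles` TSV with columns `SNP`, `EA`, `OA` supplies orientations
#' (if absent, alleles default to A/G and orientation checks are skipped).
#'
#' @param path TSV matrix path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  r <- as.matrix(m)
  snp_ids <- rownames(r)
  allele_path <- paste0(path, ".alleles")
  if (file.exists(allele_path)) {
    al <- utils::read.delim(allele_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    al <- al[match(snp_ids, al$SNP), ]
    ea <- al$EA; oa <- al$OA
  } else {
    ea <- rep("A", length(snp_ids)); oa <- rep("G", length(snp_ids))
  }
  ld_matrix(r, snp_ids, ea, oa)
}

#' Write an LD matrix (and its allele sidecar) to TSV
#' @param ld an `ld_matrix`.
#' @param path output path; alleles go to `<path>.alleles`.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = ld$snp_ids,
                   formatC(ld$r, digits = 10, format = "g"),
                   check.names = FALSE)
  names(df) <- c("SNP", ld$snp_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(SNP = ld$snp_ids, EA = ld$ea, OA = ld$oa),
                     paste0(path, ".alleles"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract an LD submatrix oriented to a set of effect alleles
#'
#' Rows/columns are re-signed so that correlations refer to the requested
#' effect alleles; SNPs whose allele pair cannot be reconciled raise an error.
#'
#' @param ld an `ld_matrix`.
#' @param snp_ids SNPs to extract (must all be present).
#' @param ea,oa optional target orientation per SNP; default: panel orientation.
#' @return numeric correlation matrix with `snp_ids` dimnames.
#' @export
ld_subset <- function(ld, snp_ids, ea = NULL, oa = NULL) {
  idx <- match(snp_ids, ld$snp_ids)
  if (anyNA(idx)) {
    stop("lookup error: SNP(s) missing from LD matrix: ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  }
  r <- ld$r[idx, idx, drop = FALSE]
  if (!is.null(ea)) {
    sign_flip <- ifelse(ea == ld$ea[idx] & oa == ld$oa[idx], 1,
                 ifelse(ea == ld$oa[idx] & oa == ld$ea[idx], -1, NA_real_))
    if (anyNA(sign_flip)) {
      stop("lookup error: allele mismatch against LD panel for: ",
           paste(snp_ids[is.na(sign_flip)], collapse = ", "))
    }
    r <- r * tcrossprod(sign_flip)
  }
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

# ---------------------------------------------------------------------------
# Harmonization

.complement <- function(a) chartr("ACGT", "TGCA", a)
.is_palindromic <- function(ea, oa) .complement(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on SNP id and orients the outcome effects to the
#' exposure's effect allele. Swapped alleles flip the outcome beta sign and
#' replace EAF by 1 - EAF. Palindromic SNPs (A/T, C/G) are oriented by allele
#' frequency when both EAFs sit on the same side of 0.5 and
#' `min(eaf, 1 - eaf) < palindrome_eaf_limit`; otherwise they are dropped.
#' Irreconcilable allele pairs are dropped as mismatches.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param palindrome_eaf_limit frequency cutoff below which a palindromic SNP
#'   is considered unambiguous (default 0.42, the usual two-sample MR choice).
#' @return data frame of class `harmonized_pairs` with columns `SNP`, `CHR`,
#'   `POS`, `EA`, `OA`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `n_exp`, `n_out`, `action`. Dropped SNPs are retained with
#'   `action` `"dropped_palindromic"` / `"dropped_mismatch"`; use
#'   `kept_pairs()` for the surviving set.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop("empty-input error: harmonize requires non-empty tables")
  }
  common <- intersect(exposure$SNP, outcome$SNP)
  if (length(common) == 0) stop("empty-input error: no shared SNPs to harmonize")
  e <- as.data.frame(exposure)[match(common, exposure$SNP), ]
  o <- as.data.frame(outcome)[match(common, outcome$SNP), ]

  same <- o$EA == e$EA & o$OA == e$OA
  swapped <- o$EA == e$OA & o$OA == e$EA
  # strand-flipped representations of the same SNP
  flip_same <- .complement(o$EA) == e$EA & .complement(o$OA) == e$OA
  flip_swap <- .complement(o$EA) == e$OA & .complement(o$OA) == e$EA

  pal <- .is_palindromic(e$EA, e$OA)
  action <- rep("dropped_mismatch", length(common))
  beta_out <- o$BETA; eaf_out <- o$EAF

  keep_as_is <- !pal & (same | flip_same)
  need_flip <- !pal & (swapped | flip_swap)
  action[keep_as_is] <- "kept"
  action[need_flip] <- "flipped"
  beta_out[need_flip] <- -beta_out[need_flip]
  eaf_out[need_flip] <- 1 - eaf_out[need_flip]

  if (any(pal)) {
    # for palindromic SNPs allele labels cannot resolve strand; use EAF
    aligned_by_label <- same | flip_same
    ef <- e$EAF; of <- o$EAF
    of_eff <- ifelse(aligned_by_label, of, 1 - of)
    same_side <- (ef - 0.5) * (of_eff - 0.5) > 0
    unambiguous <- pmin(ef, 1 - ef) < palindrome_eaf_limit &
      pmin(of_eff, 1 - of_eff) < palindrome_eaf_limit
    ok <- pal & (same | swapped | flip_same | flip_swap) & same_side & unambiguous
    action[pal] <- "dropped_palindromic"
    action[ok] <- ifelse(aligned_by_label[ok], "kept", "flipped")
    beta_out[ok & !aligned_by_label] <- -o$BETA[ok & !aligned_by_label]
    eaf_out[ok & !aligned_by_label] <- 1 - o$EAF[ok & !aligned_by_label]
  }

  out <- data.frame(
    SNP = common, CHR = e$CHR, POS = e$POS, EA = e$EA, OA = e$OA,
    beta_exp = e$BETA, se_exp = e$SE, eaf_exp = e$EAF,
    beta_out = beta_out, se_out = o$SE, eaf_out = eaf_out,
    n_exp = e$N, n_out = o$N, action = action,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$CHR, out$POS, out$SNP), ]
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' Surviving harmonized pairs
#' @param pairs output of [harmonize()].
#' @return the rows with action `kept` or `flipped`.
#' @export
kept_pairs <- function(pairs) {
  out <- pairs[pairs$action %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
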