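# Two-sample MR estimators and sensitivity filters: Wald ratio, IVW with
# multiplicative overdispersion, Cochran's Q, Steiger directionality,
# bidirectional reverse-causality check, BH-FDR.

.mr_result <- function(beta, se, method, n_snps, binary = FALSE) {
  pval <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(beta = beta, se = se, pval = pval, method = method,
                 n_snps = n_snps,
                 odds_ratio = if (binary) exp(beta) else NA_real_),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s, %d SNP%s): beta = %.4g (se %.4g), p = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              x$beta, x$se, x$pval))
  if (is.finite(x$odds_ratio)) cat(sprintf("  OR = %.4g\n", x$odds_ratio))
  invisible(x)
}

.ratio_estimates <- function(pairs, second_order = FALSE) {
  if (any(pairs$beta_exp == 0)) stop("undefined-ratio error: beta_exp = 0")
  b <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  if (second_order) {
    se <- sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
               pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  }
  list(beta = b, se = se)
}

#' Wald ratio estimate from a single instrument
#'
#' Causal estimate `beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|` (the exposure-side uncertainty is ignored, as is
#' conventional for strong instruments; `second_order = TRUE` adds it).
#'
#' @param pair single harmonized pair (1-row data frame).
#' @param binary whether the outcome is binary (adds an odds ratio).
#' @param second_order include the exposure-side variance term.
#' @return `mr_result`.
#' @export
wald_ratio <- function(pair, binary = FALSE, second_order = FALSE) {
  stopifnot(nrow(pair) == 1)
  r <- .ratio_estimates(pair, second_order)
  .mr_result(r$beta, r$se, "wald", 1L, binary)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted mean of per-variant Wald ratios with weights `1/se_j^2`
#' (equivalently the slope of a `1/se_out^2`-weighted regression of outcome
#' betas on exposure betas through the origin). The variance is inflated by
#' a multiplicative overdispersion factor `phi = max(1, Q/(J-1))`, matching
#' the conventional multiplicative random-effects IVW.
#'
#' @param pairs harmonized pairs (>= 2 rows; one row dispatches to
#'   [wald_ratio()]).
#' @param binary whether the outcome is binary.
#' @param second_order use second-order ratio SEs.
#' @return `mr_result`.
#' @export
mr_ivw <- function(pairs, binary = FALSE, second_order = FALSE) {
  if (nrow(pairs) == 0) stop("mr_ivw: no instruments")
  if (nrow(pairs) == 1) return(wald_ratio(pairs, binary, second_order))
  r <- .ratio_estimates(pairs, second_order)
  w <- 1 / r$se^2
  beta <- sum(w * r$beta) / sum(w)
  q <- sum(w * (r$beta - beta)^2)
  phi <- max(1, q / (nrow(pairs) - 1))
  se <- sqrt(phi / sum(w))
  .mr_result(beta, se, "ivw", nrow(pairs), binary)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta_fixed)^2` against the fixed-effect IVW
#' estimate, with a chi-square upper tail on `J - 1` df. In the screening
#' pipeline the filter is applied only when more than 3 instruments are used.
#'
#' @param pairs harmonized pairs (>= 2 rows).
#' @param second_order use second-order ratio SEs.
#' @return list with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, second_order = FALSE) {
  if (nrow(pairs) < 2) stop("cochran_q: needs >= 2 instruments")
  r <- .ratio_estimates(pairs, second_order)
  w <- 1 / r$se^2
  beta_fixed <- sum(w * r$beta) / sum(w)
  q <- sum(w * (r$beta - beta_fixed)^2)
  df <- nrow(pairs) - 1
  list(q_stat = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome, using `r2 = sum z_j^2 / (z_j^2 + n - 2)` per trait. The p-value
#' comes from the difference of Fisher-transformed correlations with
#' variance `1/(n_exp - 3) + 1/(n_out - 3)`. For binary outcomes the same
#' observed-scale approximation is used (a documented limitation).
#'
#' @param pairs harmonized pairs.
#' @param n_exp,n_out trait sample sizes (default from the pairs).
#' @return list with `r2_exposure`, `r2_outcome`, `direction`, `pval`.
#' @export
steiger <- function(pairs, n_exp = NULL, n_out = NULL) {
  if (is.null(n_exp)) n_exp <- stats::median(pairs$n_exp)
  if (is.null(n_out)) n_out <- stats::median(pairs$n_out)
  if (n_exp <= 3 || n_out <= 3) stop("steiger: sample sizes must exceed 3")
  z_exp <- pairs$beta_exp / pairs$se_exp
  z_out <- pairs$beta_out / pairs$se_out
  r2_exp <- sum(z_exp^2 / (z_exp^2 + n_exp - 2))
  r2_out <- sum(z_out^2 / (z_out^2 + n_out - 2))
  r2_exp <- min(r2_exp, 1); r2_out <- min(r2_out, 1)
  zdiff <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(r2_exposure = r2_exp, r2_outcome = r2_out,
       direction = if (r2_exp > r2_out) "exposure_to_outcome" else "outcome_to_exposure",
       pval = 2 * stats::pnorm(-abs(zdiff)))
}

#' Bidirectional reverse-causality check
#'
#' Instruments the outcome trait with its genome-wide-significant clumped
#' SNPs outside the exposure's cis region and runs MR of outcome on
#' exposure. A nominally significant reverse estimate (p < `alpha`) flags
#' reverse causality; with no usable reverse instruments the check is
#' `"untestable"`.
#'
#' @param outcome_ss outcome [sumstats] (reverse-direction exposure).
#' @param exposure_ss exposure [sumstats] (reverse-direction outcome).
#' @param ld [ld_matrix()] covering the outcome's significant SNPs.
#' @param region the exposure's [gene_region()]; SNPs within
#'   `cis_window_bp` of it are excluded from the reverse instruments.
#' @param cis_window_bp exclusion window, default 1 Mb.
#' @param p_threshold instrument significance threshold, default 5e-8.
#' @param alpha reverse-significance level, default 0.05.
#' @return list with `flag` (`"ok"`, `"reverse_causal"`, `"untestable"`)
#'   and the reverse `mr_result` (or NULL).
#' @export
bidirectional_check <- function(outcome_ss, exposure_ss, ld, region,
                                cis_window_bp = 1e6, p_threshold = 5e-8,
                                alpha = 0.05) {
  in_cis <- outcome_ss$CHR == region$chrom &
    outcome_ss$POS >= region$start - cis_window_bp &
    outcome_ss$POS <= region$end + cis_window_bp
  trans <- .keep_sumstats(outcome_ss, !in_cis)
  if (nrow(trans) == 0 || !any(trans$P < p_threshold)) {
    return(list(flag = "untestable", reverse_mr = NULL))
  }
  iv <- greedy_clump(trans, ld, p_threshold = p_threshold)
  if (nrow(iv) == 0) return(list(flag = "untestable", reverse_mr = NULL))
  pairs <- tryCatch(kept_pairs(harmonize(iv, exposure_ss)),
                    error = function(e) NULL)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(flag = "untestable", reverse_mr = NULL))
  }
  rev_mr <- if (nrow(pairs) == 1) wald_ratio(pairs) else mr_ivw(pairs)
  list(flag = if (rev_mr$pval < alpha) "reverse_causal" else "ok",
       reverse_mr = rev_mr)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param pvals numeric vector in (0, 1].
#' @return adjusted vector in input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  n <- length(pvals)
  ord <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * pvals[ord]))
  adj[order(ord)]
}
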