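# Bayesian colocalization: Wakefield approximate Bayes factors, two-trait
# coloc, three-trait configuration enumeration, summary-statistic
# conditional analysis, and pairwise conditional colocalization (PWCoCo).

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; clamps tiny negative differences to -Inf
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# signed log-space sum: terms with log-magnitudes lx and signs s.
# Cancellation below relative 1e-12 is treated as a structural zero.
signed_logsum <- function(lx, s) {
  m <- max(lx[is.finite(lx)], -Inf)
  if (!is.finite(m)) return(list(log = -Inf, sign = 1))
  scaled <- exp(lx - m)
  tot <- sum(s * scaled)
  if (tot <= 1e-12 * sum(scaled)) {
    return(list(log = -Inf, sign = if (tot < 0) -1 else 1))
  }
  list(log = m + log(tot), sign = 1)
}

#' Wakefield log approximate Bayes factor
#'
#' For a per-SNP estimate with variance `V = se^2`, prior effect variance
#' `W = prior_sd^2` and `z = beta/se`:
#' `labf = 0.5 log(V/(V+W)) + 0.5 z^2 W/(V+W)`.
#'
#' @param beta,se per-SNP estimate and standard error.
#' @param prior_sd prior SD of the true effect. Defaults follow the usual
#'   coloc choices: `0.15 * sd_y` for quantitative traits, `0.2` on the
#'   log-odds scale for binary traits.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param sd_y trait SD (quantitative), used to scale the default prior.
#' @return numeric vector of log-ABFs.
#' @export
wakefield_labf <- function(beta, se, trait_type = "quantitative", sd_y = 1,
                           prior_sd = NULL) {
  if (any(se <= 0)) stop("wakefield_labf: se must be positive")
  if (is.null(prior_sd)) {
    prior_sd <- if (trait_type == "binary") 0.2 else 0.15 * (if (is.null(sd_y)) 1 else sd_y)
  }
  v <- se^2
  w <- prior_sd^2
  z <- beta / se
  0.5 * log(v / (v + w)) + 0.5 * z^2 * w / (v + w)
}

#' Build a per-SNP ABF vector from summary statistics
#'
#' Excludes low-frequency variants (MAF < `maf_min`) before computing ABFs,
#' mirroring standard colocalization practice.
#'
#' @param ss a [sumstats] object (or conditional equivalent with `BETA`,
#'   `SE`, `SNP`, `EAF` columns and trait attributes).
#' @param prior_sd optional prior effect SD override.
#' @param maf_min MAF exclusion threshold, default 0.01.
#' @return list of class `abf_vector` (`snp_ids`, `labf`, `v`, `w`, `z`).
#' @export
abf_vector <- function(ss, prior_sd = NULL, maf_min = 0.01) {
  maf <- pmin(ss$EAF, 1 - ss$EAF)
  keep <- maf >= maf_min
  ss2 <- ss[keep, , drop = FALSE]
  trait_type <- attr(ss, "trait_type") %||% "quantitative"
  sd_y <- attr(ss, "sd_y") %||% 1
  if (is.null(prior_sd)) {
    prior_sd <- if (trait_type == "binary") 0.2 else 0.15 * sd_y
  }
  labf <- wakefield_labf(ss2$BETA, ss2$SE, prior_sd = prior_sd)
  structure(list(snp_ids = ss2$SNP, labf = labf, v = ss2$SE^2,
                 w = prior_sd^2, z = ss2$BETA / ss2$SE),
            class = "abf_vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.align_abf <- function(abfs) {
  ids <- abfs[[1]]$snp_ids
  for (a in abfs[-1]) {
    if (length(a$snp_ids) != length(ids) || !setequal(a$snp_ids, ids)) {
      stop("alignment error: ABF vectors cover different SNP panels")
    }
  }
  lapply(abfs, function(a) a$labf[match(ids, a$snp_ids)])
}

#' Two-trait Bayesian colocalization
#'
#' Enumerates the five hypotheses (H0 no association; H1/H2 one trait only;
#' H3 both traits, distinct causal variants; H4 both traits, shared variant)
#' with per-SNP priors `p1`, `p2` (single-trait association) and `p12`
#' (shared association). All sums are computed in log space.
#'
#' @param trait1,trait2 `abf_vector`s on the same SNP panel.
#' @param p1,p2,p12 per-SNP priors (defaults 1e-4, 1e-4, 1e-5).
#' @return list of class `coloc_result`: `pp` (named H0..H4 vector),
#'   `priors`, `n_snps`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  p1 <- unname(p1); p2 <- unname(p2); p12 <- unname(p12)
  al <- .align_abf(list(trait1, trait2))
  l1 <- al[[1]]; l2 <- al[[2]]
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
    H4 = log(p12) + ls12
  )
  norm <- logsumexp(lh)
  structure(list(pp = exp(lh - norm), priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_snps = length(l1)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc posterior probabilities (", x$n_snps, " SNPs):\n", sep = "")
  print(round(x$pp, 4))
  invisible(x)
}

# the 15 three-trait configurations: blocks of traits sharing a causal SNP
MOLOC_CONFIGS <- list(
  null = list(),
  a = list("a"), b = list("b"), c = list("c"),
  ab = list(c("a", "b")), ac = list(c("a", "c")), bc = list(c("b", "c")),
  abc = list(c("a", "b", "c")),
  a.b = list("a", "b"), a.c = list("a", "c"), b.c = list("b", "c"),
  ab.c = list(c("a", "b"), "c"),
  ac.b = list(c("a", "c"), "b"),
  bc.a = list(c("b", "c"), "a"),
  a.b.c = list("a", "b", "c")
)

#' Three-trait multi-trait colocalization
#'
#' Enumerates all 15 configurations (partitions of each associated-trait
#' subset into blocks that share a causal variant, plus the global null).
#' Blocks of one, two or three traits carry per-SNP priors `p1`, `p2`, `p3`.
#' Evidence sums run over assignments of distinct SNPs to blocks and are
#' computed with inclusion-exclusion in log space.
#'
#' @param trait_a,trait_b,trait_c `abf_vector`s on the same SNP panel.
#' @param p1,p2,p3 per-SNP priors for one/two/three-trait blocks
#'   (defaults 1e-4, 1e-6, 1e-7).
#' @return list of class `moloc_result`: `pp` over the 15 configurations
#'   (named as e.g. `"ab.c"` = a,b share a variant, c has its own),
#'   `pp_abc` (the three-way-shared headline), `priors`, `n_snps`.
#' @export
moloc_abf <- function(trait_a, trait_b, trait_c,
                      p1 = 1e-4, p2 = 1e-6, p3 = 1e-7) {
  p1 <- unname(p1); p2 <- unname(p2); p3 <- unname(p3)
  al <- .align_abf(list(trait_a, trait_b, trait_c))
  labf <- list(a = al[[1]], b = al[[2]], c = al[[3]])
  m <- length(labf$a)
  block_labf <- function(traits) Reduce(`+`, labf[traits])
  # same-SNP sums for every non-empty trait subset
  subsets <- list("a", "b", "c", c("a", "b"), c("a", "c"), c("b", "c"),
                  c("a", "b", "c"))
  lS <- stats::setNames(
    vapply(subsets, function(s) logsumexp(block_labf(s)), numeric(1)),
    vapply(subsets, paste, character(1), collapse = "")
  )
  key <- function(s) paste(sort(s), collapse = "")
  lprior <- log(c(p1, p2, p3))

  config_logev <- function(blocks) {
    k <- length(blocks)
    pri <- sum(lprior[vapply(blocks, length, integer(1))])
    if (k == 0) return(0)
    if (k == 1) return(pri + lS[[key(blocks[[1]])]])
    if (k == 2) {
      b1 <- key(blocks[[1]]); b2 <- key(blocks[[2]])
      both <- key(unlist(blocks))
      return(pri + logdiffexp(lS[[b1]] + lS[[b2]], lS[[both]]))
    }
    # three singleton blocks: inclusion-exclusion over coincident SNPs
    terms_log <- c(lS[["a"]] + lS[["b"]] + lS[["c"]],
                   lS[["a"]] + lS[["bc"]],
                   lS[["b"]] + lS[["ac"]],
                   lS[["c"]] + lS[["ab"]],
                   log(2) + lS[["abc"]])
    terms_sign <- c(1, -1, -1, -1, 1)
    pri + signed_logsum(terms_log, terms_sign)$log
  }

  lh <- vapply(MOLOC_CONFIGS, config_logev, numeric(1))
  norm <- logsumexp(lh)
  pp <- exp(lh - norm)
  structure(list(pp = pp, pp_abc = unname(pp["abc"]),
                 priors = c(p1 = p1, p2 = p2, p3 = p3), n_snps = m),
            class = "moloc_result")
}

#' @export
print.moloc_result <- function(x, ...) {
  cat("moloc posterior probabilities (", x$n_snps, " SNPs):\n", sep = "")
  print(round(sort(x$pp, decreasing = TRUE), 4))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Summary-statistic conditional analysis (COJO-style approximation)

#' Conditional summary statistics given an index SNP set
#'
#' Approximates joint/conditional estimates from marginal betas plus a
#' reference LD matrix. Effects are moved to the standardized scale via
#' `b* = z / sqrt(n - 2 + z^2)`; joint index-set coefficients solve the
#' LD-scaled normal equations `R_SS b_J = b*_S`; each SNP's conditional
#' effect subtracts its LD projection onto the index set, with the residual
#' variance bounded below at zero. Conditioning a SNP on itself gives a
#' conditional z of exactly 0.
#'
#' @param ss a [sumstats] object for the region.
#' @param ld an [ld_matrix()] covering the region (signed, allele-aware).
#' @param index_set character vector of index SNP ids.
#' @param n sample size (default: median `N` in `ss`).
#' @param r2_collinear collinearity screen on the index set, default 0.9.
#' @return data frame of class `conditional_sumstats` with `SNP`,
#'   `beta_cond`, `se_cond`, `pval_cond`, `z_cond`, plus attributes
#'   `index_snps` and `joint` (joint coefficients of the index set,
#'   per-allele scale).
#' @export
conditional_sumstats <- function(ss, ld, index_set, n = NULL,
                                 r2_collinear = 0.9) {
  if (length(index_set) == 0) stop("conditional_sumstats: empty index set")
  if (is.null(n)) n <- stats::median(ss$N)
  if (!all(index_set %in% ss$SNP)) {
    stop("lookup error: index SNP(s) absent from sumstats: ",
         paste(setdiff(index_set, ss$SNP), collapse = ", "))
  }
  r <- ld_subset(ld, ss$SNP, ea = ss$EA, oa = ss$OA)
  idx <- match(index_set, ss$SNP)
  rss <- r[idx, idx, drop = FALSE]
  if (length(idx) > 1) {
    off <- which(rss^2 > r2_collinear & row(rss) < col(rss), arr.ind = TRUE)
    if (nrow(off) > 0) {
      stop("conditioning error: collinear index pair ",
           index_set[off[1, 1]], " / ", index_set[off[1, 2]],
           sprintf(" (r^2 = %.3f)", rss[off[1, , drop = FALSE]]^2))
    }
  }
  if (min(eigen(rss, symmetric = TRUE, only.values = TRUE)$values) <= 1e-6) {
    stop("conditioning error: index-set LD matrix is ill-conditioned")
  }
  z <- ss$BETA / ss$SE
  bstd <- z / sqrt(n - 2 + z^2)
  kscale <- ss$SE * sqrt(n - 2 + z^2)   # per-allele / standardized scale
  b_s <- bstd[idx]
  b_joint <- solve(rss, b_s)
  sigma2 <- max(1 - sum(b_s * b_joint), 0)
  proj <- drop(r[, idx, drop = FALSE] %*% b_joint)
  h <- rowSums((r[, idx, drop = FALSE] %*% solve(rss)) * r[, idx, drop = FALSE])
  h <- pmin(pmax(h, 0), 1)
  b_cond <- bstd - proj
  se_cond_std <- sqrt(pmax(sigma2 * (1 - h), 0) / n)
  is_index <- seq_along(z) %in% idx
  b_cond[is_index] <- 0
  z_cond <- ifelse(se_cond_std > 0, b_cond / se_cond_std, 0)
  z_cond[is_index] <- 0
  se_cond_std[is_index | se_cond_std == 0] <- 1 / sqrt(n)   # neutral scale
  out <- data.frame(
    SNP = ss$SNP, CHR = ss$CHR, POS = ss$POS, EA = ss$EA, OA = ss$OA,
    EAF = ss$EAF, N = ss$N,
    beta_cond = kscale * b_cond, se_cond = kscale * se_cond_std,
    z_cond = z_cond,
    pval_cond = 2 * stats::pnorm(-abs(z_cond)),
    stringsAsFactors = FALSE
  )
  # joint coefficients back on the per-allele scale
  joint <- data.frame(SNP = index_set, beta_joint = kscale[idx] * b_joint,
                      se_joint = kscale[idx] * sqrt(pmax(sigma2, 0) *
                        diag(solve(rss)) / n),
                      stringsAsFactors = FALSE)
  structure(out, class = c("conditional_sumstats", "data.frame"),
            index_snps = index_set, joint = joint, sigma2 = sigma2)
}

# repackage conditional estimates as a sumstats object usable by abf_vector
conditional_as_sumstats <- function(cond, template) {
  df <- data.frame(SNP = cond$SNP, CHR = cond$CHR, POS = cond$POS,
                   EA = cond$EA, OA = cond$OA, EAF = cond$EAF,
                   BETA = cond$beta_cond, SE = cond$se_cond,
                   P = pmax(cond$pval_cond, .Machine$double.xmin),
                   N = cond$N, stringsAsFactors = FALSE)
  sumstats(df, trait_name = attr(template, "trait_name"),
           trait_type = attr(template, "trait_type"),
           sd_y = attr(template, "sd_y"))
}

#' Stepwise forward selection of independent signals
#'
#' Adds the smallest-p SNP below `p_select` (marginal first, then
#' conditional on the running index set), skipping candidates collinear
#' (r^2 > `r2_collinear`) with any selected SNP, until no SNP qualifies.
#'
#' @inheritParams conditional_sumstats
#' @param p_select selection threshold, default 5e-8.
#' @param max_signals safety cap on selected signals.
#' @return character vector of selected SNP ids (possibly empty).
#' @export
forward_select <- function(ss, ld, p_select = 5e-8, n = NULL,
                           r2_collinear = 0.9, max_signals = 10) {
  if (is.null(n)) n <- stats::median(ss$N)
  selected <- character(0)
  r <- ld_subset(ld, ss$SNP, ea = ss$EA, oa = ss$OA)
  repeat {
    if (length(selected) == 0) {
      pv <- ss$P
    } else {
      cond <- conditional_sumstats(ss, ld, selected, n = n,
                                   r2_collinear = r2_collinear)
      pv <- cond$pval_cond
    }
    ok <- !(ss$SNP %in% selected)
    if (length(selected) > 0) {
      sel_idx <- match(selected, ss$SNP)
      rmax <- apply(r[, sel_idx, drop = FALSE]^2, 1, max)
      ok <- ok & rmax <= r2_collinear
    }
    pv[!ok] <- Inf
    if (min(pv) >= p_select || length(selected) >= max_signals) break
    selected <- c(selected, ss$SNP[which.min(pv)])
  }
  selected
}

#' Pairwise conditional colocalization (PWCoCo)
#'
#' Relaxes the single-causal-variant assumption: selects independent
#' signals per trait by stepwise conditional analysis, builds the marginal
#' dataset plus one dataset per signal (conditioned on all other selected
#' signals of that trait), and runs [coloc_abf()] on every cross-trait
#' dataset pair. With no secondary signals this reduces to marginal coloc.
#'
#' @param trait1_ss,trait2_ss region [sumstats] for the two traits.
#' @param ld shared [ld_matrix()].
#' @param n1,n2 sample sizes (defaults: median `N`).
#' @param p_select stepwise selection threshold, default 5e-8.
#' @param p1,p2,p12 coloc priors.
#' @return list of class `pwcoco_result`: `best` (the max-PP(H4)
#'   `coloc_result`), `best_pair` (dataset labels), `results` (data frame of
#'   all pairs with their H3/H4), `selected1`, `selected2`.
#' @export
pwcoco <- function(trait1_ss, trait2_ss, ld, n1 = NULL, n2 = NULL,
                   p_select = 5e-8, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  common <- intersect(trait1_ss$SNP, trait2_ss$SNP)
  t1 <- .keep_sumstats(trait1_ss, match(common, trait1_ss$SNP))
  t2 <- .keep_sumstats(trait2_ss, match(common, trait2_ss$SNP))
  if (is.null(n1)) n1 <- stats::median(t1$N)
  if (is.null(n2)) n2 <- stats::median(t2$N)

  sel1 <- forward_select(t1, ld, p_select = p_select, n = n1)
  sel2 <- forward_select(t2, ld, p_select = p_select, n = n2)

  datasets <- function(ss, selected, n) {
    ds <- list(marginal = ss)
    if (length(selected) >= 2) {
      for (s in selected) {
        others <- setdiff(selected, s)
        cond <- conditional_sumstats(ss, ld, others, n = n)
        ds[[paste0("cond_keep_", s)]] <- conditional_as_sumstats(cond, ss)
      }
    }
    ds
  }
  ds1 <- datasets(t1, sel1, n1)
  ds2 <- datasets(t2, sel2, n2)

  grid <- expand.grid(d1 = names(ds1), d2 = names(ds2),
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res[[i]] <- coloc_abf(abf_vector(ds1[[grid$d1[i]]]),
                          abf_vector(ds2[[grid$d2[i]]]),
                          p1 = p1, p2 = p2, p12 = p12)
  }
  tab <- data.frame(grid,
                    pp_h3 = vapply(res, function(x) x$pp["H3"], numeric(1)),
                    pp_h4 = vapply(res, function(x) x$pp["H4"], numeric(1)))
  best <- which.max(tab$pp_h4)
  structure(list(best = res[[best]],
                 best_pair = c(tab$d1[best], tab$d2[best]),
                 results = tab, all = res,
                 selected1 = sel1, selected2 = sel2),
            class = "pwcoco_result")
}

#' @export
print.pwcoco_result <- function(x, ...) {
  cat(sprintf("pwcoco: %d x %d dataset pairs; best PP(H4) = %.3f (%s vs %s)\n",
              length(unique(x$results$d1)), length(unique(x$results$d2)),
              x$best$pp["H4"], x$best_pair[1], x$best_pair[2]))
  invisible(x)
}

#' Flag gene-dense regions
#'
#' A region is gene-dense when its +/- `window` envelope overlaps that of
#' another gene on the same chromosome; such candidates are routed through
#' [pwcoco()] instead of marginal coloc.
#'
#' @param regions list of [gene_region()] objects.
#' @param window half-width of the envelope, default 500 kb.
#' @return named logical vector.
#' @export
gene_dense_regions <- function(regions, window = 5e5) {
  n <- length(regions)
  dense <- logical(n)
  if (n > 1) {
    for (i in seq_len(n)) {
      ri <- regions[[i]]
      for (j in seq_len(n)) {
        if (i == j) next
        rj <- regions[[j]]
        if (ri$chrom == rj$chrom &&
            ri$start - window <= rj$end + window &&
            rj$start - window <= ri$end + window) {
          dense[i] <- TRUE
          break
        }
      }
    }
  }
  stats::setNames(dense, names(regions) %||%
                    vapply(regions, function(r) r$gene_id, character(1)))
}
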