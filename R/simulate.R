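# Synthetic GWAS generator: LD-structured genotypes and a
# protein -> blood pressure -> CVD causal chain with known truth.

#' Simulation configuration for the protein -> BP -> CVD chain
#'
#' Defaults describe a plausible strong-instrument architecture: a protein
#' with three cis-acting variants, a 2 mmHg/SD effect of the protein on SBP,
#' an SBP liability effect of 0.04 log-odds/mmHg on a 10%-prevalence binary
#' outcome, and a direct protein effect sized so that half of the total
#' protein effect is mediated through blood pressure.
#'
#' @param m_snps number of cis SNPs in the protein region.
#' @param maf_range minor-allele-frequency range, within (0.01, 0.5].
#' @param ld_rho adjacent-SNP latent AR(1) correlation in \[0, 1).
#' @param n_protein,n_bp,n_cvd,n_ref cohort sizes (disjoint cohorts; the
#'   reference panel mirrors the 10,000-individual LD reference design).
#' @param causal_idx indices (1-based) of causal cis-pQTLs.
#' @param gamma per-causal-SNP effects on the protein, SD units per allele
#'   (on the standardized-genotype scale).
#' @param alpha protein -> SBP effect, mmHg per SD.
#' @param theta_bp SBP -> CVD liability effect, log-odds per mmHg.
#' @param theta_direct direct protein -> CVD effect, log-odds per SD.
#' @param prevalence CVD prevalence in (0, 1).
#' @param med_fraction fraction of the BP cohort on BP-lowering medication.
#' @param m_bp_snps number of trans BP-QTL SNPs (a separate region used to
#'   instrument BP for the mediator -> outcome step).
#' @param bp_causal_idx indices of causal BP SNPs within the BP region.
#' @param kappa per-causal BP SNP effects on SBP, mmHg per allele.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 60, maf_range = c(0.05, 0.5), ld_rho = 0.6,
                       n_protein = 20000, n_bp = 20000, n_cvd = 20000,
                       n_ref = 10000,
                       causal_idx = c(15, 30, 45),
                       gamma = c(0.30, 0.22, 0.15),
                       alpha = 2.0, theta_bp = 0.04, theta_direct = 0.08,
                       prevalence = 0.10, med_fraction = 0.23,
                       m_bp_snps = 30, bp_causal_idx = seq(2, 29, by = 3),
                       kappa = NULL, seed = 1L) {
  if (is.null(kappa)) kappa <- 1.2 * (-1)^(seq_along(bp_causal_idx))
  cfg <- list(m_snps = m_snps, maf_range = maf_range, ld_rho = ld_rho,
              n_protein = n_protein, n_bp = n_bp, n_cvd = n_cvd, n_ref = n_ref,
              causal_idx = causal_idx, gamma = gamma, alpha = alpha,
              theta_bp = theta_bp, theta_direct = theta_direct,
              prevalence = prevalence, med_fraction = med_fraction,
              m_bp_snps = m_bp_snps, bp_causal_idx = bp_causal_idx,
              kappa = kappa, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_protein, n_bp, n_cvd, n_ref) < 100)) {
      stop("parameter error: all cohort sizes must be >= 100")
    }
    if (maf_range[1] <= 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
      stop("parameter error: maf_range must lie within (0.01, 0.5]")
    }
    if (ld_rho < 0 || ld_rho >= 1) stop("parameter error: ld_rho must be in [0, 1)")
    if (any(causal_idx < 1) || any(causal_idx > m_snps)) {
      stop("parameter error: causal_idx outside [1, m_snps]")
    }
    if (length(gamma) != length(causal_idx)) {
      stop("parameter error: gamma and causal_idx lengths differ")
    }
    if (prevalence <= 0 || prevalence >= 1) {
      stop("parameter error: prevalence must be in (0, 1)")
    }
    if (m_bp_snps > 0 && (any(bp_causal_idx < 1) || any(bp_causal_idx > m_bp_snps))) {
      stop("parameter error: bp_causal_idx outside [1, m_bp_snps]")
    }
  })
  invisible(cfg)
}

#' Simulate LD-structured genotype dosages
#'
#' Two independent haplotypes per individual; each haplotype is a Gaussian
#' copula draw with AR(1) latent correlation `ld_rho`, thresholded at the
#' MAF quantile. Dosage is the haplotype sum.
#'
#' @param m_snps number of SNPs.
#' @param maf_range target MAF range; per-SNP targets drawn uniformly.
#' @param ld_rho latent AR(1) correlation between adjacent SNPs.
#' @param n individuals.
#' @param seed optional seed (set only when supplied).
#' @param mafs optional explicit target MAF vector overriding `maf_range`.
#' @return list with `geno` (n x m matrix in 0/1/2), `mafs` (targets),
#'   `mafs_emp` (realized frequencies).
#' @export
simulate_genotypes <- function(m_snps, maf_range = c(0.05, 0.5), ld_rho = 0,
                               n = 1000, seed = NULL, mafs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mafs)) {
    mafs <- stats::runif(m_snps, maf_range[1], maf_range[2])
  }
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("parameter error: target MAF outside (0, 0.5]")
  }
  thresh <- stats::qnorm(mafs)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m_snps), n, m_snps)
    if (ld_rho > 0 && m_snps > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (j in 2:m_snps) z[, j] <- ld_rho * z[, j - 1] + s * z[, j]
    }
    sweep(z, 2, thresh, "<") * 1L
  }
  geno <- hap() + hap()
  list(geno = geno, mafs = mafs, mafs_emp = colMeans(geno) / 2)
}

.snp_info <- function(m, chrom, pos_start = 1e6, spacing = 2000,
                      prefix = paste0("rs", chrom, "_"), pal_frac = 0.1) {
  non_pal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"))
  pal <- list(c("A", "T"), c("C", "G"))
  pick <- function(i) {
    if (stats::runif(1) < pal_frac) pal[[sample.int(2, 1)]]
    else non_pal[[sample.int(length(non_pal), 1)]]
  }
  al <- t(vapply(seq_len(m), pick, character(2)))
  data.frame(SNP = paste0(prefix, seq_len(m)), CHR = as.character(chrom),
             POS = pos_start + spacing * (seq_len(m) - 1),
             EA = al[, 1], OA = al[, 2], stringsAsFactors = FALSE)
}

#' Apply the blood-pressure medication adjustment
#'
#' Adds 15 mmHg to SBP and 10 mmHg to DBP for individuals on BP-lowering
#' medication, the standard correction applied before BP GWAS.
#'
#' @param sbp,dbp numeric vectors, mmHg.
#' @param on_med logical vector of the same length.
#' @return list with adjusted `sbp` and `dbp`.
#' @export
adjust_for_medication <- function(sbp, dbp, on_med) {
  if (length(sbp) != length(dbp) || length(sbp) != length(on_med)) {
    stop("shape error: sbp, dbp and on_med must have equal length")
  }
  list(sbp = sbp + 15 * as.numeric(on_med),
       dbp = dbp + 10 * as.numeric(on_med))
}

# standardize dosages by model MAF (consistent across cohorts)
.std_geno <- function(g, mafs) {
  sweep(sweep(g, 2, 2 * mafs, "-"), 2, sqrt(2 * mafs * (1 - mafs)), "/")
}

#' Simulate the full protein -> BP -> CVD chain
#'
#' Four mutually disjoint cohorts (protein, BP, CVD, LD reference) share one
#' genetic architecture: a cis region driving the protein and a separate
#' trans region of direct BP QTLs. The protein is the standardized-genotype
#' score plus noise scaled to unit variance; SBP is
#' `120 + alpha * protein + kappa' g_bp + N(0, 15)`; CVD liability adds
#' `theta_bp * (SBP - 120) + theta_direct * protein` to logistic noise with
#' the case threshold set to match the target prevalence. The BP cohort's
#' observed pressures are lowered by 15/10 mmHg for medicated individuals
#' and the GWAS phenotype is the medication-adjusted value.
#'
#' @param config a [sim_config()].
#' @return list with cohorts `protein`, `bp`, `cvd`, `ref` (each holding
#'   `geno`, phenotype vectors and `snp_info`), the pooled `snp_info`,
#'   `mafs`, an `ld` reference [ld_matrix()], the protein `region`
#'   ([gene_region()]), and `truth` (true beta1/beta2/beta_te/pm).
#' @export
simulate_chain <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  m_cis <- config$m_snps
  m_bp <- config$m_bp_snps
  maf_cis <- stats::runif(m_cis, config$maf_range[1], config$maf_range[2])
  maf_bp <- if (m_bp > 0) stats::runif(m_bp, config$maf_range[1], config$maf_range[2]) else numeric(0)
  info_cis <- .snp_info(m_cis, chrom = "1", pos_start = 1e6, prefix = "rs1_")
  info_bp <- if (m_bp > 0) .snp_info(m_bp, chrom = "2", pos_start = 5e7, prefix = "rs2_") else NULL
  snp_info <- rbind(info_cis, info_bp)
  mafs <- c(maf_cis, maf_bp)

  gamma_full <- numeric(m_cis)
  gamma_full[config$causal_idx] <- config$gamma
  kappa_full <- numeric(m_bp)
  if (m_bp > 0) kappa_full[config$bp_causal_idx] <- config$kappa

  draw_geno <- function(n) {
    g1 <- simulate_genotypes(m_cis, ld_rho = config$ld_rho, n = n, mafs = maf_cis)$geno
    g2 <- if (m_bp > 0) {
      simulate_genotypes(m_bp, ld_rho = config$ld_rho, n = n, mafs = maf_bp)$geno
    } else NULL
    cbind(g1, g2)
  }

  # reference panel first: supplies the genotype correlation used for scaling
  g_ref <- draw_geno(config$n_ref)
  poly <- apply(g_ref, 2, stats::var) > 0
  if (!all(poly)) stop("simulation error: monomorphic SNP in reference panel; increase n_ref")
  C_cis <- stats::cor(g_ref[, seq_len(m_cis), drop = FALSE])
  var_gen <- drop(t(gamma_full) %*% C_cis %*% gamma_full)
  if (var_gen >= 1) stop("parameter error: genetic variance of protein >= 1; shrink gamma")
  noise_sd <- sqrt(1 - var_gen)

  make_protein <- function(g) {
    zs <- .std_geno(g[, seq_len(m_cis), drop = FALSE], maf_cis)
    drop(zs %*% gamma_full) + stats::rnorm(nrow(g), 0, noise_sd)
  }
  make_sbp <- function(g, prot) {
    direct <- if (m_bp > 0) drop(g[, m_cis + seq_len(m_bp), drop = FALSE] %*% kappa_full) else 0
    120 + config$alpha * prot + direct + stats::rnorm(nrow(g), 0, 15)
  }

  # protein cohort
  g_p <- draw_geno(config$n_protein)
  prot_p <- make_protein(g_p)
  protein <- list(geno = g_p, phenotype = prot_p, trait_type = "quantitative",
                  trait_name = "protein", snp_info = snp_info, mafs = mafs)

  # BP cohort with medication masking of the measured values
  g_b <- draw_geno(config$n_bp)
  prot_b <- make_protein(g_b)
  sbp_true <- make_sbp(g_b, prot_b)
  dbp_true <- 80 + (config$alpha / 2) * prot_b + stats::rnorm(config$n_bp, 0, 10)
  on_med <- stats::runif(config$n_bp) < config$med_fraction
  sbp_obs <- sbp_true - 15 * on_med
  dbp_obs <- dbp_true - 10 * on_med
  adj <- adjust_for_medication(sbp_obs, dbp_obs, on_med)
  bp <- list(geno = g_b, phenotype = adj$sbp, protein = prot_b,
             sbp = adj$sbp, dbp = adj$dbp,
             sbp_observed = sbp_obs, dbp_observed = dbp_obs,
             on_medication = on_med, trait_type = "quantitative",
             trait_name = "SBP", snp_info = snp_info, mafs = mafs)

  # CVD cohort: logistic liability threshold matched to prevalence
  g_c <- draw_geno(config$n_cvd)
  prot_c <- make_protein(g_c)
  sbp_c <- make_sbp(g_c, prot_c)
  lin <- config$theta_bp * (sbp_c - 120) + config$theta_direct * prot_c
  liab <- lin + stats::rlogis(config$n_cvd)
  thr <- stats::quantile(liab, 1 - config$prevalence)
  y <- as.numeric(liab > thr)
  if (sum(y) == 0 || sum(y) == config$n_cvd) {
    stop("simulation error: prevalence infeasible at this cohort size")
  }
  cvd <- list(geno = g_c, phenotype = y, trait_type = "binary",
              trait_name = "CVD", snp_info = snp_info, mafs = mafs)

  ld <- ld_matrix(stats::cor(g_ref), snp_info$SNP, snp_info$EA, snp_info$OA)
  ref <- list(geno = g_ref, snp_info = snp_info, mafs = mafs)

  beta_te <- config$theta_bp * config$alpha + config$theta_direct
  truth <- list(
    beta1_true = config$alpha,
    beta2_true = config$theta_bp,
    beta_te_true = beta_te,
    pm_true = if (beta_te == 0) NA_real_ else config$theta_bp * config$alpha / beta_te,
    pm_defined = beta_te != 0
  )

  region <- gene_region("GENE1", chrom = "1",
                        start = stats::median(info_cis$POS) - 1e4,
                        end = stats::median(info_cis$POS) + 1e4)
  list(protein = protein, bp = bp, cvd = cvd, ref = ref, ld = ld,
       snp_info = snp_info, mafs = mafs, region = region, truth = truth,
       config = config)
}

# ---------------------------------------------------------------------------
# Per-SNP association testing

#' Compute GWAS summary statistics from an individual-level cohort
#'
#' Quantitative traits: per-SNP simple linear regression (slope, SE, t-based
#' two-sided p). Binary traits: per-SNP logistic regression via IRLS
#' (`glm.fit`), with a score-test fallback when the fit fails to converge or
#' separates. Monomorphic SNPs are dropped.
#'
#' @param cohort list with `geno`, `phenotype`, `snp_info`, `trait_name`,
#'   `trait_type` (as produced by [simulate_chain()]).
#' @param trait_type override of the cohort's trait type.
#' @param trait_name override of the cohort's trait name.
#' @return a [sumstats] object.
#' @export
compute_sumstats <- function(cohort, trait_type = cohort$trait_type,
                             trait_name = cohort$trait_name) {
  g <- cohort$geno
  y <- cohort$phenotype
  n <- length(y)
  if (stats::var(y) == 0) stop("degenerate-input error: constant phenotype")
  if (trait_type == "binary" && (sum(y) == 0 || sum(y) == n)) {
    stop("degenerate-input error: binary phenotype with a single class")
  }
  eaf <- colMeans(g) / 2
  poly <- eaf > 0 & eaf < 1
  g <- g[, poly, drop = FALSE]
  info <- cohort$snp_info[poly, , drop = FALSE]
  eaf <- eaf[poly]
  m <- ncol(g)

  if (trait_type == "quantitative") {
    gc <- sweep(g, 2, colMeans(g), "-")
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    sxy <- drop(crossprod(gc, yc))
    beta <- sxy / sxx
    sse <- sum(yc^2) - beta^2 * sxx
    sse[sse < 0] <- 0
    se <- sqrt(sse / ((n - 2) * sxx))
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    sd_y <- stats::sd(y)
    n_cases <- NA_real_
  } else {
    beta <- se <- numeric(m)
    ybar <- mean(y)
    for (j in seq_len(m)) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, g[, j]), y, family = stats::binomial())
      )
      b <- fit$coefficients[2]
      s <- tryCatch(sqrt(stats::chol2inv(fit$qr$qr[1:2, 1:2])[2, 2]),
                    error = function(e) NA_real_)
      if (!fit$converged || !is.finite(b) || !is.finite(s) || abs(b) > 20 || s > 100) {
        gj <- g[, j] - mean(g[, j])           # score-test fallback
        u <- sum(gj * (y - ybar))
        v <- ybar * (1 - ybar) * sum(gj^2)
        b <- u / v
        s <- 1 / sqrt(v)
      }
      beta[j] <- b
      se[j] <- s
    }
    p <- 2 * stats::pnorm(-abs(beta / se))
    sd_y <- NULL
    n_cases <- sum(y)
  }
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  df <- data.frame(SNP = info$SNP, CHR = info$CHR, POS = info$POS,
                   EA = info$EA, OA = info$OA, EAF = eaf,
                   BETA = beta, SE = se, P = p, N = n,
                   N_CASES = n_cases, stringsAsFactors = FALSE)
  sumstats(df, trait_name = trait_name, trait_type = trait_type, sd_y = sd_y)
}

# ---------------------------------------------------------------------------
# Summary-level region simulator (cheap replicates for calibration studies)

#' Simulate region summary statistics directly at the z-score level
#'
#' Draws the vector of marginal z-scores from `N(R %*% lambda, R)`, the
#' standard multivariate sampling model for GWAS z-scores in LD, where
#' `lambda[j]` is the non-centrality of causal SNP j (roughly
#' `beta_j * sqrt(n * var(g_j)) / sd_y`). Betas are reconstituted on the
#' per-allele scale via `se_j = 1 / sqrt(n * 2 f_j (1 - f_j))`.
#'
#' @param ld an [ld_matrix()] (or plain correlation matrix with dimnames).
#' @param lambda named or positional non-centrality vector (zeros for
#'   non-causal SNPs), length equal to the panel.
#' @param n GWAS sample size.
#' @param mafs per-SNP allele frequencies (defaults to 0.3).
#' @param trait_name,trait_type trait metadata.
#' @param snp_info optional SNP annotation (defaults to the LD panel ids on
#'   chromosome 1).
#' @return a [sumstats] object.
#' @export
simulate_region_sumstats <- function(ld, lambda, n, mafs = NULL,
                                     trait_name = "trait",
                                     trait_type = "quantitative",
                                     snp_info = NULL) {
  r <- if (inherits(ld, "ld_matrix")) ld$r else as.matrix(ld)
  m <- nrow(r)
  stopifnot(length(lambda) == m)
  if (is.null(mafs)) mafs <- rep(0.3, m)
  ch <- chol(r + 1e-10 * diag(m))
  z <- drop(r %*% lambda) + drop(crossprod(ch, stats::rnorm(m)))
  se <- 1 / sqrt(n * 2 * mafs * (1 - mafs))
  beta <- z * se
  p <- 2 * stats::pnorm(-abs(z))
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  if (is.null(snp_info)) {
    if (inherits(ld, "ld_matrix")) {
      snp_info <- data.frame(SNP = ld$snp_ids, CHR = "1",
                             POS = 1e6 + 2000 * (seq_len(m) - 1),
                             EA = ld$ea, OA = ld$oa, stringsAsFactors = FALSE)
    } else {
      snp_info <- .snp_info(m, chrom = "1", pal_frac = 0)
    }
  }
  df <- data.frame(SNP = snp_info$SNP, CHR = snp_info$CHR, POS = snp_info$POS,
                   EA = snp_info$EA, OA = snp_info$OA, EAF = mafs,
                   BETA = beta, SE = se, P = p, N = n, stringsAsFactors = FALSE)
  sumstats(df, trait_name = trait_name, trait_type = trait_type, sd_y = 1)
}

# ---------------------------------------------------------------------------
# Multi-protein screening panel

#' Simulate a multi-protein screening panel
#'
#' Builds `n_proteins` independent cis regions (one chromosome each), a trans
#' BP-QTL region, and three disjoint cohorts. Proteins listed in
#' `causal_proteins` affect SBP (effect `alpha`) and, through BP plus a
#' direct path, the binary CVD outcome; the rest are null. Used to validate
#' the screening funnel against known truth.
#'
#' @param n_proteins number of proteins.
#' @param causal_proteins indices of proteins with a true BP effect.
#' @param m_per_gene cis SNPs per protein region.
#' @param alpha protein -> SBP effect (mmHg per SD) for causal proteins.
#' @param theta_bp SBP -> CVD liability effect (log-odds per mmHg).
#' @param theta_direct direct protein -> CVD effect for causal proteins.
#' @param n_protein,n_bp,n_cvd,n_ref cohort sizes.
#' @param gamma per-region causal cis effects (recycled across proteins).
#' @param ld_rho,maf_range,prevalence,med_fraction as in [sim_config()].
#' @param seed integer seed.
#' @return list with `proteins` (named list of [sumstats]), `regions`
#'   (named list of [gene_region()]), `bp`, `dbp` and `cvd` sumstats, `ld`,
#'   and `truth` (per-protein truth table).
#' @export
simulate_screen_panel <- function(n_proteins = 20, causal_proteins = 1:5,
                                  m_per_gene = 30, alpha = 5.0,
                                  theta_bp = 0.05, theta_direct = 0.35,
                                  n_protein = 8000, n_bp = 12000,
                                  n_cvd = 20000, n_ref = 4000,
                                  gamma = c(0.30, 0.22, 0.15),
                                  ld_rho = 0.5, maf_range = c(0.05, 0.5),
                                  prevalence = 0.10, med_fraction = 0.23,
                                  seed = 1L) {
  set.seed(seed)
  m_bp <- 30
  bp_causal <- seq(2, 29, by = 3)
  kappa <- 1.5 * (-1)^seq_along(bp_causal)
  causal_snp_idx <- round(seq(5, m_per_gene - 4, length.out = length(gamma)))

  blocks <- vector("list", n_proteins + 1)
  infos <- vector("list", n_proteins + 1)
  for (p in seq_len(n_proteins)) {
    infos[[p]] <- .snp_info(m_per_gene, chrom = as.character(p),
                            pos_start = 1e6, prefix = sprintf("rs%d_", p))
    blocks[[p]] <- stats::runif(m_per_gene, maf_range[1], maf_range[2])
  }
  infos[[n_proteins + 1]] <- .snp_info(m_bp, chrom = "BP", pos_start = 1e6,
                                       prefix = "rsBP_")
  blocks[[n_proteins + 1]] <- stats::runif(m_bp, maf_range[1], maf_range[2])
  snp_info <- do.call(rbind, infos)
  mafs <- unlist(blocks)
  block_cols <- split(seq_len(nrow(snp_info)),
                      rep(seq_len(n_proteins + 1),
                          times = c(rep(m_per_gene, n_proteins), m_bp)))

  draw_geno <- function(n) {
    do.call(cbind, lapply(blocks, function(mf) {
      simulate_genotypes(length(mf), ld_rho = ld_rho, n = n, mafs = mf)$geno
    }))
  }

  g_ref <- draw_geno(n_ref)
  gamma_full <- numeric(m_per_gene)
  gamma_full[causal_snp_idx] <- gamma

  protein_values <- function(g) {
    vapply(seq_len(n_proteins), function(p) {
      cols <- block_cols[[p]]
      zs <- .std_geno(g[, cols, drop = FALSE], mafs[cols])
      C <- stats::cor(g_ref[, cols, drop = FALSE])
      vg <- drop(t(gamma_full) %*% C %*% gamma_full)
      drop(zs %*% gamma_full) + stats::rnorm(nrow(g), 0, sqrt(max(1 - vg, 0.05)))
    }, numeric(nrow(g)))
  }

  alpha_vec <- numeric(n_proteins)
  alpha_vec[causal_proteins] <- alpha
  theta_vec <- numeric(n_proteins)
  theta_vec[causal_proteins] <- theta_direct
  kappa_full <- numeric(m_bp)
  kappa_full[bp_causal] <- kappa
  bp_cols <- block_cols[[n_proteins + 1]]

  sbp_of <- function(g, prot) {
    120 + drop(prot %*% alpha_vec) + drop(g[, bp_cols, drop = FALSE] %*% kappa_full) +
      stats::rnorm(nrow(g), 0, 15)
  }

  # protein cohort
  g_p <- draw_geno(n_protein)
  prot_p <- protein_values(g_p)
  proteins <- stats::setNames(lapply(seq_len(n_proteins), function(p) {
    compute_sumstats(list(geno = g_p, phenotype = prot_p[, p],
                          snp_info = snp_info),
                     trait_type = "quantitative",
                     trait_name = sprintf("protein_%d", p))
  }), sprintf("protein_%d", p = seq_len(n_proteins)))

  # BP cohort (medication masking + adjustment, as in the single chain)
  g_b <- draw_geno(n_bp)
  prot_b <- protein_values(g_b)
  sbp_true <- sbp_of(g_b, prot_b)
  dbp_true <- 80 + drop(prot_b %*% (alpha_vec / 2)) + stats::rnorm(n_bp, 0, 10)
  on_med <- stats::runif(n_bp) < med_fraction
  adj <- adjust_for_medication(sbp_true - 15 * on_med, dbp_true - 10 * on_med, on_med)
  bp_ss <- compute_sumstats(list(geno = g_b, phenotype = adj$sbp,
                                 snp_info = snp_info),
                            trait_type = "quantitative", trait_name = "SBP")
  dbp_ss <- compute_sumstats(list(geno = g_b, phenotype = adj$dbp,
                                  snp_info = snp_info),
                             trait_type = "quantitative", trait_name = "DBP")

  # CVD cohort
  g_c <- draw_geno(n_cvd)
  prot_c <- protein_values(g_c)
  sbp_c <- sbp_of(g_c, prot_c)
  lin <- theta_bp * (sbp_c - 120) + drop(prot_c %*% theta_vec)
  liab <- lin + stats::rlogis(n_cvd)
  y <- as.numeric(liab > stats::quantile(liab, 1 - prevalence))
  cvd_ss <- compute_sumstats(list(geno = g_c, phenotype = y,
                                  snp_info = snp_info),
                             trait_type = "binary", trait_name = "CVD")

  ld <- ld_matrix(stats::cor(g_ref), snp_info$SNP, snp_info$EA, snp_info$OA)
  regions <- stats::setNames(lapply(seq_len(n_proteins), function(p) {
    center <- stats::median(infos[[p]]$POS)
    gene_region(sprintf("GENE_%d", p), chrom = as.character(p),
                start = center - 1e4, end = center + 1e4)
  }), sprintf("protein_%d", seq_len(n_proteins)))

  beta_te <- theta_bp * alpha + theta_direct
  truth <- data.frame(
    protein_id = sprintf("protein_%d", seq_len(n_proteins)),
    causal = seq_len(n_proteins) %in% causal_proteins,
    beta1_true = alpha_vec,
    beta_te_true = ifelse(seq_len(n_proteins) %in% causal_proteins, beta_te, 0),
    pm_true = ifelse(seq_len(n_proteins) %in% causal_proteins,
                     theta_bp * alpha / beta_te, NA_real_),
    stringsAsFactors = FALSE
  )
  list(proteins = proteins, regions = regions, bp = bp_ss, dbp = dbp_ss,
       cvd = cvd_ss, ld = ld, truth = truth, snp_info = snp_info)
}
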