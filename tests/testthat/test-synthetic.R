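test_that("genotype simulation is deterministic and respects target MAFs", {
  g1 <- simulate_genotypes(20, c(0.05, 0.5), ld_rho = 0.4, n = 500, seed = 9)
  g2 <- simulate_genotypes(20, c(0.05, 0.5), ld_rho = 0.4, n = 500, seed = 9)
  expect_identical(g1$geno, g2$geno)
  expect_true(all(g1$geno %in% 0:2))
  big <- simulate_genotypes(50, c(0.05, 0.5), ld_rho = 0.3, n = 10000, seed = 10)
  expect_true(all(abs(big$mafs_emp - big$mafs) < 0.02))
  expect_error(simulate_genotypes(5, n = 100, mafs = c(0.1, 0.2, 0.6, 0.1, 0.1)),
               "parameter error")
})

test_that("ld_rho = 0 gives independent SNPs; ld_rho > 0 induces decay", {
  g <- simulate_genotypes(10, c(0.2, 0.5), ld_rho = 0, n = 5000, seed = 12)$geno
  cc <- cor(g)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  g2 <- simulate_genotypes(10, c(0.2, 0.5), ld_rho = 0.8, n = 5000, seed = 13)$geno
  c2 <- cor(g2)
  adj <- mean(c2[cbind(1:9, 2:10)])
  expect_gt(adj, 0.3)
})

test_that("chain truth records follow the structural parameters", {
  base <- list(m_snps = 20, causal_idx = c(5, 10, 15),
               n_protein = 500, n_bp = 500, n_cvd = 500, n_ref = 300,
               m_bp_snps = 0, bp_causal_idx = integer(0), kappa = numeric(0))
  null_cfg <- do.call(sim_config, c(base, list(alpha = 0, theta_direct = 0, seed = 1)))
  sim0 <- simulate_chain(null_cfg)
  expect_equal(sim0$truth$beta_te_true, 0)
  expect_false(sim0$truth$pm_defined)
  expect_true(is.na(sim0$truth$pm_true))

  full <- do.call(sim_config, c(base, list(theta_direct = 0, seed = 2)))
  sim1 <- simulate_chain(full)
  expect_equal(sim1$truth$pm_true, 1)

  half <- do.call(sim_config, c(base, list(alpha = 2, theta_bp = 0.04,
                                           theta_direct = 0.08, seed = 3)))
  expect_equal(simulate_chain(half)$truth$pm_true, 0.5)
})

test_that("regressing simulated SBP on protein recovers alpha", {
  est <- replicate(20, {
    cfg <- sim_config(m_snps = 10, causal_idx = c(3, 6, 9),
                      gamma = c(0.3, 0.2, 0.15),
                      n_protein = 200, n_bp = 2000, n_cvd = 200, n_ref = 300,
                      m_bp_snps = 0, bp_causal_idx = integer(0),
                      kappa = numeric(0), alpha = 2,
                      seed = sample.int(1e6, 1))
    sim <- simulate_chain(cfg)
    # underlying SBP (pre-medication masking) regressed on the protein
    sbp <- sim$bp$sbp_observed + 15 * sim$bp$on_medication
    coef(lm(sbp ~ sim$bp$protein))[2]
  })
  expect_lt(abs(mean(est) - 2), 3 * sd(est) / sqrt(20))
})

test_that("medication adjustment adds exactly 15/10 mmHg where flagged", {
  out <- adjust_for_medication(130, 80, TRUE)
  expect_equal(out$sbp, 145)
  expect_equal(out$dbp, 90)
  sbp <- c(120, 130, 140); dbp <- c(70, 80, 90)
  none <- adjust_for_medication(sbp, dbp, rep(FALSE, 3))
  expect_identical(none$sbp, sbp)
  expect_identical(none$dbp, dbp)
  on <- c(TRUE, FALSE, TRUE)
  adj <- adjust_for_medication(sbp, dbp, on)
  expect_equal(mean(adj$sbp - sbp), 15 * mean(on))
  expect_error(adjust_for_medication(sbp, dbp[1:2], on), "shape error")
})

test_that("null SNP p-values are uniform and causal SNPs are recovered", {
  set.seed(21)
  g <- simulate_genotypes(500, c(0.1, 0.5), ld_rho = 0, n = 800)$geno
  info <- netmr:::.snp_info(500, chrom = "1", pal_frac = 0)
  y <- rnorm(800)
  ss <- compute_sumstats(list(geno = g, phenotype = y, snp_info = info),
                         trait_type = "quantitative", trait_name = "null")
  ks <- ks.test(ss$P, "punif")
  expect_gt(ks$p.value, 0.01)

  # causal SNP recovery at n = 10,000
  set.seed(22)
  sim <- simulate_genotypes(5, c(0.2, 0.4), ld_rho = 0, n = 10000)
  y2 <- 0.3 * sim$geno[, 3] + rnorm(10000)
  ss2 <- compute_sumstats(list(geno = sim$geno, phenotype = y2,
                               snp_info = netmr:::.snp_info(5, "1", pal_frac = 0)),
                          trait_type = "quantitative", trait_name = "q")
  expect_lt(abs(ss2$BETA[3] - 0.3), 3 * ss2$SE[3])

  # permuting the phenotype destroys associations
  ss3 <- compute_sumstats(list(geno = sim$geno, phenotype = sample(y2),
                               snp_info = netmr:::.snp_info(5, "1", pal_frac = 0)),
                          trait_type = "quantitative", trait_name = "perm")
  expect_gt(min(ss3$P), 1e-4)
})

test_that("binary GWAS recovers a log-odds effect and rejects degenerate input", {
  set.seed(23)
  g <- simulate_genotypes(4, c(0.3, 0.4), ld_rho = 0, n = 8000)$geno
  eta <- -2 + 0.4 * g[, 2]
  y <- rbinom(8000, 1, plogis(eta))
  cohort <- list(geno = g, phenotype = y,
                 snp_info = netmr:::.snp_info(4, "1", pal_frac = 0))
  ss <- compute_sumstats(cohort, trait_type = "binary", trait_name = "d")
  expect_lt(abs(ss$BETA[2] - 0.4), 3 * ss$SE[2])
  expect_equal(unique(ss$N_CASES), sum(y))
  cohort$phenotype <- rep(0, 8000)
  expect_error(compute_sumstats(cohort, trait_type = "binary"),
               "degenerate-input")
})

test_that("cis instruments recover alpha across replicates (parameter recovery)", {
  nrep <- 100
  est <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- sim_config(m_snps = 20, causal_idx = c(5, 11, 17),
                      gamma = c(0.3, 0.25, 0.2), alpha = 2,
                      n_protein = 2500, n_bp = 2500, n_cvd = 200, n_ref = 800,
                      m_bp_snps = 0, bp_causal_idx = integer(0),
                      kappa = numeric(0), seed = 1000 + r)
    sim <- simulate_chain(cfg)
    prot <- compute_sumstats(sim$protein)
    bp <- compute_sumstats(sim$bp)
    iv <- greedy_clump(select_cis(prot, sim$region), sim$ld)
    pairs <- if (nrow(iv) > 0) kept_pairs(harmonize(iv, bp)) else iv
    est[r] <- if (nrow(pairs) > 0) mr_ivw(pairs)$beta else NA_real_
  }
  est <- est[!is.na(est)]
  expect_gt(length(est), 90)
  expect_lt(abs(mean(est) - 2), 2 * sd(est) / sqrt(length(est)))
})

test_that("larger protein GWAS gives smaller IVW standard errors", {
  se_at <- function(n_protein, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(m_snps = 20, causal_idx = c(5, 11, 17),
                        gamma = c(0.25, 0.2, 0.15), alpha = 2,
                        n_protein = n_protein, n_bp = 3000, n_cvd = 200,
                        n_ref = 800, m_bp_snps = 0,
                        bp_causal_idx = integer(0), kappa = numeric(0),
                        seed = s)
      sim <- simulate_chain(cfg)
      prot <- compute_sumstats(sim$protein)
      bp <- compute_sumstats(sim$bp)
      iv <- greedy_clump(select_cis(prot, sim$region), sim$ld)
      if (nrow(iv) == 0) return(NA_real_)
      pairs <- kept_pairs(harmonize(iv, bp))
      if (nrow(pairs) == 0) return(NA_real_)
      mr_ivw(pairs)$se
    }, numeric(1))
  }
  seeds <- 300 + 1:12
  se_small <- se_at(600, seeds)
  se_large <- se_at(6000, seeds)
  expect_lt(median(se_large, na.rm = TRUE), median(se_small, na.rm = TRUE))
})
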