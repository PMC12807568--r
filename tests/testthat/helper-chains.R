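# Shared chain-level estimation used by the mediation acceptance tests:
# run the full summary-statistics route (cis MR for beta1 and beta_TE,
# trans-BP MR for beta2) on one simulated chain.

mediation_chain_config <- function(theta_direct, seed,
                                   alpha = 2, theta_bp = 0.04) {
  # strong-instrument regime: large cis-pQTL effects (top plasma pQTLs
  # explain tens of percent of protein variance) and a case-enriched CVD
  # GWAS (~25% cases, as in large CAD meta-analyses)
  # common variants only (MAF 0.2-0.5): near-threshold low-MAF instruments
  # would re-introduce winner's-curse attenuation of the selected effects
  sim_config(
    m_snps = 30, maf_range = c(0.2, 0.5),
    causal_idx = c(8, 16, 24), gamma = c(0.45, 0.35, 0.30),
    alpha = alpha, theta_bp = theta_bp, theta_direct = theta_direct,
    n_protein = 6000, n_bp = 8000, n_cvd = 20000, n_ref = 1000,
    m_bp_snps = 24, bp_causal_idx = seq(2, 23, by = 3),
    kappa = 4.0 * (-1)^(1:8), prevalence = 0.25, seed = seed
  )
}

estimate_mediation_once <- function(cfg) {
  sim <- simulate_chain(cfg)
  prot <- compute_sumstats(sim$protein)
  bp <- compute_sumstats(sim$bp)
  cvd <- compute_sumstats(sim$cvd)

  iv <- greedy_clump(select_cis(prot, sim$region), sim$ld)
  if (nrow(iv) == 0) return(NULL)
  p1 <- kept_pairs(harmonize(iv, bp))
  pte <- kept_pairs(harmonize(iv, cvd))
  if (nrow(p1) == 0 || nrow(pte) == 0) return(NULL)
  mr1 <- mr_ivw(p1)
  mrte <- mr_ivw(pte, binary = TRUE)

  trans <- netmr:::.keep_sumstats(bp, bp$CHR == "2")
  iv2 <- greedy_clump(trans, sim$ld)
  if (nrow(iv2) == 0) return(NULL)
  p2 <- kept_pairs(harmonize(iv2, cvd))
  if (nrow(p2) == 0) return(NULL)
  mr2 <- mr_ivw(p2, binary = TRUE)

  proportion_mediated(mr1$beta, mr1$se, mr2$beta, mr2$se, mrte$beta, mrte$se)
}
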