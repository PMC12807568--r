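test_that("Wald ratio arithmetic and edge cases", {
  p <- toy_pairs(0.5, 0.05, 0.25, 0.05)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(w$method, "wald")

  p0 <- toy_pairs(0.5, 0.05, 0, 0.05)
  w0 <- wald_ratio(p0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pval, 1)
  expect_error(wald_ratio(toy_pairs(0, 0.05, 0.1, 0.05)), "undefined-ratio")
  expect_equal(wald_ratio(p, binary = TRUE)$odds_ratio, exp(0.5))
})

test_that("first-order Wald SE matches a parametric bootstrap for strong instruments", {
  set.seed(41)
  be <- 0.5; se_e <- 0.02; bo <- 0.2; se_o <- 0.04   # |be|/se_e = 25
  boot <- (bo + rnorm(1e5, 0, se_o)) / (be + rnorm(1e5, 0, se_e))
  w <- wald_ratio(toy_pairs(be, se_e, bo, se_o))
  expect_lt(abs(w$se - sd(boot)) / sd(boot), 0.10)
})

test_that("IVW identities: equal weights, single-pair dispatch, weighted slope", {
  eq <- toy_pairs(c(1, 1), c(0.01, 0.01), c(0.2, 0.4), c(0.05, 0.05))
  expect_equal(mr_ivw(eq)$beta, 0.3)

  single <- toy_pairs(0.4, 0.03, 0.1, 0.02)
  expect_equal(mr_ivw(single)$beta, wald_ratio(single)$beta)
  expect_equal(mr_ivw(single)$method, "wald")

  set.seed(42)
  pairs <- toy_pairs(runif(8, 0.2, 0.6), runif(8, 0.01, 0.03),
                     rnorm(8, 0.1, 0.05), runif(8, 0.02, 0.06))
  fit <- lm(beta_out ~ 0 + beta_exp, data = pairs,
            weights = 1 / pairs$se_out^2)
  expect_equal(mr_ivw(pairs)$beta, unname(coef(fit)[1]), tolerance = 1e-10)
})

test_that("IVW is invariant to flipping every instrument's orientation", {
  set.seed(43)
  pairs <- toy_pairs(runif(6, 0.2, 0.6), runif(6, 0.01, 0.03),
                     rnorm(6, 0.1, 0.05), runif(6, 0.02, 0.06))
  flipped <- pairs
  flipped$beta_exp <- -pairs$beta_exp
  flipped$beta_out <- -pairs$beta_out
  expect_equal(mr_ivw(pairs)$beta, mr_ivw(flipped)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(pairs)$se, mr_ivw(flipped)$se, tolerance = 1e-12)
})

test_that("Cochran's Q: degenerate and hand-computed cases", {
  same <- toy_pairs(c(1, 1, 1), 0.01, c(0.3, 0.3, 0.3), 0.05)
  q0 <- cochran_q(same)
  expect_equal(q0$q_stat, 0, tolerance = 1e-20)
  expect_equal(q0$pval, 1)
  expect_equal(q0$df, 2)

  # ratios {0, 1} with unit weights: Q = 0.5
  q <- cochran_q(toy_pairs(c(1, 1), 0.01, c(0, 1), c(1, 1)))
  expect_equal(q$q_stat, 0.5)
})

test_that("Steiger direction and symmetry", {
  dom <- toy_pairs(10 * 0.01, 0.01, 1 * 0.01, 0.01)  # z_exp 10, z_out 1
  s <- steiger(dom, n_exp = 10000, n_out = 10000)
  expect_equal(s$direction, "exposure_to_outcome")
  expect_lt(s$pval, 1e-6)

  sym <- toy_pairs(0.05, 0.01, 0.05, 0.01)
  s2 <- steiger(sym, n_exp = 10000, n_out = 10000)
  expect_equal(s2$pval, 1)
  expect_error(steiger(sym, n_exp = 2, n_out = 10), "exceed 3")
})

test_that("Steiger gets the direction right on simulated chains", {
  nrep <- 100
  correct <- logical(nrep)
  fmeans <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- sim_config(m_snps = 20, causal_idx = c(5, 11, 17),
                      gamma = c(0.3, 0.25, 0.2), alpha = 2,
                      n_protein = 2000, n_bp = 2000, n_cvd = 200, n_ref = 600,
                      m_bp_snps = 0, bp_causal_idx = integer(0),
                      kappa = numeric(0), seed = 5000 + r)
    sim <- simulate_chain(cfg)
    prot <- compute_sumstats(sim$protein)
    bp <- compute_sumstats(sim$bp)
    iv <- greedy_clump(select_cis(prot, sim$region), sim$ld)
    pairs <- kept_pairs(harmonize(iv, bp))
    correct[r] <- steiger(pairs)$direction == "exposure_to_outcome"
    fmeans[r] <- instrument_strength(pairs)$f_mean
  }
  expect_gt(mean(fmeans), 30)
  expect_gte(mean(correct), 0.95)
})

test_that("bidirectional check flags true reverse paths and not forward-only ones", {
  # summary-level construction: trait A (instrumented by SNPs 1-20 in its
  # cis region) causally drives trait B; B has its own variants 21-40.
  set.seed(44)
  m <- 40
  ld <- ar1_ld(m, 0.3)
  region_a <- gene_region("A", "1", 1e6, 1e6 + 2000 * 19)
  region_b <- gene_region("B", "1", 1e6 + 2000 * 20, 1e6 + 2000 * 39)
  flags_fwd <- flags_rev <- character(60)
  for (r in 1:60) {
    lam_a <- c(rep(8, 20), rep(0, 20))
    a <- simulate_region_sumstats(ld, lam_a, n = 20000, trait_name = "A")
    # B inherits A's signals (scaled) and adds its own block
    lam_b <- 0.5 * lam_a + c(rep(0, 20), rep(8, 20))
    b <- simulate_region_sumstats(ld, lam_b, n = 20000, trait_name = "B")
    flags_fwd[r] <- bidirectional_check(b, a, ld, region_a,
                                        cis_window_bp = 0)$flag
    flags_rev[r] <- bidirectional_check(a, b, ld, region_b,
                                        cis_window_bp = 0)$flag
  }
  expect_lte(mean(flags_fwd == "reverse_causal"), 0.10)
  expect_gt(mean(flags_rev == "reverse_causal"), 0.90)

  # zero significant SNPs -> untestable
  null_b <- simulate_region_sumstats(ld, rep(0, m), n = 1000, trait_name = "B")
  a1 <- simulate_region_sumstats(ld, c(rep(8, 20), rep(0, 20)), n = 20000)
  expect_equal(bidirectional_check(null_b, a1, ld, region_a)$flag, "untestable")
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(45)
  for (r in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})
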