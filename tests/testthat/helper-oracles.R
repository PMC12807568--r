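# Independent oracle implementations and small fixture builders.
# These deliberately use brute-force enumeration / textbook formulas and
# share no code with the package internals they check.

# -- fixtures ---------------------------------------------------------------

ar1_ld <- function(m, rho, ids = paste0("s", seq_len(m))) {
  r <- outer(seq_len(m), seq_len(m), function(i, j) rho^abs(i - j))
  ld_matrix(r, ids, rep("A", m), rep("G", m))
}

toy_sumstats_df <- function(m, chrom = "1", pos0 = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(m)
  se <- runif(m, 0.01, 0.1)
  data.frame(
    SNP = paste0("s", seq_len(m)), CHR = chrom,
    POS = pos0 + 2000 * (seq_len(m) - 1),
    EA = rep(c("A", "C", "G", "T"), length.out = m),
    OA = rep(c("G", "A", "T", "C"), length.out = m),
    EAF = runif(m, 0.05, 0.95), BETA = z * se, SE = se,
    P = 2 * pnorm(-abs(z)), N = 10000, stringsAsFactors = FALSE
  )
}

make_abf <- function(labf, ids = paste0("s", seq_along(labf))) {
  structure(list(snp_ids = ids, labf = labf, v = rep(1, length(labf)),
                 w = 0.04, z = rep(0, length(labf))), class = "abf_vector")
}

toy_pairs <- function(beta_exp, se_exp, beta_out, se_out) {
  data.frame(SNP = paste0("s", seq_along(beta_exp)),
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             n_exp = 10000, n_out = 10000,
             action = "kept", stringsAsFactors = FALSE)
}

# -- oracles ----------------------------------------------------------------

# textbook step-up BH: sort, adjust p_(i) * n / i, enforce monotonicity by
# an explicit backward loop
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Wakefield ABF by numerical integration of the likelihood ratio over the
# effect prior
oracle_abf_quadrature <- function(beta_hat, v, w) {
  num <- integrate(function(b) dnorm(beta_hat, b, sqrt(v)) * dnorm(b, 0, sqrt(w)),
                   -Inf, Inf, rel.tol = 1e-10)$value
  den <- dnorm(beta_hat, 0, sqrt(v))
  num / den
}

# exhaustive two-trait colocalization over causal-variant assignments
oracle_coloc_enum <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  m <- length(bf1)
  h0 <- 1
  h1 <- sum(p1 * bf1)
  h2 <- sum(p2 * bf2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + p1 * p2 * bf1[i] * bf2[j]
  }
  h4 <- sum(p12 * bf1 * bf2)
  ev <- c(H0 = h0, H1 = h1, H2 = h2, H3 = h3, H4 = h4)
  ev / sum(ev)
}

# exhaustive three-trait enumeration over all 15 configurations and all
# assignments of distinct SNPs to causal blocks
oracle_moloc_enum <- function(labf_a, labf_b, labf_c,
                              p1 = 1e-4, p2 = 1e-6, p3 = 1e-7) {
  bf <- list(a = exp(labf_a), b = exp(labf_b), c = exp(labf_c))
  m <- length(bf$a)
  pri <- c(p1, p2, p3)
  configs <- netmr:::MOLOC_CONFIGS
  block_bf <- function(traits, i) prod(vapply(traits, function(t) bf[[t]][i], 1))
  ev <- vapply(configs, function(blocks) {
    k <- length(blocks)
    if (k == 0) return(1)
    prior <- prod(pri[vapply(blocks, length, integer(1))])
    tot <- 0
    idx <- as.matrix(expand.grid(rep(list(seq_len(m)), k)))
    for (r in seq_len(nrow(idx))) {
      snps <- idx[r, ]
      if (anyDuplicated(snps)) next
      tot <- tot + prod(vapply(seq_len(k), function(b)
        block_bf(blocks[[b]], snps[b]), 1))
    }
    prior * tot
  }, numeric(1))
  ev / sum(ev)
}

# straightforward re-implementation of greedy clumping
oracle_clump <- function(df, rmat, p_threshold = 5e-8, r2_threshold = 0.001,
                         window_kb = 10000) {
  df <- df[df$P < p_threshold, , drop = FALSE]
  kept <- character(0)
  while (nrow(df) > 0) {
    i <- order(df$P, df$CHR, df$POS, df$SNP)[1]
    idx <- df$SNP[i]
    kept <- c(kept, idx)
    drop <- df$CHR == df$CHR[i] &
      abs(df$POS - df$POS[i]) <= window_kb * 1000 &
      rmat[idx, df$SNP]^2 >= r2_threshold
    drop[i] <- TRUE
    df <- df[!drop, , drop = FALSE]
  }
  kept
}
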