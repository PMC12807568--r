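---
title: "netmr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netmr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plasma proteins are attractive intervention targets for hypertension and
cardiovascular disease, but observational protein–disease associations are
confounded. `netmr` implements the summary-statistics workflow used to
triangulate causal protein effects: *cis*-pQTL Mendelian randomization
(MR) of each protein on blood pressure (BP) and on cardiovascular
outcomes, Bayesian colocalization to exclude LD confounding, and network
(two-step) MR to estimate how much of a protein's disease effect is
mediated by BP. A synthetic-data module generates the whole causal chain
with known truth so that every stage of the pipeline can be validated
quantitatively.

## Data model

Summary statistics are plain data frames (`sumstats`) with columns
`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N[, N_CASES]` and trait metadata
in attributes; effects are per copy of the effect allele (mmHg for BP, SD
units for proteins, log-odds for binary outcomes). Invariants (SE > 0,
EAF in (0,1), biallelic SNVs, unique ids) are enforced at construction;
violating rows are dropped and counted, never silently altered. The LD
reference (`ld_matrix`) stores signed allelic correlations with the
allele pair that defines each SNP's orientation, so downstream code can
re-sign r for any requested orientation (`ld_subset()`).

### Harmonization

Outcome effects are oriented to the exposure's effect allele: swapped
alleles negate the beta and reflect the frequency; strand-flipped
representations (complement pairs) are recognized. Palindromic SNPs (A/T,
C/G) carry no strand information in their labels, so they are oriented by
allele frequency when both EAFs are on the same side of 0.5 and
informative (`min(eaf, 1-eaf) < 0.42`), and dropped otherwise. The 0.42
default mirrors common two-sample-MR practice and is configurable; it is
a convention, not an estimate.

## Instrument selection

`select_cis()` keeps SNPs within ±1 Mb of the gene body (inclusive at
both bounds, anchored on gene start *and* end rather than the TSS) with
MAF > 0.01. `greedy_clump()` keeps P < 5e-8 candidates and repeatedly
takes the smallest-p survivor as an index, discarding SNPs within
10,000 kb at r² ≥ 0.001; ties break deterministically on
`(CHR, POS, SNP)`. Clumping runs on the exposure before harmonization
(the instrument count is re-checked afterwards). Instrument strength is
the per-SNP F ≈ (β/σ)²; the weak-instrument filter uses the mean across
instruments by default (`f_rule = "min"` is available — the conventional
wording does not distinguish the two).

## MR estimators and sensitivity battery

* Wald ratio: `beta_out/beta_exp`, first-order SE `se_out/|beta_exp|`.
  The exposure-side variance term is available (`second_order = TRUE`)
  but off by default, matching the standard toolchain at F ≫ 10.
* IVW: 1/SE²-weighted mean of ratios, identical to the origin-constrained
  weighted regression slope. The variance is `phi / sum(w)` with
  `phi = max(1, Q/(J-1))`: multiplicative random effects that can widen
  but never shrink the fixed-effect SE. A deliberate consequence is that
  the IVW test is mildly conservative under the null (rejection ≈ 3.8% at
  the 5% level for J = 10), because `phi` is floored at 1; we keep this
  behaviour since it reproduces the conventional estimator exactly.
* Cochran's Q against the fixed-effect estimate, chi-square on J−1 df;
  the screening pipeline applies the Q > 0.05 filter only when more than
  3 instruments are used.
* Steiger directionality: per-trait `r² = Σ z²/(z² + n − 2)`, direction
  by comparison, p from the difference of Fisher-transformed
  correlations. For binary outcomes the same observed-scale
  approximation is used; liability-scale conversion is out of scope and
  a known limitation.
* Bidirectional MR: the outcome's genome-wide-significant clumped SNPs
  outside the exposure's cis window instrument the reverse direction; a
  nominal p < 0.05 reverse estimate flags reverse causality, and absence
  of usable reverse instruments yields `"untestable"` rather than a
  flag. Because the threshold is nominal, roughly one in twenty truly
  forward-only relationships will be flagged by chance; interpret
  single-candidate exclusions accordingly.

BH-FDR is applied across proteins within each outcome trait by default;
a pooled family is available because the analysis-level FDR family is a
genuine judgment call.

## Colocalization

Per-SNP evidence is the Wakefield log-ABF
`0.5 log(V/(V+W)) + 0.5 z² W/(V+W)` with prior effect SD `0.15·sd_y`
(quantitative) or 0.2 log-odds (binary) — the cited software's defaults.
Low-frequency variants (MAF < 0.01) are excluded before ABFs are formed.

Two-trait posteriors use per-SNP priors p1 = p2 = 1e-4, p12 = 1e-5; the
three-trait enumeration covers all 15 configurations (partitions of the
associated-trait subset into blocks sharing one causal variant) with
block priors p1/p2/p3 = 1e-4/1e-6/1e-7 by block size. All sums are
log-space (`logsumexp`); products of sums minus coincident terms use
`logdiffexp` and a signed log-sum with cancellation below relative 1e-12
treated as a structural zero (exactly the single-SNP case, where
configurations needing two distinct variants are impossible). Raw
exponentials of log-ABFs are never formed — they overflow near |z| ≈ 40.

Decision thresholds wired into the pipeline: PP ≥ 70% strong evidence
(two- and three-trait), PP > 50% suggestive (three-trait only).

### Conditional analysis and PWCoCo

Multi-signal regions violate coloc's single-causal-variant assumption.
`conditional_sumstats()` implements the standard summary-statistic
approximation: z-scores move to the standardized scale via
`b* = z/sqrt(n − 2 + z²)`, joint index-set coefficients solve
`R_SS b_J = b*_S`, and each SNP's conditional effect subtracts its LD
projection onto the index set, with residual variance `1 − b*_S' b_J`
floored at zero and the SE from the same linear algebra. Conditioning a
SNP on itself gives conditional z = 0 by construction. Index sets with
pairwise r² > 0.9 are refused (naming the collinear pair), and the
index-set LD matrix must have minimum eigenvalue > 1e-6. The conditional
estimate is the projection residual (not divided by 1 − h), matching the
conventional summary-statistic conditional framework; against a joint
individual-level regression this is accurate when index and target SNPs
are not strongly correlated, which the collinearity screen enforces.

`pwcoco()` selects independent signals per trait by stepwise forward
selection (add the smallest conditional p < 5e-8, re-condition, stop),
builds the marginal dataset plus one dataset per signal conditioned on
the trait's other signals, colocalizes every cross-trait pair, and
reports the best PP(H4) pair with the full matrix. With at most one
signal per trait it reduces exactly to marginal coloc. Gene-dense
candidates — a ±500 kb envelope overlapping another gene's — are routed
through PWCoCo automatically in the pipeline.

## Network-MR mediation

`proportion_mediated()` combines β₁ (protein→BP), β₂ (BP→CVD) and βTE
(protein→CVD): `pm = β₁β₂/βTE`, with the first-order delta-method
variance treating the three estimates as independent — justified by the
three non-overlapping GWAS cohorts; covariance terms are omitted by
design. The raw pm is reported untruncated alongside a [0,1]-capped
display value (published tables cap at 100%), and mediation is only
interpreted when sign(β₁β₂) = sign(βTE) (consistency check).

β₂'s instruments are BP's genome-wide clumped SNPs *excluding the cis
windows of every screened protein*, not just the protein under test. In
a desk-scale synthetic panel most genome-wide BP loci are protein-driven
and carry direct outcome paths, so per-protein exclusion leaves β₂
contaminated by horizontal pleiotropy (we measured ≈2-fold inflation of
pm before adopting the stricter rule); at biobank scale, where BP loci
number in the hundreds, the two rules coincide in practice.

## The synthetic world

`simulate_chain()` draws four mutually disjoint cohorts (protein GWAS,
BP GWAS, CVD GWAS, LD reference — disjointness enforces the two-sample
assumption) from one architecture:

* Genotypes: two haplotypes per individual from a Gaussian copula with
  AR(1) latent correlation `ld_rho` (default 0.6), thresholded at the MAF
  quantile. This yields realistic-looking local LD decay but is *not* a
  human LD map; clumping behaviour maps onto it only qualitatively.
* Protein: sum of standardized causal-genotype effects (`gamma`, default
  0.30/0.22/0.15 at three cis SNPs) plus noise scaled so Var = 1; the
  genetic variance uses the reference panel's realized genotype
  correlation so all cohorts share one architecture.
* SBP: `120 + alpha·protein + kappa' g_bp + N(0, 15)` mmHg, with a
  separate trans region of direct BP QTLs used to instrument BP in the
  mediation step. Measured pressures are lowered by 15/10 mmHg for the
  medicated fraction (default 23%, the UKB treated share) and
  `adjust_for_medication()` restores them before association testing —
  the standard +15/+10 mmHg correction. Residual medication confounding
  is not simulated: medication assignment is random, because no
  generative model for prescription behaviour is part of the stated
  design.
* CVD: liability `theta_bp·(SBP−120) + theta_direct·protein` plus
  standard logistic noise, thresholded at the empirical quantile matching
  the target prevalence — i.e. an exact logistic model with intercept.
  True mediated proportion: `theta_bp·alpha / (theta_bp·alpha +
  theta_direct)`; defaults (α = 2 mmHg/SD, θ_bp = 0.04 log-odds/mmHg,
  θ_direct = 0.08) put it at 0.5.

GWAS are simple per-SNP regressions: OLS for quantitative traits
(vectorized), IRLS logistic for binary traits with a score-test fallback
under separation or non-convergence. `simulate_region_sumstats()` offers
a cheap summary-level alternative (z ~ N(Rλ, R)) for calibration studies
that need hundreds of replicates. `simulate_screen_panel()` scales the
chain to many proteins (default 20, 5 causal) for end-to-end funnel
validation.

### What a green test does and does not establish

The simulator provides LD structure, winner's-curse-prone thresholds,
medication masking, case-control outcomes and multi-signal regions, so
parameter-recovery and calibration tests exercise the estimators under
the failure modes they are designed for. It does **not** emulate real
human LD, sample overlap, population stratification, assay (aptamer)
artefacts, or pleiotropy beyond the protein→CVD direct path — green
tests say the estimators are correctly implemented and calibrated in the
stated world, not that real-data output is unbiased.

Two quantitative caveats discovered and documented while validating the
mediation stage, both properties of the estimand rather than bugs:

* *Non-collapsibility*: marginal per-SNP log-odds are attenuated by
  roughly `1/sqrt(1 + var(liability)/3.29)` relative to conditional
  effects. The attenuation cancels in pm only when it hits β₂ and βTE
  symmetrically, which holds when θ_bp is small (the default); inflating
  θ_bp to boost power breaks the symmetry.
* *Selection on the denominator*: instruments whose exposure z-scores sit
  near the 5e-8 threshold have inflated selected effects (winner's curse,
  plus argmax-z index selection within clumps), attenuating the MR ratio.
  The recovery tests therefore use uniformly strong instruments
  (common variants, per-allele effects giving z ≳ 14), the regime the
  mediation design presumes.

## Numerical and degenerate-input choices

* All posterior arithmetic in log space; `logdiffexp` clamps tiny
  negative differences to −Inf (structural zeros).
* IVW overdispersion floored at 1; single-instrument sets dispatch to the
  Wald ratio.
* Clumping ties break on `(CHR, POS, SNP)`; output is row-order
  invariant.
* p-values are floored at `.Machine$double.xmin` so they remain in (0,1].
* Empty cis windows, zero-instrument proteins, and untestable reverse
  directions are recorded verdicts, not errors; constant phenotypes,
  single-class binary outcomes, zero exposure effects and zero total
  effects raise typed errors.
* The per-protein audit trail (`fail_reasons`) makes every exclusion
  reproducible; `funnel_counts()` reports the stage-by-stage flow.

## Known limitations

* Steiger r² for binary traits is on the observed scale.
* No MR-Egger / weighted-median / MR-PRESSO; the design relies on cis
  instruments plus colocalization instead of pleiotropy-robust averaging.
* LD is synthetic; no GWAS-VCF input, liftover, or strand inference.
* The delta-method CI for pm is symmetric and first-order; with weak
  total effects the ratio distribution is skewed and coverage degrades —
  use strong-instrument settings or report the capped interval.
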