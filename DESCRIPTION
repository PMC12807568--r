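Package: netmr
Title: Proteome-Wide cis-MR, Colocalization and Network-MR Mediation
Version: 0.1.0
Authors@R: person("netmr", "maintainers", email = "netmr@example.org",
    role = c("aut", "cre"))
Description: Tools for screening plasma proteins for causal effects on blood
    pressure and cardiovascular disease from GWAS summary statistics:
    cis-pQTL instrument selection with greedy LD clumping, two-sample
    Mendelian randomization (Wald ratio, inverse-variance weighting,
    Cochran's Q, Steiger directionality, bidirectional checks),
    Bayesian colocalization for two and three traits, pairwise conditional
    colocalization for regions with multiple independent signals, and
    network-MR mediation with delta-method intervals. Includes a synthetic
    GWAS generator with LD-structured genotypes and a known
    protein -> blood pressure -> disease causal chain for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
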