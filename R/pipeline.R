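# Orchestration of the proteome-wide screen: cis selection -> clumping ->
# harmonization -> MR -> sensitivity filters -> FDR -> colocalization ->
# mediation, with a full audit trail per protein.

#' Pipeline configuration
#'
#' Collects every threshold used by the screening funnel, with the
#' conventional defaults: genome-wide significance 5e-8, clumping r^2 0.001
#' in a 10,000 kb window, cis window +/- 1 Mb, MAF floor 0.01, FDR 0.05,
#' mean-F floor 10, colocalization evidence threshold PP 0.70, coloc priors
#' (1e-4, 1e-4, 1e-5) and three-trait priors (1e-4, 1e-6, 1e-7).
#'
#' @param p_threshold instrument significance threshold.
#' @param r2_threshold clumping r^2 threshold.
#' @param window_kb clumping window (kb).
#' @param cis_window_bp cis window around the gene body (bp).
#' @param maf_min minor-allele-frequency floor.
#' @param fdr_alpha FDR significance level.
#' @param f_min minimum mean F-statistic.
#' @param f_rule `"mean"` or `"min"`: which instrument-strength summary the
#'   weak-instrument filter applies to.
#' @param q_alpha heterogeneity filter level (applied when > `q_min_snps`
#'   instruments).
#' @param q_min_snps instrument count above which the Q filter applies.
#' @param steiger_alpha significance level for a reverse Steiger call.
#' @param reverse_alpha significance level for the bidirectional MR flag.
#' @param pp_strong colocalization PP threshold for strong evidence.
#' @param pp_suggestive multi-trait suggestive threshold.
#' @param coloc_priors,moloc_priors prior vectors.
#' @param palindrome_eaf_limit harmonization frequency cutoff.
#' @param min_region_snps minimum SNP panel for colocalization.
#' @param fdr_family `"per_trait"` (default) or `"pooled"` across outcomes.
#' @param mhc_exclude optional `gene_region` blacklist (e.g. the MHC);
#'   proteins whose region overlaps any entry are dropped up front.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                            window_kb = 10000, cis_window_bp = 1e6,
                            maf_min = 0.01, fdr_alpha = 0.05,
                            f_min = 10, f_rule = c("mean", "min"),
                            q_alpha = 0.05, q_min_snps = 3,
                            steiger_alpha = 0.05, reverse_alpha = 0.05,
                            pp_strong = 0.70, pp_suggestive = 0.50,
                            coloc_priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                            moloc_priors = c(p1 = 1e-4, p2 = 1e-6, p3 = 1e-7),
                            palindrome_eaf_limit = 0.42,
                            min_region_snps = 25,
                            fdr_family = c("per_trait", "pooled"),
                            mhc_exclude = list()) {
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, cis_window_bp = cis_window_bp,
                 maf_min = maf_min, fdr_alpha = fdr_alpha, f_min = f_min,
                 f_rule = match.arg(f_rule), q_alpha = q_alpha,
                 q_min_snps = q_min_snps, steiger_alpha = steiger_alpha,
                 reverse_alpha = reverse_alpha, pp_strong = pp_strong,
                 pp_suggestive = pp_suggestive, coloc_priors = coloc_priors,
                 moloc_priors = moloc_priors,
                 palindrome_eaf_limit = palindrome_eaf_limit,
                 min_region_snps = min_region_snps,
                 fdr_family = match.arg(fdr_family),
                 mhc_exclude = mhc_exclude),
            class = "pipeline_config")
}

.overlaps_region <- function(region, blacklist) {
  any(vapply(blacklist, function(b) {
    region$chrom == b$chrom && region$start <= b$end && b$start <= region$end
  }, logical(1)))
}

# one protein against one outcome: the full instrument + MR + filter battery
.screen_one <- function(protein_ss, region, outcome_ss, ld, cfg) {
  rec <- list(n_snps = 0L, beta = NA_real_, se = NA_real_, pval = NA_real_,
              method = NA_character_, f_mean = NA_real_, f_min = NA_real_,
              q_stat = NA_real_, q_pval = NA_real_,
              steiger_direction = NA_character_, steiger_pval = NA_real_,
              reverse_flag = NA_character_, fail_reasons = character(0),
              instruments = character(0))
  cis <- select_cis(protein_ss, region, window_bp = cfg$cis_window_bp,
                    maf_min = cfg$maf_min)
  iv <- if (nrow(cis) > 0) {
    greedy_clump(cis, ld, p_threshold = cfg$p_threshold,
                 r2_threshold = cfg$r2_threshold, window_kb = cfg$window_kb)
  } else cis
  if (nrow(iv) == 0) {
    rec$fail_reasons <- "no_instruments"
    return(rec)
  }
  pairs <- tryCatch(
    kept_pairs(harmonize(iv, outcome_ss,
                         palindrome_eaf_limit = cfg$palindrome_eaf_limit)),
    error = function(e) NULL)
  if (is.null(pairs) || nrow(pairs) == 0) {
    rec$fail_reasons <- "no_instruments"
    return(rec)
  }
  rec$instruments <- pairs$SNP
  rec$n_snps <- nrow(pairs)
  binary <- attr(outcome_ss, "trait_type") == "binary"
  mr <- if (nrow(pairs) == 1) wald_ratio(pairs, binary = binary)
        else mr_ivw(pairs, binary = binary)
  rec$beta <- mr$beta; rec$se <- mr$se; rec$pval <- mr$pval
  rec$method <- mr$method

  fs <- instrument_strength(pairs)
  rec$f_mean <- fs$f_mean; rec$f_min <- fs$f_min
  f_used <- if (cfg$f_rule == "mean") fs$f_mean else fs$f_min
  if (f_used < cfg$f_min) rec$fail_reasons <- c(rec$fail_reasons, "weak_instruments")

  if (nrow(pairs) > 1) {
    q <- cochran_q(pairs)
    rec$q_stat <- q$q_stat; rec$q_pval <- q$pval
    if (nrow(pairs) > cfg$q_min_snps && q$pval <= cfg$q_alpha) {
      rec$fail_reasons <- c(rec$fail_reasons, "heterogeneity")
    }
  }

  st <- steiger(pairs)
  rec$steiger_direction <- st$direction
  rec$steiger_pval <- st$pval
  if (st$direction == "outcome_to_exposure" && st$pval < cfg$steiger_alpha) {
    rec$fail_reasons <- c(rec$fail_reasons, "reverse_causality_steiger")
  }

  bd <- bidirectional_check(outcome_ss, protein_ss, ld, region,
                            cis_window_bp = cfg$cis_window_bp,
                            p_threshold = cfg$p_threshold,
                            alpha = cfg$reverse_alpha)
  rec$reverse_flag <- bd$flag
  if (bd$flag == "reverse_causal") {
    rec$fail_reasons <- c(rec$fail_reasons, "reverse_causality_bidirectional")
  }
  rec
}

.records_to_df <- function(recs, protein_ids, outcome_id) {
  data.frame(
    protein_id = protein_ids, outcome_id = outcome_id,
    n_snps = vapply(recs, `[[`, integer(1), "n_snps"),
    method = vapply(recs, function(r) r$method %||% NA_character_, character(1)),
    beta = vapply(recs, `[[`, numeric(1), "beta"),
    se = vapply(recs, `[[`, numeric(1), "se"),
    pval = vapply(recs, `[[`, numeric(1), "pval"),
    f_mean = vapply(recs, `[[`, numeric(1), "f_mean"),
    q_pval = vapply(recs, `[[`, numeric(1), "q_pval"),
    steiger_direction = vapply(recs, `[[`, character(1), "steiger_direction"),
    reverse_flag = vapply(recs, `[[`, character(1), "reverse_flag"),
    fail_reasons = vapply(recs, function(r)
      paste(r$fail_reasons, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

.apply_fdr <- function(df, cfg) {
  df$fdr_adjusted_p <- NA_real_
  families <- if (cfg$fdr_family == "per_trait") split(seq_len(nrow(df)), df$outcome_id)
              else list(seq_len(nrow(df)))
  for (idx in families) {
    tested <- idx[!is.na(df$pval[idx])]
    df$fdr_adjusted_p[tested] <- bh_fdr(df$pval[tested])
  }
  fdr_fail <- !is.na(df$fdr_adjusted_p) & df$fdr_adjusted_p >= cfg$fdr_alpha
  df$fail_reasons <- ifelse(
    fdr_fail,
    ifelse(df$fail_reasons == "", "not_fdr_significant",
           paste(df$fail_reasons, "not_fdr_significant", sep = ";")),
    df$fail_reasons)
  na_p <- is.na(df$pval)
  df$passed <- !na_p & df$fail_reasons == ""
  df
}

#' Proteome-wide screen of proteins against a blood-pressure trait
#'
#' Runs, per protein: cis selection, LD clumping, harmonization, Wald/IVW
#' MR, Cochran's Q (when more than `q_min_snps` instruments), Steiger and
#' bidirectional reverse-causality checks, and the weak-instrument F filter;
#' then applies BH-FDR across proteins. Every protein appears in the output
#' with either `passed = TRUE` or a non-empty `fail_reasons`.
#'
#' @param proteins named list of protein [sumstats].
#' @param regions named list of [gene_region()]s (same names).
#' @param outcome_ss the BP trait [sumstats].
#' @param ld shared [ld_matrix()].
#' @param config a [pipeline_config()].
#' @return data frame of screen records (one row per protein).
#' @export
run_screen <- function(proteins, regions, outcome_ss, ld,
                       config = pipeline_config()) {
  stopifnot(length(proteins) > 0, all(names(proteins) %in% names(regions)))
  ids <- names(proteins)
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    region <- regions[[ids[i]]]
    if (length(config$mhc_exclude) > 0 && .overlaps_region(region, config$mhc_exclude)) {
      recs[[i]] <- list(n_snps = 0L, beta = NA_real_, se = NA_real_,
                        pval = NA_real_, method = NA_character_,
                        f_mean = NA_real_, f_min = NA_real_,
                        q_stat = NA_real_, q_pval = NA_real_,
                        steiger_direction = NA_character_,
                        steiger_pval = NA_real_, reverse_flag = NA_character_,
                        fail_reasons = "mhc_excluded", instruments = character(0))
      next
    }
    recs[[i]] <- .screen_one(proteins[[ids[i]]], region, outcome_ss, ld, config)
  }
  df <- .records_to_df(recs, ids, attr(outcome_ss, "trait_name"))
  .apply_fdr(df, config)
}

#' Outcome-stage screen of BP-associated proteins against CVD outcomes
#'
#' Applies the identical filter battery to each surviving protein against
#' each CVD outcome, with FDR within outcome (or pooled, per the config),
#' and records whether the BP and CVD effect directions agree.
#'
#' @param screen_records output of [run_screen()] (the BP stage).
#' @param proteins,regions,ld as in [run_screen()].
#' @param outcomes named list of CVD outcome [sumstats].
#' @param config a [pipeline_config()].
#' @return data frame with one row per surviving protein x outcome,
#'   including `direction_concordant`.
#' @export
run_outcome_stage <- function(screen_records, proteins, regions, outcomes, ld,
                              config = pipeline_config()) {
  survivors <- screen_records$protein_id[screen_records$passed]
  if (length(survivors) == 0) stop("run_outcome_stage: no surviving proteins")
  out <- vector("list", length(outcomes))
  for (k in seq_along(outcomes)) {
    recs <- lapply(survivors, function(id) {
      .screen_one(proteins[[id]], regions[[id]], outcomes[[k]], ld, config)
    })
    df <- .records_to_df(recs, survivors,
                         attr(outcomes[[k]], "trait_name") %||% names(outcomes)[k])
    bp_beta <- screen_records$beta[match(survivors, screen_records$protein_id)]
    df$bp_beta <- bp_beta
    df$direction_concordant <- !is.na(df$beta) & sign(df$beta) == sign(bp_beta)
    out[[k]] <- df
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  .apply_fdr(df, config)
}

# MR of BP on a CVD outcome using genome-wide BP instruments outside the
# cis windows of every screened protein: BP loci driven by an assayed
# protein with a direct outcome path would otherwise contaminate beta2
# with horizontal pleiotropy (a dominant fraction of BP loci in a
# desk-scale synthetic panel, a negligible one at UKB scale).
.mr_bp_on_outcome <- function(bp_ss, outcome_ss, ld, exclude_regions, cfg) {
  if (inherits(exclude_regions, "gene_region")) {
    exclude_regions <- list(exclude_regions)
  }
  in_cis <- rep(FALSE, nrow(bp_ss))
  for (reg in exclude_regions) {
    in_cis <- in_cis | (bp_ss$CHR == reg$chrom &
      bp_ss$POS >= reg$start - cfg$cis_window_bp &
      bp_ss$POS <= reg$end + cfg$cis_window_bp)
  }
  trans <- .keep_sumstats(bp_ss, !in_cis)
  iv <- greedy_clump(trans, ld, p_threshold = cfg$p_threshold,
                     r2_threshold = cfg$r2_threshold,
                     window_kb = cfg$window_kb)
  if (nrow(iv) == 0) return(NULL)
  pairs <- tryCatch(kept_pairs(harmonize(iv, outcome_ss)), error = function(e) NULL)
  if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
  binary <- attr(outcome_ss, "trait_type") == "binary"
  if (nrow(pairs) == 1) wald_ratio(pairs, binary = binary)
  else mr_ivw(pairs, binary = binary)
}

#' Colocalization prioritization and network-MR mediation
#'
#' For each candidate that passed both screening stages: colocalize the
#' protein signal with BP and with the CVD outcome over the cis panel
#' (gene-dense candidates are routed through [pwcoco()]), run three-trait
#' colocalization, prioritize candidates with concordant directions and
#' both PP(H4) at or above `pp_strong`, and estimate the proportion of the
#' protein's CVD effect mediated through BP (with BP instrumented by its
#' genome-wide SNPs outside the cis windows of all screened proteins).
#'
#' @param outcome_records output of [run_outcome_stage()].
#' @param screen_records output of [run_screen()].
#' @param proteins,regions,ld as in [run_screen()].
#' @param bp_ss the BP [sumstats] used in the first stage.
#' @param outcomes named list of CVD outcome [sumstats].
#' @param config a [pipeline_config()].
#' @return list with `candidates` (data frame: coloc PPs, moloc PP,
#'   `prioritized`, mediation estimates) and `mediation` (named list of
#'   `mediation_result`s for prioritized candidates).
#' @export
prioritize_and_mediate <- function(outcome_records, screen_records,
                                   proteins, regions, bp_ss, outcomes, ld,
                                   config = pipeline_config()) {
  cand <- outcome_records[outcome_records$passed, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(candidates = data.frame(), mediation = list()))
  }
  dense <- gene_dense_regions(regions)
  rows <- vector("list", nrow(cand))
  mediation <- list()
  beta2_cache <- list()

  for (i in seq_len(nrow(cand))) {
    pid <- cand$protein_id[i]
    oid <- cand$outcome_id[i]
    region <- regions[[pid]]
    outcome_ss <- outcomes[[oid]]
    prot_ss <- proteins[[pid]]

    cis_p <- select_cis(prot_ss, region, window_bp = config$cis_window_bp,
                        maf_min = config$maf_min)
    panel <- Reduce(intersect, list(cis_p$SNP, bp_ss$SNP, outcome_ss$SNP))
    row <- list(protein_id = pid, outcome_id = oid,
                bp_trait = attr(bp_ss, "trait_name"),
                direction_concordant = cand$direction_concordant[i],
                coloc_bp_pp4 = NA_real_, coloc_cvd_pp4 = NA_real_,
                moloc_pp_abc = NA_real_, gene_dense = unname(dense[pid]),
                status = "ok", prioritized = FALSE,
                pm = NA_real_, se_pm = NA_real_,
                pm_ci_low = NA_real_, pm_ci_high = NA_real_,
                consistent = NA)
    if (length(panel) < config$min_region_snps) {
      row$status <- "insufficient_region"
      rows[[i]] <- row
      next
    }
    sub <- function(ss) .keep_sumstats(ss, match(panel, ss$SNP))
    t_prot <- sub(prot_ss); t_bp <- sub(bp_ss); t_out <- sub(outcome_ss)
    pri <- config$coloc_priors

    if (isTRUE(dense[pid])) {
      pw_bp <- pwcoco(t_prot, t_bp, ld, p1 = pri[1], p2 = pri[2], p12 = pri[3])
      pw_out <- pwcoco(t_prot, t_out, ld, p1 = pri[1], p2 = pri[2], p12 = pri[3])
      row$coloc_bp_pp4 <- unname(pw_bp$best$pp["H4"])
      row$coloc_cvd_pp4 <- unname(pw_out$best$pp["H4"])
    } else {
      c_bp <- coloc_abf(abf_vector(t_prot, maf_min = config$maf_min),
                        abf_vector(t_bp, maf_min = config$maf_min),
                        p1 = pri[1], p2 = pri[2], p12 = pri[3])
      c_out <- coloc_abf(abf_vector(t_prot, maf_min = config$maf_min),
                         abf_vector(t_out, maf_min = config$maf_min),
                         p1 = pri[1], p2 = pri[2], p12 = pri[3])
      row$coloc_bp_pp4 <- unname(c_bp$pp["H4"])
      row$coloc_cvd_pp4 <- unname(c_out$pp["H4"])
    }
    mp <- config$moloc_priors
    ml <- moloc_abf(abf_vector(t_prot, maf_min = config$maf_min),
                    abf_vector(t_bp, maf_min = config$maf_min),
                    abf_vector(t_out, maf_min = config$maf_min),
                    p1 = mp[1], p2 = mp[2], p3 = mp[3])
    row$moloc_pp_abc <- ml$pp_abc

    row$prioritized <- isTRUE(row$direction_concordant) &&
      row$coloc_bp_pp4 >= config$pp_strong &&
      row$coloc_cvd_pp4 >= config$pp_strong

    if (row$prioritized) {
      key <- oid
      if (is.null(beta2_cache[[key]])) {
        beta2_cache[[key]] <- .mr_bp_on_outcome(bp_ss, outcome_ss, ld,
                                                regions, config)
      }
      mr2 <- beta2_cache[[key]]
      b1 <- screen_records[screen_records$protein_id == pid, ]
      bte <- cand[i, ]
      if (!is.null(mr2)) {
        med <- proportion_mediated(b1$beta, b1$se, mr2$beta, mr2$se,
                                   bte$beta, bte$se)
        row$pm <- med$pm; row$se_pm <- med$se_pm
        row$pm_ci_low <- med$ci95[1]; row$pm_ci_high <- med$ci95[2]
        row$consistent <- med$consistent
        mediation[[paste(pid, oid, sep = "|")]] <- med
      } else {
        row$status <- "no_bp_instruments"
      }
    }
    rows[[i]] <- row
  }
  candidates <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(candidates) <- NULL
  list(candidates = candidates, mediation = mediation)
}

#' Stage-by-stage funnel counts
#'
#' Summarizes a full run the way screening studies report their flow:
#' proteins tested, FDR-significant, surviving sensitivity filters,
#' outcome-associated, colocalization-prioritized.
#'
#' @param screen_records,outcome_records,prioritized outputs of the three
#'   pipeline stages (`prioritized` = `prioritize_and_mediate()$candidates`).
#' @return named integer vector.
#' @export
funnel_counts <- function(screen_records, outcome_records = NULL,
                          prioritized = NULL) {
  out <- c(
    tested = length(unique(screen_records$protein_id)),
    fdr_significant = length(unique(screen_records$protein_id[
      !is.na(screen_records$fdr_adjusted_p) &
        screen_records$fdr_adjusted_p < 0.05])),
    bp_associated = length(unique(screen_records$protein_id[screen_records$passed]))
  )
  if (!is.null(outcome_records)) {
    out <- c(out, cvd_associated = length(unique(
      outcome_records$protein_id[outcome_records$passed])))
  }
  if (!is.null(prioritized) && nrow(prioritized) > 0) {
    out <- c(out, prioritized = length(unique(
      prioritized$protein_id[prioritized$prioritized])))
  }
  out
}
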