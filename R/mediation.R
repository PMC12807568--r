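# Network (two-step) MR mediation: proportion of the protein -> CVD effect
# transmitted through blood pressure, with delta-method uncertainty.

#' Proportion mediated with delta-method confidence interval
#'
#' Combines three MR estimates from non-overlapping samples:
#' `beta1` (exposure -> mediator), `beta2` (mediator -> outcome) and
#' `beta_te` (exposure -> outcome, total effect). The proportion mediated is
#' `pm = beta1 * beta2 / beta_te`; its variance follows from the first-order
#' delta method treating the three estimates as independent:
#' `var(pm) = (beta2/beta_te)^2 se1^2 + (beta1/beta_te)^2 se2^2 +
#'  (beta1*beta2/beta_te^2)^2 se_te^2`.
#' Both the raw estimate and a \[0, 1\]-capped display value are returned.
#'
#' @param beta1,se1 exposure -> mediator estimate and SE.
#' @param beta2,se2 mediator -> outcome estimate and SE.
#' @param beta_te,se_te total-effect estimate and SE.
#' @return list of class `mediation_result`: `beta1`, `beta2`, `beta_te`
#'   (with SEs), `pm`, `se_pm`, `ci95` (pm +/- 1.96 se), `pm_capped`,
#'   `ci95_capped`, `consistent`.
#' @export
proportion_mediated <- function(beta1, se1, beta2, se2, beta_te, se_te) {
  if (beta_te == 0) stop("undefined-mediation error: beta_te = 0")
  if (any(c(se1, se2, se_te) <= 0)) stop("proportion_mediated: SEs must be positive")
  pm <- beta1 * beta2 / beta_te
  var_pm <- (beta2 / beta_te)^2 * se1^2 +
    (beta1 / beta_te)^2 * se2^2 +
    (beta1 * beta2 / beta_te^2)^2 * se_te^2
  se_pm <- sqrt(var_pm)
  ci <- c(pm - 1.96 * se_pm, pm + 1.96 * se_pm)
  structure(list(
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    beta_te = beta_te, se_te = se_te,
    pm = pm, se_pm = se_pm, ci95 = ci,
    pm_capped = min(max(pm, 0), 1),
    ci95_capped = pmin(pmax(ci, 0), 1),
    consistent = consistency_check(beta1, beta2, beta_te)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("proportion mediated: %.1f%% (95%% CI %.1f%%, %.1f%%)%s\n",
              100 * x$pm, 100 * x$ci95[1], 100 * x$ci95[2],
              if (x$consistent) "" else "  [inconsistent mediation]"))
  invisible(x)
}

#' Mediation consistency check
#'
#' The indirect path and the total effect must point the same way:
#' `sign(beta1 * beta2) == sign(beta_te)`, with all three nonzero.
#'
#' @param beta1,beta2,beta_te the three effect estimates.
#' @return logical.
#' @export
consistency_check <- function(beta1, beta2, beta_te) {
  if (beta1 == 0 || beta2 == 0 || beta_te == 0) return(FALSE)
  sign(beta1 * beta2) == sign(beta_te)
}
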