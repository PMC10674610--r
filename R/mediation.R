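#' @title Two-step MR mediation
#' @description Decomposes the total effect of an exposure on an outcome
#'   into the part flowing through a mediator: step one estimates the
#'   exposure -> mediator effect (beta1) by univariable IVW; step two
#'   estimates the mediator -> outcome effect adjusted for the exposure
#'   (beta2) by multivariable IVW.  The indirect effect is `beta1 * beta2`
#'   and the mediation proportion is the indirect effect over the total
#'   effect, with delta-method confidence intervals.  Binary-outcome
#'   effects enter on the log-odds scale.
#' @name mediation
NULL

#' Mediator admissibility screen
#'
#' A mediator enters the mediation model only if (a) the exposure affects
#' the mediator, (b) the mediator shows no reverse effect on the exposure
#' (bidirectionality would invalidate the two-step decomposition), and
#' (c) the mediator is causally associated with the outcome in univariable
#' MR.  Each input may be an `mr_estimate` (gated on its p-value) or a
#' `causal_call` (gated on its sensitivity-aware verdict).
#'
#' @param forward exposure -> mediator result
#' @param reverse mediator -> exposure result
#' @param outcome_link mediator -> outcome univariable result
#' @param alpha significance level for the gate (default 0.05)
#' @return list with `admissible` (logical) and `reason`
#' @export
mediator_validity_screen <- function(forward, reverse, outcome_link, alpha = 0.05) {
  passes <- function(x) {
    if (inherits(x, "causal_call")) return(x$verdict == "causal")
    x$pvalue < alpha
  }
  if (!passes(forward)) {
    return(list(admissible = FALSE, reason = "no exposure->mediator effect"))
  }
  if (passes(reverse)) {
    return(list(admissible = FALSE, reason = "reverse causation"))
  }
  if (!passes(outcome_link)) {
    return(list(admissible = FALSE, reason = "mediator not associated with outcome in UVMR"))
  }
  list(admissible = TRUE, reason = "admissible")
}

#' Mediation proportion with delta-method confidence interval
#'
#' `P = beta1 * beta2 / beta_total`.  The indirect-effect variance uses the
#' product-of-independent-estimates delta form
#' `beta2^2 se1^2 + beta1^2 se2^2`.  `ci_method = "delta_fixed_total"`
#' treats the total effect as fixed (`var(P) = se_indirect^2 /
#' beta_total^2`); `"delta_full"` additionally propagates total-effect
#' uncertainty (`+ beta1^2 beta2^2 se_total^2 / beta_total^4`), assuming
#' the three estimates are independent, as in a two-sample design with
#' non-overlapping cohorts.  Proportions outside [0, 1] are reported
#' unclamped with an `inconsistent` flag.
#'
#' @param beta1,se1 exposure -> mediator estimate and SE
#' @param beta2,se2 mediator -> outcome direct estimate and SE
#' @param beta_total,se_total total-effect estimate and SE
#' @param ci_method `"delta_fixed_total"` (default) or `"delta_full"`
#' @param alpha CI level
#' @param mediator_name label carried into the result
#' @return a `mediation_result`
#' @export
mediation_proportion <- function(beta1, se1, beta2, se2, beta_total, se_total = 0,
                                 ci_method = c("delta_fixed_total", "delta_full"),
                                 alpha = 0.05, mediator_name = "mediator") {
  ci_method <- match.arg(ci_method)
  if (beta_total == 0) {
    mr_abort("mediation proportion undefined for a zero total effect",
             "mrsuite_undefined_proportion_error")
  }
  if (any(c(se1, se2, se_total) < 0)) abort_config("standard errors must be >= 0")
  indirect <- beta1 * beta2
  var_indirect <- beta2^2 * se1^2 + beta1^2 * se2^2
  proportion <- indirect / beta_total
  var_p <- var_indirect / beta_total^2
  if (ci_method == "delta_full") {
    var_p <- var_p + beta1^2 * beta2^2 * se_total^2 / beta_total^4
  }
  se_p <- sqrt(var_p)
  ci <- ci_normal(proportion, se_p, alpha)
  structure(list(
    mediator_name = mediator_name,
    beta_total = beta_total, se_total = se_total,
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    indirect = indirect, se_indirect = sqrt(var_indirect),
    proportion = proportion, se_proportion = se_p,
    proportion_ci_low = ci[1], proportion_ci_high = ci[2],
    ci_method = ci_method,
    inconsistent = proportion < 0 || proportion > 1,
    excluded = FALSE, exclusion_reason = NA_character_
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s\n", x$mediator_name))
  if (x$excluded) {
    cat(sprintf("  excluded: %s\n", x$exclusion_reason))
  }
  cat(sprintf(
    "  beta1 = %.4f, beta2 = %.4f, indirect = %.4f, total = %.4f\n",
    x$beta1, x$beta2, x$indirect, x$beta_total
  ))
  cat(sprintf(
    "  proportion mediated = %.2f%% (95%% CI %.2f%% to %.2f%%)%s\n",
    100 * x$proportion, 100 * x$proportion_ci_low, 100 * x$proportion_ci_high,
    if (x$inconsistent) " [inconsistent-mediation flag]" else ""
  ))
  invisible(x)
}

#' Tidy mediation results into a table
#' @param x a `mediation_result` or list of them
#' @return data frame, one row per mediator
#' @export
mediation_tidy <- function(x) {
  if (inherits(x, "mediation_result")) x <- list(x)
  do.call(rbind, lapply(x, function(m) {
    data.frame(
      mediator = m$mediator_name, beta1 = m$beta1, se1 = m$se1,
      beta2 = m$beta2, se2 = m$se2, beta_total = m$beta_total,
      se_total = m$se_total, indirect = m$indirect,
      se_indirect = m$se_indirect, proportion = m$proportion,
      proportion_ci_low = m$proportion_ci_low,
      proportion_ci_high = m$proportion_ci_high,
      inconsistent = m$inconsistent, excluded = m$excluded,
      exclusion_reason = m$exclusion_reason,
      stringsAsFactors = FALSE
    )
  }))
}

# subset a gwas_table to a set of variant IDs, preserving metadata
gt_subset <- function(tab, ids) {
  d <- as.data.frame(tab)
  gwas_table(d[d$variant_id %in% ids, , drop = FALSE],
             trait = trait_label(tab), binary = is_binary_trait(tab))
}

#' Run the two-step MR mediation analysis for one mediator
#'
#' Orchestrates the full decomposition against one outcome cohort: total
#' effect (exposure -> outcome, univariable IVW on the exposure's
#' instruments), beta1 (exposure -> mediator, univariable IVW), the
#' mediator validity screen (forward effect, reverse mediator -> exposure
#' MR, mediator -> outcome UVMR), and beta2 (the mediator's coefficient
#' from multivariable IVW of exposure and mediator on the outcome, using
#' the union of both traits' instruments).  Every intermediate estimate is
#' attached to the result.
#'
#' @param exposure,mediator,outcome `gwas_table`s
#' @param config list of settings: `selection` (a [selection_config()]),
#'   `alpha` (gate level, default 0.05), `ci_method` (passed to
#'   [mediation_proportion()])
#' @return a `mediation_result` with an `estimates` element logging each
#'   stage
#' @export
run_two_step <- function(exposure, mediator, outcome, config = list()) {
  sel <- config$selection %||% selection_config()
  alpha <- config$alpha %||% 0.05
  ci_method <- config$ci_method %||% "delta_fixed_total"

  iv_x <- select_instruments(exposure, sel)$instruments
  # instrument the mediator with its own variants: the exposure's
  # instruments are removed so that exposure-driven associations passing
  # significance in the mediator GWAS cannot contaminate the reverse MR
  # screen or the mediator -> outcome UVMR
  sel_m <- sel
  sel_m$excluded_variants <- union(sel$excluded_variants, iv_x)
  iv_m <- select_instruments(mediator, sel_m)$instruments

  est <- list()
  est$total <- mr_ivw(harmonize(gt_subset(exposure, iv_x), outcome))
  est$beta1 <- mr_ivw(harmonize(gt_subset(exposure, iv_x), mediator))
  est$reverse <- mr_ivw(harmonize(gt_subset(mediator, iv_m), exposure))
  est$mediator_outcome <- mr_ivw(harmonize(gt_subset(mediator, iv_m), outcome))

  iv_union <- union(iv_x, iv_m)
  est$mvmr <- mvmr_ivw(harmonize(
    list(gt_subset(exposure, iv_union), gt_subset(mediator, iv_union)),
    outcome
  ))
  beta2 <- est$mvmr$betas[2]
  se2 <- est$mvmr$ses[2]

  screen <- mediator_validity_screen(est$beta1, est$reverse, est$mediator_outcome, alpha)

  out <- mediation_proportion(
    beta1 = est$beta1$beta, se1 = est$beta1$se,
    beta2 = beta2, se2 = se2,
    beta_total = est$total$beta, se_total = est$total$se,
    ci_method = ci_method, alpha = alpha,
    mediator_name = trait_label(mediator)
  )
  out$excluded <- !screen$admissible
  out$exclusion_reason <- if (screen$admissible) NA_character_ else screen$reason
  out$estimates <- est
  out
}
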