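#' Worked mediation example from published summary estimates
#'
#' The package ships a small table of published MR summary estimates for
#' relative carbohydrate intake and hypertension from a two-cohort
#' European-ancestry analysis (`carbohydrate_hypertension_published.tsv`
#' under `extdata`): the pooled univariable total effect of carbohydrate
#' intake on hypertension (odds-ratio scale), and, for five admissible
#' mediators (major depressive disorder, depressive symptoms, neuroticism,
#' waist-to-hip ratio, hip circumference), the exposure -> mediator effect
#' (beta1) and the pooled multivariable mediator -> hypertension odds
#' ratio adjusted for carbohydrate intake (whose log is beta2).  This
#' function recomputes each mediator's mediation proportion with
#' delta-method CIs from those inputs, converting odds ratios to log odds.
#' Standard errors are recovered from the reported 95% confidence limits.
#'
#' @param path the estimates TSV; defaults to the packaged file
#' @param ci_method passed to [mediation_proportion()]
#' @return data frame from [mediation_tidy()], one row per mediator, with
#'   proportions on the 0-1 scale
#' @export
mediation_from_published <- function(path = system.file("extdata",
                                       "carbohydrate_hypertension_published.tsv",
                                       package = "mrsuite"),
                                     ci_method = "delta_fixed_total") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  se_from_ci <- function(lo, hi) (hi - lo) / (2 * stats::qnorm(0.975))
  to_log <- function(row) {
    if (row$scale == "or") {
      list(est = log(row$est), se = se_from_ci(log(row$lo), log(row$hi)))
    } else {
      list(est = row$est, se = se_from_ci(row$lo, row$hi))
    }
  }
  total <- to_log(tab[tab$quantity == "total_or", ])
  mediators <- unique(tab$label[tab$quantity == "beta1"])
  results <- lapply(mediators, function(m) {
    b1 <- to_log(tab[tab$label == m & tab$quantity == "beta1", ])
    b2 <- to_log(tab[tab$label == m & tab$quantity == "or2", ])
    mediation_proportion(
      beta1 = b1$est, se1 = b1$se, beta2 = b2$est, se2 = b2$se,
      beta_total = total$est, se_total = total$se,
      ci_method = ci_method, mediator_name = m
    )
  })
  mediation_tidy(results)
}
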