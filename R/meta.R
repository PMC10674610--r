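#' Pool causal estimates across outcome cohorts
#'
#' Fixed-effect inverse-variance pooling of per-cohort MR estimates with
#' between-cohort heterogeneity assessment (Cochran's Q and I-squared).
#' Under `model_rule = "auto"` the fixed-effect model is used when the
#' heterogeneity test is non-significant, mirroring the usual decision
#' procedure; otherwise a DerSimonian-Laird random-effects pool is used and
#' the switch recorded.
#'
#' @param estimates data frame with columns `label`, `beta`, `se` (one row
#'   per cohort), or a list of `mr_estimate`s with a `labels` attribute
#' @param model_rule `"auto"` (default), `"fixed"` or `"random"`
#' @param het_alpha heterogeneity-test level driving the auto rule
#' @param alpha CI level
#' @return a `meta_result`: `pooled_beta`, `pooled_se`, `ci_low`,
#'   `ci_high`, `pvalue`, `model`, `Q_between`, `Q_pvalue`, `I2`
#'   (percent), `tau2`, `inputs`
#' @export
pool_estimates <- function(estimates, model_rule = c("auto", "fixed", "random"),
                           het_alpha = 0.05, alpha = 0.05) {
  model_rule <- match.arg(model_rule)
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "mr_estimate"))) {
    estimates <- data.frame(
      label = names(estimates) %||% paste0("cohort", seq_along(estimates)),
      beta = vapply(estimates, `[[`, numeric(1), "beta"),
      se = vapply(estimates, `[[`, numeric(1), "se"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(estimates) < 2L) {
    mr_abort("meta-analysis needs at least 2 estimates", "mrsuite_insufficient_data_error")
  }
  if (any(estimates$se <= 0)) abort_config("all standard errors must be > 0")

  w <- 1 / estimates$se^2
  pooled_fixed <- sum(w * estimates$beta) / sum(w)
  Q <- sum(w * (estimates$beta - pooled_fixed)^2)
  df <- nrow(estimates) - 1L
  Q_p <- stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0

  model <- switch(model_rule,
    fixed = "fixed",
    random = "random",
    auto = if (Q_p > het_alpha) "fixed" else "random"
  )
  if (model == "fixed") {
    pooled <- pooled_fixed
    pooled_se <- 1 / sqrt(sum(w))
    tau2 <- 0
  } else {
    # DerSimonian-Laird between-cohort variance
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (estimates$se^2 + tau2)
    pooled <- sum(wr * estimates$beta) / sum(wr)
    pooled_se <- 1 / sqrt(sum(wr))
  }
  ci <- ci_normal(pooled, pooled_se, alpha)
  structure(list(
    pooled_beta = pooled, pooled_se = pooled_se,
    ci_low = ci[1], ci_high = ci[2],
    pvalue = pval_z(pooled, pooled_se),
    model = model, model_rule = model_rule,
    Q_between = Q, Q_df = df, Q_pvalue = Q_p, I2 = I2, tau2 = tau2,
    inputs = estimates
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> pooled beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
    x$pooled_beta, x$pooled_se, x$ci_low, x$ci_high, x$pvalue
  ))
  cat(sprintf(
    "  model: %s; Q = %.3f (p = %.3g), I2 = %.1f%%, %d cohorts\n",
    x$model, x$Q_between, x$Q_pvalue, x$I2, nrow(x$inputs)
  ))
  invisible(x)
}

#' Tidy a meta-analysis result with its per-cohort inputs
#'
#' Layout for forest-plot style reporting: one row per cohort plus one
#' pooled row.
#'
#' @param x a `meta_result`
#' @return data frame
#' @export
meta_tidy <- function(x) {
  z <- stats::qnorm(0.975)
  rows <- data.frame(
    label = x$inputs$label, beta = x$inputs$beta, se = x$inputs$se,
    ci_low = x$inputs$beta - z * x$inputs$se,
    ci_high = x$inputs$beta + z * x$inputs$se,
    pooled = FALSE, stringsAsFactors = FALSE
  )
  rbind(rows, data.frame(
    label = sprintf("pooled (%s)", x$model), beta = x$pooled_beta,
    se = x$pooled_se, ci_low = x$ci_low, ci_high = x$ci_high, pooled = TRUE,
    stringsAsFactors = FALSE
  ))
}
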