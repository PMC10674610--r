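#' @title Configuration-driven MR study pipeline
#' @description Orchestrates the two-phase study design: phase one runs
#'   bidirectional univariable and multivariable MR between the exposure
#'   and each outcome cohort with the full sensitivity suite and pooled
#'   cross-cohort estimates; phase two screens a mediator panel and
#'   quantifies mediation proportions.  Causal verdicts require agreement
#'   between the main IVW analysis and at least one sensitivity method with
#'   no evidence of directional pleiotropy.
#' @name pipeline
NULL

#' Build or load a run configuration
#'
#' @param x a list, or path to a YAML file with the same structure:
#'   `seed` (mandatory), `alpha`, `output_dir`, trait entries `exposure`
#'   (exactly one), `co_exposures`, `mediators`, `outcomes` (each a list
#'   with `path`, `label`, `binary`, optional `column_map` and
#'   `case_fraction`), `selection` (arguments to [selection_config()]) and
#'   `estimators` (`n_boot`, `n_sim`, `ivw_model`, `ci_method`)
#' @return a validated `run_config`
#' @export
run_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.list(x)) abort_config("run configuration must be a list or YAML path")
  if (is.null(x$seed)) abort_config("run configuration requires a seed")
  if (!is.list(x$exposure) || is.null(x$exposure$path)) {
    abort_config("run configuration requires exactly one exposure entry with a path")
  }
  if (is.null(x$outcomes) || length(x$outcomes) < 1L) {
    abort_config("run configuration requires at least one outcome cohort")
  }
  x$alpha <- x$alpha %||% 0.05
  x$co_exposures <- x$co_exposures %||% list()
  x$mediators <- x$mediators %||% list()
  x$selection <- do.call(selection_config, x$selection %||% list())
  est <- x$estimators %||% list()
  x$estimators <- list(
    n_boot = est$n_boot %||% 1000L,
    n_sim = est$n_sim %||% 1000L,
    ivw_model = est$ivw_model %||% "random_multiplicative",
    ci_method = est$ci_method %||% "delta_fixed_total"
  )
  structure(x, class = "run_config")
}

# read every trait table referenced by the configuration up front so that
# configuration errors surface before any computation
load_config_tables <- function(config) {
  read_entry <- function(entry) {
    if (is.null(entry$path)) abort_config("trait entry missing a path")
    read_gwas_table(entry$path,
      column_map = entry$column_map, trait_label = entry$label %||% basename(entry$path),
      binary = isTRUE(entry$binary)
    )
  }
  list(
    exposure = read_entry(config$exposure),
    co_exposures = lapply(config$co_exposures, read_entry),
    mediators = lapply(config$mediators, read_entry),
    outcomes = lapply(config$outcomes, read_entry)
  )
}

#' Run the univariable sensitivity suite
#'
#' IVW plus the four sensitivity estimators (weighted median, weighted
#' mode, MR-Egger, MR-PRESSO) on one harmonized exposure-outcome pair.
#' Estimators whose instrument-count preconditions are not met are skipped
#' with a note.
#'
#' @param data a `harmonized_set` with one exposure
#' @param n_boot bootstrap replicates for median/mode SEs
#' @param n_sim MR-PRESSO simulation count
#' @param seed RNG seed
#' @param ivw_model IVW variant
#' @return named list of `mr_estimate`s (always containing `ivw`)
#' @export
mr_sensitivity_suite <- function(data, n_boot = 1000, n_sim = 1000, seed = 1L,
                                 ivw_model = "random_multiplicative") {
  seeds <- child_seeds(seed, 3)
  out <- list(ivw = mr_ivw(data, model = ivw_model))
  maybe <- function(expr) tryCatch(expr, mrsuite_insufficient_instruments_error = function(e) NULL)
  out$weighted_median <- maybe(mr_weighted_median(data, n_boot = n_boot, seed = seeds[1]))
  out$weighted_mode <- maybe(mr_weighted_mode(data, n_boot = n_boot, seed = seeds[2]))
  out$egger <- maybe(mr_egger(data))
  out$presso <- maybe(mr_presso(data, n_sim = n_sim, seed = seeds[3]))
  out[!vapply(out, is.null, logical(1))]
}

#' Sensitivity-gated causal verdict
#'
#' The main IVW estimate is called causal only if it is significant, at
#' least one sensitivity estimate is significant with the same direction
#' of effect, and the Egger intercept shows no evidence of directional
#' pleiotropy.
#'
#' @param ivw the main `mr_estimate`
#' @param sensitivity list of sensitivity `mr_estimate`s
#' @param egger_intercept_p Egger intercept p-value
#' @param alpha gate level (default 0.05)
#' @return a `causal_call` with `verdict` (`"causal"`/`"not_causal"`),
#'   `supporting_methods` and per-criterion `reasons`
#' @export
causal_call <- function(ivw, sensitivity, egger_intercept_p, alpha = 0.05) {
  if (!length(sensitivity)) abort_config("causal_call requires at least one sensitivity estimate")
  ivw_sig <- ivw$pvalue < alpha
  support <- vapply(sensitivity, function(s) {
    s$pvalue < alpha && sign(s$beta) == sign(ivw$beta)
  }, logical(1))
  supporting <- names(sensitivity)[support] %||% character()
  no_pleiotropy <- is.na(egger_intercept_p) || egger_intercept_p > alpha
  verdict <- if (ivw_sig && any(support) && no_pleiotropy) "causal" else "not_causal"
  structure(list(
    ivw_estimate = ivw,
    supporting_methods = supporting,
    egger_intercept_p = egger_intercept_p,
    verdict = verdict,
    pvalue = ivw$pvalue,
    beta = ivw$beta,
    reasons = list(
      ivw_significant = ivw_sig,
      sensitivity_support = any(support),
      no_pleiotropy = no_pleiotropy
    )
  ), class = "causal_call")
}

#' @export
print.causal_call <- function(x, ...) {
  cat(sprintf(
    "<causal_call> %s (IVW p = %.3g; support: %s; intercept p = %.3g)\n",
    x$verdict, x$ivw_estimate$pvalue,
    if (length(x$supporting_methods)) paste(x$supporting_methods, collapse = ", ") else "none",
    x$egger_intercept_p
  ))
  invisible(x)
}

# run the suite plus gating for one pair (internal)
analyze_pair <- function(exp_tab, out_tab, instruments, config, seed) {
  hs <- harmonize(gt_subset(exp_tab, instruments), out_tab)
  suite <- mr_sensitivity_suite(hs,
    n_boot = config$estimators$n_boot, n_sim = config$estimators$n_sim,
    seed = seed, ivw_model = config$estimators$ivw_model
  )
  egger_p <- if (!is.null(suite$egger)) suite$egger$intercept_pvalue else NA_real_
  call <- causal_call(suite$ivw, suite[setdiff(names(suite), "ivw")], egger_p, config$alpha)
  list(harmonized = hs, suite = suite, call = call)
}

#' Bidirectional UVMR and MVMR analysis
#'
#' Phase one of the study design.  Forward: exposure -> each outcome
#' cohort with the full sensitivity suite and causal gating, plus
#' multivariable MR adjusting for every co-exposure that itself carries a
#' forward causal call (the adjustment-set rule).  Reverse: each outcome
#' cohort -> exposure with its own instruments, plus the Steiger
#' directionality test.  With two or more cohorts the per-cohort IVW and
#' MV-IVW estimates are pooled by fixed-effect meta-analysis (auto-switch
#' to random effects under heterogeneity).
#'
#' @param config a [run_config()]
#' @return list with `forward`, `reverse`, `mvmr`, `pooled`, `manifest`
#' @export
run_bidirectional <- function(config) {
  config <- run_config(unclass(config))
  tabs <- load_config_tables(config)
  seeds <- child_seeds(config$seed, 4 + 2 * length(tabs$outcomes) +
    length(tabs$co_exposures) * length(tabs$outcomes))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }
  manifest <- list()
  log_stage <- function(stage, ...) {
    manifest[[length(manifest) + 1L]] <<- c(list(stage = stage), list(...))
  }

  iv_x <- select_instruments(tabs$exposure, config$selection)
  log_stage("select_instruments", trait = trait_label(tabs$exposure),
            n_instruments = length(iv_x$instruments), audit = iv_x$audit)

  forward <- list()
  reverse <- list()
  mvmr_res <- list()
  for (i in seq_along(tabs$outcomes)) {
    out_tab <- tabs$outcomes[[i]]
    lab <- trait_label(out_tab)

    fw <- analyze_pair(tabs$exposure, out_tab, iv_x$instruments, config, next_seed())
    log_stage("forward_uvmr", cohort = lab, verdict = fw$call$verdict,
              beta = fw$call$beta, pvalue = fw$call$pvalue)

    # adjustment set: co-exposures with their own forward causal call
    adj <- list()
    for (co in tabs$co_exposures) {
      iv_co <- select_instruments(co, config$selection)
      co_fw <- analyze_pair(co, out_tab, iv_co$instruments, config, next_seed())
      log_stage("co_exposure_uvmr", cohort = lab, trait = trait_label(co),
                verdict = co_fw$call$verdict)
      if (co_fw$call$verdict == "causal") {
        adj[[trait_label(co)]] <- list(table = co, instruments = iv_co$instruments)
      } else {
        log_stage("adjustment_set", cohort = lab, trait = trait_label(co),
                  action = "excluded from MVMR adjustment (no causal forward call)")
      }
    }
    mv <- NULL
    if (length(adj)) {
      iv_union <- Reduce(union, c(list(iv_x$instruments),
                                  lapply(adj, `[[`, "instruments")))
      hs_mv <- harmonize(
        c(list(gt_subset(tabs$exposure, iv_union)),
          lapply(adj, function(a) gt_subset(a$table, iv_union))),
        out_tab
      )
      mv <- mvmr_ivw(hs_mv, model = config$estimators$ivw_model)
      mv$conditional_F <- as.numeric(conditional_f(hs_mv))
      log_stage("forward_mvmr", cohort = lab,
                adjusted_for = names(adj), beta = mv$betas[1])
    }

    # the reverse arm instruments the outcome on its own summary statistics;
    # when the outcome has no genome-wide hits the arm is reported as
    # not_causal with the failure on record rather than aborting the run
    rv_seed <- next_seed()
    rv <- tryCatch({
      rv_iv <- select_instruments(out_tab, config$selection)
      analyze_pair(out_tab, tabs$exposure, rv_iv$instruments, config, rv_seed)
    }, mrsuite_insufficient_instruments_error = function(e) {
      list(harmonized = NULL, suite = NULL, call = structure(list(
        ivw_estimate = NULL, supporting_methods = character(),
        egger_intercept_p = NA_real_, verdict = "not_causal",
        pvalue = NA_real_, beta = NA_real_,
        reasons = list(no_instruments = conditionMessage(e))
      ), class = "causal_call"))
    })
    steiger <- steiger_test(fw$harmonized,
      case_fraction = config$outcomes[[i]]$case_fraction %||% NULL
    )
    log_stage("reverse_uvmr", cohort = lab, verdict = rv$call$verdict,
              steiger_forward = steiger$direction_correct)

    forward[[lab]] <- c(fw, list(steiger = steiger))
    reverse[[lab]] <- rv
    mvmr_res[[lab]] <- mv
  }

  pooled <- list()
  if (length(tabs$outcomes) >= 2L) {
    pooled$forward_ivw <- pool_estimates(lapply(forward, function(f) f$suite$ivw))
    rv_ests <- lapply(reverse, function(r) r$suite$ivw)
    pooled$reverse_ivw <- pool_estimates(rv_ests)
    if (all(!vapply(mvmr_res, is.null, logical(1)))) {
      mv_df <- data.frame(
        label = names(mvmr_res),
        beta = vapply(mvmr_res, function(m) m$betas[1], numeric(1)),
        se = vapply(mvmr_res, function(m) m$ses[1], numeric(1)),
        stringsAsFactors = FALSE
      )
      pooled$forward_mvmr <- pool_estimates(mv_df)
    }
    log_stage("meta_pool",
              forward_pooled_beta = pooled$forward_ivw$pooled_beta,
              model = pooled$forward_ivw$model)
  }

  res <- list(forward = forward, reverse = reverse, mvmr = mvmr_res,
              pooled = pooled, manifest = manifest, config = config)
  write_run_outputs(res, config)
  res
}

#' Two-step MR over a configured mediator panel
#'
#' Phase two of the study design.  Each configured mediator is screened
#' (forward effect, reverse causation, outcome association) and, when
#' admissible, its mediation proportion is estimated; with several outcome
#' cohorts the total effect and the mediator's adjusted effect are pooled
#' by fixed-effect meta-analysis before the proportion is formed.  Results
#' are ranked by proportion, descending; excluded mediators are listed
#' with reasons.
#'
#' @param config a [run_config()]
#' @return list with `results` (per-mediator `mediation_result`s),
#'   `table` (ranked tidy table), `excluded` and `manifest`
#' @export
run_mediation_panel <- function(config) {
  config <- run_config(unclass(config))
  tabs <- load_config_tables(config)
  manifest <- list()
  if (!length(tabs$mediators)) {
    warning("no mediators configured; returning an empty mediation table")
    return(list(results = list(), table = mediation_tidy(list()), excluded = list(),
                manifest = manifest))
  }
  two_cfg <- list(selection = config$selection, alpha = config$alpha,
                  ci_method = config$estimators$ci_method)

  results <- list()
  for (med in tabs$mediators) {
    lab <- trait_label(med)
    per_cohort <- lapply(tabs$outcomes, function(out_tab) {
      run_two_step(tabs$exposure, med, out_tab, two_cfg)
    })
    if (length(per_cohort) == 1L) {
      res <- per_cohort[[1]]
    } else {
      # pool the outcome-facing pieces across cohorts; beta1 and the
      # reverse screen do not involve the outcome and are cohort-invariant
      labels <- vapply(tabs$outcomes, trait_label, character(1))
      pool_of <- function(getter) {
        pool_estimates(data.frame(
          label = labels,
          beta = vapply(per_cohort, function(r) getter(r)$beta, numeric(1)),
          se = vapply(per_cohort, function(r) getter(r)$se, numeric(1)),
          stringsAsFactors = FALSE
        ))
      }
      p_total <- pool_of(function(r) r$estimates$total)
      p_beta2 <- pool_estimates(data.frame(
        label = labels,
        beta = vapply(per_cohort, function(r) r$estimates$mvmr$betas[2], numeric(1)),
        se = vapply(per_cohort, function(r) r$estimates$mvmr$ses[2], numeric(1)),
        stringsAsFactors = FALSE
      ))
      p_mo <- pool_of(function(r) r$estimates$mediator_outcome)
      first <- per_cohort[[1]]
      screen <- mediator_validity_screen(
        first$estimates$beta1,
        first$estimates$reverse,
        list(pvalue = p_mo$pvalue),
        config$alpha
      )
      res <- mediation_proportion(
        beta1 = first$estimates$beta1$beta, se1 = first$estimates$beta1$se,
        beta2 = p_beta2$pooled_beta, se2 = p_beta2$pooled_se,
        beta_total = p_total$pooled_beta, se_total = p_total$pooled_se,
        ci_method = config$estimators$ci_method, alpha = config$alpha,
        mediator_name = lab
      )
      res$excluded <- !screen$admissible
      res$exclusion_reason <- if (screen$admissible) NA_character_ else screen$reason
      res$estimates <- list(per_cohort = per_cohort, pooled_total = p_total,
                            pooled_beta2 = p_beta2, pooled_mediator_outcome = p_mo)
    }
    manifest[[length(manifest) + 1L]] <- list(
      stage = "mediation", mediator = lab, excluded = res$excluded,
      reason = res$exclusion_reason, proportion = res$proportion
    )
    results[[lab]] <- res
  }

  admissible <- results[!vapply(results, `[[`, logical(1), "excluded")]
  excluded <- results[vapply(results, `[[`, logical(1), "excluded")]
  tab <- mediation_tidy(results)
  if (length(admissible)) {
    ord <- order(-vapply(admissible, `[[`, numeric(1), "proportion"))
    tab <- rbind(
      mediation_tidy(admissible[ord]),
      if (length(excluded)) mediation_tidy(excluded)
    )
  }
  out <- list(results = results, table = tab,
              excluded = lapply(excluded, `[[`, "exclusion_reason"),
              manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(config$output_dir, "mediation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$output_dir, "mediation_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# write tidy outputs and the run manifest (internal)
write_run_outputs <- function(res, config) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fw_rows <- do.call(rbind, lapply(names(res$forward), function(lab) {
    t <- mr_tidy(res$forward[[lab]]$suite)
    cbind(cohort = lab, direction = "forward", t)
  }))
  rv_rows <- do.call(rbind, lapply(names(res$reverse), function(lab) {
    if (is.null(res$reverse[[lab]]$suite)) return(NULL)   # reverse arm had no instruments
    t <- mr_tidy(res$reverse[[lab]]$suite)
    cbind(cohort = lab, direction = "reverse", t)
  }))
  utils::write.table(rbind(fw_rows, rv_rows),
    file.path(config$output_dir, "uvmr_estimates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (length(res$pooled)) {
    pooled_rows <- do.call(rbind, lapply(names(res$pooled), function(nm) {
      cbind(analysis = nm, meta_tidy(res$pooled[[nm]]))
    }))
    utils::write.table(pooled_rows,
      file.path(config$output_dir, "pooled_estimates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  jsonlite::write_json(res$manifest,
    file.path(config$output_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(NULL)
}
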