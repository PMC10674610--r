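#' @title Multivariable MR estimators
#' @description Direct-effect estimation for two or more exposures jointly
#'   instrumented: MV-IVW, MVMR-Egger, MVMR-median (weighted least absolute
#'   deviations), MVMR-Lasso (per-SNP penalized intercepts), and conditional
#'   instrument-strength diagnostics.
#' @name mvmr
NULL

new_mvmr_estimate <- function(method, exposure_names, betas, ses, alpha = 0.05,
                              binary = FALSE, ...) {
  z <- stats::qnorm(1 - alpha / 2)
  est <- list(
    method = method, exposure_names = exposure_names,
    betas = as.numeric(betas), ses = as.numeric(ses),
    ci_low = betas - z * ses, ci_high = betas + z * ses,
    pvalues = pval_z(betas, ses),
    odds_ratios = exp(betas), outcome_binary = binary,
    conditional_F = rep(NA_real_, length(betas)),
    Q = NA_real_, Q_df = NA_real_, Q_pvalue = NA_real_,
    intercept = NA_real_, intercept_se = NA_real_, intercept_pvalue = NA_real_,
    penalized_snp_ids = character()
  )
  extra <- list(...)
  est[names(extra)] <- extra
  structure(est, class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("<mvmr_estimate> %s (%d exposures)\n", x$method, length(x$betas)))
  print(mvmr_tidy(x))
  invisible(x)
}

#' Tidy a multivariable MR estimate
#' @param x an `mvmr_estimate` or list of them
#' @return data frame with one row per exposure per method
#' @export
mvmr_tidy <- function(x) {
  if (inherits(x, "mvmr_estimate")) x <- list(x)
  do.call(rbind, lapply(x, function(e) {
    data.frame(
      method = e$method, exposure = e$exposure_names,
      beta = e$betas, se = e$ses, ci_low = e$ci_low, ci_high = e$ci_high,
      odds_ratio = e$odds_ratios, pvalue = e$pvalues,
      conditional_F = e$conditional_F,
      Q = e$Q, Q_pvalue = e$Q_pvalue,
      intercept = e$intercept, intercept_pvalue = e$intercept_pvalue,
      stringsAsFactors = FALSE
    )
  }))
}

check_mv <- function(data, min_extra = 1L, min_K = 1L) {
  if (!inherits(data, "harmonized_set")) abort_config("expected a harmonized_set")
  K <- ncol(data$beta_X)
  if (K < min_K) {
    abort_config(sprintf("this estimator requires K >= %d exposures", min_K))
  }
  L <- nrow(data$beta_X)
  if (L < K + min_extra) {
    abort_insufficient(sprintf("need at least %d instruments for K = %d exposures", K + min_extra, K))
  }
  qrx <- qr(data$beta_X)
  if (qrx$rank < K) {
    bad <- data$exposure_names[setdiff(seq_len(K), qrx$pivot[seq_len(qrx$rank)])]
    mr_abort(
      sprintf("exposure-effect matrix is rank deficient (collinear: %s)", paste(bad, collapse = ", ")),
      "mrsuite_collinearity_error"
    )
  }
  list(X = data$beta_X, by = data$beta_Y, sy = data$se_Y, K = K, L = L,
       ids = data$variant_ids, binary = data$binary_Y)
}

# weighted normal-equations fit; returns coefficients, unscaled vcov, weighted RSS
wls_fit <- function(X, y, w) {
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  list(coefs = coefs, vcov = solve(XtWX), rss = sum(w * resid^2), resid = resid)
}

#' Multivariable IVW estimate
#'
#' Zero-intercept weighted multiple regression of the outcome associations
#' on the K exposure-effect columns with weights `1/se_Y^2`; each
#' coefficient is the direct effect of that exposure conditional on the
#' others.  The multiplicative random-effects model inflates SEs by
#' `max(1, sqrt(Q/(L-K)))`.
#'
#' @param data a `harmonized_set` with K >= 2 exposures
#' @param model `"random_multiplicative"` (default) or `"fixed"`
#' @param alpha CI level
#' @return an `mvmr_estimate`
#' @export
mvmr_ivw <- function(data, model = c("random_multiplicative", "fixed"), alpha = 0.05) {
  model <- match.arg(model)
  d <- check_mv(data)
  w <- 1 / d$sy^2
  fit <- wls_fit(d$X, d$by, w)
  df <- d$L - d$K
  scale <- if (model == "random_multiplicative") max(1, sqrt(fit$rss / df)) else 1
  ses <- sqrt(diag(fit$vcov)) * scale
  new_mvmr_estimate(
    if (model == "fixed") "MV-IVW (fixed)" else "MV-IVW",
    data$exposure_names, fit$coefs, ses, alpha, d$binary,
    Q = fit$rss, Q_df = df, Q_pvalue = stats::pchisq(fit$rss, df, lower.tail = FALSE)
  )
}

#' Multivariable MR-Egger estimate
#'
#' As [mvmr_ivw()] but with a free intercept after sign-orienting all rows
#' so the chosen exposure's effects are non-negative; the intercept test is
#' the multivariable pleiotropy diagnostic.
#'
#' @inheritParams mvmr_ivw
#' @param orient_on index of the exposure used for sign orientation
#'   (default 1)
#' @return an `mvmr_estimate` with intercept fields populated
#' @export
mvmr_egger <- function(data, orient_on = 1L, alpha = 0.05) {
  d <- check_mv(data, min_extra = 2L, min_K = 2L)
  flip <- d$X[, orient_on] < 0
  X <- d$X
  X[flip, ] <- -X[flip, ]
  by <- ifelse(flip, -d$by, d$by)
  w <- 1 / d$sy^2
  Xa <- cbind(intercept = 1, X)
  fit <- wls_fit(Xa, by, w)
  df <- d$L - d$K - 1L
  scale <- max(1, sqrt(fit$rss / df))
  ses_all <- sqrt(diag(fit$vcov)) * scale
  new_mvmr_estimate(
    "MVMR-Egger", data$exposure_names, fit$coefs[-1], ses_all[-1], alpha, d$binary,
    Q = fit$rss, Q_df = df, Q_pvalue = stats::pchisq(fit$rss, df, lower.tail = FALSE),
    intercept = unname(fit$coefs[1]), intercept_se = unname(ses_all[1]),
    intercept_pvalue = unname(pval_z(fit$coefs[1], ses_all[1]))
  )
}

# exact weighted median: smallest value whose cumulative weight reaches half
wmedian_exact <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  x[which(cw >= cw[length(cw)] / 2)[1]]
}

# weighted least-absolute-deviations fit by cyclic coordinate descent with
# exact weighted-median coordinate updates (each update minimizes the
# weighted-L1 objective in that coordinate exactly, so the iteration
# settles on a vertex in finitely many sweeps); warm-started from WLS
wlad_fit <- function(X, y, w, tol = 1e-8, max_iter = 1000) {
  coefs <- wls_fit(X, y, w)$coefs
  K <- ncol(X)
  obj <- function(b) sum(w * abs(y - drop(X %*% b)))
  last_obj <- obj(coefs)
  for (it in seq_len(max_iter)) {
    old <- coefs
    for (k in seq_len(K)) {
      xk <- X[, k]
      keep <- xk != 0
      if (!any(keep)) next
      r <- y - drop(X[, -k, drop = FALSE] %*% coefs[-k])
      coefs[k] <- wmedian_exact(r[keep] / xk[keep], w[keep] * abs(xk[keep]))
    }
    new_obj <- obj(coefs)
    # each exact median update is non-increasing in the objective, so a
    # stalled objective (e.g. ties between neighboring vertices) means the
    # descent is finished even if the iterates still alternate
    if (max(abs(coefs - old)) < tol ||
        last_obj - new_obj < tol * (1 + last_obj)) {
      return(list(coefs = coefs, iterations = it, converged = TRUE))
    }
    last_obj <- new_obj
  }
  cond <- structure(
    class = c("mrsuite_convergence_error", "mrsuite_error", "error", "condition"),
    list(message = sprintf("coordinate descent did not settle in %d sweeps", max_iter),
         call = sys.call(-1), last_iterate = coefs)
  )
  stop(cond)
}

#' Multivariable median estimate
#'
#' Minimizes the weighted sum of absolute residuals of the outcome on the
#' exposure columns (weights `1/se_Y^2`), robust to a minority of
#' pleiotropic instruments; solved by cyclic coordinate descent with exact
#' weighted-median updates, warm-started from weighted least squares.
#' SEs from a seeded parametric bootstrap.
#'
#' @inheritParams mvmr_ivw
#' @param n_boot bootstrap replicates (default 200)
#' @param seed RNG seed
#' @return an `mvmr_estimate`
#' @export
mvmr_median <- function(data, n_boot = 200, seed = NULL, alpha = 0.05) {
  d <- check_mv(data, min_extra = 2L)
  w <- 1 / d$sy^2
  fit <- wlad_fit(d$X, d$by, w)
  ses <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      Xb <- d$X + matrix(stats::rnorm(d$L * d$K), d$L, d$K) * data$se_X
      yb <- stats::rnorm(d$L, d$by, d$sy)
      wlad_fit(Xb, yb, w)$coefs
    }, numeric(d$K))
    apply(matrix(boots, nrow = d$K), 1, stats::sd)
  })
  new_mvmr_estimate("MVMR-median", data$exposure_names, fit$coefs, ses, alpha, d$binary)
}

#' Multivariable Lasso estimate
#'
#' Augments the MV-IVW regression with one L1-penalized intercept per SNP
#' (exposure coefficients unpenalized).  Instruments absorbing a non-zero
#' intercept are treated as pleiotropic and dropped; the penalty strength
#' follows a heterogeneity stopping rule: descending a log-spaced grid from
#' the smallest all-zero penalty, the first (largest) lambda whose retained
#' SNPs show acceptable heterogeneity (Q below its chi-square 95th
#' percentile) is used.  Final estimates come from MV-IVW on the surviving
#' SNPs.
#'
#' @inheritParams mvmr_ivw
#' @param lambda_grid optional penalty grid (descending); default 50
#'   log-spaced values below the data-driven maximum
#' @return an `mvmr_estimate` with `penalized_snp_ids` and `lambda`
#' @export
mvmr_lasso <- function(data, lambda_grid = NULL, alpha = 0.05) {
  d <- check_mv(data, min_extra = 2L, min_K = 2L)
  w <- 1 / d$sy^2

  # full-set fit; if already homogeneous no instrument needs a pleiotropy
  # intercept (the infinite-penalty limit)
  full <- mvmr_ivw(data, alpha = alpha)
  if (full$Q < stats::qchisq(0.95, full$Q_df)) {
    full$method <- "MVMR-Lasso"
    full$lambda <- Inf
    return(full)
  }

  fit0 <- wls_fit(d$X, d$by, w)
  if (is.null(lambda_grid)) {
    lambda_max <- max(2 * w * abs(fit0$resid))
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-3), length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  # block coordinate descent: exposures by WLS on (y - a), intercepts by
  # per-SNP soft thresholding
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  coefs <- fit0$coefs
  a <- rep(0, d$L)
  lasso_result <- function(retained, a, lambda) {
    est <- mvmr_ivw(hs_subset(data, retained), alpha = alpha)
    est$method <- "MVMR-Lasso"
    est$penalized_snp_ids <- d$ids[a != 0]
    est$lambda <- lambda
    est
  }
  fallback <- NULL
  for (lambda in lambda_grid) {
    for (it in 1:500) {
      r <- d$by - drop(d$X %*% coefs)
      a_new <- soft(r, lambda / (2 * w))
      fitb <- wls_fit(d$X, d$by - a_new, w)
      delta <- max(abs(c(fitb$coefs - coefs, a_new - a)))
      coefs <- fitb$coefs
      a <- a_new
      if (delta < 1e-10) break
    }
    retained <- which(a == 0)
    if (length(retained) <= d$K) next
    fallback <- list(retained = retained, a = a, lambda = lambda)
    sub <- hs_subset(data, retained)
    fit_sub <- wls_fit(sub$beta_X, sub$beta_Y, 1 / sub$se_Y^2)
    df_sub <- length(retained) - d$K
    if (fit_sub$rss < stats::qchisq(0.95, df_sub)) {
      return(lasso_result(retained, a, lambda))
    }
  }
  if (is.null(fallback)) {
    mr_abort(
      "every penalty level penalizes all (or nearly all) instruments",
      "mrsuite_degenerate_selection_error"
    )
  }
  warning("no penalty level met the heterogeneity criterion; reporting the most-penalized workable fit")
  lasso_result(fallback$retained, fallback$a, fallback$lambda)
}

#' Conditional instrument-strength (F) statistics
#'
#' For each exposure, the strength of its instruments conditional on the
#' co-exposures: the weighted residual sum of squares from regressing that
#' exposure's instrument effects on the other exposures' effects (weights
#' `1/se^2` of the focal exposure), divided by `L - K + 1`.  The
#' degrees-of-freedom convention is recorded in the `df_convention`
#' attribute so cross-software comparisons are explicit.
#'
#' @param data a `harmonized_set` with K >= 2 exposures
#' @return named numeric vector of conditional F statistics
#' @export
conditional_f <- function(data) {
  d <- check_mv(data, min_K = 2L)
  out <- numeric(d$K)
  for (k in seq_len(d$K)) {
    w <- 1 / data$se_X[, k]^2
    others <- d$X[, -k, drop = FALSE]
    fit <- wls_fit(others, d$X[, k], w)
    out[k] <- fit$rss / (d$L - d$K + 1)
  }
  names(out) <- data$exposure_names
  attr(out, "df_convention") <- "F_k = Q_k / (L - K + 1), Q_k the weighted RSS of exposure k's effects regressed on the co-exposures"
  out
}
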