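#' @title Univariable two-sample MR estimators
#' @description Wald ratio, inverse-variance weighted (IVW), MR-Egger,
#'   weighted median, weighted mode and MR-PRESSO estimators operating on a
#'   [harmonize()]d set with a single exposure, plus Cochran's Q, instrument
#'   F statistics and the Steiger directionality test.
#' @name uvmr
NULL

new_mr_estimate <- function(method, beta, se, pvalue, n_snps, alpha = 0.05,
                            binary = FALSE, ...) {
  ci <- ci_normal(beta, se, alpha)
  est <- list(
    method = method, beta = beta, se = se,
    ci_low = ci[1], ci_high = ci[2], pvalue = pvalue,
    odds_ratio = exp(beta), or_ci_low = exp(ci[1]), or_ci_high = exp(ci[2]),
    outcome_binary = binary, n_snps = n_snps,
    Q = NA_real_, Q_df = NA_real_, Q_pvalue = NA_real_,
    egger_intercept = NA_real_, intercept_se = NA_real_, intercept_pvalue = NA_real_,
    outlier_ids = character()
  )
  extra <- list(...)
  est[names(extra)] <- extra
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, %d SNP(s)\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps
  ))
  if (x$outcome_binary) {
    cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", x$odds_ratio, x$or_ci_low, x$or_ci_high))
  }
  if (is.finite(x$Q)) {
    cat(sprintf("  Q = %.3f (df %d, p = %.3g)\n", x$Q, x$Q_df, x$Q_pvalue))
  }
  if (is.finite(x$egger_intercept)) {
    cat(sprintf(
      "  intercept = %.4f (se %.4f, p = %.3g)\n",
      x$egger_intercept, x$intercept_se, x$intercept_pvalue
    ))
  }
  invisible(x)
}

#' Tidy one or more MR estimates into a table
#'
#' Produces the per-method results layout used for reporting: method,
#' number of SNPs, beta with CI, OR with CI, p-value.
#'
#' @param x an `mr_estimate` or a list of them
#' @return data frame with one row per estimate
#' @export
mr_tidy <- function(x) {
  if (inherits(x, "mr_estimate")) x <- list(x)
  do.call(rbind, lapply(x, function(e) {
    data.frame(
      method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
      ci_low = e$ci_low, ci_high = e$ci_high,
      odds_ratio = e$odds_ratio, or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
      pvalue = e$pvalue, Q = e$Q, Q_pvalue = e$Q_pvalue,
      egger_intercept = e$egger_intercept, intercept_pvalue = e$intercept_pvalue,
      stringsAsFactors = FALSE
    )
  }))
}

# unpack a K = 1 harmonized set
check_uv <- function(data) {
  if (!inherits(data, "harmonized_set")) abort_config("expected a harmonized_set")
  if (ncol(data$beta_X) != 1L) abort_config("univariable estimators require exactly one exposure")
  list(
    bx = data$beta_X[, 1], sx = data$se_X[, 1],
    by = data$beta_Y, sy = data$se_Y,
    ids = data$variant_ids, binary = data$binary_Y
  )
}

#' Wald ratio estimate from a single instrument
#'
#' The elemental MR estimate: `beta_Y / beta_X`.  The default standard
#' error is the first-order delta approximation `se_Y / |beta_X|`; with
#' `second_order = TRUE` the `beta_Y^2 se_X^2 / beta_X^4` term is added,
#' accounting for uncertainty in the instrument-exposure association.
#'
#' @param beta_X,se_X instrument-exposure effect and SE
#' @param beta_Y,se_Y instrument-outcome effect and SE
#' @param second_order include the exposure-side variance term
#' @param alpha CI level (default 0.05 for 95% CIs)
#' @param binary outcome on the log-odds scale (adds OR reporting)
#' @return an `mr_estimate`
#' @export
wald_ratio <- function(beta_X, se_X, beta_Y, se_Y, second_order = FALSE,
                       alpha = 0.05, binary = FALSE) {
  if (beta_X == 0) mr_abort("Wald ratio undefined for beta_X = 0", "mrsuite_undefined_ratio_error")
  beta <- beta_Y / beta_X
  v <- se_Y^2 / beta_X^2
  if (second_order) v <- v + beta_Y^2 * se_X^2 / beta_X^4
  se <- sqrt(v)
  new_mr_estimate("Wald ratio", beta, se, pval_z(beta, se), 1L, alpha, binary)
}

#' Inverse-variance weighted estimate
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights `1/se_Y^2`, the main MR analysis.  Under the multiplicative
#' random-effects model the standard error is inflated by
#' `max(1, sqrt(Q/(L-1)))` to absorb between-instrument heterogeneity.
#' A single instrument falls back to the Wald ratio with a message.
#'
#' @param data a `harmonized_set` with one exposure
#' @param model `"random_multiplicative"` (default) or `"fixed"`
#' @param alpha CI level
#' @return an `mr_estimate` with Q diagnostics attached
#' @export
mr_ivw <- function(data, model = c("random_multiplicative", "fixed"), alpha = 0.05) {
  model <- match.arg(model)
  d <- check_uv(data)
  L <- length(d$bx)
  if (L == 0L) abort_insufficient("no instruments available for IVW")
  if (L == 1L) {
    message("single instrument: IVW reduces to the Wald ratio")
    est <- wald_ratio(d$bx, d$sx, d$by, d$sy, alpha = alpha, binary = d$binary)
    est$method <- "IVW"
    return(est)
  }
  w <- 1 / d$sy^2
  beta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fixed <- 1 / sqrt(sum(w * d$bx^2))
  Q <- sum(w * (d$by - beta * d$bx)^2)
  scale <- if (model == "random_multiplicative") max(1, sqrt(Q / (L - 1))) else 1
  se <- se_fixed * scale
  new_mr_estimate(
    if (model == "fixed") "IVW (fixed)" else "IVW", beta, se,
    pval_z(beta, se), L, alpha, d$binary,
    Q = Q, Q_df = L - 1L, Q_pvalue = stats::pchisq(Q, L - 1, lower.tail = FALSE)
  )
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept, rows oriented so all exposure effects are non-negative.  The
#' slope is the pleiotropy-robust causal estimate; the intercept with its
#' own test estimates average directional pleiotropy.  Both SEs carry a
#' multiplicative residual scale floored at 1.
#'
#' @inheritParams mr_ivw
#' @return an `mr_estimate` with intercept fields populated
#' @export
mr_egger <- function(data, alpha = 0.05) {
  d <- check_uv(data)
  L <- length(d$bx)
  if (L < 3L) abort_insufficient("MR-Egger requires at least 3 instruments")
  flip <- d$bx < 0
  bx <- ifelse(flip, -d$bx, d$bx)
  by <- ifelse(flip, -d$by, d$by)
  w <- 1 / d$sy^2
  # weighted normal equations for (intercept, slope)
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * by)
  coefs <- solve(XtWX, XtWy)
  resid <- by - X %*% coefs
  rss <- sum(w * resid^2)
  scale <- max(1, sqrt(rss / (L - 2)))
  vcov_u <- solve(XtWX)
  se_int <- sqrt(vcov_u[1, 1]) * scale
  se_slope <- sqrt(vcov_u[2, 2]) * scale
  slope <- coefs[2]
  intercept <- coefs[1]
  new_mr_estimate(
    "MR-Egger", slope, se_slope, pval_z(slope, se_slope), L, alpha, d$binary,
    Q = rss, Q_df = L - 2L, Q_pvalue = stats::pchisq(rss, L - 2, lower.tail = FALSE),
    egger_intercept = intercept, intercept_se = se_int,
    intercept_pvalue = pval_z(intercept, se_int)
  )
}

# per-SNP Wald ratios and first-order weights (internal)
uv_ratios <- function(d) {
  r <- d$by / d$bx
  se_r <- d$sy / abs(d$bx)
  list(r = r, w = 1 / se_r^2)
}

weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  L <- length(r)
  if (p[L] < 0.5) return(r[L])
  k <- max(which(p < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

# parametric bootstrap SE over per-SNP sampling distributions (internal)
boot_se <- function(d, stat, n_boot, seed) {
  L <- length(d$bx)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(L, d$bx, d$sx)
      by <- stats::rnorm(L, d$by, d$sy)
      stat(list(bx = bx, sx = d$sx, by = by, sy = d$sy))
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted median estimate
#'
#' The weight-interpolated 50th percentile of the per-SNP Wald ratios with
#' inverse-variance weights, consistent when instruments holding at least
#' half the weight are valid.  The SE comes from a seeded parametric
#' bootstrap resampling per-SNP effects from their sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return an `mr_estimate`
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL, alpha = 0.05) {
  d <- check_uv(data)
  L <- length(d$bx)
  if (L < 3L) abort_insufficient("weighted median requires at least 3 instruments")
  rw <- uv_ratios(d)
  beta <- weighted_median_point(rw$r, rw$w)
  stat <- function(dd) {
    rr <- uv_ratios(dd)
    weighted_median_point(rr$r, rr$w)
  }
  se <- boot_se(d, stat, n_boot, seed)
  new_mr_estimate("Weighted median", beta, se, pval_z(beta, se), L, alpha, d$binary)
}

weighted_mode_point <- function(r, w, phi = 1, grid_n = 512) {
  L <- length(r)
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) return(r[1])
  m <- stats::mad(r)
  h <- phi * 0.9 * min(s, if (m > 0) m else s) * L^(-1 / 5)
  grid <- seq(mean(r) - 3 * s, mean(r) + 3 * s, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, r, h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' Maximizer of a weighted normal-kernel density over the per-SNP Wald
#' ratios, consistent when the largest cluster of instruments is valid.
#' Bandwidth follows a modified Silverman rule on the ratio spread scaled
#' by `bandwidth_factor`; the density is maximized on a 512-point grid over
#' mean +/- 3 sd of the ratios.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the Silverman-rule bandwidth
#'   (default 1)
#' @return an `mr_estimate`
#' @export
mr_weighted_mode <- function(data, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL, alpha = 0.05) {
  d <- check_uv(data)
  L <- length(d$bx)
  if (L < 3L) abort_insufficient("weighted mode requires at least 3 instruments")
  rw <- uv_ratios(d)
  beta <- weighted_mode_point(rw$r, rw$w, bandwidth_factor)
  stat <- function(dd) {
    rr <- uv_ratios(dd)
    weighted_mode_point(rr$r, rr$w, bandwidth_factor)
  }
  se <- boot_se(d, stat, n_boot, seed)
  new_mr_estimate("Weighted mode", beta, se, pval_z(beta, se), L, alpha, d$binary)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of horizontally pleiotropic instruments.  The
#' global test compares the observed weighted residual sum of squares
#' (against leave-one-out IVW predictions) with its parametric null
#' distribution; per-SNP outlier p-values come from the same simulation
#' with Bonferroni correction; when outliers are found, the causal estimate
#' is recomputed by IVW on the remaining instruments and a distortion test
#' compares the shift against random same-size exclusions.
#'
#' @inheritParams mr_ivw
#' @param n_sim parametric simulations for the null distribution (default
#'   1000)
#' @param outlier_alpha familywise level for outlier flagging (default 0.05)
#' @param seed RNG seed
#' @return an `mr_estimate` (outlier-corrected when outliers are found)
#'   with fields `global_pvalue`, `distortion_pvalue`, `outlier_ids` and
#'   `raw_estimate`
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed = NULL,
                      alpha = 0.05) {
  d <- check_uv(data)
  L <- length(d$bx)
  if (L < 4L) abort_insufficient("MR-PRESSO requires at least 4 instruments")
  w <- 1 / d$sy^2

  loo_slopes <- function(bx, by) {
    sxy <- sum(w * bx * by)
    sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  b_loo <- loo_slopes(d$bx, d$by)
  res_obs <- w * (d$by - b_loo * d$bx)^2
  rss_obs <- sum(res_obs)

  sim <- with_seed(seed, {
    bx_s <- matrix(stats::rnorm(n_sim * L, rep(d$bx, each = n_sim), rep(d$sx, each = n_sim)), n_sim, L)
    by_s <- matrix(stats::rnorm(n_sim * L, rep(b_loo * d$bx, each = n_sim), rep(d$sy, each = n_sim)), n_sim, L)
    W <- matrix(w, n_sim, L, byrow = TRUE)
    sxy <- rowSums(W * bx_s * by_s)
    sxx <- rowSums(W * bx_s^2)
    b_loo_s <- (sxy - W * bx_s * by_s) / (sxx - W * bx_s^2)
    res_s <- W * (by_s - b_loo_s * bx_s)^2
    list(res = res_s, rss = rowSums(res_s))
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + colSums(sim$res >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  outliers <- which(p_snp * L < outlier_alpha)

  raw <- mr_ivw(data, alpha = alpha)
  raw$method <- "MR-PRESSO (raw)"

  if (length(outliers) == 0L) {
    est <- raw
    est$method <- "MR-PRESSO"
    est$global_pvalue <- global_p
    est$distortion_pvalue <- NA_real_
    est$outlier_ids <- character()
    est$raw_estimate <- NULL
    return(est)
  }
  if (length(outliers) == L) {
    mr_abort("MR-PRESSO flagged every instrument as an outlier", "mrsuite_degenerate_outlier_error")
  }
  keep <- setdiff(seq_len(L), outliers)
  corrected <- mr_ivw(hs_subset(data, keep), alpha = alpha)
  corrected$method <- "MR-PRESSO (outlier-corrected)"

  # distortion: compare the observed shift against random exclusions of the
  # same size, resampled from all instruments
  n_out <- length(outliers)
  dist_obs <- (raw$beta - corrected$beta) / abs(corrected$beta)
  dist_sim <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(L, n_out)
      kb <- setdiff(seq_len(L), drop)
      bk <- sum(w[kb] * d$bx[kb] * d$by[kb]) / sum(w[kb] * d$bx[kb]^2)
      (raw$beta - bk) / abs(bk)
    }, numeric(1))
  })
  distortion_p <- (1 + sum(abs(dist_sim) >= abs(dist_obs))) / (n_sim + 1)

  corrected$global_pvalue <- global_p
  corrected$distortion_pvalue <- distortion_p
  corrected$outlier_ids <- d$ids[outliers]
  corrected$raw_estimate <- raw
  corrected
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (b_j - b_fixed)^2` with `w_j = 1/se_j^2` and the
#' fixed-effect pooled value as center; p-value from chi-square with
#' `L - 1` degrees of freedom; `I2 = max(0, (Q - df)/Q)` as a fraction.
#'
#' @param betas per-instrument (or per-cohort) estimates
#' @param ses their standard errors
#' @return list with `Q`, `df`, `pvalue`, `I2`
#' @export
cochran_q <- function(betas, ses) {
  if (length(betas) < 2L) mr_abort("Cochran's Q needs at least 2 estimates", "mrsuite_insufficient_data_error")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  df <- length(betas) - 1L
  list(
    Q = Q, df = df,
    pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
    I2 = if (Q > 0) max(0, (Q - df) / Q) else 0
  )
}

#' Instrument strength diagnostics
#'
#' Per-SNP F statistic `(beta_X/se_X)^2`; a mean F below 10 flags
#' conventionally weak instruments.
#'
#' @param data a `harmonized_set` with one exposure
#' @return list with `per_snp_F`, `mean_F`, `min_F`, `weak_flag`
#' @export
instrument_strength <- function(data) {
  d <- check_uv(data)
  if (!length(d$bx)) abort_insufficient("no instruments")
  f <- (d$bx / d$sx)^2
  list(per_snp_F = f, mean_F = mean(f), min_F = min(f), weak_flag = mean(f) < 10)
}

# variance explained by instruments in one trait (internal)
r2_trait <- function(beta, se, n, binary, eaf = NULL, case_fraction = NULL) {
  if (!binary) {
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  } else {
    if (is.null(eaf) || anyNA(eaf)) {
      abort_config("Steiger binary-trait conversion requires eaf for every instrument")
    }
    if (is.null(case_fraction)) {
      abort_config("Steiger binary-trait conversion requires case_fraction")
    }
    # observed-scale approximation: linearized log-odds effect times
    # genotype variance over phenotype variance cf(1-cf)
    sum(beta^2 * case_fraction * (1 - case_fraction) * 2 * eaf * (1 - eaf))
  }
}

#' MR Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome; causality is inferred to run from the trait in which they
#' explain more variance.  Binary traits use an observed-scale
#' approximation of r-squared from log-odds effects, allele frequency and
#' case fraction (flagged `approximate` in the result).  The test statistic
#' is a two-sample z-test on Fisher-transformed correlations.
#'
#' @param data a `harmonized_set` with one exposure
#' @param n_exposure,n_outcome GWAS sample sizes; defaults to the median of
#'   the per-variant `n` columns when present
#' @param case_fraction cases/(cases+controls) for a binary outcome
#' @return list with `r2_exposure`, `r2_outcome`, `direction_correct`,
#'   `z_statistic`, `pvalue`, `approximate`
#' @export
steiger_test <- function(data, n_exposure = NULL, n_outcome = NULL,
                         case_fraction = NULL) {
  d <- check_uv(data)
  n_exposure <- n_exposure %||% stats::median(data$n_X[, 1], na.rm = TRUE)
  n_outcome <- n_outcome %||% stats::median(data$n_Y, na.rm = TRUE)
  if (!is_scalar_number(n_exposure) || !is_scalar_number(n_outcome) ||
      n_exposure <= 3 || n_outcome <= 3) {
    abort_config("Steiger test requires positive sample sizes for both traits")
  }
  r2x <- r2_trait(d$bx, d$sx, n_exposure, data$binary_X[1], data$eaf, case_fraction)
  r2y <- r2_trait(d$by, d$sy, n_outcome, data$binary_Y, data$eaf, case_fraction)
  r2x <- min(r2x, 1)
  r2y <- min(r2y, 1)
  zx <- atanh(sqrt(r2x))
  zy <- atanh(sqrt(r2y))
  z <- (zx - zy) / sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(
    r2_exposure = r2x, r2_outcome = r2y,
    direction_correct = r2x > r2y,
    z_statistic = z, pvalue = 2 * stats::pnorm(-abs(z)),
    approximate = data$binary_X[1] || data$binary_Y
  )
}
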