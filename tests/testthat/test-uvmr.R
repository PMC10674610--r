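test_that("Wald ratio arithmetic, null behavior and error path", {
  e <- wald_ratio(0.10, 0.01, 0.05, 0.02)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
  expect_equal(e$odds_ratio, exp(0.5))

  null <- wald_ratio(1, 0.1, 0, 0.1)
  expect_equal(null$beta, 0)
  expect_equal(null$pvalue, 1)

  expect_error(wald_ratio(0, 0.1, 0.2, 0.1), class = "mrsuite_undefined_ratio_error")
})

test_that("second-order Wald SE matches a Monte-Carlo oracle for a strong instrument", {
  e <- wald_ratio(0.1, 0.01, 0.05, 0.02, second_order = TRUE)
  set.seed(101)
  draws <- rnorm(1e6, 0.05, 0.02) / rnorm(1e6, 0.1, 0.01)
  expect_lt(abs(e$se - sd(draws)) / sd(draws), 0.02)
})

test_that("IVW recovers a perfect-fit line with zero heterogeneity", {
  hs <- mrsuite:::hs_from_vectors(c(1, 2), c(0.1, 0.1), c(0.5, 1.0), c(0.1, 0.1))
  e <- mr_ivw(hs)
  expect_equal(e$beta, 0.5)
  expect_equal(e$Q, 0)
})

test_that("single-instrument IVW equals the Wald ratio exactly", {
  hs <- mrsuite:::hs_from_vectors(0.1, 0.01, 0.05, 0.02)
  expect_message(e <- mr_ivw(hs), "Wald ratio")
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_identical(e$beta, w$beta)
  expect_identical(e$se, w$se)
})

test_that("IVW and MR-Egger match a generic weighted-regression oracle to 1e-10", {
  hs <- uv_set(L = 20, beta = 0.4, seed = 5)
  d <- list(bx = hs$beta_X[, 1], by = hs$beta_Y, sy = hs$se_Y)
  w <- 1 / d$sy^2

  ivw <- mr_ivw(hs)
  fit0 <- lm(d$by ~ 0 + d$bx, weights = w)
  expect_equal(ivw$beta, unname(coef(fit0)[1]), tolerance = 1e-10)
  sig0 <- summary(fit0)$sigma
  se_oracle <- summary(fit0)$coefficients[1, 2] / sig0 * max(1, sig0)
  expect_equal(ivw$se, se_oracle, tolerance = 1e-10)

  egger <- mr_egger(hs)
  bx <- abs(d$bx)                        # orientation: all exposure effects >= 0
  by <- d$by * sign(d$bx)
  fit1 <- lm(by ~ bx, weights = w)
  expect_equal(egger$beta, unname(coef(fit1)[2]), tolerance = 1e-10)
  expect_equal(egger$egger_intercept, unname(coef(fit1)[1]), tolerance = 1e-10)
  sig1 <- summary(fit1)$sigma
  expect_equal(egger$se,
               summary(fit1)$coefficients[2, 2] / sig1 * max(1, sig1),
               tolerance = 1e-10)
})

test_that("MR-Egger recovers an exact line and a zero intercept on noiseless data", {
  hs <- mrsuite:::hs_from_vectors(c(1, 2, 3), rep(0.1, 3),
                                  c(0.7, 1.2, 1.7), rep(0.1, 3))
  e <- mr_egger(hs)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$egger_intercept, 0.2, tolerance = 1e-12)

  hs0 <- uv_set(L = 10, beta = 0.3, seed = 2, noise = FALSE, se_x = 0)
  e0 <- mr_egger(hs0)
  expect_equal(e0$egger_intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(mrsuite:::hs_from_vectors(1:2, c(1, 1), 1:2, c(1, 1))),
               class = "mrsuite_insufficient_instruments_error")
})

test_that("weighted median interpolates the 50th weight percentile", {
  # equal weights: plain median of the ratios
  hs <- mrsuite:::hs_from_vectors(rep(1, 3), rep(0.1, 3),
                                  c(0.4, 0.5, 0.9), rep(0.1, 3))
  e <- mr_weighted_median(hs, n_boot = 50, seed = 1)
  expect_equal(e$beta, 0.5, tolerance = 1e-9)

  # one instrument holding essentially all the weight dominates
  hs2 <- mrsuite:::hs_from_vectors(rep(1, 3), rep(0.1, 3),
                                   c(0.2, 0.8, 0.9), c(1e-4, 1, 1))
  e2 <- mr_weighted_median(hs2, n_boot = 50, seed = 1)
  expect_equal(e2$beta, 0.2, tolerance = 1e-6)
})

test_that("weighted-median bootstrap SE agrees with a larger independent bootstrap", {
  hs <- uv_set(L = 20, beta = 0.4, seed = 9, se_x = 0.02)
  e <- mr_weighted_median(hs, n_boot = 2000, seed = 77)
  # fresh, independently seeded bootstrap an order of magnitude larger
  d <- list(bx = hs$beta_X[, 1], sx = hs$se_X[, 1], by = hs$beta_Y, sy = hs$se_Y)
  set.seed(770077)
  big <- replicate(20000, {
    bx <- rnorm(20, d$bx, d$sx)
    by <- rnorm(20, d$by, d$sy)
    r <- by / bx
    mrsuite:::weighted_median_point(r, (abs(bx) / d$sy)^2)
  })
  expect_lt(abs(e$se - sd(big)) / sd(big), 0.10)
})

test_that("weighted mode finds the cluster, not the mean", {
  hs <- mrsuite:::hs_from_vectors(rep(1, 4), rep(0.05, 4),
                                  c(0.50, 0.50, 0.51, 0.90), rep(0.08, 4))
  e <- mr_weighted_mode(hs, n_boot = 50, seed = 1)
  expect_lt(abs(e$beta - 0.50), 0.02)

  # a point mass returns itself
  hs0 <- mrsuite:::hs_from_vectors(rep(1, 3), rep(0.05, 3),
                                   rep(0.5, 3), rep(0.05, 3))
  expect_equal(mr_weighted_mode(hs0, n_boot = 10, seed = 1)$beta, 0.5)
})

test_that("widening the mode bandwidth pulls a bimodal set toward the pooled center", {
  by <- c(0.20, 0.21, 0.22, 0.78, 0.80)
  hs <- mrsuite:::hs_from_vectors(rep(1, 5), rep(0.05, 5), by, rep(0.05, 5))
  est <- vapply(c(1, 2, 4, 8), function(phi) {
    mr_weighted_mode(hs, bandwidth_factor = phi, n_boot = 10, seed = 1)$beta
  }, numeric(1))
  center <- mean(by)
  gaps <- abs(est - center)
  expect_true(all(diff(gaps) <= 1e-9))   # monotone shrinkage toward the center
})

test_that("MR-PRESSO flags a planted outlier and repairs the estimate", {
  pleio <- rep(0, 20)
  pleio[7] <- 10 * 0.05                    # displaced by 10 SEs
  hs <- uv_set(L = 20, beta = 0.3, seed = 21, pleio = pleio)
  e <- mr_presso(hs, n_sim = 1000, seed = 5)
  expect_true(hs$variant_ids[7] %in% e$outlier_ids)
  expect_lt(abs(e$beta - 0.3), abs(e$raw_estimate$beta - 0.3))

  clean <- uv_set(L = 20, beta = 0.3, seed = 22)
  e0 <- mr_presso(clean, n_sim = 1000, seed = 5)
  expect_gt(e0$global_pvalue, 0.05)
  expect_length(e0$outlier_ids, 0)
  expect_error(mr_presso(uv_set(L = 3), n_sim = 10),
               class = "mrsuite_insufficient_instruments_error")
})

test_that("MR-PRESSO is bit-identical under a fixed seed", {
  hs <- uv_set(L = 15, beta = 0.3, seed = 31, pleio = c(rep(0, 14), 0.4))
  a <- mr_presso(hs, n_sim = 500, seed = 9)
  b <- mr_presso(hs, n_sim = 500, seed = 9)
  expect_identical(a, b)
})

test_that("Cochran's Q closed forms and clamped I-squared", {
  same <- cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.1))
  expect_equal(same$Q, 0)
  expect_equal(same$I2, 0)

  q <- cochran_q(c(0, 1), c(1, 1))
  expect_equal(q$Q, 0.5)
  expect_equal(q$I2, 0)
  expect_equal(q$pvalue, pchisq(0.5, 1, lower.tail = FALSE))

  expect_error(cochran_q(0.5, 0.1), class = "mrsuite_insufficient_data_error")
})

test_that("instrument F statistics and the weak-instrument flag", {
  hs <- mrsuite:::hs_from_vectors(c(0.1, 0.03), c(0.01, 0.01), c(0, 0), c(1, 1))
  d <- instrument_strength(hs)
  expect_equal(d$per_snp_F, c(100, 9))
  expect_equal(d$mean_F, 54.5)
  expect_false(d$weak_flag)

  weak <- instrument_strength(mrsuite:::hs_from_vectors(0.03, 0.01, 0, 1))
  expect_true(weak$weak_flag)
})

test_that("Steiger directionality: dominance, symmetry and the Fisher-z oracle", {
  st <- simulate_two_sample(simulation_config(L = 20, beta_XY_direct = 0.2, seed = 17))
  hs <- harmonize(st$tables$exposure, st$tables$outcome)
  s <- steiger_test(hs)
  expect_true(s$direction_correct)
  expect_lt(s$pvalue, 1e-6)

  # equal explained variance is exactly inconclusive
  hs_eq <- mrsuite:::hs_from_vectors(0.1, 0.02, 0.1, 0.02,
                                     n_X = 5000, n_Y = 5000)
  s_eq <- steiger_test(hs_eq)
  expect_equal(s_eq$z_statistic, 0)
  expect_equal(s_eq$pvalue, 1)

  # closed-form oracle for the two-sample z-test on Fisher-transformed r
  r2x <- 0.02; r2y <- 0.01; n <- 10000
  z_oracle <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) / sqrt(2 / (n - 3))
  p_oracle <- 2 * pnorm(-abs(z_oracle))
  tx <- sqrt(r2x * (n - 2) / (1 - r2x))  # invert r2 = t^2/(t^2 + n - 2)
  ty <- sqrt(r2y * (n - 2) / (1 - r2y))
  hs_o <- mrsuite:::hs_from_vectors(0.1, 0.1 / tx, 0.1, 0.1 / ty, n_X = n, n_Y = n)
  s_o <- steiger_test(hs_o)
  expect_equal(s_o$pvalue, p_oracle, tolerance = 1e-10)
})

test_that("ratio estimators are scale- and sign-equivariant", {
  hs <- uv_set(L = 15, beta = 0.4, seed = 3)
  for (c_mult in c(2, -0.5)) {
    hs2 <- hs
    hs2$beta_X <- hs$beta_X * c_mult
    hs2$se_X <- hs$se_X * abs(c_mult)
    expect_equal(mr_ivw(hs2)$beta, mr_ivw(hs)$beta / c_mult, tolerance = 1e-10)
    expect_equal(mr_weighted_median(hs2, n_boot = 10, seed = 1)$beta,
                 mr_weighted_median(hs, n_boot = 10, seed = 1)$beta / c_mult,
                 tolerance = 1e-10)
  }
  neg <- hs
  neg$beta_Y <- -hs$beta_Y
  a <- mr_ivw(hs); b <- mr_ivw(neg)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$Q, a$Q, tolerance = 1e-12)
  ea <- mr_egger(hs); eb <- mr_egger(neg)
  expect_equal(eb$intercept_pvalue, ea$intercept_pvalue, tolerance = 1e-12)
  fa <- instrument_strength(hs); fb <- instrument_strength(neg)
  expect_equal(fa$per_snp_F, fb$per_snp_F)
})

test_that("Egger with its intercept pinned to zero is fixed-effect IVW", {
  hs <- uv_set(L = 12, beta = 0.4, seed = 8)
  w <- 1 / hs$se_Y^2
  bx <- abs(hs$beta_X[, 1])
  by <- hs$beta_Y * sign(hs$beta_X[, 1])
  refit <- lm(by ~ 0 + bx, weights = w)    # the constrained regression
  expect_equal(unname(coef(refit)[1]), mr_ivw(hs, model = "fixed")$beta,
               tolerance = 1e-12)
})
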