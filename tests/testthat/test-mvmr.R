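test_that("MV-IVW recovers exact linear structure and matches the WLS oracle", {
  exact <- mv_set(L = 20, betas = c(0.3, -0.2), seed = 1, noise = FALSE, se_x = 0)
  e <- mvmr_ivw(exact)
  expect_equal(e$betas, c(0.3, -0.2), tolerance = 1e-10)

  noisy <- mv_set(L = 30, betas = c(0.3, -0.2), seed = 2)
  e2 <- mvmr_ivw(noisy)
  w <- 1 / noisy$se_Y^2
  fit <- lm(noisy$beta_Y ~ 0 + noisy$beta_X, weights = w)
  expect_equal(e2$betas, unname(coef(fit)), tolerance = 1e-10)
  sig <- summary(fit)$sigma
  expect_equal(e2$ses,
               unname(summary(fit)$coefficients[, 2]) / sig * max(1, sig),
               tolerance = 1e-10)
})

test_that("MV-IVW error paths: collinearity and too few instruments", {
  X <- cbind(1:10 / 10, 2 * (1:10 / 10))
  hs <- mrsuite:::hs_from_vectors(X, matrix(0.01, 10, 2), rnorm(10), rep(0.1, 10))
  expect_error(mvmr_ivw(hs), class = "mrsuite_collinearity_error")

  small <- mv_set(L = 2, betas = c(0.3, -0.2), seed = 3)
  expect_error(mvmr_ivw(small), class = "mrsuite_insufficient_instruments_error")
})

test_that("MVMR-Egger recovers a planted intercept and is orientation-idempotent", {
  exact <- mv_set(L = 20, betas = c(0.3, -0.2), seed = 4, noise = FALSE, se_x = 0)
  # plant a constant intercept on the orientation of the first exposure
  or_sign <- sign(exact$beta_X[, 1])
  exact$beta_Y <- exact$beta_Y + 0.1 * or_sign
  e <- mvmr_egger(exact)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$betas, c(0.3, -0.2), tolerance = 1e-10)

  # pre-orienting the data by hand leaves the result unchanged
  flip <- exact$beta_X[, 1] < 0
  pre <- exact
  pre$beta_X[flip, ] <- -pre$beta_X[flip, ]
  pre$beta_Y[flip] <- -pre$beta_Y[flip]
  e2 <- mvmr_egger(pre)
  expect_equal(e2$betas, e$betas, tolerance = 1e-12)
  expect_equal(e2$intercept, e$intercept, tolerance = 1e-12)
})

test_that("MVMR-Egger matches the weighted regression oracle with intercept", {
  noisy <- mv_set(L = 30, betas = c(0.3, -0.2), seed = 5)
  e <- mvmr_egger(noisy)
  flip <- noisy$beta_X[, 1] < 0
  X <- noisy$beta_X; X[flip, ] <- -X[flip, ]
  by <- ifelse(flip, -noisy$beta_Y, noisy$beta_Y)
  fit <- lm(by ~ X, weights = 1 / noisy$se_Y^2)
  expect_equal(e$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(e$betas, unname(coef(fit)[-1]), tolerance = 1e-10)
})

test_that("MVMR-median is robust, consistent with the univariable median, and exact on clean data", {
  exact <- mv_set(L = 20, betas = c(0.3, -0.2), seed = 6, noise = FALSE, se_x = 0)
  e <- mvmr_median(exact, n_boot = 20, seed = 1)
  expect_equal(e$betas, c(0.3, -0.2), tolerance = 1e-6)

  # K = 1: close to the univariable weighted median on the same data
  uv <- uv_set(L = 30, beta = 0.4, seed = 7)
  m_mv <- mvmr_median(uv, n_boot = 20, seed = 1)
  m_uv <- mr_weighted_median(uv, n_boot = 20, seed = 1)
  expect_lt(abs(m_mv$betas[1] - m_uv$beta), 0.05)

  # a gross outlier distorts the median fit less than MV-IVW on average
  bias <- vapply(1:25, function(s) {
    out <- mv_set(L = 30, betas = c(0.3, -0.2), seed = 200 + s,
                  intercepts = c(rep(0, 29), 0.6))
    med <- mvmr_median(out, n_boot = 2, seed = 1)
    ivw <- mvmr_ivw(out)
    c(sum(abs(med$betas - c(0.3, -0.2))), sum(abs(ivw$betas - c(0.3, -0.2))))
  }, numeric(2))
  expect_lt(mean(bias[1, ]), mean(bias[2, ]))
})

test_that("MVMR-Lasso: penalty limit, planted pleiotropy, and the tuning rule", {
  noisy <- mv_set(L = 30, betas = c(0.3, -0.2), seed = 9)
  inf_pen <- mvmr_lasso(noisy, lambda_grid = 1e9)
  ivw <- mvmr_ivw(noisy)
  expect_equal(inf_pen$betas, ivw$betas, tolerance = 1e-12)
  expect_length(inf_pen$penalized_snp_ids, 0)

  planted <- mv_set(L = 30, betas = c(0.3, -0.2), seed = 10,
                    intercepts = c(rep(0, 29), 8 * 0.05))
  e <- mvmr_lasso(planted)
  expect_true(planted$variant_ids[30] %in% e$penalized_snp_ids)
  # the stopping rule settles at the largest workable penalty, never the floor
  expect_gt(e$lambda, 0)
  grid <- exp(seq(log(500), log(0.5), length.out = 50))
  e2 <- mvmr_lasso(planted, lambda_grid = grid)
  expect_gt(e2$lambda, min(grid))
})

test_that("conditional F: collinear columns are weak, orthogonal columns match univariable F", {
  # two nearly identical exposures carry no conditional strength
  withr::with_seed(11, {
    b <- runif(30, 0.05, 0.15)
    X <- cbind(b, b + rnorm(30, 0, 1e-4))
  })
  hs <- mrsuite:::hs_from_vectors(X, matrix(0.01, 30, 2), rnorm(30), rep(0.1, 30))
  cf <- conditional_f(hs)
  expect_lt(max(cf), 1)

  # orthogonal block-diagonal design: conditional ~ univariable strength
  withr::with_seed(12, {
    b1 <- c(runif(50, 0.08, 0.15) * sample(c(-1, 1), 50, TRUE), rep(0, 50))
    b2 <- c(rep(0, 50), runif(50, 0.08, 0.15) * sample(c(-1, 1), 50, TRUE))
  })
  X2 <- cbind(b1, b2)
  hs2 <- mrsuite:::hs_from_vectors(X2, matrix(0.01, 100, 2), rnorm(100), rep(0.1, 100))
  cf2 <- conditional_f(hs2)
  uni_F <- colMeans((X2 / 0.01)^2)
  expect_lt(abs(cf2[[1]] - uni_F[1]) / uni_F[1], 0.10)
  expect_lt(abs(cf2[[2]] - uni_F[2]) / uni_F[2], 0.10)

  # the outcome column plays no role
  hs3 <- hs2
  hs3$beta_Y <- hs2$beta_Y * 10
  expect_equal(conditional_f(hs3), cf2)
})

test_that("all four MVMR estimators agree on noiseless exact-fit data", {
  exact <- mv_set(L = 25, betas = c(0.3, -0.2), seed = 13, noise = FALSE, se_x = 0)
  truth <- c(0.3, -0.2)
  expect_equal(mvmr_ivw(exact)$betas, truth, tolerance = 1e-8)
  expect_equal(mvmr_egger(exact)$betas, truth, tolerance = 1e-8)
  expect_equal(mvmr_median(exact, n_boot = 10, seed = 1)$betas, truth, tolerance = 1e-6)
  expect_equal(mvmr_lasso(exact)$betas, truth, tolerance = 1e-8)
})

test_that("a pure-noise co-exposure barely moves the primary MV-IVW estimate", {
  moved <- vapply(1:40, function(s) {
    uv <- uv_set(L = 30, beta = 0.4, seed = 100 + s)
    withr::with_seed(s, noise_col <- rnorm(30, 0, 0.02))
    mv <- mrsuite:::hs_from_vectors(
      cbind(uv$beta_X[, 1], noise_col),
      cbind(uv$se_X[, 1], rep(0.02, 30)),
      uv$beta_Y, uv$se_Y
    )
    e_uv <- mr_ivw(uv)
    e_mv <- mvmr_ivw(mv)
    abs(e_mv$betas[1] - e_uv$beta) / sqrt(e_mv$ses[1]^2 + e_uv$se^2)
  }, numeric(1))
  expect_gt(mean(moved < 1), 0.9)
})
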