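# Summary-level fixtures built directly from the sampling model of
# two-sample MR: instrument-exposure effects with their SEs, and
# instrument-outcome effects generated from a known causal slope (plus
# optional pleiotropy).  Fast enough for estimator unit tests; the
# individual-level generator in the package covers end-to-end realism.

uv_set <- function(L = 20, beta = 0.5, seed = 1, se_y = 0.05, se_x = 0.01,
                   pleio = rep(0, L), noise = TRUE) {
  withr::with_seed(seed, {
    bx_true <- runif(L, 0.05, 0.15) * sample(c(-1, 1), L, replace = TRUE)
    bx <- bx_true + rnorm(L, 0, se_x)
    by <- beta * bx_true + pleio + if (noise) rnorm(L, 0, se_y) else 0
    mrsuite:::hs_from_vectors(bx, rep(se_x, L), by, rep(se_y, L))
  })
}

mv_set <- function(L = 30, betas = c(0.3, -0.2), seed = 1, se_y = 0.05,
                   se_x = 0.01, intercepts = rep(0, L), noise = TRUE) {
  K <- length(betas)
  withr::with_seed(seed, {
    X <- matrix(runif(L * K, 0.05, 0.15) * sample(c(-1, 1), L * K, replace = TRUE), L, K)
    by <- drop(X %*% betas) + intercepts + if (noise) rnorm(L, 0, se_y) else 0
    mrsuite:::hs_from_vectors(X, matrix(se_x, L, K), by, rep(se_y, L))
  })
}

# build a gwas_table from marginal effects plus sampling noise
toy_table <- function(ids, marg, se, n, trait, seed, binary = FALSE) {
  withr::with_seed(seed, {
    beta <- marg + rnorm(length(marg), 0, se)
    z <- beta / se
    gwas_table(data.frame(
      variant_id = ids, effect_allele = "A", other_allele = "G",
      eaf = 0.3, beta = beta, se = se,
      pvalue = pmax(2 * pnorm(-abs(z)), 1e-300), n = n,
      stringsAsFactors = FALSE
    ), trait = trait, binary = binary)
  })
}

# A consistent multi-mediator world written as summary statistics:
# exposure X with 40 instruments; mediators M1 (proportion 0.5),
# M2 (proportion 0.2) and M3 (reverse-causal, no outcome effect), each
# with 40 instruments of their own; outcome Y assembled from the causal
# chain.  Tables are written as TSVs so the pipeline exercises its file
# interface end to end.
toy_world <- function(dir = tempfile("world"), seed = 42, noise_seed = seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Lb <- 40
  blocks <- list(X = 1:Lb, M1 = Lb + 1:Lb, M2 = 2 * Lb + 1:Lb, M3 = 3 * Lb + 1:Lb)
  Ltot <- 4 * Lb
  ids <- sprintf("rs%04d", seq_len(Ltot))
  se <- 0.012
  n <- 25000

  b_XM1 <- -0.5; b_M1Y <- 0.5     # indirect -0.25
  b_XM2 <- -0.25; b_M2Y <- 0.4    # indirect -0.10
  b_XM3 <- -0.4; b_M3X <- -0.35   # bidirectional, no M3 -> Y effect
  direct <- -0.15
  total <- direct + b_XM1 * b_M1Y + b_XM2 * b_M2Y  # -0.5

  withr::with_seed(seed, {
    eff <- function(block) {
      v <- numeric(Ltot)
      v[blocks[[block]]] <- runif(Lb, 0.08, 0.16) * sample(c(-1, 1), Lb, replace = TRUE)
      v
    }
    g_x <- eff("X"); g_m1 <- eff("M1"); g_m2 <- eff("M2"); g_m3 <- eff("M3")

    marg_X <- g_x + b_M3X * g_m3
    marg_M1 <- b_XM1 * marg_X + g_m1
    marg_M2 <- b_XM2 * marg_X + g_m2
    marg_M3 <- b_XM3 * marg_X + g_m3
    marg_Y <- direct * marg_X + b_M1Y * marg_M1 + b_M2Y * marg_M2

    tabs <- list(
      exposure = toy_table(ids, marg_X, se, n, "exposure", noise_seed + 1),
      M1 = toy_table(ids, marg_M1, se, n, "M1", noise_seed + 2),
      M2 = toy_table(ids, marg_M2, se, n, "M2", noise_seed + 3),
      M3 = toy_table(ids, marg_M3, se, n, "M3", noise_seed + 4),
      outcome = toy_table(ids, marg_Y, se, n, "outcome", noise_seed + 5)
    )
    paths <- lapply(names(tabs), function(nm) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(as.data.frame(tabs[[nm]]), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p
    })
    names(paths) <- names(tabs)
    list(dir = dir, paths = paths, tables = tabs,
         truth = list(total = total, prop_M1 = b_XM1 * b_M1Y / total,
                      prop_M2 = b_XM2 * b_M2Y / total))
  })
}
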