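write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(
    SNP = c("rs1", "rs2", "rs3"),
    A1 = c("A", "C", "T"), A2 = c("G", "T", "C"),
    freq = c(0.2, 0.4, 0.3),
    b = c(0.10, -0.05, 0.02), se = c(0.01, 0.02, 0.01),
    p = c(1e-20, 1e-9, 0.03), N = c(1000, 1000, 1000),
    stringsAsFactors = FALSE
  )
}

cmap <- c(variant_id = "SNP", effect_allele = "A1", other_allele = "A2",
          eaf = "freq", beta = "b", se = "se", pvalue = "p", n = "N")

test_that("a well-formed table parses row for row with an empty skip report", {
  tab <- read_gwas_table(write_tsv(base_rows()), cmap, "carb")
  expect_s3_class(tab, "gwas_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$beta, c(0.10, -0.05, 0.02))
  expect_equal(tab$effect_allele, c("A", "C", "T"))
  expect_true(all(skip_report(tab) == 0L))
})

test_that("invalid rows are dropped and counted by cause", {
  rows <- base_rows()
  rows$se[2] <- 0                          # non-positive SE
  rows <- rbind(rows, rows[1, ], rows[1, ])  # one duplicate, one indel
  rows$SNP[5] <- "rs9"
  rows$A1[5] <- "AT"                       # indel-like allele
  path <- write_tsv(rows)
  tab <- read_gwas_table(path, cmap, "carb")
  rep <- skip_report(tab)
  expect_equal(nrow(tab), 2L)
  expect_equal(unname(rep[["nonpositive_se"]]), 1L)
  expect_equal(unname(rep[["bad_allele"]]), 1L)
})

test_that("configuration errors name the offending column", {
  rows <- base_rows()
  err <- expect_error(
    read_gwas_table(write_tsv(rows), c(cmap, beta = "nonexistent"), "carb"),
    class = "mrsuite_config_error"
  )
  expect_match(conditionMessage(err), "nonexistent")
  # beta mapped onto a text column: nothing parses
  expect_error(
    read_gwas_table(write_tsv(rows), c(cmap, beta = "A1"), "carb"),
    class = "mrsuite_config_error"
  )
})

mk_tab <- function(df, trait, binary = FALSE) gwas_table(df, trait, binary)

test_that("harmonization aligns swapped outcome alleles by negating beta", {
  expo <- mk_tab(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "G",
    eaf = 0.2, beta = 0.10, se = 0.01, pvalue = 1e-10, n = 100
  ), "exposure")
  outc <- mk_tab(data.frame(
    variant_id = "rs1", effect_allele = "G", other_allele = "A",
    eaf = 0.8, beta = -0.05, se = 0.02, pvalue = 0.01, n = 100
  ), "outcome")
  hs <- harmonize(expo, outc)
  expect_equal(hs$beta_Y, 0.05)
  expect_equal(hs$variant_ids, "rs1")
})

test_that("palindromic and incompatible variants are dropped per the rules", {
  expo <- mk_tab(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "A"), other_allele = c("T", "G", "G"),
    eaf = c(0.2, 0.3, 0.3), beta = c(0.1, 0.2, 0.3), se = rep(0.01, 3),
    pvalue = rep(1e-10, 3), n = rep(100, 3)
  ), "exposure")
  outc <- mk_tab(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "A"), other_allele = c("T", "G", "C"),
    eaf = c(0.2, 0.3, 0.3), beta = c(0.1, 0.2, 0.3), se = rep(0.01, 3),
    pvalue = rep(0.5, 3), n = rep(100, 3)
  ), "outcome")
  hs <- harmonize(expo, outc, palindrome_mode = "drop")
  expect_equal(hs$variant_ids, "rs2")  # rs1 palindromic, rs3 incompatible
  expect_equal(unname(hs$drop_log[["palindromic"]]), 1L)
  expect_equal(unname(hs$drop_log[["incompatible"]]), 1L)
})

test_that("infer_by_eaf resolves palindromic strand and refuses the ambiguity band", {
  expo <- mk_tab(data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = "A", other_allele = "T",
    eaf = c(0.2, 0.5), beta = c(0.1, 0.1), se = 0.01, pvalue = 1e-10, n = 100
  ), "exposure")
  # rs1 reported on the other strand: its A frequency is 0.8
  outc <- mk_tab(data.frame(
    variant_id = c("rs1", "rs2"), effect_allele = "A", other_allele = "T",
    eaf = c(0.8, 0.5), beta = c(0.3, 0.3), se = 0.02, pvalue = 0.5, n = 100
  ), "outcome")
  hs <- harmonize(expo, outc, palindrome_mode = "infer_by_eaf")
  expect_equal(hs$variant_ids, "rs1")      # rs2 inside the ambiguity band
  expect_equal(hs$beta_Y, -0.3)            # strand flip negates the effect
  expect_equal(unname(hs$drop_log[["ambiguous_eaf"]]), 1L)
})

test_that("harmonization is involutive and invariant to outcome allele coding", {
  st <- simulate_two_sample(simulation_config(L = 15, n_exposure = 2000,
    n_outcome = 2000, beta_XY_direct = 0.3, seed = 11))
  expo <- st$tables$exposure
  outc <- st$tables$outcome
  hs <- harmonize(expo, outc)

  # re-harmonizing the aligned data changes nothing
  realigned <- as.data.frame(expo)
  realigned$beta <- hs$beta_X[, 1][match(realigned$variant_id, hs$variant_ids)]
  out2 <- as.data.frame(outc)
  m <- match(hs$variant_ids, out2$variant_id)
  aligned_out <- data.frame(
    variant_id = hs$variant_ids,
    effect_allele = expo$effect_allele[match(hs$variant_ids, expo$variant_id)],
    other_allele = expo$other_allele[match(hs$variant_ids, expo$variant_id)],
    eaf = hs$eaf, beta = hs$beta_Y, se = hs$se_Y,
    pvalue = out2$pvalue[m], n = out2$n[m]
  )
  hs2 <- harmonize(expo, mk_tab(aligned_out, "outcome"))
  expect_equal(hs2$beta_Y, hs$beta_Y)
  expect_equal(hs2$variant_ids, hs$variant_ids)

  # flipping the reported effect allele of every outcome row is a no-op
  flipped <- as.data.frame(outc)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  hs3 <- harmonize(expo, mk_tab(flipped, "outcome"))
  expect_equal(hs3$beta_Y, hs$beta_Y)
  expect_equal(hs3$eaf, hs$eaf)
})

sel_tab <- function(p, ids = paste0("rs", seq_along(p))) {
  mk_tab(data.frame(
    variant_id = ids, effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.01, pvalue = p, n = 1000
  ), "trait")
}

test_that("instrument selection applies the significance threshold and greedy pruning", {
  res <- select_instruments(sel_tab(c(1e-9, 1e-7)))
  expect_equal(res$instruments, "rs1")

  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  res2 <- select_instruments(sel_tab(c(1e-10, 1e-9)), ld_matrix = ld)
  expect_equal(res2$instruments, "rs1")

  expect_error(select_instruments(sel_tab(c(0.5, 0.9))),
               class = "mrsuite_insufficient_instruments_error")
})

test_that("greedy pruning matches an independent oracle and ignores row order", {
  set.seed(7)
  n <- 6
  ids <- paste0("rs", 1:n)
  p <- sort(runif(n, 1e-12, 1e-9))
  r2 <- matrix(runif(n * n, 0, 0.8), n, n, dimnames = list(ids, ids))
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  thr <- 0.4

  res <- select_instruments(sel_tab(p, ids), selection_config(ld_r2_threshold = thr),
                            ld_matrix = r2)

  # independent re-derivation: walk candidates by ascending p (ties by id),
  # keep those compatible with everything already kept
  oracle <- character()
  for (v in ids[order(p, ids)]) {
    if (!length(oracle) || all(r2[v, oracle] < thr)) oracle <- c(oracle, v)
  }
  expect_equal(res$instruments, oracle)

  # validity and maximality of the retained set
  kept <- res$instruments
  off <- r2[kept, kept][upper.tri(diag(length(kept)))]
  expect_true(all(off < thr))
  for (v in setdiff(ids, kept)) expect_true(any(r2[v, kept] >= thr))

  # row order of the input is irrelevant
  shuf <- sel_tab(p, ids)
  perm <- c(4, 2, 6, 1, 3, 5)
  shuf2 <- gwas_table(as.data.frame(shuf)[perm, ], "trait")
  res_shuf <- select_instruments(shuf2, selection_config(ld_r2_threshold = thr),
                                 ld_matrix = r2)
  expect_equal(res_shuf$instruments, res$instruments)
})

test_that("exclusion lists and proxy substitution are honored in order", {
  # rs3 misses genome-wide significance on its own and only enters as rs1's proxy
  tab <- sel_tab(c(1e-10, 1e-9, 1e-7), ids = c("rs1", "rs2", "rs3"))
  proxies <- data.frame(variant_id = "rs1", proxy_id = "rs3", r2 = 0.95)
  cfg <- selection_config(excluded_variants = "rs1", proxy_table = proxies)
  res <- select_instruments(tab, cfg)
  expect_false("rs1" %in% res$instruments)
  expect_true("rs3" %in% res$instruments)
  expect_true(any(grepl("proxy substitution", res$audit)))
})

test_that("harmonized sets serialize to one tidy row per variant", {
  st <- simulate_two_sample(simulation_config(L = 8, n_exposure = 1000,
    n_outcome = 1000, seed = 3))
  hs <- harmonize(st$tables$exposure, st$tables$outcome)
  df <- harmonized_as_data_frame(hs)
  expect_equal(nrow(df), n_variants(hs))
  expect_true(all(c("beta_exposure", "beta_outcome") %in% names(df)))
})
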