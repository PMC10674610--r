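#' GWAS summary-association tables
#'
#' A `gwas_table` is a data frame with one row per variant and columns
#' `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pvalue`, `n`.  `beta` is the per-allele effect in SD units for
#' continuous traits and on the log-odds scale for binary traits.  Trait
#' label and binary flag travel as attributes so downstream estimators can
#' report odds ratios where appropriate.
#'
#' @param df data frame holding the eight standard columns
#' @param trait trait label
#' @param binary logical; effects on the log-odds scale
#' @return a validated `gwas_table`
#' @export
gwas_table <- function(df, trait, binary = FALSE) {
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_config(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(df$eaf)) df$eaf <- NA_real_
  if (is.null(df$n)) df$n <- NA_real_
  df <- df[, c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se", "pvalue", "n")]
  df$variant_id <- as.character(df$variant_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  if (anyDuplicated(df$variant_id)) {
    abort_config(sprintf("duplicated variant_id in trait '%s'", trait))
  }
  bad_se <- !is.finite(df$se) | df$se <= 0
  if (any(bad_se)) abort_config("all standard errors must be finite and > 0")
  bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  if (any(bad_eaf)) abort_config("eaf must lie in [0, 1]")
  if (any(df$effect_allele == df$other_allele)) {
    abort_config("effect and other allele must differ")
  }
  structure(df,
    class = c("gwas_table", "data.frame"),
    trait = trait, binary = isTRUE(binary)
  )
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf(
    "<gwas_table> trait '%s' (%s), %d variants\n",
    attr(x, "trait"), if (attr(x, "binary")) "binary" else "continuous", nrow(x)
  ))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

trait_label <- function(x) attr(x, "trait")
is_binary_trait <- function(x) isTRUE(attr(x, "binary"))

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab or comma separated, header required) and
#' maps its columns onto the standard schema.  Alleles are upper-cased;
#' multi-allelic or indel records (alleles other than a single A/C/G/T) and
#' rows with non-positive SE or unparseable numeric fields are dropped and
#' counted in the attached skip report.
#'
#' @param path file path
#' @param column_map named character vector mapping standard names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`) to the file's column names; `eaf` and `n` are optional
#' @param trait_label trait label attached to the result
#' @param binary logical; effects are log odds ratios
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#' @return a `gwas_table`; the drop counts are available via
#'   `skip_report()`
#' @export
read_gwas_table <- function(path, column_map = NULL, trait_label = "trait",
                            binary = FALSE, sep = NULL) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE, quote = "\"",
    comment.char = ""
  )
  std <- c(
    variant_id = "variant_id", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf", beta = "beta",
    se = "se", pvalue = "pvalue", n = "n"
  )
  if (!is.null(column_map)) std[names(column_map)] <- column_map
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  for (col in required) {
    if (!std[[col]] %in% names(raw)) {
      abort_config(sprintf("mapped column '%s' (for %s) not present in %s", std[[col]], col, path))
    }
  }
  out <- data.frame(
    variant_id = raw[[std[["variant_id"]]]],
    effect_allele = toupper(raw[[std[["effect_allele"]]]]),
    other_allele = toupper(raw[[std[["other_allele"]]]]),
    stringsAsFactors = FALSE
  )
  num <- function(col) {
    if (!std[[col]] %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[std[[col]]]]))
  }
  out$eaf <- num("eaf")
  out$beta <- num("beta")
  out$se <- num("se")
  out$pvalue <- num("pvalue")
  out$n <- num("n")

  skip <- c(
    bad_numeric = 0L, nonpositive_se = 0L, bad_allele = 0L,
    bad_pvalue = 0L, duplicate_id = 0L
  )
  bad_numeric <- !is.finite(out$beta) | !is.finite(out$se) | !is.finite(out$pvalue)
  if (all(bad_numeric) && nrow(out) > 0) {
    abort_config(sprintf(
      "column mapping for '%s' yields no parseable numeric data (beta/se/pvalue)", path
    ))
  }
  skip[["bad_numeric"]] <- sum(bad_numeric)
  out <- out[!bad_numeric, , drop = FALSE]

  bad_se <- out$se <= 0
  skip[["nonpositive_se"]] <- sum(bad_se)
  out <- out[!bad_se, , drop = FALSE]

  single_base <- function(a) a %in% c("A", "C", "G", "T")
  bad_allele <- !single_base(out$effect_allele) | !single_base(out$other_allele) |
    out$effect_allele == out$other_allele
  skip[["bad_allele"]] <- sum(bad_allele)
  out <- out[!bad_allele, , drop = FALSE]

  bad_p <- out$pvalue <= 0 | out$pvalue > 1
  skip[["bad_pvalue"]] <- sum(bad_p)
  out <- out[!bad_p, , drop = FALSE]

  dup <- duplicated(out$variant_id)
  skip[["duplicate_id"]] <- sum(dup)
  out <- out[!dup, , drop = FALSE]

  if (nrow(out) == 0L) {
    abort_empty(sprintf("no usable rows left in %s after filtering", path))
  }
  tab <- gwas_table(out, trait = trait_label, binary = binary)
  attr(tab, "skip_report") <- skip
  tab
}

#' Skip report of a parsed table
#' @param x a `gwas_table` returned by [read_gwas_table()]
#' @return named integer vector of per-cause drop counts
#' @export
skip_report <- function(x) attr(x, "skip_report") %||% c(
  bad_numeric = 0L, nonpositive_se = 0L, bad_allele = 0L,
  bad_pvalue = 0L, duplicate_id = 0L
)

#' Instrument-selection configuration
#'
#' @param p_threshold genome-wide significance cutoff (default 5e-8)
#' @param ld_r2_threshold LD pruning cutoff on r-squared (default 0.001)
#' @param ld_window_kb pruning window in kb, honored when positions are
#'   available in the LD matrix metadata (default 10000)
#' @param excluded_variants variant IDs to drop (e.g. confounder-associated)
#' @param proxy_table data frame with columns `variant_id`, `proxy_id`, `r2`
#' @param min_proxy_r2 minimum LD for proxy substitution (default 0.8)
#' @return a `selection_config` list
#' @export
selection_config <- function(p_threshold = 5e-8, ld_r2_threshold = 0.001,
                             ld_window_kb = 10000, excluded_variants = character(),
                             proxy_table = NULL, min_proxy_r2 = 0.8) {
  if (!is_scalar_number(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    abort_config("p_threshold must lie in (0, 1)")
  }
  if (!is_scalar_number(ld_r2_threshold) || ld_r2_threshold < 0 || ld_r2_threshold > 1) {
    abort_config("ld_r2_threshold must lie in [0, 1]")
  }
  if (min_proxy_r2 < ld_r2_threshold) {
    abort_config("min_proxy_r2 must be >= ld_r2_threshold")
  }
  if (!is.null(proxy_table)) {
    need <- c("variant_id", "proxy_id", "r2")
    if (!all(need %in% names(proxy_table))) {
      abort_config("proxy_table needs columns variant_id, proxy_id, r2")
    }
  }
  structure(list(
    p_threshold = p_threshold,
    ld_r2_threshold = ld_r2_threshold,
    ld_window_kb = ld_window_kb,
    excluded_variants = as.character(excluded_variants),
    proxy_table = proxy_table,
    min_proxy_r2 = min_proxy_r2
  ), class = "selection_config")
}

#' Select genetic instruments from one trait's summary statistics
#'
#' Applies the study-style instrument filter: genome-wide significance,
#' removal of excluded (e.g. confounder-associated) variants, proxy
#' substitution for excluded/missing variants with a proxy at
#' `r2 > min_proxy_r2`, and greedy LD pruning by ascending p-value so that
#' no retained pair has `r2 >= ld_r2_threshold`.  Ties on p-value are broken
#' lexicographically by variant ID so the result is independent of row
#' order.
#'
#' @param records a `gwas_table`
#' @param config a [selection_config()]
#' @param ld_matrix optional symmetric r-squared matrix with variant IDs as
#'   dimnames, covering all p-passing candidates; when absent the candidates
#'   are assumed pre-pruned and a warning is recorded in the audit log
#' @return list with `instruments` (character IDs in selection order) and
#'   `audit` (character log)
#' @export
select_instruments <- function(records, config = selection_config(), ld_matrix = NULL) {
  audit <- character()
  df <- as.data.frame(records)
  pass <- df[df$pvalue < config$p_threshold, , drop = FALSE]
  audit <- c(audit, sprintf(
    "%d of %d variants pass p < %.3g", nrow(pass), nrow(df), config$p_threshold
  ))

  excl <- intersect(pass$variant_id, config$excluded_variants)
  if (length(excl)) {
    audit <- c(audit, sprintf("excluded %d variant(s): %s", length(excl), paste(excl, collapse = ", ")))
    pass <- pass[!pass$variant_id %in% excl, , drop = FALSE]
  }

  # proxy substitution: excluded (or absent-from-outcome) variants with a
  # strong proxy re-enter under the proxy ID
  if (!is.null(config$proxy_table) && length(excl)) {
    pt <- config$proxy_table
    for (v in excl) {
      hit <- pt[pt$variant_id == v & pt$r2 > config$min_proxy_r2, , drop = FALSE]
      if (nrow(hit)) {
        best <- hit[which.max(hit$r2), ]
        prow <- df[df$variant_id == best$proxy_id, , drop = FALSE]
        if (nrow(prow) && !best$proxy_id %in% pass$variant_id) {
          pass <- rbind(pass, prow)
          audit <- c(audit, sprintf(
            "proxy substitution: %s -> %s (r2 = %.3f)", v, best$proxy_id, best$r2
          ))
        }
      }
    }
  }

  if (nrow(pass) == 0L) abort_insufficient("no instruments retained after filtering")

  ord <- order(pass$pvalue, pass$variant_id)
  pass <- pass[ord, , drop = FALSE]

  if (is.null(ld_matrix)) {
    audit <- c(audit, "no LD matrix supplied; candidates assumed pre-pruned")
    keep <- pass$variant_id
  } else {
    missing_ld <- setdiff(pass$variant_id, rownames(ld_matrix))
    if (length(missing_ld)) {
      abort_config(sprintf(
        "LD matrix does not cover candidate(s): %s", paste(missing_ld, collapse = ", ")
      ))
    }
    keep <- character()
    for (v in pass$variant_id) {
      if (!length(keep) || all(ld_matrix[v, keep] < config$ld_r2_threshold)) {
        keep <- c(keep, v)
      }
    }
    audit <- c(audit, sprintf(
      "greedy LD pruning at r2 < %.4g retained %d of %d candidates",
      config$ld_r2_threshold, length(keep), nrow(pass)
    ))
  }
  if (!length(keep)) abort_insufficient("no instruments retained after LD pruning")
  list(instruments = keep, audit = audit)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every trait's per-variant effect to the effect allele of the first
#' exposure.  Outcome (or co-exposure) rows whose effect/other alleles are
#' swapped relative to the reference have beta negated and eaf replaced by
#' 1 - eaf.  Palindromic variants (A/T or C/G) are dropped under
#' `palindrome_mode = "drop"`, or aligned by comparing allele frequencies to
#' 0.5 under `"infer_by_eaf"` (variants whose eaf falls inside the ambiguity
#' band on either side are dropped as unresolvable).  Variants with
#' incompatible allele pairs are dropped.  Variant order follows the first
#' exposure's table.
#'
#' @param exposures a `gwas_table` or list of them (first entry is the
#'   reference exposure)
#' @param outcome a `gwas_table`
#' @param palindrome_mode `"drop"` (default) or `"infer_by_eaf"`
#' @param eaf_ambiguity_band frequency interval around 0.5 within which
#'   strand inference is refused (default `c(0.42, 0.58)`)
#' @return a `harmonized_set`: list with `exposure_names`, `outcome_name`,
#'   `variant_ids`, `beta_X`/`se_X` (L x K matrices), `beta_Y`/`se_Y`,
#'   `binary_X`/`binary_Y`, `eaf` (reference-exposure eaf), `n_X`/`n_Y`,
#'   and `drop_log` (per-cause counts)
#' @export
harmonize <- function(exposures, outcome,
                      palindrome_mode = c("drop", "infer_by_eaf"),
                      eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_mode <- match.arg(palindrome_mode)
  if (inherits(exposures, "gwas_table")) exposures <- list(exposures)
  K <- length(exposures)
  if (K < 1) abort_config("at least one exposure table is required")

  ref <- as.data.frame(exposures[[1]])
  traits <- c(exposures[-1], list(outcome))
  shared <- ref$variant_id
  for (tr in traits) shared <- intersect(shared, tr$variant_id)
  drop_log <- c(not_shared = length(ref$variant_id) - length(shared),
                palindromic = 0L, ambiguous_eaf = 0L, incompatible = 0L)
  if (!length(shared)) {
    abort_empty(sprintf(
      "no variants shared across all traits (drops: %s)",
      paste(names(drop_log), drop_log, sep = "=", collapse = ", ")
    ))
  }
  # preserve first exposure's order
  shared <- ref$variant_id[ref$variant_id %in% shared]
  ref <- ref[match(shared, ref$variant_id), , drop = FALSE]

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_palindromic <- function(a1, a2) comp[a1] == a2

  # align one trait's rows (matched to `shared`) to the reference alleles;
  # returns aligned data frame plus per-row keep/drop decisions
  align <- function(tab) {
    d <- as.data.frame(tab)
    d <- d[match(shared, d$variant_id), , drop = FALSE]
    status <- rep("ok", nrow(d))
    same <- d$effect_allele == ref$effect_allele & d$other_allele == ref$other_allele
    swapped <- d$effect_allele == ref$other_allele & d$other_allele == ref$effect_allele
    flip_same <- comp[d$effect_allele] == ref$effect_allele &
      comp[d$other_allele] == ref$other_allele
    flip_swapped <- comp[d$effect_allele] == ref$other_allele &
      comp[d$other_allele] == ref$effect_allele
    pal <- is_palindromic(ref$effect_allele, ref$other_allele)

    for (i in seq_len(nrow(d))) {
      if (pal[i]) {
        if (palindrome_mode == "drop") {
          status[i] <- "palindromic"
        } else {
          # infer strand by comparing frequencies to 0.5
          f_ref <- ref$eaf[i]
          f_i <- d$eaf[i]
          amb <- function(f) {
            is.na(f) || (f >= eaf_ambiguity_band[1] && f <= eaf_ambiguity_band[2])
          }
          if (amb(f_ref) || amb(f_i)) {
            status[i] <- "ambiguous_eaf"
          } else if (!same[i] && !swapped[i]) {
            status[i] <- "incompatible"
          } else {
            # nominal frequency of the reference effect allele; if it falls
            # on the wrong side of 0.5 the row is read on the other strand,
            # which for a palindromic pair swaps the allele labels
            f_nom <- if (same[i]) f_i else 1 - f_i
            flipped <- (f_nom > 0.5) != (f_ref > 0.5)
            negate <- xor(swapped[i], flipped)
            if (negate) d$beta[i] <- -d$beta[i]
            d$eaf[i] <- if (flipped) 1 - f_nom else f_nom
          }
        }
      } else if (same[i]) {
        # nothing to do
      } else if (swapped[i] || flip_swapped[i]) {
        d$beta[i] <- -d$beta[i]
        d$eaf[i] <- 1 - d$eaf[i]
      } else if (flip_same[i]) {
        # other strand, same orientation: effects already aligned
      } else {
        status[i] <- "incompatible"
      }
    }
    list(data = d, status = status)
  }

  aligned <- lapply(traits, align)
  keep <- rep(TRUE, length(shared))
  for (a in aligned) {
    st <- a$status
    drop_log[["palindromic"]] <- drop_log[["palindromic"]] + sum(st == "palindromic" & keep)
    drop_log[["ambiguous_eaf"]] <- drop_log[["ambiguous_eaf"]] + sum(st == "ambiguous_eaf" & keep)
    drop_log[["incompatible"]] <- drop_log[["incompatible"]] + sum(st == "incompatible" & keep)
    keep <- keep & st == "ok"
  }
  if (!any(keep)) {
    abort_empty(sprintf(
      "zero variants survive harmonization (drops: %s)",
      paste(names(drop_log), drop_log, sep = "=", collapse = ", ")
    ))
  }

  ids <- shared[keep]
  exp_aligned <- c(list(list(data = ref, status = rep("ok", length(shared)))),
                   aligned[seq_len(K - 1)])
  beta_X <- vapply(exp_aligned, function(a) a$data$beta[keep], numeric(sum(keep)))
  se_X <- vapply(exp_aligned, function(a) a$data$se[keep], numeric(sum(keep)))
  n_X <- vapply(exp_aligned, function(a) a$data$n[keep], numeric(sum(keep)))
  beta_X <- matrix(beta_X, ncol = K)
  se_X <- matrix(se_X, ncol = K)
  n_X <- matrix(n_X, ncol = K)
  out_al <- aligned[[K]]$data

  structure(list(
    exposure_names = vapply(exposures, trait_label, character(1)),
    outcome_name = trait_label(outcome),
    variant_ids = ids,
    beta_X = beta_X,
    se_X = se_X,
    beta_Y = out_al$beta[keep],
    se_Y = out_al$se[keep],
    eaf = ref$eaf[keep],
    n_X = n_X,
    n_Y = out_al$n[keep],
    binary_X = vapply(exposures, is_binary_trait, logical(1)),
    binary_Y = is_binary_trait(outcome),
    drop_log = drop_log
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "<harmonized_set> %s -> %s, %d variants, %d exposure(s)\n",
    paste(x$exposure_names, collapse = " + "), x$outcome_name,
    length(x$variant_ids), ncol(x$beta_X)
  ))
  invisible(x)
}

#' Number of variants in a harmonized set
#' @param x a `harmonized_set`
#' @export
n_variants <- function(x) length(x$variant_ids)

#' Serialize a harmonized set to a tidy data frame
#'
#' One row per variant; exposure columns are suffixed with the trait label.
#'
#' @param x a `harmonized_set`
#' @return data frame suitable for writing with [utils::write.table()]
#' @export
harmonized_as_data_frame <- function(x) {
  out <- data.frame(variant_id = x$variant_ids, stringsAsFactors = FALSE)
  for (k in seq_along(x$exposure_names)) {
    out[[paste0("beta_", x$exposure_names[k])]] <- x$beta_X[, k]
    out[[paste0("se_", x$exposure_names[k])]] <- x$se_X[, k]
  }
  out[[paste0("beta_", x$outcome_name)]] <- x$beta_Y
  out[[paste0("se_", x$outcome_name)]] <- x$se_Y
  out$eaf <- x$eaf
  out
}

# subset a harmonized set to variant indices/ids (internal)
hs_subset <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$variant_ids)
  x$variant_ids <- x$variant_ids[idx]
  x$beta_X <- x$beta_X[idx, , drop = FALSE]
  x$se_X <- x$se_X[idx, , drop = FALSE]
  x$beta_Y <- x$beta_Y[idx]
  x$se_Y <- x$se_Y[idx]
  x$eaf <- x$eaf[idx]
  x$n_X <- x$n_X[idx, , drop = FALSE]
  x$n_Y <- x$n_Y[idx]
  x
}

# build a harmonized set directly from numeric vectors (internal, used by
# tests and simulations where alleles are already aligned)
hs_from_vectors <- function(beta_X, se_X, beta_Y, se_Y, ids = NULL,
                            exposure_names = NULL, outcome_name = "outcome",
                            binary_Y = FALSE, eaf = NULL, n_X = NULL, n_Y = NULL) {
  beta_X <- as.matrix(beta_X)
  se_X <- as.matrix(se_X)
  K <- ncol(beta_X)
  L <- nrow(beta_X)
  structure(list(
    exposure_names = exposure_names %||% paste0("exposure", seq_len(K)),
    outcome_name = outcome_name,
    variant_ids = ids %||% paste0("rs", seq_len(L)),
    beta_X = beta_X, se_X = se_X,
    beta_Y = as.numeric(beta_Y), se_Y = as.numeric(se_Y),
    eaf = eaf %||% rep(NA_real_, L),
    n_X = if (is.null(n_X)) matrix(NA_real_, L, K) else as.matrix(n_X),
    n_Y = n_Y %||% rep(NA_real_, L),
    binary_X = rep(FALSE, K), binary_Y = binary_Y,
    drop_log = c(not_shared = 0L, palindromic = 0L, ambiguous_eaf = 0L, incompatible = 0L)
  ), class = "harmonized_set")
}
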