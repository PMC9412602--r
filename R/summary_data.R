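# Reading, validating, selecting and harmonising GWAS summary statistics.

GWAS_MANDATORY <- c("snp_id", "effect_allele", "other_allele", "eaf",
                    "beta", "se", "pval")
GWAS_OPTIONAL <- c("chrom", "pos", "n", "gene")

#' Column-name mapping for GWAS summary-statistic tables
#'
#' Builds a dialect (named character vector) translating the column names
#' used by a particular consortium file to the canonical names `snp_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, `n`. Names are canonical, values are the names found in the file.
#'
#' @param ... Named arguments, e.g. `snp_id = "rsid"`, `pval = "P"`.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_summary_table()].
#' @export
#' @examples
#' gwas_dialect(snp_id = "rsid", effect_allele = "A1", other_allele = "A2")
gwas_dialect <- function(...) {
  d <- c(...)
  unknown <- setdiff(names(d), c(GWAS_MANDATORY, GWAS_OPTIONAL))
  if (length(unknown) > 0) {
    abort(sprintf("unknown canonical column(s) in dialect: %s",
                  paste(unknown, collapse = ", ")))
  }
  d
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated summary-statistic file into a validated tibble of
#' per-SNP association records. Alleles are uppercased; rows with a
#' non-positive standard error are rejected and recorded in the selection
#' log rather than silently dropped.
#'
#' P-values below the smallest representable double (e.g. `8.43e-610`)
#' underflow to zero on read; such rows are kept, since a zero p-value
#' passes every significance threshold.
#'
#' @param path Path to a TSV file with a header row. Lines starting with
#'   `#` are treated as comments.
#' @param dialect Optional column-name mapping from [gwas_dialect()] when
#'   the file does not use the canonical column names.
#' @param trait Optional trait label stored in the `trait` column.
#' @return A tibble with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval` (plus `chrom`, `pos`, `n`, `gene`, `trait`
#'   when available), one row per retained SNP, with a `selection_log`
#'   attribute listing rejected rows.
#' @export
read_summary_table <- function(path, dialect = NULL, trait = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        abort(sprintf("dialect maps `%s` to `%s`, which is not a column of %s",
                      canon, src, path))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  assert_cols(raw, GWAS_MANDATORY, sprintf("summary table %s", path))

  numeric_cols <- intersect(c("eaf", "beta", "se", "pval", "pos", "n"), names(raw))
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad) > 0) {
      abort(sprintf(
        "unparsable numeric value '%s' in column `%s` of %s (data row %d)",
        raw[[col]][bad[1]], col, path, bad[1]))
    }
    raw[[col]] <- parsed
  }

  out <- dplyr::mutate(raw,
    effect_allele = toupper(.data$effect_allele),
    other_allele = toupper(.data$other_allele))
  if (!is.null(trait)) out$trait <- trait

  log <- new_selection_log()
  bad_se <- !is.na(out$se) & out$se <= 0 | is.na(out$se)
  if (any(bad_se)) {
    for (i in which(bad_se)) {
      log <- log_removal(log, out$snp_id[i], "non_positive_se",
                         sprintf("se = %s", format(out$se[i])))
    }
    out <- out[!bad_se, , drop = FALSE]
  }
  validate_gwas(out)
  set_selection_log(tibble::as_tibble(out), log)
}

# invariant checks shared by the reader and the simulator round-trip
validate_gwas <- function(data) {
  assert_cols(data, GWAS_MANDATORY, "GWAS record table")
  if (any(data$se <= 0)) abort("all standard errors must be positive")
  if (any(data$eaf < 0 | data$eaf > 1, na.rm = TRUE)) {
    abort("effect-allele frequencies must lie in [0, 1]")
  }
  same <- data$effect_allele == data$other_allele
  if (any(same)) {
    abort(sprintf("effect and other allele identical for %s",
                  paste(data$snp_id[same], collapse = ", ")))
  }
  if (anyDuplicated(data$snp_id)) {
    abort(sprintf("duplicate snp_id in trait table: %s",
                  paste(unique(data$snp_id[duplicated(data$snp_id)]),
                        collapse = ", ")))
  }
  invisible(data)
}

#' Select genome-wide significant instruments
#'
#' Keeps the records whose association p-value is strictly below the
#' significance threshold, preserving the input order.
#'
#' @param data A summary-statistic tibble (see [read_summary_table()]).
#' @param p_threshold Significance level; the conventional genome-wide
#'   threshold 5e-8 by default.
#' @return The subset of `data` with `pval < p_threshold`; removed rows are
#'   appended to the selection log.
#' @export
select_instruments <- function(data, p_threshold = 5e-8) {
  assert_scalar_prob(p_threshold, "p_threshold", open_right = FALSE)
  assert_cols(data, c("snp_id", "pval"))
  keep <- data$pval < p_threshold
  log <- selection_log(data)
  for (i in which(!keep)) {
    log <- log_removal(log, data$snp_id[i], "p_threshold",
                       sprintf("pval %.3g >= %.3g", data$pval[i], p_threshold))
  }
  set_selection_log(data[keep, , drop = FALSE], log)
}

#' Read a pairwise LD r-squared matrix
#'
#' Accepts either a three-column TSV (`snp_a`, `snp_b`, `r2`) of pairwise
#' values, or a square matrix with rsID row/column headers. Pairs absent
#' from the long format are treated as unlinked (r-squared 0).
#'
#' @param path Path to the TSV file.
#' @return A symmetric numeric matrix with unit diagonal, rsID dimnames.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    for (i in seq_len(nrow(raw))) {
      m[raw$snp_a[i], raw$snp_b[i]] <- raw$r2[i]
      m[raw$snp_b[i], raw$snp_a[i]] <- raw$r2[i]
    }
    return(m)
  }
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

validate_ld_matrix <- function(r2_matrix) {
  if (!is.matrix(r2_matrix) || nrow(r2_matrix) != ncol(r2_matrix)) {
    abort("LD matrix must be square")
  }
  if (max(abs(r2_matrix - t(r2_matrix))) > 1e-8) {
    abort("LD matrix must be symmetric")
  }
  if (any(r2_matrix < -1e-12 | r2_matrix > 1 + 1e-12)) {
    abort("LD r-squared entries must lie in [0, 1]")
  }
  if (max(abs(diag(r2_matrix) - 1)) > 1e-8) {
    abort("LD matrix diagonal must be 1")
  }
  invisible(r2_matrix)
}

# r2 between two rsIDs, 0 (logged by callers) when a pair is absent
ld_r2 <- function(r2_matrix, a, b) {
  if (a %in% rownames(r2_matrix) && b %in% colnames(r2_matrix)) {
    r2_matrix[a, b]
  } else {
    NA_real_
  }
}

#' Greedy LD pruning of candidate instruments
#'
#' Standard clumping: candidates are visited in ascending p-value order and
#' a SNP is dropped when its r-squared with any already-kept SNP reaches
#' the threshold. SNP pairs missing from the matrix are treated as unlinked
#' and noted in the selection log.
#'
#' @param data A summary-statistic tibble.
#' @param r2_matrix Symmetric LD r-squared matrix (see [read_ld_matrix()]).
#' @param r2_threshold Pruning bound; a pair with `r2 >= r2_threshold` is
#'   considered linked. Default 0.01.
#' @return The pruned tibble in the original row order, selection log
#'   extended with every dropped SNP.
#' @export
ld_prune <- function(data, r2_matrix, r2_threshold = 0.01) {
  assert_cols(data, c("snp_id", "pval"))
  validate_ld_matrix(r2_matrix)
  log <- selection_log(data)
  visit <- order(data$pval)
  kept <- character(0)
  drop <- rep(FALSE, nrow(data))
  for (i in visit) {
    id <- data$snp_id[i]
    linked <- FALSE
    for (k in kept) {
      r2 <- ld_r2(r2_matrix, id, k)
      if (is.na(r2)) {
        log <- log_removal(log, id, "ld_pair_missing",
                           sprintf("no r2 entry for (%s, %s); assumed 0", id, k))
        r2 <- 0
      }
      if (r2 >= r2_threshold) {
        linked <- TRUE
        log <- log_removal(log, id, "ld_prune",
                           sprintf("r2 = %.3g with kept SNP %s", r2, k))
        break
      }
    }
    if (linked) drop[i] <- TRUE else kept <- c(kept, id)
  }
  set_selection_log(data[!drop, , drop = FALSE], log)
}

#' Find a proxy SNP in the outcome dataset
#'
#' When an exposure instrument is absent from the outcome GWAS, the most
#' strongly correlated outcome SNP with `r2 > r2_min` can stand in for it.
#' Ties on r-squared are broken by smaller association p-value, then by
#' lexicographic rsID.
#'
#' @param target rsID missing from the outcome table.
#' @param outcome_data Outcome summary-statistic tibble.
#' @param r2_matrix LD r-squared matrix covering the target and candidates.
#' @param r2_min Minimum (strict) r-squared for an acceptable proxy;
#'   default 0.8.
#' @return A one-row tibble (the chosen outcome record, plus its `r2` with
#'   the target), or `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(target, outcome_data, r2_matrix, r2_min = 0.8) {
  assert_cols(outcome_data, c("snp_id", "pval"))
  if (target %in% outcome_data$snp_id) {
    abort(sprintf("`%s` is present in the outcome data; no proxy needed", target))
  }
  r2 <- vapply(outcome_data$snp_id, function(id) {
    v <- ld_r2(r2_matrix, target, id)
    if (is.na(v)) 0 else v
  }, numeric(1))
  ok <- which(r2 > r2_min)
  if (length(ok) == 0) return(NULL)
  cand <- outcome_data[ok, , drop = FALSE]
  cand$r2 <- unname(r2[ok])
  ord <- order(-cand$r2, cand$pval, cand$snp_id)
  cand[ord[1], , drop = FALSE]
}

#' Is a variant palindromic?
#'
#' A biallelic SNP is palindromic when its two alleles are strand
#' complements of one another ({A,T} or {C,G}), so the strand cannot be
#' resolved from the alleles alone. Indels (multi-base alleles) are never
#' palindromic.
#'
#' @param effect_allele,other_allele Character vectors of alleles.
#' @return Logical vector.
#' @export
#' @examples
#' is_palindromic(c("A", "A", "C"), c("T", "G", "G"))
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  single <- nchar(ea) == 1 & nchar(oa) == 1
  pal <- (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
  pal & single
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  chars <- strsplit(a, "")[[1]]
  if (!all(chars %in% names(COMPLEMENT))) return(NA_character_)
  paste(rev(COMPLEMENT[chars]), collapse = "")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared SNP to the exposure's
#' effect allele: matching alleles are copied, swapped alleles flip the
#' sign of the outcome beta and mirror its allele frequency, and alleles
#' reported on the opposite strand are complemented before the same rules
#' apply. Palindromic SNPs (whose strand cannot be inferred from alleles)
#' are removed when `drop_palindromic` is `TRUE`; allele sets that cannot
#' be reconciled are removed and logged. Instruments missing from the
#' outcome table can be replaced by LD proxies when an r-squared matrix is
#' supplied.
#'
#' @param exposure,outcome Summary-statistic tibbles
#'   (see [read_summary_table()]).
#' @param drop_palindromic Remove palindromic SNPs (default `TRUE`).
#' @param r2_matrix Optional LD matrix enabling proxy substitution for
#'   instruments absent from `outcome`.
#' @param proxy_r2 Minimum r-squared for a proxy (strict; default 0.8).
#' @param f_method F-statistic estimator passed to [f_statistic()].
#' @param exposure_name Trait label recorded in the result.
#' @return A tibble of harmonised instruments with columns `snp_id`,
#'   `beta_x`, `se_x`, `pval_x`, `beta_y`, `se_y`, `pval_y`, `eaf_x`,
#'   `eaf_y`, `f_stat`, `proxy_of`, plus an `exposure` column, carrying a
#'   `selection_log` attribute.
#' @export
harmonise <- function(exposure, outcome, drop_palindromic = TRUE,
                      r2_matrix = NULL, proxy_r2 = 0.8,
                      f_method = c("ratio", "r2"),
                      exposure_name = NULL) {
  f_method <- match.arg(f_method)
  assert_cols(exposure, GWAS_MANDATORY, "exposure")
  assert_cols(outcome, GWAS_MANDATORY, "outcome")
  exposure_name <- exposure_name %||% attr(exposure, "trait") %||%
    (if ("trait" %in% names(exposure)) exposure$trait[1] else "exposure")

  log <- selection_log(exposure)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    proxy_of <- ""
    if (ex$snp_id %in% outcome$snp_id) {
      out <- outcome[outcome$snp_id == ex$snp_id, ][1, ]
    } else if (!is.null(r2_matrix)) {
      out <- find_proxy(ex$snp_id, outcome, r2_matrix, r2_min = proxy_r2)
      if (is.null(out)) {
        log <- log_removal(log, ex$snp_id, "no_outcome_record",
                           "absent from outcome data; no proxy above threshold")
        next
      }
      proxy_of <- ex$snp_id
      log <- log_removal(log, ex$snp_id, "proxy_substituted",
                         sprintf("replaced by %s (r2 = %.3g)", out$snp_id, out$r2))
    } else {
      log <- log_removal(log, ex$snp_id, "no_outcome_record",
                         "absent from outcome data")
      next
    }

    h <- harmonise_pair(ex, out, drop_palindromic = drop_palindromic)
    if (is.character(h)) {
      log <- log_removal(log, ex$snp_id, h$rule %||% h, attr(h, "detail") %||% "")
      next
    }
    if (is.null(h)) next
    if (!is.null(attr(h, "drop_rule"))) {
      log <- log_removal(log, ex$snp_id, attr(h, "drop_rule"),
                         attr(h, "drop_detail"))
      next
    }
    h$proxy_of <- proxy_of
    rows[[i]] <- h
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble::tibble(snp_id = character(), beta_x = numeric(),
                          se_x = numeric(), pval_x = numeric(),
                          beta_y = numeric(), se_y = numeric(),
                          pval_y = numeric(), eaf_x = numeric(),
                          eaf_y = numeric(), f_stat = numeric(),
                          proxy_of = character())
  }
  res$f_stat <- f_statistic(res$beta_x, res$se_x,
                            eaf = res$eaf_x,
                            n = if ("n" %in% names(exposure)) {
                              exposure$n[match(ifelse(res$proxy_of == "",
                                                      res$snp_id, res$proxy_of),
                                               exposure$snp_id)]
                            } else NULL,
                            method = f_method)
  res$exposure <- exposure_name
  set_selection_log(res, log)
}

# Align one exposure/outcome record pair. Returns a one-row tibble, with a
# drop_rule attribute when the SNP must be removed.
harmonise_pair <- function(ex, out, drop_palindromic = TRUE) {
  base <- tibble::tibble(
    snp_id = out$snp_id,
    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval,
    beta_y = out$beta, se_y = out$se, pval_y = out$pval,
    eaf_x = ex$eaf, eaf_y = out$eaf,
    f_stat = NA_real_, proxy_of = "")

  if (is_palindromic(ex$effect_allele, ex$other_allele) && drop_palindromic) {
    attr(base, "drop_rule") <- "palindromic"
    attr(base, "drop_detail") <- sprintf("%s/%s", ex$effect_allele, ex$other_allele)
    return(base)
  }

  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(out$effect_allele); oa_y <- toupper(out$other_allele)

  aligned <- function(b) b
  swapped <- function(b) {
    b$beta_y <- -b$beta_y
    b$eaf_y <- 1 - b$eaf_y
    b
  }
  if (ea_y == ea_x && oa_y == oa_x) return(aligned(base))
  if (ea_y == oa_x && oa_y == ea_x) return(swapped(base))

  # strand flip: complement the outcome alleles, then apply the same rules
  cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
  if (!is.na(cea) && !is.na(coa)) {
    if (cea == ea_x && coa == oa_x) return(aligned(base))
    if (cea == oa_x && coa == ea_x) return(swapped(base))
  }
  attr(base, "drop_rule") <- "incompatible_alleles"
  attr(base, "drop_detail") <- sprintf("exposure %s/%s vs outcome %s/%s",
                                       ea_x, oa_x, ea_y, oa_y)
  base
}

#' Instrument-strength F statistic
#'
#' The default estimator is the square of the standardised effect,
#' `F = (beta/se)^2`, the usual approximation when only summary statistics
#' are available. The alternative `"r2"` estimator uses the variance
#' explained, `R2 = 2 * eaf * (1 - eaf) * beta^2`, with
#' `F = R2 * (n - 2) / (1 - R2)`; it requires `eaf` and `n`.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param eaf,n Effect-allele frequency and sample size (only for
#'   `method = "r2"`).
#' @param method `"ratio"` (default) or `"r2"`.
#' @return Numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(-0.055, 0.007)
f_statistic <- function(beta, se, eaf = NULL, n = NULL,
                        method = c("ratio", "r2")) {
  method <- match.arg(method)
  if (any(se <= 0)) abort("standard errors must be positive")
  if (method == "ratio") {
    return((beta / se)^2)
  }
  if (is.null(eaf) || is.null(n)) {
    abort("`eaf` and `n` are required for the r2-based F statistic")
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  r2 * (n - 2) / (1 - r2)
}

#' Remove weak instruments
#'
#' Drops harmonised instruments whose F statistic falls below the
#' conventional weak-instrument bound (10 by default), logging each
#' removal. An empty result raises a warning, not an error.
#'
#' @param data Harmonised instrument tibble (see [harmonise()]).
#' @param f_min Minimum F statistic retained.
#' @return Filtered tibble with the selection log extended.
#' @export
filter_weak <- function(data, f_min = 10) {
  assert_cols(data, c("snp_id", "f_stat"))
  log <- selection_log(data)
  weak <- data$f_stat < f_min
  for (i in which(weak)) {
    log <- log_removal(log, data$snp_id[i], "weak_instrument",
                       sprintf("F = %.3g < %.3g", data$f_stat[i], f_min))
  }
  out <- data[!weak, , drop = FALSE]
  if (nrow(out) == 0) warn("no instruments remain after the F-statistic filter")
  set_selection_log(out, log)
}
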