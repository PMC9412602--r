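# Synthetic two-sample GWAS summary statistics with known ground truth.

#' Define a synthetic two-sample summary-statistic scenario
#'
#' A scenario fixes the generative model for two-sample MR summary data:
#' per-SNP exposure effects are drawn half-normal — positive, in the
#' oriented convention of harmonised data where the effect allele is the
#' exposure-increasing one, and truncated away from zero so no instrument
#' is degenerate. The latent SNP-outcome
#' effect is `gamma_j = sum_k theta_k * beta_xjk + alpha_j`, where the
#' pleiotropic term `alpha_j` is zero for valid instruments, and the
#' observed effects add normal measurement error with the stated standard
#' errors. Defaults describe a well-powered null study with strong
#' instruments and no pleiotropy; see the methods vignette for the
#' rationale behind each value.
#'
#' @param n_snp Number of instruments J (default 20).
#' @param k_factors Number of exposures K (default 1).
#' @param theta_true True causal effect per exposure (recycled to K;
#'   default 0, the null).
#' @param beta_x_scale SD of the latent SNP-exposure effects (default
#'   0.15 SD of exposure per allele, the scale of the stronger iron-status
#'   loci).
#' @param se_x,se_y Measurement SEs of the exposure and outcome effects
#'   (scalars or per-SNP vectors; defaults 0.01, giving F well above the
#'   weak-instrument bound).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct
#'   effects) or `"directional"` (shared-sign direct effects).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the pleiotropic
#'   effect `alpha` for invalid instruments (defaults 0.05 and 0.01; the
#'   mean applies to the directional mode only).
#' @param invalid_fraction Fraction of instruments given pleiotropy when
#'   the mode is not `"none"` (default 0.3).
#' @param eaf_range Range of simulated effect-allele frequencies
#'   (default 0.05-0.95).
#' @param allow_palindromic Whether palindromic allele pairs may be drawn
#'   (default `FALSE`; enable to exercise the palindrome filter).
#' @param seed RNG seed (mandatory).
#' @return An object of class `mr_scenario`.
#' @export
mr_scenario <- function(n_snp = 20, k_factors = 1, theta_true = 0,
                        beta_x_scale = 0.15, se_x = 0.01, se_y = 0.01,
                        pleiotropy_mode = c("none", "balanced", "directional"),
                        pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                        invalid_fraction = 0.3,
                        eaf_range = c(0.05, 0.95),
                        allow_palindromic = FALSE, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (n_snp < 1 || k_factors < 1) abort("`n_snp` and `k_factors` must be positive")
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    abort("`invalid_fraction` must lie in [0, 1]")
  }
  if (any(se_x <= 0) || any(se_y <= 0)) abort("all SEs must be positive")
  if (beta_x_scale <= 0) abort("`beta_x_scale` must be positive")
  theta_true <- rep_len(theta_true, k_factors)
  structure(list(n_snp = n_snp, k_factors = k_factors,
                 theta_true = theta_true, beta_x_scale = beta_x_scale,
                 se_x = se_x, se_y = se_y,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 eaf_range = eaf_range,
                 allow_palindromic = allow_palindromic, seed = seed),
            class = "mr_scenario")
}

#' @export
print.mr_scenario <- function(x, ...) {
  cat(sprintf(
    "<mr_scenario: J = %d, K = %d, theta = (%s), pleiotropy %s, seed %s>\n",
    x$n_snp, x$k_factors, paste(x$theta_true, collapse = ", "),
    x$pleiotropy_mode, format(x$seed)))
  invisible(x)
}

# non-palindromic allele pairs (plus palindromic ones when allowed)
ALLELE_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                     c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# latent draws shared by both emitters
draw_latents <- function(sc) {
  j <- sc$n_snp; k <- sc$k_factors
  # effects are emitted in the oriented convention (effect allele =
  # exposure-increasing allele), i.e. positive, as after harmonisation;
  # truncation away from zero avoids weak-instrument degeneracy
  beta_x <- abs(matrix(rnorm(j * k, 0, sc$beta_x_scale), j, k))
  small <- beta_x < 0.5 * sc$beta_x_scale
  while (any(small)) {
    beta_x[small] <- abs(rnorm(sum(small), 0, sc$beta_x_scale))
    small <- beta_x < 0.5 * sc$beta_x_scale
  }
  alpha <- rep(0, j)
  invalid <- rep(FALSE, j)
  if (sc$pleiotropy_mode != "none" && sc$invalid_fraction > 0) {
    n_invalid <- round(sc$invalid_fraction * j)
    invalid[sample.int(j, n_invalid)] <- TRUE
    mu <- if (sc$pleiotropy_mode == "directional") sc$pleiotropy_mean else 0
    alpha[invalid] <- rnorm(sum(invalid), mu, sc$pleiotropy_sd)
  }
  gamma <- drop(beta_x %*% sc$theta_true) + alpha
  se_x <- rep_len(sc$se_x, j)
  se_y <- rep_len(sc$se_y, j)
  pairs <- if (sc$allow_palindromic) c(ALLELE_PAIRS, PALINDROMIC_PAIRS) else ALLELE_PAIRS
  alleles <- pairs[sample.int(length(pairs), j, replace = TRUE)]
  list(snp_id = sprintf("snp%04d", seq_len(j)),
       beta_x = beta_x, gamma = gamma, alpha = alpha, invalid = invalid,
       se_x = se_x, se_y = se_y,
       obs_x = beta_x + matrix(rnorm(j * k), j, k) * se_x,
       obs_y = gamma + rnorm(j) * se_y,
       eaf = runif(j, sc$eaf_range[1], sc$eaf_range[2]),
       ea = vapply(alleles, `[[`, character(1), 1),
       oa = vapply(alleles, `[[`, character(1), 2))
}

#' Simulate two-sample GWAS summary tables
#'
#' Draws one exposure summary table per risk factor and one outcome table
#' in the same dialect that [read_summary_table()] reads, together with a
#' truth record holding every latent quantity. Identical seeds give
#' bit-identical tables.
#'
#' @param scenario An [mr_scenario()].
#' @return A list with elements `exposures` (named list of tibbles),
#'   `outcome` (tibble) and `truth` (list: `theta_true`, latent `beta_x`,
#'   `gamma`, `alpha`, `invalid`, `scenario`).
#' @export
#' @examples
#' sim <- simulate_summary_stats(mr_scenario(n_snp = 10, seed = 1))
#' sim$exposures[[1]]
simulate_summary_stats <- function(scenario) {
  stopifnot(inherits(scenario, "mr_scenario"))
  lat <- withr::with_seed(scenario$seed, draw_latents(scenario))
  j <- scenario$n_snp
  base <- tibble::tibble(
    snp_id = lat$snp_id,
    chrom = "1",
    pos = seq_len(j) * 1000L,
    effect_allele = lat$ea,
    other_allele = lat$oa,
    eaf = lat$eaf)
  exposures <- lapply(seq_len(scenario$k_factors), function(k) {
    out <- base
    out$beta <- lat$obs_x[, k]
    out$se <- lat$se_x
    out$pval <- z_pvalue(out$beta, out$se)
    out$n <- 50000L
    out
  })
  names(exposures) <- paste0("exposure_", seq_len(scenario$k_factors))
  outcome <- base
  outcome$beta <- lat$obs_y
  outcome$se <- lat$se_y
  outcome$pval <- z_pvalue(outcome$beta, outcome$se)
  outcome$n <- 50000L
  list(exposures = exposures, outcome = outcome,
       truth = list(theta_true = scenario$theta_true,
                    beta_x = lat$beta_x, gamma = lat$gamma,
                    alpha = lat$alpha, invalid = lat$invalid,
                    scenario = scenario))
}

#' Simulate an already-harmonised instrument set
#'
#' Shortcut for simulation studies: the same generative draw as
#' [simulate_summary_stats()] emitted directly as a harmonised instrument
#' tibble (first exposure when K > 1), skipping the table round trip.
#'
#' @inheritParams simulate_summary_stats
#' @param factor Which exposure column to pair with the outcome
#'   (default 1).
#' @return A harmonised instrument tibble with a `truth` attribute.
#' @export
simulate_instruments <- function(scenario, factor = 1) {
  stopifnot(inherits(scenario, "mr_scenario"))
  lat <- withr::with_seed(scenario$seed, draw_latents(scenario))
  out <- tibble::tibble(
    snp_id = lat$snp_id,
    beta_x = lat$obs_x[, factor],
    se_x = lat$se_x,
    pval_x = z_pvalue(lat$obs_x[, factor], lat$se_x),
    beta_y = lat$obs_y,
    se_y = lat$se_y,
    pval_y = z_pvalue(lat$obs_y, lat$se_y),
    eaf_x = lat$eaf, eaf_y = lat$eaf,
    f_stat = (lat$obs_x[, factor] / lat$se_x)^2,
    proxy_of = "",
    exposure = paste0("exposure_", factor))
  attr(out, "truth") <- list(theta_true = scenario$theta_true,
                             beta_x = lat$beta_x, gamma = lat$gamma,
                             alpha = lat$alpha, invalid = lat$invalid)
  out
}

#' Write simulated summary tables to disk
#'
#' Emits the exposure and outcome tibbles as TSVs in the dialect
#' [read_summary_table()] reads, and the truth record as JSON.
#'
#' @param sim Result of [simulate_summary_stats()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_summary_stats <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(sim$exposures)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(sim$exposures[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "outcome.tsv")
  readr::write_tsv(sim$outcome, p)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$beta_x <- as.data.frame(truth$beta_x)
  truth$scenario <- unclass(truth$scenario)
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}
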